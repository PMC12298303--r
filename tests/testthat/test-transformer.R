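# Architecture contracts, gradient correctness and training behavior of the
# transformer decomposer.

test_that("tonic pooling branch: constants, kernels, ramps, linearity", {
  expect_equal(scl_branch(rep(1.5, 1440), 481), rep(1.5, 1440))

  # the three SCL granularities at 8 Hz
  expect_identical(pool_kernel_for(60), 481L)
  expect_identical(pool_kernel_for(30), 241L)
  expect_identical(pool_kernel_for(1), 9L)

  # brute-force window-averaging oracle on a 100-sample ramp
  x <- seq(0, 1, length.out = 100)
  k <- 11L; h <- 5L
  got <- scl_branch(x, k)
  xp <- c(rep(x[1], h), x, rep(x[100], h))
  oracle <- vapply(1:100, function(i) mean(xp[i:(i + k - 1)]), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  # interior of a ramp is reproduced exactly
  expect_equal(got[(h + 1):(100 - h)], x[(h + 1):(100 - h)],
               tolerance = 1e-12)

  # linearity: scl(a x + b) = a scl(x) + b
  y <- stats::rnorm(200)
  expect_equal(scl_branch(3 * y + 2, 21), 3 * scl_branch(y, 21) + 2,
               tolerance = 1e-10)

  expect_error(scl_branch(x, 10), "odd")
  expect_error(scl_branch(x, 201), "exceeds")

  # max pooling dominates average pooling
  expect_true(all(scl_branch(y, 21, pooling = "max") >=
                    scl_branch(y, 21) - 1e-12))
})

test_that("model configuration validates the architecture contract", {
  cfg <- model_config()
  expect_equal(cfg$n_encoder, 1L)
  expect_equal(cfg$n_decoder, 2L)
  expect_equal(cfg$embed_dim, 32L)
  expect_equal(cfg$ff_dim, 16L)
  expect_equal(cfg$n_heads, 4L)
  expect_equal(cfg$pool_kernel, 481L)

  expect_error(model_config(embed_dim = 32, n_heads = 3), "divisible")
  expect_error(model_config(pool_kernel = 480), "odd")
  expect_error(model_config(pool_kernel = 2001, frame_len = 1440),
               "exceed")
})

test_that("building is deterministic and counts parameters consistently", {
  a <- feel_transformer(model_config(), seed = 7)
  b <- feel_transformer(model_config(), seed = 7)
  expect_identical(a$params, b$params)
  expect_identical(n_params(a), n_params(b))
  expect_gt(n_params(a), 1e4)   # CPU-scale network
  c <- feel_transformer(model_config(), seed = 8)
  expect_false(identical(a$params, c$params))
})

test_that("forward pass honors the shape and additivity contracts", {
  cfg <- tiny_model_config()
  m <- feel_transformer(cfg, seed = 1)
  sf <- synthesize_frame(tiny_sim_config(seed = 5))
  dec <- predict(m, sf$frame)
  expect_s3_class(dec, "eda_decomposition")
  expect_length(dec$phasic, 128)
  expect_equal(dec$tonic + dec$phasic, attr(dec, "reconstruction"),
               tolerance = 1e-12)
  # wrong length is rejected
  expect_error(predict(m, eda_frame(rep(1, 64), rate = 8)), "frame_len")
})

test_that("untrained model has a zero phasic and a pooled reconstruction", {
  m <- feel_transformer(tiny_model_config(), seed = 2)
  sf <- synthesize_frame(tiny_sim_config(seed = 9))
  dec <- predict(m, sf$frame)
  expect_identical(dec$phasic, numeric(128))
  expect_equal(attr(dec, "reconstruction"),
               scl_branch(sf$frame$samples, 33), tolerance = 1e-12)
})

test_that("the tonic branch is independent of the learned weights", {
  cfg <- tiny_model_config()
  m1 <- feel_transformer(cfg, seed = 1)
  m2 <- feel_transformer(cfg, seed = 99)
  m2$params$proj_W[] <- stats::rnorm(length(m2$params$proj_W))
  sf <- synthesize_frame(tiny_sim_config(seed = 3))
  d1 <- predict(m1, sf$frame)
  d2 <- predict(m2, sf$frame)
  expect_identical(d1$tonic, d2$tonic)
  expect_false(identical(d1$phasic, d2$phasic))
})

test_that("backpropagation matches finite differences everywhere", {
  cfg <- model_config(embed_dim = 4, ff_dim = 3, n_heads = 2,
                      pool_kernel = 9, frame_len = 32, decomp_kernel = 5)
  m <- feel_transformer(cfg, seed = 3)
  set.seed(9)
  m$params$proj_W <- matrix(stats::rnorm(4, sd = 0.3), 4, 1)
  m$params$proj_b <- 0.1
  x <- matrix(stats::rnorm(2 * 32, mean = 1.5, sd = 0.2), 2, 32)
  loss_fn <- function(mm)
    mean((x - edadecomp:::ft_forward(mm, x)$reconstruction)^2)
  fw <- edadecomp:::ft_forward(m, x, keep_cache = TRUE)
  grads <- edadecomp:::ft_backward(m, fw$cache,
                                   2 * (fw$reconstruction - x) / length(x))
  eps <- 1e-6
  set.seed(41)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm2 <- m; mm2$params[[nm]][i] <- p[i] - eps
      num <- (loss_fn(mp) - loss_fn(mm2)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_equal(ana, num, tolerance = 1e-3 + 1e-10,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training reduces validation loss, deterministically", {
  sfs <- synthesize_frames(40, tiny_sim_config(seed = 31))
  cfg <- tiny_model_config(standardize = TRUE)
  m <- feel_transformer(cfg, seed = 1)
  ctl <- train_config(max_epochs = 20, batch_size = 8, patience = 20,
                      weight_decay = 0, val_fraction = 0.2, seed = 5)
  fit <- ft_train(m, sfs, ctl)
  h <- fit$history
  expect_true(all(h$val_loss >= 0))
  expect_true(all(stats::na.omit(h$train_loss) >= 0))
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])

  fit2 <- ft_train(feel_transformer(cfg, seed = 1), sfs, ctl)
  expect_identical(fit$history, fit2$history)

  expect_error(ft_train(m, list(), ctl), "non-empty")
  expect_error(ft_train(m, sfs[1], ctl), "at least 2")
})

test_that("checkpoints round-trip through save and load", {
  m <- feel_transformer(tiny_model_config(), seed = 4)
  path <- tempfile(fileext = ".rds")
  ft_save(m, path)
  back <- ft_load(path)
  expect_identical(back$params, m$params)
  expect_identical(unclass(back$config), unclass(m$config))
})

test_that("hyperparameter search returns a grid member minimizing loss", {
  full <- hyper_grid()
  expect_equal(nrow(full$grid), 48)

  sfs <- synthesize_frames(10, tiny_sim_config(seed = 77))
  ctl <- train_config(max_epochs = 2, batch_size = 8, seed = 3)
  base <- tiny_model_config()

  single <- hyper_grid(embed_choices = 8, ff_choices = 4, head_choices = 2)
  best <- hyperparameter_search(sfs, single, ctl, base)
  expect_equal(best$embed_dim, 8L)
  expect_equal(best$ff_dim, 4L)
  expect_equal(best$n_heads, 2L)

  small <- hyper_grid(embed_choices = c(4, 8), ff_choices = 4,
                      head_choices = 2)
  best2 <- hyperparameter_search(sfs, small, ctl, base)
  expect_true(best2$embed_dim %in% c(4L, 8L))
  res <- attr(best2, "search")
  expect_equal(nrow(res), 2)
  expect_equal(best2$embed_dim,
               res$embed_dim[which.min(res$val_loss)])
})
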