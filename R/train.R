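#' Training configuration
#'
#' Unsupervised training minimizes the mean squared error between each frame
#' and its reconstruction (pooled tonic + learned phasic) with Adam at
#' learning rate 0.001 and weight decay 0.1. Loop details the architecture
#' does not pin down -- batch size 32, up to 100 epochs, early-stopping
#' patience 10, a 90/10 train/validation split -- are package defaults,
#' documented here and freely configurable.
#'
#' @param lr Learning rate (default 0.001).
#' @param weight_decay L2 weight decay added to the gradient, Adam-coupled
#'   (default 0.1).
#' @param batch_size Frames per gradient step (default 32).
#' @param max_epochs Epoch cap (default 100).
#' @param patience Epochs without validation improvement before stopping
#'   (default 10).
#' @param val_fraction Fraction of frames held out for validation
#'   (default 0.1).
#' @param seed Seed driving the split, the batch order and (via the model
#'   builder) initialization (default 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, weight_decay = 0.1, batch_size = 32,
                         max_epochs = 100, patience = 10,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

frames_to_matrix <- function(frames) {
  if (is.matrix(frames)) return(frames)
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of frames or a matrix",
         call. = FALSE)
  rows <- lapply(frames, function(f) {
    if (inherits(f, "synthetic_frame")) f$frame$samples
    else if (inherits(f, "eda_frame")) f$samples
    else as.numeric(f)
  })
  ns <- vapply(rows, length, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all frames must have the same length", call. = FALSE)
  do.call(rbind, rows)
}

ft_loss <- function(model, x) {
  fw <- ft_forward(model, x)
  mean((x - fw$reconstruction)^2)
}

#' Train the transformer decomposer
#'
#' Seeded, early-stopped minimization of the reconstruction MSE. Each epoch
#' shuffles the training frames (deterministically from the seed), takes
#' Adam steps over mini-batches with full backpropagation through the
#' attention, decomposition and normalization layers, then scores the
#' held-out validation frames; the best-validation parameters are restored
#' at the end. Epoch 0 of the history records the validation loss of the
#' untrained model.
#'
#' @param model A `feel_transformer` (see [feel_transformer]).
#' @param frames List of [eda_frame] / `synthetic_frame` objects (at least
#'   2, so a train/validation split exists), or a numeric matrix with one
#'   frame per row.
#' @param control A [train_config].
#' @return An object of class `ft_fit`: list with `model` (trained), and
#'   `history` (data frame of epoch, train_loss, val_loss).
#' @export
ft_train <- function(model, frames, control = train_config()) {
  stopifnot(inherits(model, "feel_transformer"),
            inherits(control, "train_config"))
  x <- frames_to_matrix(frames)
  n <- nrow(x)
  if (n < 2L)
    stop("need at least 2 frames for a train/validation split",
         call. = FALSE)
  n_val <- max(1L, round(control$val_fraction * n))
  perm <- with_sim_seed(control$seed, 101L, sample.int(n))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  if (length(tr_idx) == 0L) { tr_idx <- val_idx }
  x_tr <- x[tr_idx, , drop = FALSE]
  x_val <- x[val_idx, , drop = FALSE]

  par <- model$params
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  step <- 0L
  lr <- control$lr; wd <- control$weight_decay
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  val0 <- ft_loss(model, x_val)
  history <- data.frame(epoch = 0L, train_loss = NA_real_, val_loss = val0)
  best_val <- val0
  best_par <- par
  stall <- 0L

  n_tr <- nrow(x_tr)
  for (epoch in seq_len(control$max_epochs)) {
    ord <- with_sim_seed(control$seed, 1000L + epoch, sample.int(n_tr))
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n_tr, by = control$batch_size)) {
      idx <- ord[start:min(n_tr, start + control$batch_size - 1L)]
      xb <- x_tr[idx, , drop = FALSE]
      model$params <- par
      fw <- ft_forward(model, xb, keep_cache = TRUE)
      resid <- fw$reconstruction - xb
      loss <- mean(resid^2)
      ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
      dphasic <- 2 * resid / length(resid)
      grads <- ft_backward(model, fw$cache, dphasic)
      step <- step + 1L
      bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
      for (nm in names(par)) {
        gk <- grads[[nm]]
        if (is.null(gk)) next
        if (wd > 0) gk <- gk + wd * par[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gk
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gk * gk
        par[[nm]] <- par[[nm]] -
          lr * (mom[[nm]] / bc1) / (sqrt(vel[[nm]] / bc2) + eps)
      }
    }
    model$params <- par
    val_loss <- ft_loss(model, x_val)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                val_loss = val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_par <- par
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  model$params <- best_par
  model$trained <- TRUE
  structure(list(model = model, history = history, best_val = best_val,
                 control = control),
            class = "ft_fit")
}

#' @export
print.ft_fit <- function(x, ...) {
  cat(sprintf("<ft_fit> %d epochs, best validation MSE %.6g\n",
              max(x$history$epoch), x$best_val))
  invisible(x)
}

#' Hyperparameter grid
#'
#' The architecture search space: 4 embedding sizes x 3 feed-forward widths
#' x 4 head counts = 48 configurations. Combinations whose embedding is not
#' divisible by the head count are enumerated but skipped during search.
#'
#' @param embed_choices Embedding dimensions (default 8, 16, 32, 64).
#' @param ff_choices Feed-forward widths (default 4, 8, 16).
#' @param head_choices Attention head counts (default 2, 4, 8, 16).
#' @return Object of class `hyper_grid`; its `grid` element is a data frame
#'   with one row per configuration.
#' @export
hyper_grid <- function(embed_choices = c(8, 16, 32, 64),
                       ff_choices = c(4, 8, 16),
                       head_choices = c(2, 4, 8, 16)) {
  g <- expand.grid(embed_dim = embed_choices, ff_dim = ff_choices,
                   n_heads = head_choices, KEEP.OUT.ATTRS = FALSE)
  structure(list(grid = g), class = "hyper_grid")
}

#' Grid search over architecture hyperparameters
#'
#' Trains one model per grid configuration on the same frames and training
#' control, and returns the configuration with the lowest validation MSE.
#' Ties are broken toward fewer parameters, then grid order. Invalid
#' combinations (embedding not divisible by heads) are skipped.
#'
#' @param frames Frames as in [ft_train].
#' @param grid A [hyper_grid].
#' @param control A [train_config].
#' @param base_config Template [model_config] supplying all non-searched
#'   fields (pooling kernel, frame length, ...).
#' @return The winning [model_config]; attribute `"search"` holds a data
#'   frame of per-configuration validation losses and parameter counts.
#' @export
hyperparameter_search <- function(frames, grid = hyper_grid(),
                                  control = train_config(),
                                  base_config = model_config()) {
  stopifnot(inherits(grid, "hyper_grid"))
  g <- grid$grid
  if (nrow(g) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  res <- data.frame(g, val_loss = NA_real_, n_params = NA_integer_)
  cfgs <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    if (g$embed_dim[i] %% g$n_heads[i] != 0) next
    cfg <- base_config
    cfg$embed_dim <- as.integer(g$embed_dim[i])
    cfg$ff_dim <- as.integer(g$ff_dim[i])
    cfg$n_heads <- as.integer(g$n_heads[i])
    cfgs[[i]] <- cfg
    mdl <- feel_transformer(cfg, seed = control$seed)
    fit <- ft_train(mdl, frames, control)
    res$val_loss[i] <- fit$best_val
    res$n_params[i] <- n_params(mdl)
  }
  ok <- which(!is.na(res$val_loss))
  if (length(ok) == 0L)
    stop("no valid configuration in the grid", call. = FALSE)
  best <- ok[order(res$val_loss[ok], res$n_params[ok])][1L]
  out <- cfgs[[best]]
  attr(out, "search") <- res
  out
}

#' Save / load a trained model
#'
#' The checkpoint is an opaque versioned blob (RDS) holding parameters and
#' configuration; a human-readable JSON sidecar of the configuration is
#' written next to it when the jsonlite package is available.
#'
#' @param model A `feel_transformer`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `ft_save` returns `path` invisibly; `ft_load` returns the model.
#' @export
ft_save <- function(model, path) {
  stopifnot(inherits(model, "feel_transformer"))
  obj <- list(format = "edadecomp-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- paste0(path, ".json")
    jsonlite::write_json(unclass(model$config), side, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname ft_save
#' @export
ft_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "edadecomp-checkpoint"))
    stop("not an edadecomp checkpoint: ", path, call. = FALSE)
  obj$model
}
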