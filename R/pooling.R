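#' Centered moving average with replicate padding
#'
#' The workhorse smoother of the package: it implements both the weight-free
#' tonic (SCL) branch of the transformer and the trend extraction inside its
#' series-decomposition sublayers. The series is padded at both ends by
#' replicating the edge samples, so the output has the input's length and no
#' edge droop (droop would corrupt the end-minus-start tonic-slope feature).
#'
#' @param x Numeric vector, or a matrix smoothed column-wise.
#' @param window Odd window length in samples.
#' @return Smoothed vector/matrix of the same shape.
#' @export
moving_average <- function(x, window) {
  if (window < 1 || window != round(window))
    stop("window must be a positive integer", call. = FALSE)
  if (is.matrix(x)) return(apply(x, 2L, moving_average, window = window))
  n <- length(x)
  if (window > n)
    stop(sprintf("window %d exceeds signal length %d", window, n),
         call. = FALSE)
  if (window == 1L) return(x)
  h_l <- (window - 1L) %/% 2L   # left pad
  h_r <- window - 1L - h_l      # right pad
  xp <- c(rep(x[1L], h_l), x, rep(x[n], h_r))
  cs <- cumsum(c(0, xp))
  (cs[(window + 1L):(n + window)] - cs[1:n]) / window
}

# Adjoint (transpose) of moving_average as a linear operator; needed to
# backpropagate through the series-decomposition sublayers. Verified against
# finite differences in the test suite.
moving_average_adjoint <- function(g, window) {
  if (is.matrix(g))
    return(apply(g, 2L, moving_average_adjoint, window = window))
  n <- length(g)
  if (window == 1L) return(g)
  h_l <- (window - 1L) %/% 2L
  h_r <- window - 1L - h_l
  np <- n + window - 1L
  # gp[s] = (1/window) * sum of g[t] over windows t covering padded pos s
  cs <- cumsum(c(0, g))
  t_lo <- pmax(1L, seq_len(np) - window + 1L)
  t_hi <- pmin(n, seq_len(np))
  gp <- (cs[t_hi + 1L] - cs[t_lo]) / window
  gx <- gp[(h_l + 1L):(h_l + n)]
  if (h_l > 0L) gx[1L] <- gx[1L] + sum(gp[1:h_l])
  if (h_r > 0L) gx[n] <- gx[n] + sum(gp[(h_l + n + 1L):np])
  gx
}

#' Tonic (SCL) branch: pooling of the raw frame
#'
#' The skin-conductance level is modeled by a weight-free 1-D pooling of the
#' raw input frame with an odd kernel; no learned parameters touch it, so the
#' tonic output is auditable and identical across model states. Average
#' pooling is the default; max pooling is available as an option.
#'
#' The three canonical kernels are `rate * g + 1` samples for SCL
#' granularities g = 60, 30 and 1 s: 481, 241 and 9 samples at 8 Hz.
#'
#' @param frame An [eda_frame] or numeric vector.
#' @param pool_kernel Odd kernel length in samples, at most the frame length.
#' @param pooling Either "avg" (default) or "max".
#' @return Numeric vector of the same length: the tonic component (uS).
#' @export
scl_branch <- function(frame, pool_kernel, pooling = c("avg", "max")) {
  pooling <- match.arg(pooling)
  x <- if (inherits(frame, "eda_frame")) frame$samples else as.numeric(frame)
  if (pool_kernel %% 2L == 0L)
    stop("pool_kernel must be odd (centered window)", call. = FALSE)
  if (pool_kernel > length(x))
    stop("pool_kernel exceeds the frame length", call. = FALSE)
  if (pooling == "avg") return(moving_average(x, pool_kernel))
  # centered running max with replicate padding
  n <- length(x)
  h <- (pool_kernel - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  vapply(seq_len(n), function(i) max(xp[i:(i + pool_kernel - 1L)]),
         numeric(1))
}

#' Kernel length for an SCL granularity
#'
#' @param granularity_s SCL granularity in seconds (60, 30 or 1 for the
#'   three canonical configurations).
#' @param rate Sampling rate in Hz.
#' @return Odd kernel length `rate * granularity_s + 1`.
#' @export
pool_kernel_for <- function(granularity_s, rate = 8) {
  as.integer(rate * granularity_s + 1)
}
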