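#' Decomposition container
#'
#' Holds the tonic and phasic component of one frame. For residual-based
#' methods (Theil detrending, external backends as wrapped here) the
#' components satisfy `tonic + phasic == frame` exactly; for the transformer
#' they sum to the model's reconstruction of the frame.
#'
#' @param tonic Numeric vector (uS).
#' @param phasic Numeric vector (uS), same length.
#' @param method Label of the producing method.
#' @return An object of class `eda_decomposition`.
#' @export
eda_decomposition <- function(tonic, phasic, method = "unknown") {
  tonic <- as.numeric(tonic); phasic <- as.numeric(phasic)
  if (length(tonic) != length(phasic))
    stop("tonic and phasic must have equal length", call. = FALSE)
  if (!all(is.finite(tonic)) || !all(is.finite(phasic)))
    stop("decomposition components must be finite", call. = FALSE)
  structure(list(tonic = tonic, phasic = phasic, method = method),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("<eda_decomposition> method=%s, n=%d, phasic range %.4f uS\n",
              x$method, length(x$tonic), diff(range(x$phasic))))
  invisible(x)
}

#' Theil-Sen robust line fit
#'
#' Estimates the slope as the median of all pairwise slopes
#' `(y_j - y_i)/(t_j - t_i)` and the intercept as
#' `median(y) - slope * median(t)`, so the fitted line passes through the
#' coordinate-wise median point. Up to `max_exact` samples the full set of
#' pairwise slopes is used; above that a seeded random subsample of
#' `n_pairs` pairs keeps the estimator tractable with negligible loss of
#' precision (the default frame of 1440 samples is handled exactly).
#'
#' @param frame An [eda_frame] or numeric vector of conductance values.
#' @param rate Sampling rate in Hz, used to build the time axis when `frame`
#'   is a bare vector.
#' @param max_exact Largest sample count for which all pairs are enumerated
#'   (default 2000).
#' @param n_pairs Number of random pairs above that threshold (default 2e6).
#' @param subsample_seed Seed for the random-pair fallback.
#' @return List with `slope` (uS/s) and `intercept` (uS at t = 0), class
#'   `line_fit`.
#' @export
theil_sen_fit <- function(frame, rate = NULL, max_exact = 2000,
                          n_pairs = 2e6, subsample_seed = 1L) {
  if (inherits(frame, "eda_frame")) {
    y <- frame$samples
    t <- (seq_along(y) - 1) / frame$rate
  } else {
    y <- as.numeric(frame)
    if (is.null(rate)) rate <- 8
    t <- (seq_along(y) - 1) / rate
  }
  n <- length(y)
  if (n < 2L) stop("need at least two samples for a line fit", call. = FALSE)
  if (n <= max_exact) {
    ij <- utils::combn(n, 2L)
    slopes <- (y[ij[2L, ]] - y[ij[1L, ]]) / (t[ij[2L, ]] - t[ij[1L, ]])
  } else {
    slopes <- with_sim_seed(subsample_seed, 0L, {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      keep <- i != j
      (y[j[keep]] - y[i[keep]]) / (t[j[keep]] - t[i[keep]])
    })
  }
  slope <- stats::median(slopes)
  intercept <- stats::median(y) - slope * stats::median(t)
  structure(list(slope = slope, intercept = intercept), class = "line_fit")
}

#' Theil detrending decomposition
#'
#' The data-driven baseline: the tonic component is the Theil-Sen line
#' evaluated on the frame's time grid, and the phasic component is the
#' residual `frame - tonic`, so additivity is exact by construction.
#'
#' @param frame An [eda_frame].
#' @param ... Passed to [theil_sen_fit].
#' @return An [eda_decomposition] with method `"theil"`.
#' @export
detrend_decompose <- function(frame, ...) {
  stopifnot(inherits(frame, "eda_frame"))
  fit <- theil_sen_fit(frame, ...)
  t <- (seq_along(frame$samples) - 1) / frame$rate
  tonic <- fit$intercept + fit$slope * t
  eda_decomposition(tonic, frame$samples - tonic, method = "theil")
}

#' Adapter to published EDA decomposers
#'
#' Thin bridge to the cvxEDA and sparsEDA implementations in the Python
#' package neurokit2, for comparison runs. Only the backend's tonic
#' component is taken; the phasic component is always recomputed as
#' `frame - tonic` so the additivity contract matches every other method in
#' the package. When no usable Python with neurokit2 is on the PATH the
#' function raises an informative capability error instead of failing
#' mid-pipeline.
#'
#' @param frame An [eda_frame].
#' @param backend One of `"cvxeda"`, `"sparseda"`.
#' @param python Python executable to probe (default `"python"`).
#' @return An [eda_decomposition] with the backend's name as method.
#' @export
external_decompose <- function(frame, backend = c("cvxeda", "sparseda"),
                               python = "python") {
  stopifnot(inherits(frame, "eda_frame"))
  backend <- match.arg(backend)
  nk_method <- c(cvxeda = "cvxeda", sparseda = "sparseda")[[backend]]
  have <- nzchar(Sys.which(python)) &&
    suppressWarnings(system2(python, c("-c", shQuote("import neurokit2")),
                             stdout = FALSE, stderr = FALSE)) == 0L
  if (!have)
    stop(sprintf(paste0(
      "backend '%s' needs a python interpreter with the 'neurokit2' ",
      "package on the PATH (pip install neurokit2); none was found"),
      backend), call. = FALSE)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.csv(data.frame(eda_us = frame$samples), fin, row.names = FALSE)
  code <- sprintf(paste0(
    "import pandas as pd, neurokit2 as nk\n",
    "x = pd.read_csv('%s')['eda_us'].to_numpy()\n",
    "s = nk.eda_phasic(x, sampling_rate=%g, method='%s')\n",
    "s.to_csv('%s', index=False)\n"), fin, frame$rate, nk_method, fout)
  status <- system2(python, c("-c", shQuote(code)))
  if (status != 0L || !file.exists(fout))
    stop(sprintf("backend '%s' failed (python exit status %d)",
                 backend, status), call. = FALSE)
  res <- utils::read.csv(fout)
  tonic <- res[["EDA_Tonic"]]
  if (is.null(tonic) || length(tonic) != length(frame$samples))
    stop(sprintf("backend '%s' returned an unusable tonic component",
                 backend), call. = FALSE)
  eda_decomposition(tonic, frame$samples - tonic, method = backend)
}
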