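#' Detect SCR peaks in a phasic trace
#'
#' Documented native detector applied identically to every method's phasic
#' output (comparisons are only fair when the same detector and parameters
#' score every decomposition). A sample is a candidate peak if it is a local
#' maximum; candidates are kept if their topographic prominence reaches
#' `min_amplitude`, and of any pair closer than `min_separation` only the
#' larger survives.
#'
#' @param phasic Numeric vector (uS).
#' @param rate Sampling rate in Hz (default 8).
#' @param min_amplitude Minimum prominence in uS (default 0.01).
#' @param min_separation Minimum pairwise spacing in seconds (default 1).
#' @return Object of class `peak_set`: list with `indices` (strictly
#'   increasing sample positions) and `amplitudes` (`phasic[indices]`).
#' @export
detect_peaks <- function(phasic, rate = 8, min_amplitude = 0.01,
                         min_separation = 1) {
  phasic <- as.numeric(phasic)
  if (!all(is.finite(phasic))) stop("phasic must be finite", call. = FALSE)
  n <- length(phasic)
  empty <- structure(list(indices = integer(0), amplitudes = numeric(0)),
                     class = "peak_set")
  if (n < 3L) return(empty)
  d <- diff(phasic)
  # local maxima, plateau-tolerant: last non-zero slope up, next down
  sgn <- sign(d)
  filled <- sgn
  for (i in seq(2L, n - 1L)) if (filled[i] == 0) filled[i] <- filled[i - 1L]
  cand <- which(filled[-(n - 1L)] > 0 & sgn[-1L] < 0) + 1L
  cand <- cand[cand > 1L & cand < n]
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(i) {
    h <- phasic[i]
    l <- i; lmin <- h
    while (l > 1L && phasic[l - 1L] <= h) { l <- l - 1L
      if (phasic[l] < lmin) lmin <- phasic[l] }
    if (l == 1L) lmin <- min(phasic[1L:i])
    r <- i; rmin <- h
    while (r < n && phasic[r + 1L] <= h) { r <- r + 1L
      if (phasic[r] < rmin) rmin <- phasic[r] }
    if (r == n) rmin <- min(phasic[i:n])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_amplitude]
  if (length(keep) == 0L) return(empty)
  # min-separation: greedily keep the highest peaks
  min_gap <- min_separation * rate
  ord <- keep[order(phasic[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord)
    if (all(abs(i - chosen) >= min_gap)) chosen <- c(chosen, i)
  chosen <- sort(chosen)
  structure(list(indices = chosen, amplitudes = phasic[chosen]),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks, mean amplitude %.4f uS\n",
              length(x$indices),
              if (length(x$amplitudes)) mean(x$amplitudes) else NA_real_))
  invisible(x)
}

#' Tonic slope of a frame
#'
#' The end-to-end slope `(last - first) / duration` in uS/s -- deliberately
#' simple, so it measures the decomposition rather than a fitting method.
#'
#' @param tonic Numeric tonic trace (uS).
#' @param duration_s Frame duration in seconds (default 180).
#' @return Slope in uS/s.
#' @export
tonic_slope <- function(tonic, duration_s = 180) {
  tonic <- as.numeric(tonic)
  if (length(tonic) < 2L) stop("need at least two samples", call. = FALSE)
  (tonic[length(tonic)] - tonic[1L]) / duration_s
}

#' Slope band boundaries
#'
#' Slopes are binned into falling / stable / rising bands with boundaries at
#' -0.001 and +0.001 uS/s (the boundaries that render the pooled slope
#' histogram uniform); the stable band is closed on both sides.
#'
#' @param lower Lower boundary, uS/s (default -0.001).
#' @param upper Upper boundary, uS/s (default 0.001).
#' @return Object of class `slope_bins`.
#' @export
slope_bins <- function(lower = -0.001, upper = 0.001) {
  if (!(lower < upper)) stop("boundaries must be ordered", call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 labels = c("falling", "stable", "rising")),
            class = "slope_bins")
}

#' Bin a tonic slope into falling / stable / rising
#'
#' @param slope Slope(s) in uS/s.
#' @param bins A [slope_bins].
#' @return Ordered factor with levels falling < stable < rising.
#' @export
bin_slope <- function(slope, bins = slope_bins()) {
  lab <- ifelse(slope < bins$lower, "falling",
                ifelse(slope > bins$upper, "rising", "stable"))
  factor(lab, levels = bins$labels, ordered = TRUE)
}

check_hist <- function(p, name, tol = 0.05) {
  p <- as.numeric(p)
  if (any(p < 0)) stop(name, " must be non-negative", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > tol)
    stop(sprintf("%s sums to %.3f, not 1", name, s), call. = FALSE)
  p / s   # renormalize rounded inputs
}

#' Relative entropy (Kullback-Leibler divergence)
#'
#' `sum(p * log(p / q))` in nats, with the convention `0 * log(0) == 0`.
#' Rounded inputs (e.g. histograms printed as percentages) are renormalized
#' to sum to one before the computation.
#'
#' @param p Proportion histogram.
#' @param q Reference histogram of the same length, strictly positive
#'   wherever `p` is.
#' @return Divergence in nats (non-negative; 0 iff `p == q`).
#' @export
relative_entropy <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length", call. = FALSE)
  p <- check_hist(p, "p")
  q <- check_hist(q, "q")
  if (any(q == 0 & p > 0))
    stop("q has zero mass where p is positive", call. = FALSE)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Jensen-Shannon distance between histograms
#'
#' `sqrt((KL(p||m) + KL(q||m)) / 2)` with `m = (p+q)/2`; natural log by
#' default, so the maximum (disjoint supports) is `sqrt(log(2))`. It is a
#' metric on histograms: symmetric, zero iff equal, triangle inequality.
#'
#' @param p,q Proportion histograms of the same length.
#' @param base Logarithm base (default `exp(1)`).
#' @return Distance in `[0, sqrt(log(2, base))]`.
#' @export
jensen_shannon_distance <- function(p, q, base = exp(1)) {
  if (length(p) != length(q))
    stop("p and q must have the same length", call. = FALSE)
  p <- check_hist(p, "p")
  q <- check_hist(q, "q")
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / m[nz])) / log(base)
  }
  sqrt(pmax(0, (kl(p) + kl(q)) / 2))
}

# bin-edge families of the reporting histograms; left-closed, right-open,
# last bin open-ended
hist_edges <- list(
  peak_count = c(0, 5, 10, 15, 20, 25, 30, Inf),
  peak_amplitude = c(0, 0.005, 0.10, 0.20, 0.40, Inf),
  phasic_range = c(0, 0.02, 0.05, 0.10, 0.50, 1.0, 10, Inf)
)

# integer count bins are labelled by their largest member ("10-14"),
# continuous bins by their edges ("0.1-0.2")
hist_labels <- function(edges, integer_bins = FALSE) {
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  ifelse(is.finite(hi),
         paste0(lo, "-", if (integer_bins) hi - 1 else hi),
         paste0(lo, "+"))
}

bin_proportions <- function(values, edges, what, integer_bins = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("no values to histogram (", what, ")", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop(what, " values must be finite and non-negative", call. = FALSE)
  idx <- findInterval(values, edges, rightmost.closed = FALSE)
  h <- tabulate(idx, nbins = length(edges) - 1L) / length(values)
  names(h) <- hist_labels(edges, integer_bins)
  h
}

#' Reporting histograms
#'
#' Proportion histograms over the fixed bin families used in the comparison
#' report: per-frame peak counts (0-4, 5-9, ..., 30+), peak amplitudes in uS
#' (0-0.005, 0.005-0.10, 0.10-0.20, 0.20-0.40, 0.40+), and per-frame phasic
#' amplitude ranges in uS (0-0.02, 0.02-0.05, 0.05-0.10, 0.10-0.50, 0.50-1,
#' 1-10, 10+). Bins are left-closed and right-open; the last is open-ended.
#'
#' @param values Non-negative values to bin (counts, amplitudes or ranges).
#' @return Named proportion vector summing to 1.
#' @export
peak_count_histogram <- function(values)
  bin_proportions(values, hist_edges$peak_count, "peak count",
                  integer_bins = TRUE)

#' @rdname peak_count_histogram
#' @export
peak_amplitude_histogram <- function(values)
  bin_proportions(values, hist_edges$peak_amplitude, "peak amplitude")

#' @rdname peak_count_histogram
#' @export
phasic_range_histogram <- function(values)
  bin_proportions(values, hist_edges$phasic_range, "phasic range")

#' Compare decomposition methods on a common set of frames
#'
#' Runs every decomposer on every frame, scores all phasic outputs with the
#' same peak detector, and assembles the full feature report: per-method
#' tonic-slope histograms with their relative entropy against the uniform
#' thirds, peak-count and peak-amplitude histograms with means, phasic
#' amplitude-range histograms, and pairwise Jensen-Shannon distance matrices
#' for the count and amplitude histograms. A decomposer failing on a frame
#' is logged and that frame is excluded from that method's statistics.
#'
#' @param frames List of [eda_frame] objects (at least one).
#' @param decomposers Named list (at least two entries) of functions mapping
#'   an [eda_frame] to an [eda_decomposition].
#' @param bins A [slope_bins].
#' @param min_amplitude,min_separation Shared peak-detector parameters.
#' @return Object of class `feature_report`.
#' @export
compare_methods <- function(frames, decomposers, bins = slope_bins(),
                            min_amplitude = 0.01, min_separation = 1) {
  if (length(frames) < 1L) stop("need at least one frame", call. = FALSE)
  if (length(decomposers) < 2L || is.null(names(decomposers)) ||
      any(!nzchar(names(decomposers))))
    stop("need a named list of at least two decomposers", call. = FALSE)
  methods <- names(decomposers)
  per <- list()
  failures <- data.frame(method = character(0), frame = integer(0),
                         error = character(0))
  for (m in methods) {
    slopes <- numeric(0); counts <- numeric(0)
    amps <- numeric(0); ranges <- numeric(0)
    for (i in seq_along(frames)) {
      fr <- frames[[i]]
      dec <- tryCatch(decomposers[[m]](fr), error = function(e) e)
      if (inherits(dec, "error")) {
        failures <- rbind(failures,
                          data.frame(method = m, frame = i,
                                     error = conditionMessage(dec)))
        next
      }
      slopes <- c(slopes, tonic_slope(dec$tonic, duration_s = fr$duration))
      pk <- detect_peaks(dec$phasic, rate = fr$rate,
                         min_amplitude = min_amplitude,
                         min_separation = min_separation)
      counts <- c(counts, length(pk$indices))
      amps <- c(amps, pmax(0, pk$amplitudes))
      ranges <- c(ranges, diff(range(dec$phasic)))
    }
    if (length(slopes) == 0L)
      stop("decomposer '", m, "' failed on every frame", call. = FALSE)
    sl <- table(bin_slope(slopes, bins)) / length(slopes)
    sl <- as.numeric(sl); names(sl) <- bins$labels
    per[[m]] <- list(
      slope_histogram = sl,
      slope_entropy = relative_entropy(sl, rep(1 / 3, 3)),
      mean_peaks = mean(counts),
      peak_count_histogram = peak_count_histogram(counts),
      mean_amplitude = if (length(amps)) mean(amps) else NA_real_,
      peak_amplitude_histogram =
        if (length(amps)) peak_amplitude_histogram(amps) else NULL,
      phasic_range_histogram = phasic_range_histogram(ranges))
  }
  js_matrix <- function(field) {
    M <- matrix(0, length(methods), length(methods),
                dimnames = list(methods, methods))
    for (a in methods) for (b in methods) {
      ha <- per[[a]][[field]]; hb <- per[[b]][[field]]
      M[a, b] <- if (is.null(ha) || is.null(hb)) NA_real_
                 else jensen_shannon_distance(ha, hb)
    }
    M
  }
  if (nrow(failures) > 0L)
    warning(sprintf("%d frame/method decompositions failed and were excluded",
                    nrow(failures)), call. = FALSE)
  structure(list(methods = per,
                 js_peak_count = js_matrix("peak_count_histogram"),
                 js_peak_amplitude = js_matrix("peak_amplitude_histogram"),
                 failures = failures),
            class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("<feature_report>\n")
  for (m in names(x$methods)) {
    pm <- x$methods[[m]]
    cat(sprintf(
      "  %-10s slope %s entropy %.2e | mean peaks %.1f | mean ampl %.3f\n",
      m, paste(sprintf("%.0f%%", 100 * pm$slope_histogram), collapse = "/"),
      pm$slope_entropy, pm$mean_peaks, pm$mean_amplitude))
  }
  if (nrow(x$failures)) cat(sprintf("  (%d failures logged)\n",
                                    nrow(x$failures)))
  invisible(x)
}

#' Ground-truth event recall on a synthetic frame
#'
#' Scores a phasic estimate against the known events of a
#' `synthetic_frame`: a true event counts as recovered when a detected peak
#' of sufficient amplitude lies within `tol_s` seconds of the event's
#' expected peak time (onset plus the Bateman kernel's time-to-peak). The
#' amplitude floor keeps incidental noise peaks from counting as
#' recoveries.
#'
#' @param sf A `synthetic_frame` (see [synthesize_frame]).
#' @param phasic Phasic estimate for that frame (uS).
#' @param min_true_amplitude Only events at least this large are scored
#'   (default 0.2 uS).
#' @param tol_s Matching window in seconds (default 1).
#' @param min_detected_amplitude Detected peak must reach this value
#'   (default half of `min_true_amplitude`).
#' @param ... Passed to [detect_peaks].
#' @return List with `recall`, `n_events`, `n_recovered`.
#' @export
event_recall <- function(sf, phasic, min_true_amplitude = 0.2, tol_s = 1,
                         min_detected_amplitude = min_true_amplitude / 2,
                         ...) {
  stopifnot(inherits(sf, "synthetic_frame"))
  p <- sf$bateman
  t_star <- (p$tau_rise * p$tau_decay / (p$tau_decay - p$tau_rise)) *
    log(p$tau_decay / p$tau_rise)
  keep <- which(sf$event_amplitudes >= min_true_amplitude)
  if (length(keep) == 0L)
    return(list(recall = NA_real_, n_events = 0L, n_recovered = 0L))
  pk <- detect_peaks(phasic, rate = sf$frame$rate, ...)
  pt <- pk$indices / sf$frame$rate
  ok <- pk$amplitudes >= min_detected_amplitude
  hits <- vapply(sf$event_times[keep], function(ev)
    any(ok & abs(pt - (ev + t_star)) <= tol_s), logical(1))
  list(recall = mean(hits), n_events = length(keep),
       n_recovered = sum(hits))
}
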