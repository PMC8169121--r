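# Sniff-cycle detection and statistics from intranasal thermistor traces.
# Inhalation onsets are the troughs of the (cooling) temperature signal,
# exhalation onsets the peaks; a sniff runs inhalation-to-inhalation.

#' Construct a sniff trace
#'
#' @param samples numeric temperature samples (arbitrary units).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param t0 session-clock time of the first sample (s).
#' @export
sniff_trace <- function(samples, sample_rate, t0 = 0) {
  check_scalar(sample_rate, "sample_rate", lower = 1e-9)
  if (!all(is.finite(samples))) stop_invalid("samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t0 = t0), class = "sniff_trace")
}

#' Construct a sniff-event set
#'
#' Durations are inhalation-to-inhalation, so there is one sniff (and one
#' duration) per inhalation except the last.
#'
#' @param inhalation_s strictly increasing inhalation onset times (s).
#' @param exhalation_s exhalation onset times, each between consecutive
#'   inhalations.
#' @param kept_mask logical per sniff; defaults to all TRUE.
#' @export
sniff_events <- function(inhalation_s, exhalation_s = numeric(0),
                         kept_mask = NULL) {
  if (is.unsorted(inhalation_s, strictly = TRUE))
    stop_invalid("inhalation onsets must be strictly increasing")
  durations <- diff(inhalation_s)
  if (any(durations <= 0)) stop_invalid("durations must be positive")
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, length(durations))
  if (length(kept_mask) != length(durations))
    stop_invalid("kept_mask must have one entry per sniff")
  structure(list(inhalation_s = as.numeric(inhalation_s),
                 exhalation_s = as.numeric(exhalation_s),
                 durations = durations, kept_mask = kept_mask),
            class = "sniff_events")
}

#' Boxcar-smooth a sniff trace
#'
#' Moving average of the stated width (default 25 ms); length preserved,
#' edges handled by shrinking the window to the available samples.
#'
#' @param trace `sniff_trace`.
#' @param window window width in seconds.
#' @return smoothed `sniff_trace`.
#' @export
smooth_trace <- function(trace, window = 0.025) {
  w <- max(1L, round(window * trace$sample_rate))
  n <- length(trace$samples)
  if (w > n) stop_invalid("smoothing window longer than trace")
  half <- (w - 1) %/% 2
  cs <- cumsum(c(0, trace$samples))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  sniff_trace(out, trace$sample_rate, trace$t0)
}

#' Detect sniff events from a smoothed thermistor trace
#'
#' Finds troughs (inhalation onsets) and peaks (exhalation onsets) as
#' alternating local extrema with a minimum prominence, then optionally
#' refines each extremum location on a raw (unsmoothed) companion trace
#' within half a smoothing window. A flat trace yields an empty event set.
#'
#' @param trace smoothed `sniff_trace`.
#' @param prominence minimum extremum prominence as a fraction of the trace
#'   range (default 0.2); the absolute threshold used is
#'   `prominence * diff(range(samples))`.
#' @param inhalation_is_trough polarity flag: TRUE (default) when cooling
#'   inhalation produces troughs; set FALSE for inverted hardware.
#' @param refine_trace optional raw (unsmoothed) `sniff_trace` on the same
#'   clock; each detected extremum is relocated to the vertex of a local
#'   parabolic fit, giving sub-sample localization that is robust to
#'   measurement noise.
#' @param refine_frac refinement half-window as a fraction of the local
#'   sniff period (default 0.17, inside the near-quadratic region of the
#'   extremum).
#' @return `sniff_events` (times on the session clock).
#' @export
detect_sniffs <- function(trace, prominence = 0.2, inhalation_is_trough = TRUE,
                          refine_trace = NULL, refine_frac = 0.17) {
  x <- trace$samples
  if (!inhalation_is_trough) x <- -x
  rng <- diff(range(x))
  if (rng == 0) return(sniff_events(numeric(0)))
  thr <- prominence * rng
  troughs <- find_peaks_prominence(-x, thr)
  if (length(troughs) < 1) return(sniff_events(numeric(0)))
  peaks <- find_peaks_prominence(x, thr)
  # parabolic-vertex refinement: least-squares quadratic over a window
  # scaled to the local sniff period, extremum relocated to the vertex
  # (clamped to the window)
  spacing <- function(idx, k) {
    lo <- if (k > 1) idx[k] - idx[k - 1] else NA
    hi <- if (k < length(idx)) idx[k + 1] - idx[k] else NA
    m <- min(lo, hi, na.rm = TRUE)
    if (!is.finite(m)) round(0.2 * trace$sample_rate) else m
  }
  refine <- function(idx, signflip) {
    if (is.null(refine_trace) || length(idx) == 0) return(idx)
    y <- refine_trace$samples
    if (xor(signflip, !inhalation_is_trough)) y <- -y
    vapply(seq_along(idx), function(k) {
      i <- idx[k]
      h <- max(2L, round(refine_frac * spacing(idx, k)))
      lo <- max(1L, i - h); hi <- min(length(y), i + h)
      tt <- (lo:hi) - i
      fit <- stats::lm.fit(cbind(1, tt, tt^2), y[lo:hi])
      b1 <- fit$coefficients[2]; b2 <- fit$coefficients[3]
      if (!is.finite(b2) || b2 >= 0) return(as.numeric(i))
      i + max(-h, min(h, -b1 / (2 * b2)))
    }, numeric(1))
  }
  troughs <- refine(troughs, signflip = TRUE)
  peaks <- refine(peaks, signflip = FALSE)
  inh <- trace$t0 + (troughs - 1) / trace$sample_rate
  # keep the first exhalation (peak) following each inhalation
  ex <- trace$t0 + (peaks - 1) / trace$sample_rate
  keep_ex <- numeric(0)
  if (length(inh) >= 1 && length(ex) > 0) {
    for (i in seq_along(inh)) {
      hi <- if (i < length(inh)) inh[i + 1] else Inf
      inside <- ex[ex > inh[i] & ex < hi]
      if (length(inside) > 0) keep_ex <- c(keep_ex, inside[1])
    }
  }
  sniff_events(inh, keep_ex)
}

# Local maxima with topographic prominence >= prom. The prominence of a
# peak is its height above the higher of the two saddle minima separating
# it from higher ground (or from the record edge).
find_peaks_prominence <- function(x, prom) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  # include plateau edges missed above (strictly rising then flat handled)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- x[i]
    lmin <- h; j <- i
    while (j > 1L) { j <- j - 1L; if (x[j] > h) break; lmin <- min(lmin, x[j]) }
    rmin <- h; j <- i
    while (j < n) { j <- j + 1L; if (x[j] > h) break; rmin <- min(rmin, x[j]) }
    keep[k] <- (h - max(lmin, rmin)) >= prom
  }
  cand[keep]
}

#' Filter sniffs by duration percentiles
#'
#' Marks as excluded every sniff whose inhalation-to-inhalation duration is
#' strictly below the 5th or strictly above the 95th percentile of the
#' session's duration distribution (linear-interpolation quantiles; ties at
#' the thresholds are kept).
#'
#' @param events `sniff_events`.
#' @param lower,upper percentile bounds (defaults 0.05, 0.95).
#' @return `sniff_events` with updated `kept_mask`.
#' @export
filter_sniff_durations <- function(events, lower = 0.05, upper = 0.95) {
  d <- events$durations
  if (length(d) < 2) stop_invalid("need at least 2 sniffs to filter")
  q <- quantile(d, c(lower, upper), names = FALSE, type = 7)
  eps <- 1e-9 * median(d) # ties at the thresholds are kept
  events$kept_mask <- d >= q[1] - eps & d <= q[2] + eps
  events
}

#' Instantaneous sniff rate on a time base
#'
#' rate(t) = 1 / duration of the kept sniff enclosing t; NA outside the
#' sniff record or inside filtered-out sniffs.
#'
#' @param events `sniff_events`.
#' @param timebase numeric times (s).
#' @return numeric rate series (Hz) aligned to `timebase`.
#' @export
instantaneous_rate <- function(events, timebase) {
  inh <- events$inhalation_s
  if (length(inh) < 2 || sum(events$kept_mask) < 1)
    stop_invalid("need at least one kept sniff")
  idx <- findInterval(timebase, inh)
  out <- rep(NA_real_, length(timebase))
  ok <- idx >= 1 & idx <= length(events$durations)
  ok[ok] <- events$kept_mask[idx[ok]]
  out[ok] <- 1 / events$durations[idx[ok]]
  out
}

#' Sniff phase of time points
#'
#' phase = (t - inhalation onset) / sniff duration, in \[0, 1); NA for
#' times outside any kept sniff.
#'
#' @param t numeric times (s).
#' @param events `sniff_events`.
#' @return numeric phases.
#' @export
sniff_phase <- function(t, events) {
  inh <- events$inhalation_s
  idx <- findInterval(t, inh)
  out <- rep(NA_real_, length(t))
  ok <- idx >= 1 & idx <= length(events$durations)
  ok[ok] <- events$kept_mask[idx[ok]]
  out[ok] <- (t[ok] - inh[idx[ok]]) / events$durations[idx[ok]]
  out
}

#' Compare two sniff-duration distributions
#'
#' Two-sample Kolmogorov-Smirnov test (thin wrapper over [stats::ks.test]).
#'
#' @param a,b numeric duration samples.
#' @return list with `statistic` and `p_value`.
#' @export
compare_duration_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop_invalid("inputs must be non-empty")
  k <- suppressWarnings(ks.test(a, b))
  list(statistic = unname(k$statistic), p_value = unname(k$p.value))
}
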