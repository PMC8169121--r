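# Per-frame kinematic parameters from three-point (nose, head, body)
# tracking, and their synchrony with the sniff cycle.
#
# Conventions: nose speed is the Euclidean frame-to-frame displacement of
# the snout tip; yaw velocity is the change of the unsigned angle between
# the nose-head segment and the head-body segment (centrifugal, i.e.
# away from the body axis, is positive); Z-velocity is the change of the
# snout-to-head distance, a 2-D proxy for pitch/vertical motion.

#' Compute kinematic parameters from a three-point trajectory
#'
#' @param traj data.frame with columns `time_s`, `nose_x`, `nose_y`,
#'   `head_x`, `head_y`, `body_x`, `body_y` (any consistent length unit;
#'   velocities come out per frame).
#' @return data.frame with `frame`, `time_s`, `nose_speed`, `yaw_vel`,
#'   `z_vel`; the first frame (and frames after missing keypoints) is NA.
#' @export
compute_kinematics <- function(traj) {
  need <- c("time_s", "nose_x", "nose_y", "head_x", "head_y", "body_x", "body_y")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop_invalid("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(traj)
  if (n < 2) stop_invalid("need >= 2 frames")
  dx <- diff(traj$nose_x); dy <- diff(traj$nose_y)
  nose_speed <- c(NA, sqrt(dx^2 + dy^2))
  # unsigned angle between (nose - head) and (head - body)
  v1x <- traj$nose_x - traj$head_x; v1y <- traj$nose_y - traj$head_y
  v2x <- traj$head_x - traj$body_x; v2y <- traj$head_y - traj$body_y
  dot <- v1x * v2x + v1y * v2y
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  cosang <- pmin(pmax(dot / (n1 * n2), -1), 1)
  ang <- acos(cosang)
  yaw_vel <- c(NA, diff(ang))
  zdist <- sqrt((traj$nose_x - traj$head_x)^2 + (traj$nose_y - traj$head_y)^2)
  z_vel <- c(NA, diff(zdist))
  data.frame(frame = seq_len(n) - 1L, time_s = traj$time_s,
             nose_speed = nose_speed, yaw_vel = yaw_vel, z_vel = z_vel)
}

#' Drop trials containing tracking glitches
#'
#' A trial is excluded when any frame's nose speed exceeds the criterion
#' (100 pixels per frame by default; speeds must be in px/frame).
#'
#' @param kin_list list of kinematic data.frames (from
#'   [compute_kinematics()], px units).
#' @param criterion glitch threshold in px/frame.
#' @return the retained subset, with attribute `dropped` giving the indices
#'   removed.
#' @export
exclude_glitch_trials <- function(kin_list, criterion = 100) {
  bad <- vapply(kin_list, function(k)
    any(k$nose_speed > criterion, na.rm = TRUE), logical(1))
  out <- kin_list[!bad]
  attr(out, "dropped") <- which(bad)
  out
}

#' Shift tracking-derived streams onto the sniff clock
#'
#' Advances a per-frame series by `shift` frames (default 2, i.e. 25 ms at
#' 80 Hz) relative to the sniff recording, compensating the video-pipeline
#' latency. Vacated frames are NA.
#'
#' @param x numeric per-frame series (or integer label sequence).
#' @param shift integer frames (positive = advance).
#' @return shifted series, same length.
#' @export
align_tracking_to_sniff <- function(x, shift = 2L) {
  shift <- as.integer(shift)
  n <- length(x)
  if (shift == 0L) return(x)
  out <- rep(NA * x[1], n)
  if (shift > 0L) {
    if (shift < n) out[(shift + 1L):n] <- x[1:(n - shift)]
  } else {
    if (-shift < n) out[1:(n + shift)] <- x[(1L - shift):n]
  }
  out
}

#' Sniff-triggered matrix of a kinematic series
#'
#' Extracts a window (default 400 ms) centered on each inhalation whose
#' window lies fully inside the record; rows are events, columns are lags.
#'
#' @param values numeric per-frame series.
#' @param frame_times frame times (s), evenly sampled.
#' @param inhalations inhalation onset times (s).
#' @param window full window width in seconds (default 0.4).
#' @return list of class `triggered_matrix`: `mat` (events x lags),
#'   `lags_s`, `grand_mean` (column means ignoring NA).
#' @export
sniff_triggered <- function(values, frame_times, inhalations, window = 0.4) {
  if (length(values) != length(frame_times)) stop_invalid("length mismatch")
  dt <- median(diff(frame_times))
  half <- round((window / 2) / dt)
  lags <- (-half):half
  rows <- list()
  for (t0 in inhalations) {
    i0 <- round((t0 - frame_times[1]) / dt) + 1
    if (i0 - half >= 1 && i0 + half <= length(values))
      rows[[length(rows) + 1]] <- values[i0 + lags]
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(lags))
  gm <- if (nrow(mat)) colMeans(mat, na.rm = TRUE) else rep(NA_real_, length(lags))
  structure(list(mat = mat, lags_s = lags * dt, grand_mean = gm),
            class = "triggered_matrix")
}

#' Modulation index of a non-negative curve
#'
#' MI = (max - min) / (max + min); NA for an all-zero (or all-NA) curve.
#'
#' @param curve numeric, non-negative.
#' @return MI in \[0, 1\].
#' @export
modulation_index <- function(curve) {
  curve <- curve[is.finite(curve)]
  if (length(curve) == 0) return(NA_real_)
  if (any(curve < 0)) stop_invalid("curve must be non-negative")
  mx <- max(curve); mn <- min(curve)
  if (mx + mn == 0) return(NA_real_)
  (mx - mn) / (mx + mn)
}

#' Cross-correlation and spectral coherence between kinematics and sniffing
#'
#' Both series must share a sampling clock (resample beforehand if needed).
#' Cross-correlation is Pearson-normalized ([stats::ccf]); coherence is
#' Welch-averaged magnitude-squared coherence (Hann windows).
#'
#' @param kin,sniff numeric series on a common clock.
#' @param fs sampling rate in Hz.
#' @param max_lag_s maximum cross-correlation lag (default 0.2 s).
#' @param coh_window_s Welch window length in seconds (default 1).
#' @return list with data.frames `crosscorr` (lag_s, cor) and `coherence`
#'   (freq_hz, coh).
#' @export
sniff_kinematic_synchrony <- function(kin, sniff, fs, max_lag_s = 0.2,
                                      coh_window_s = 1) {
  if (length(kin) != length(sniff)) stop_invalid("length mismatch")
  nwin <- round(coh_window_s * fs)
  if (length(kin) < 2 * nwin) stop_invalid("series shorter than two windows")
  ok <- is.finite(kin) & is.finite(sniff)
  k <- kin; s <- sniff
  k[!ok] <- mean(kin[ok]); s[!ok] <- mean(sniff[ok])
  cc <- ccf(k, s, lag.max = round(max_lag_s * fs), plot = FALSE)
  crosscorr <- data.frame(lag_s = as.numeric(cc$lag) / fs,
                          cor = as.numeric(cc$acf))
  coh <- welch_coherence(k, s, fs, nwin)
  list(crosscorr = crosscorr, coherence = coh)
}

# Welch magnitude-squared coherence with 50% overlap Hann windows.
welch_coherence <- function(x, y, fs, nwin) {
  step <- max(1L, nwin %/% 2L)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))
  nf <- nwin %/% 2L
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  for (s0 in starts) {
    xs <- x[s0:(s0 + nwin - 1L)]; ys <- y[s0:(s0 + nwin - 1L)]
    X <- fft((xs - mean(xs)) * win)[2:(nf + 1L)]
    Y <- fft((ys - mean(ys)) * win)[2:(nf + 1L)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  data.frame(freq_hz = seq_len(nf) * fs / nwin, coh = coh)
}

#' Trial-shuffle permutation test for sniff-locked modulation
#'
#' The observed statistic is the modulation index of the grand-mean
#' sniff-triggered curve pooled over trials. The null re-pairs each trial's
#' sniff times with another trial's kinematics (random derangement,
#' truncated to the shared record length) and recomputes the statistic;
#' p = (1 + #{null >= observed}) / (1 + n).
#'
#' @param kin_trials list of data.frames with `time_s`, `value` (per trial).
#' @param sniff_trials list of inhalation-onset vectors (s, trial clock).
#' @param n number of permutations (default 1000).
#' @param window triggered-window width in seconds.
#' @param seed integer seed.
#' @return list with `observed`, `null` (length-n vector), `p`.
#' @export
trial_shuffle_test <- function(kin_trials, sniff_trials, n = 1000,
                               window = 0.4, seed = 1) {
  m <- length(kin_trials)
  if (m < 2 || length(sniff_trials) != m)
    stop_invalid("need >= 2 trials with matching sniff trains")
  if (n < 1) stop_invalid("n must be >= 1")
  # Precompute, for every (kinematics i, sniff train j) pairing, the column
  # sum and row count of the triggered matrix; any pairing's grand mean is
  # then a weighted average, so each permutation costs O(m) work.
  nlag <- NULL
  sums <- vector("list", m); cnts <- matrix(0, m, m)
  for (i in seq_len(m)) {
    sums[[i]] <- vector("list", m)
    for (j in seq_len(m)) {
      kt <- kin_trials[[i]]
      tm <- sniff_triggered(kt$value, kt$time_s,
                            sniff_trials[[j]][sniff_trials[[j]] <= max(kt$time_s)],
                            window = window)
      if (is.null(nlag)) nlag <- length(tm$lags_s)
      sums[[i]][[j]] <- if (nrow(tm$mat)) colSums(tm$mat, na.rm = TRUE) else numeric(nlag)
      cnts[i, j] <- nrow(tm$mat)
    }
  }
  stat_for <- function(pairing) {
    tot <- numeric(nlag); nr <- 0
    for (i in seq_len(m)) {
      tot <- tot + sums[[i]][[pairing[i]]]
      nr <- nr + cnts[i, pairing[i]]
    }
    if (nr == 0) return(NA_real_)
    modulation_index(tot / nr)
  }
  observed <- stat_for(seq_len(m))
  null <- with_seed(seed, vapply(seq_len(n), function(k)
    stat_for(derangement(m)), numeric(1)))
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (1 + n)
  list(observed = observed, null = null, p = p)
}

#' Path tortuosity
#'
#' Total path length divided by the straight-line distance between the
#' first and last points; >= 1, NA when the endpoints coincide.
#'
#' @param x,y coordinates along the path.
#' @return tortuosity ratio.
#' @export
tortuosity <- function(x, y) {
  if (length(x) < 2) stop_invalid("need >= 2 points")
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord == 0) return(NA_real_)
  path / chord
}
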