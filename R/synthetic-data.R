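# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth and a fixed seed: AR-HMM
# trajectories, thermistor-like sniff traces with planted events,
# sniff-locked kinematic series with known modulation depth, full
# behavioral sessions, and gridded plume recordings.

#' Generate a random, stable AR-HMM parameter set
#'
#' States are made distinguishable by placing their stationary means on a
#' circle of radius `separation` (first two dimensions) and giving each
#' state its own contraction/rotation dynamics; all spectral radii are < 1
#' so simulated trajectories stay bounded.
#'
#' @param S number of states (>= 1).
#' @param d trajectory dimension (>= 1).
#' @param separation radius of the circle of stationary means, in trajectory
#'   units; larger values make states easier to separate.
#' @param persistence self-transition probability (off-diagonal mass spread
#'   uniformly).
#' @param noise_sd marginal innovation standard deviation.
#' @param seed integer seed.
#' @return `arhmm_params` with uniform initial distribution.
#' @export
gen_arhmm_params <- function(S, d, separation = 3, persistence = 0.9,
                             noise_sd = 0.3, seed = 1) {
  if (S < 1 || d < 1) stop_invalid("S and d must be >= 1")
  check_scalar(separation, "separation", lower = 1e-12)
  trans <- if (S == 1L) matrix(1, 1, 1) else {
    m <- matrix((1 - persistence) / (S - 1), S, S)
    diag(m) <- persistence
    m
  }
  with_seed(seed, {
    A <- vector("list", S); b <- vector("list", S); Q <- vector("list", S)
    for (s in seq_len(S)) {
      rho <- 0.8
      if (d >= 2) {
        theta <- runif(1, -0.4, 0.4)
        R2 <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
        As <- diag(rho, d)
        As[1:2, 1:2] <- rho * R2
      } else {
        As <- matrix(rho, 1, 1)
      }
      mu <- rep(0, d)
      ang <- 2 * base::pi * (s - 1) / S
      mu[1] <- separation * cos(ang)
      if (d >= 2) mu[2] <- separation * sin(ang)
      A[[s]] <- As
      b[[s]] <- as.numeric((diag(d) - As) %*% mu)
      Q[[s]] <- diag(noise_sd^2, d)
    }
    arhmm_params(pi = trans, A = A, b = b, Q = Q)
  })
}

#' Simulate trials from an AR-HMM
#'
#' @param params `arhmm_params`.
#' @param n_trials number of trials.
#' @param length_range integer range of trial lengths in frames (min >= 2);
#'   lengths drawn uniformly.
#' @param seed integer seed.
#' @return list with `trajectories` (list of T x d matrices) and
#'   `true_labels` (list of integer vectors).
#' @export
simulate_trials <- function(params, n_trials, length_range = c(100, 200),
                            seed = 1) {
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  if (min(length_range) < 2) stop_invalid("trial length must be >= 2")
  S <- params$S; d <- params$d
  with_seed(seed, {
    trajectories <- vector("list", n_trials)
    true_labels <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      T_ <- if (length_range[1] == length_range[2]) length_range[1] else
        sample(seq(length_range[1], length_range[2]), 1)
      z <- integer(T_)
      x <- matrix(0, T_, d)
      z[1] <- sample.int(S, 1, prob = params$init)
      mu1 <- tryCatch(solve(diag(d) - params$A[[z[1]]], params$b[[z[1]]]),
                      error = function(e) rep(0, d)) # unit-root state: start at 0
      x[1, ] <- mu1 + rnorm(d, sd = sqrt(diag(params$Q[[z[1]]])))
      for (t in 2:T_) {
        z[t] <- sample.int(S, 1, prob = params$pi[z[t - 1], ])
        L <- t(safe_chol(params$Q[[z[t]]]))
        x[t, ] <- params$A[[z[t]]] %*% x[t - 1, ] + params$b[[z[t]]] +
          L %*% rnorm(d)
      }
      trajectories[[i]] <- x
      true_labels[[i]] <- z
    }
    list(trajectories = trajectories, true_labels = true_labels)
  })
}

#' Generate a thermistor-like sniff trace with known events
#'
#' Plants inhalation onsets by drawing successive sniff durations from a
#' (possibly time-varying) rate profile, then renders a smooth oscillatory
#' waveform whose troughs fall exactly on the planted onsets: phase is
#' interpolated through the onset times with a monotone spline and the
#' waveform is -cos(2*pi*phase) + 0.15*cos(4*pi*phase) (non-sinusoidal but
#' with smooth curvature at every extremum, so boxcar smoothing does not
#' displace the troughs). Exhalation onsets sit at the mid-cycle peaks.
#'
#' @param duration trace length in seconds.
#' @param rate_profile sniff rate in Hz: a constant or a function of time
#'   (seconds). Must stay within (0, Nyquist).
#' @param outlier_fraction fraction of sniffs whose duration is scaled by
#'   3x or 1/3x, planting duration outliers for filter testing.
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param duration_jitter lognormal sd of per-sniff duration jitter
#'   (default 0.05).
#' @param noise_sd additive Gaussian noise sd on the unit-amplitude trace.
#' @param seed integer seed.
#' @return list with `trace` (a `sniff_trace`) and `true_events` (list with
#'   `inhalation_s`, `exhalation_s`).
#' @export
gen_sniff_trace <- function(duration, rate_profile = 5, outlier_fraction = 0,
                            sample_rate = 1000, duration_jitter = 0.05,
                            noise_sd = 0.02, seed = 1) {
  check_scalar(duration, "duration", lower = 1e-6)
  check_scalar(outlier_fraction, "outlier_fraction", 0, 1)
  ratefun <- if (is.function(rate_profile)) rate_profile else function(t) rate_profile + 0 * t
  if (max(ratefun(seq(0, duration, length.out = 50))) >= sample_rate / 2)
    stop_invalid("sniff rate exceeds the Nyquist frequency of sample_rate")
  if (min(ratefun(seq(0, duration, length.out = 50))) <= 0)
    stop_invalid("rate profile must be positive")
  with_seed(seed, {
    onsets <- numeric(0)
    t <- 0.01 + 0.6 / ratefun(0) # leave a partial cycle before the first trough
    repeat {
      onsets <- c(onsets, t)
      dur <- 1 / ratefun(t) * exp(rnorm(1, 0, duration_jitter))
      if (outlier_fraction > 0 && runif(1) < outlier_fraction)
        dur <- dur * sample(c(3, 1 / 3), 1)
      if (t + dur + 0.7 / ratefun(min(t + dur, duration)) > duration) break
      t <- t + dur
    }
    n <- length(onsets)
    if (n < 2) stop_invalid("duration too short for the requested rate")
    tt <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
    # monotone phase through (onset_i, i - 1); linear continuation outside,
    # so the first and last troughs keep full flanks
    phase_fun <- splinefun(onsets, seq_len(n) - 1, method = "monoH.FC")
    phase <- phase_fun(pmin(pmax(tt, onsets[1]), onsets[n]))
    d1 <- onsets[2] - onsets[1]; dn <- onsets[n] - onsets[n - 1]
    pre <- tt < onsets[1]; post <- tt > onsets[n]
    phase[pre] <- (tt[pre] - onsets[1]) / d1
    phase[post] <- (n - 1) + (tt[post] - onsets[n]) / dn
    y <- -cos(2 * pi * phase) + 0.15 * cos(4 * pi * phase)
    y <- y + rnorm(length(y), 0, noise_sd)
    exhal <- vapply(seq_len(n - 1), function(i) {
      # peak at phase i - 0.5: invert the monotone phase map by bisection
      lo <- onsets[i]; hi <- onsets[i + 1]; target <- i - 0.5
      for (k in 1:40) {
        mid <- (lo + hi) / 2
        if (phase_fun(mid) < target) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
    list(trace = sniff_trace(y, sample_rate = sample_rate, t0 = 0),
         true_events = list(inhalation_s = onsets, exhalation_s = exhal))
  })
}

#' Generate a sniff-locked kinematic series with known modulation depth
#'
#' series(t) = baseline * (1 + depth * cos(2*pi*phase(t))) + noise, where
#' phase is the sniff phase (0 at inhalation onset). Outside the sniff
#' record the series sits at baseline.
#'
#' @param events `sniff_events` (or a list with `inhalation_s`).
#' @param depth modulation depth in \[0, 1\].
#' @param baseline positive baseline level.
#' @param frame_rate sampling rate of the kinematic series (default 80 Hz).
#' @param duration series length in seconds (default: past last inhalation).
#' @param noise_sd additive noise sd.
#' @param seed integer seed.
#' @return data.frame with columns `time_s`, `value`.
#' @export
gen_sniff_locked_kinematics <- function(events, depth, baseline = 1,
                                        frame_rate = 80, duration = NULL,
                                        noise_sd = 0.02, seed = 1) {
  check_scalar(depth, "depth", 0, 1)
  inh <- if (inherits(events, "sniff_events")) events$inhalation_s else events$inhalation_s
  if (is.null(duration)) duration <- max(inh) + 0.5
  tt <- seq(0, duration, by = 1 / frame_rate)
  idx <- findInterval(tt, inh)
  phase <- rep(NA_real_, length(tt))
  ok <- idx >= 1 & idx < length(inh)
  phase[ok] <- (tt[ok] - inh[idx[ok]]) / (inh[idx[ok] + 1] - inh[idx[ok]])
  mod <- ifelse(is.na(phase), 1, 1 + depth * cos(2 * pi * phase))
  with_seed(seed, {
    val <- baseline * mod + rnorm(length(tt), 0, noise_sd)
  })
  data.frame(time_s = tt, value = val)
}
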