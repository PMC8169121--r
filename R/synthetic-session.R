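# Synthetic behavioral sessions with planted ground truth.
#
# Arena frame: longitudinal 0 -> 25 cm (initiation port at 0, odor ports
# at 25), lateral 0 -> 15 cm, decision line at 15 cm. The left port sits at
# high lateral coordinate. Each trial has an investigation epoch (slow,
# tortuous casting near the initiation port, fast sniffing) followed by an
# approach epoch (fast, directed movement to the chosen port, slower
# sniffing); each epoch alternates between two movement sub-modes on a
# sub-second timescale, so a fitted AR-HMM sees a two-block transition
# structure. Choices follow a logistic read-out of the (noisy) left-right
# concentration difference, keeping correct and incorrect trials populated.

#' Session generator configuration
#'
#' @param n_trials trials per session (default 20).
#' @param frame_rate video frame rate, Hz (default 80).
#' @param decision_line_cm longitudinal position of the decision line.
#' @param ratio stimulus condition label (default "80:20").
#' @param choice_rule "logistic" (default) or "always_correct".
#' @param gradient_strength mean left-right concentration difference driving
#'   the logistic choice (2 gives ~80 percent correct at unit noise).
#' @param inv_rate,app_rate sniff rates (Hz) planted in investigation and
#'   approach epochs.
#' @param inv_speed,app_speed nominal nose speeds (cm/s) of the two epochs.
#' @param modulation_depth sniff-locked nose-oscillation depth in \[0, 1\].
#' @param px_per_cm pixel scale carried in metadata (default 20).
#' @param sniff_sample_rate thermistor sampling rate, Hz.
#' @param iti_s inter-trial interval (s).
#' @export
session_config <- function(n_trials = 20, frame_rate = 80,
                           decision_line_cm = 15, ratio = "80:20",
                           choice_rule = c("logistic", "always_correct"),
                           gradient_strength = 2,
                           inv_rate = 10, app_rate = 5,
                           inv_speed = 2.5, app_speed = 14,
                           modulation_depth = 0.3, px_per_cm = 20,
                           sniff_sample_rate = 1000, iti_s = 4) {
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  list(n_trials = n_trials, frame_rate = frame_rate,
       decision_line_cm = decision_line_cm, ratio = ratio,
       choice_rule = match.arg(choice_rule),
       gradient_strength = gradient_strength,
       inv_rate = inv_rate, app_rate = app_rate,
       inv_speed = inv_speed, app_speed = app_speed,
       modulation_depth = modulation_depth, px_per_cm = px_per_cm,
       sniff_sample_rate = sniff_sample_rate, iti_s = iti_s)
}

clip01 <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# one trial's body path + epoch labels; returns list(pos (T x 2 long/lat),
# epoch (1 = investigation, 2 = approach))
gen_trial_path <- function(cfg, choice) {
  fr <- cfg$frame_rate
  dt <- 1 / fr
  inv_frames <- round(runif(1, 0.9, 1.6) * fr)
  target_lat <- if (choice == "left") 11.25 else 3.75
  pos <- matrix(NA_real_, 0, 2)
  p <- c(0.8, 7.5 + rnorm(1, 0, 0.5))
  v <- c(0, 0)
  epoch <- integer(0)
  mode_len <- function() max(6L, round(rnorm(1, 14, 3)))
  # investigation: casting near the port, alternating lateral sweep modes
  m <- sample(1:2, 1); left_in_mode <- mode_len()
  for (t in seq_len(inv_frames)) {
    if (left_in_mode == 0L) { m <- 3L - m; left_in_mode <- mode_len() }
    left_in_mode <- left_in_mode - 1L
    sweep_dir <- if (m == 1L) 1 else -1
    dir_ <- c(0.3, sweep_dir * 0.95)
    dir_ <- dir_ / sqrt(sum(dir_^2))
    v <- 0.7 * v + 0.3 * dir_ * cfg$inv_speed * dt +
      rnorm(2, 0, cfg$inv_speed * dt * 0.35)
    p <- clip01(p + v, c(0.2, 0.2), c(24.8, 14.8))
    pos <- rbind(pos, p)
    epoch <- c(epoch, 1L)
  }
  # approach: directed surge/adjust alternation toward the chosen port
  m <- 1L; left_in_mode <- max(10L, round(rnorm(1, 22, 4)))
  max_app <- round(4 * fr)
  for (t in seq_len(max_app)) {
    if (left_in_mode == 0L) { m <- 3L - m
      left_in_mode <- max(10L, round(rnorm(1, 22, 4))) }
    left_in_mode <- left_in_mode - 1L
    tgt <- c(24.5, target_lat)
    dir_ <- tgt - p
    dir_ <- dir_ / max(sqrt(sum(dir_^2)), 1e-9)
    sp <- if (m == 1L) cfg$app_speed else 0.55 * cfg$app_speed
    ns <- if (m == 1L) 0.06 else 0.15
    v <- 0.6 * v + 0.4 * dir_ * sp * dt + rnorm(2, 0, cfg$app_speed * dt * ns)
    p <- clip01(p + v, c(0.2, 0.2), c(24.8, 14.8))
    pos <- rbind(pos, p)
    epoch <- c(epoch, 2L)
    if (p[1] >= 24) break
  }
  list(pos = unname(pos), epoch = epoch)
}

#' Simulate a full behavioral session
#'
#' Generates trials with three-point trajectories (80 Hz), thermistor sniff
#' traces with known events, stimulus sides, choices and outcomes, plus
#' planted ground truth (epoch labels, true sniff onsets, modulation
#' depth).
#'
#' @param cfg [session_config()].
#' @param mouse_id,session_id identifiers carried in the bundle.
#' @param seed integer seed.
#' @return a `session_bundle`: list with `mouse_id`, `session_id`,
#'   `frame_rate`, `px_per_cm`, `left_is_high_lat`, and `trials`, each trial
#'   holding `trajectory` (data.frame, cm), `sniff` (`sniff_events`),
#'   `sniff_trace`, `meta`, and `truth` (epoch labels, true events).
#' @export
simulate_session <- function(cfg = session_config(), mouse_id = "m1",
                             session_id = "s1", seed = 1) {
  fr <- cfg$frame_rate
  trials <- vector("list", cfg$n_trials)
  with_seed(seed, {
    t_clock <- 0
    for (i in seq_len(cfg$n_trials)) {
      side <- sample(c("left", "right"), 1)
      if (cfg$choice_rule == "always_correct") {
        choice <- side
      } else {
        dc <- cfg$gradient_strength + rnorm(1, 0, 1.5)
        p_correct <- plogis(dc)
        choice <- if (runif(1) < p_correct) side else setdiff(c("left", "right"), side)
      }
      path <- gen_trial_path(cfg, choice)
      T_ <- nrow(path$pos)
      tt <- t_clock + (seq_len(T_) - 1) / fr
      # heading from heavily smoothed velocity (body orientation turns slowly)
      vel <- rbind(c(0.1, 0), diff(path$pos))
      for (k in 2:T_) vel[k, ] <- 0.9 * vel[k - 1, ] + 0.1 * vel[k, ]
      hd <- vel / pmax(sqrt(rowSums(vel^2)), 1e-9)
      # sniffing: rate by epoch, planted events on the trial clock
      ratefun <- function(ts) {
        idx <- clip01(floor((ts - t_clock) * fr) + 1, 1, T_)
        ifelse(path$epoch[idx] == 1L, cfg$inv_rate, cfg$app_rate)
      }
      sn <- gen_sniff_trace(duration = T_ / fr,
                            rate_profile = function(u) ratefun(u + t_clock),
                            sample_rate = cfg$sniff_sample_rate,
                            duration_jitter = 0.04,
                            seed = NULL_seed())
      inh_trial <- sn$true_events$inhalation_s
      # sniff-locked extension of the nose along the heading
      phase <- rep(NA_real_, T_)
      rel_t <- tt - t_clock
      idx <- findInterval(rel_t, inh_trial)
      ok <- idx >= 1 & idx < length(inh_trial)
      phase[ok] <- (rel_t[ok] - inh_trial[idx[ok]]) /
        (inh_trial[idx[ok] + 1] - inh_trial[idx[ok]])
      ext <- 1.5 + cfg$modulation_depth * 0.6 * cos(2 * pi * ifelse(is.na(phase), 0.25, phase))
      body <- path$pos
      head <- body + 2.0 * hd
      nose <- head + ext * hd
      traj <- data.frame(frame = seq_len(T_) - 1L, time_s = tt,
                         nose_x = nose[, 1], nose_y = nose[, 2],
                         head_x = head[, 1], head_y = head[, 2],
                         body_x = body[, 1], body_y = body[, 2])
      events <- sniff_events(t_clock + inh_trial,
                             t_clock + sn$true_events$exhalation_s)
      sn$trace$t0 <- t_clock
      cross <- which(path$pos[, 1] >= cfg$decision_line_cm)
      meta <- list(start_s = tt[1], end_s = tt[T_], side = side,
                   ratio = cfg$ratio, choice = choice,
                   correct = identical(choice, side),
                   decision_cross_s = if (length(cross)) tt[cross[1]] else NA_real_,
                   iti_start_s = tt[T_], iti_end_s = tt[T_] + cfg$iti_s)
      trials[[i]] <- list(trajectory = traj, sniff = events,
                          sniff_trace = sn$trace, meta = meta,
                          truth = list(epoch = path$epoch,
                                       inhalation_s = t_clock + inh_trial,
                                       modulation_depth = cfg$modulation_depth))
      t_clock <- tt[T_] + cfg$iti_s
    }
  })
  structure(list(mouse_id = mouse_id, session_id = session_id,
                 frame_rate = fr, px_per_cm = cfg$px_per_cm,
                 left_is_high_lat = TRUE, config = cfg, trials = trials),
            class = "session_bundle")
}

# generators called inside with_seed() must not reset the RNG stream
NULL_seed <- function() NULL

#' Generate a gridded plume-recording session
#'
#' Emulates PID sampling on a 7 x 5 grid (7 longitudinal x 5 lateral
#' locations) with mirror-imaged left/right mean concentration fields and
#' additive noise. The left field decays with distance from the left odor
#' port (high lateral side), the right field is its lateral mirror.
#'
#' @param n_trials_per_bin trials per location per side (default 15).
#' @param trial_s trial duration, seconds (default 2).
#' @param sample_rate PID sampling rate, Hz (default 1000).
#' @param noise_sd additive noise sd (concentration units).
#' @param decay_cm exponential decay length of the plume (default 10).
#' @param peak concentration at the source (default 1).
#' @param mirror if FALSE, the right field equals the left field (identical
#'   distributions; useful for null checks).
#' @param seed integer seed.
#' @return `plume_grid` with attribute `mean_fields` (list of the two
#'   noiseless 5 x 7 fields).
#' @export
gen_plume_session <- function(n_trials_per_bin = 15, trial_s = 2,
                              sample_rate = 1000, noise_sd = 0.1,
                              decay_cm = 10, peak = 1, mirror = TRUE,
                              seed = 1) {
  long_pos <- seq(2.5, 22.5, length.out = 7)
  lat_pos <- seq(1.5, 13.5, length.out = 5)
  locations <- expand.grid(row = seq_len(5), col = seq_len(7))
  locations$long_cm <- long_pos[locations$col]
  locations$lat_cm <- lat_pos[locations$row]
  src_left <- c(25, 11.25); src_right <- c(25, 3.75)
  field_for <- function(src) {
    f <- matrix(0, 5, 7)
    for (li in seq_len(nrow(locations))) {
      d <- sqrt((locations$long_cm[li] - src[1])^2 +
                  (locations$lat_cm[li] - src[2])^2)
      f[locations$row[li], locations$col[li]] <- peak * exp(-d / decay_cm)
    }
    f
  }
  fL <- field_for(src_left)
  fR <- if (mirror) field_for(src_right) else fL
  n_samp <- round(trial_s * sample_rate)
  trials <- list()
  with_seed(seed, {
    for (li in seq_len(nrow(locations))) {
      for (sd_ in c("left", "right")) {
        mu <- if (sd_ == "left") fL[locations$row[li], locations$col[li]]
              else fR[locations$row[li], locations$col[li]]
        for (k in seq_len(n_trials_per_bin)) {
          trials[[length(trials) + 1]] <- list(
            location = li, side = sd_,
            trace = mu + rnorm(n_samp, 0, noise_sd),
            sample_rate = sample_rate)
        }
      }
    }
  })
  out <- plume_grid(locations, trials)
  attr(out, "mean_fields") <- list(left = fL, right = fR)
  out
}
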