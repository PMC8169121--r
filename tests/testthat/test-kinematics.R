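# Kinematic parameters and sniff-kinematic synchrony.

frame_df <- function(n, nose, head, body) {
  data.frame(time_s = (seq_len(n) - 1) / 80,
             nose_x = nose[, 1], nose_y = nose[, 2],
             head_x = head[, 1], head_y = head[, 2],
             body_x = body[, 1], body_y = body[, 2])
}

test_that("a stationary mouse has zero speed, yaw and z velocity", {
  n <- 10
  pt <- function(x, y) matrix(rep(c(x, y), each = n), n)
  k <- compute_kinematics(frame_df(n, pt(3, 1), pt(2, 1), pt(1, 1)))
  expect_true(all(k$nose_speed[-1] == 0))
  expect_true(all(k$yaw_vel[-1] == 0))
  expect_true(all(k$z_vel[-1] == 0))
  expect_true(all(is.na(k[1, c("nose_speed", "yaw_vel", "z_vel")])))
})

test_that("nose translation along the body axis gives speed and +z", {
  n <- 5
  nose <- cbind(3 + 3 * (seq_len(n) - 1), rep(0, n)) # 3 units/frame away from head
  head <- matrix(rep(c(2, 0), each = n), n)
  body <- matrix(rep(c(1, 0), each = n), n)
  k <- compute_kinematics(frame_df(n, nose, head, body))
  expect_equal(k$nose_speed[-1], rep(3, n - 1))
  expect_equal(k$z_vel[-1], rep(3, n - 1))
})

test_that("rigid nose rotation about the head gives yaw velocity +omega", {
  om <- 0.1
  n <- 8
  ang <- om * (seq_len(n) - 1) # angle away from the body axis
  nose <- cbind(2 + cos(ang), sin(ang))
  head <- matrix(rep(c(2, 0), each = n), n)
  body <- matrix(rep(c(1, 0), each = n), n)
  k <- compute_kinematics(frame_df(n, nose, head, body))
  expect_equal(k$yaw_vel[-1], rep(om, n - 1), tolerance = 1e-10)
  # analytic nose speed on the unit circle: 2 sin(om/2)
  expect_equal(k$nose_speed[-1], rep(2 * sin(om / 2), n - 1), tolerance = 1e-10)
})

test_that("glitch exclusion drops exactly the trials with super-threshold frames", {
  mk <- function(speeds) data.frame(nose_speed = speeds)
  trials <- list(mk(c(NA, 5, 20)), mk(c(NA, 150, 3)), mk(c(NA, 99, 99)),
                 mk(c(NA, 101, 1)))
  out <- exclude_glitch_trials(trials)
  expect_length(out, 2)
  expect_identical(attr(out, "dropped"), c(2L, 4L))
})

test_that("tracking alignment shifts by whole frames and round-trips", {
  x <- c(rep(0, 9), 1, rep(0, 10))
  expect_identical(align_tracking_to_sniff(x, 0L), x)
  s <- align_tracking_to_sniff(x, 2L)
  expect_equal(which(s == 1), 12)
  back <- align_tracking_to_sniff(s, -2L)
  expect_equal(back[3:18], x[3:18])
})

test_that("sniff-triggered windows align and exclude edge events", {
  tt <- seq(0, 10, by = 1 / 80)
  const <- sniff_triggered(rep(2, length(tt)), tt, c(1, 2, 3))
  expect_equal(nrow(const$mat), 3)
  expect_true(all(const$mat == 2))
  expect_equal(const$lags_s[1], -0.2, tolerance = 1e-9)
  # event 100 ms from the record edge is dropped
  edge <- sniff_triggered(rep(2, length(tt)), tt, c(0.1, 5))
  expect_equal(nrow(edge$mat), 1)
  # sniff-locked cosine peaks at lag zero
  g <- gen_sniff_trace(20, 6, sample_rate = 1000, duration_jitter = 0.01, seed = 1)
  kin <- gen_sniff_locked_kinematics(g$true_events, depth = 0.6,
                                     noise_sd = 0.01, seed = 2)
  tm <- sniff_triggered(kin$value, kin$time_s, g$true_events$inhalation_s)
  expect_equal(which.max(tm$grand_mean), which(tm$lags_s == 0))
})

test_that("modulation index follows its closed forms", {
  expect_equal(modulation_index(rep(4, 10)), 0)
  expect_equal(modulation_index(c(0, 1, 2)), 1)
  th <- seq(0, 2 * pi, length.out = 101) # grid contains both extrema
  expect_equal(modulation_index(2 + cos(th)), 0.5, tolerance = 1e-8)
  expect_true(is.na(modulation_index(rep(0, 5))))
  expect_error(modulation_index(c(-1, 2)), "non-negative")
})

test_that("cross-correlation and coherence behave on constructed signals", {
  fs <- 80
  set.seed(3)
  tt <- seq(0, 40, by = 1 / fs)
  x <- sin(2 * pi * 6 * tt) + 0.1 * rnorm(length(tt))
  syn_same <- sniff_kinematic_synchrony(x, x, fs)
  expect_equal(max(syn_same$crosscorr$cor), 1, tolerance = 1e-6)
  expect_equal(syn_same$crosscorr$cor[syn_same$crosscorr$lag_s == 0], 1,
               tolerance = 1e-6)
  co <- syn_same$coherence
  expect_gt(co$coh[which.min(abs(co$freq_hz - 6))], 0.99)
  # independent white noise: correlations within the null band
  a <- rnorm(4000); b <- rnorm(4000)
  syn0 <- sniff_kinematic_synchrony(a, b, fs)
  expect_lt(max(abs(syn0$crosscorr$cor)), 3 / sqrt(4000) * 1.5)
  # 25 ms delayed copy peaks at +25 ms
  shift <- 2 # frames, 25 ms at 80 Hz
  kin_del <- c(rep(0, shift), x[1:(length(x) - shift)])
  synd <- sniff_kinematic_synchrony(kin_del, x, fs)
  expect_equal(synd$crosscorr$lag_s[which.max(synd$crosscorr$cor)], shift / fs)
  expect_error(sniff_kinematic_synchrony(1:10, 1:10, fs), "shorter")
})

test_that("trial-shuffle test detects planted locking and respects conventions", {
  tr <- locked_trial_set(0.5, 15, seed0 = 100)
  res <- trial_shuffle_test(tr$kin, tr$sniffs, n = 300, seed = 1)
  expect_lt(res$p, 0.01)
  tr0 <- locked_trial_set(0, 15, seed0 = 300)
  res0 <- trial_shuffle_test(tr0$kin, tr0$sniffs, n = 300, seed = 1)
  expect_gt(res0$p, 0.05)
  # one-sided convention: p in (0, 1], smallest attainable value 1/(n+1)
  expect_gte(res$p, 1 / 301); expect_lte(res0$p, 1)
  expect_length(res$null, 300)
  expect_error(trial_shuffle_test(tr$kin[1], tr$sniffs[1]), ">= 2 trials")
})

test_that("tortuosity is path length over chord length", {
  expect_equal(tortuosity(c(0, 1, 2), c(0, 0, 0)), 1)
  expect_equal(tortuosity(c(0, 1, 1), c(0, 0, 1)), 2 / sqrt(2))
  set.seed(4)
  x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
  expect_gte(tortuosity(x, y), 1)
  expect_true(is.na(tortuosity(c(0, 1, 0), c(0, 1, 0))))
})

test_that("modulation-depth recovery improves with sniff count", {
  # seed-averaged error at roughly 50, 200 and 1000 sniffs
  mean_err <- function(dur) mean(vapply(1:4, function(s) {
    g <- gen_sniff_trace(dur, 6, sample_rate = 1000, duration_jitter = 0.01,
                         seed = s)
    kin <- gen_sniff_locked_kinematics(g$true_events, depth = 0.4,
                                       noise_sd = 0.3, seed = 100 + s)
    tm <- sniff_triggered(kin$value, kin$time_s, g$true_events$inhalation_s)
    abs(modulation_index(pmax(tm$grand_mean, 0)) - 0.4)
  }, numeric(1)))
  errs <- vapply(c(8, 34, 170), mean_err, numeric(1))
  expect_true(all(diff(errs) < 0))
})
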