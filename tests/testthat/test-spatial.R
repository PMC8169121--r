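# Spatial maps, I.A.I., reorientation, and outcome permutation tests.

test_that("occupancy maps conserve counts and tile the arena", {
  o <- occupancy_map(c(3.2), c(7.7), bin_size = 0.5)
  expect_equal(dim(o$grid), c(30, 50))
  expect_equal(sum(o$grid), 1)
  expect_equal(o$grid[16, 7], 1) # lat 7.5-8.0, long 3.0-3.5
  set.seed(1)
  o2 <- occupancy_map(runif(5000, 0, 25), runif(5000, 0, 15), bin_size = 1)
  expect_equal(dim(o2$grid), c(15, 25))
  expect_equal(sum(o2$grid), 5000)
  # out-of-arena points are clipped and counted
  o3 <- occupancy_map(c(-1, 30), c(5, 5), bin_size = 1)
  expect_equal(attr(o3, "n_clipped"), 2)
  expect_equal(sum(o3$grid), 2)
  # normalized mode returns fractions
  expect_equal(sum(occupancy_map(runif(100, 0, 25), runif(100, 0, 15),
                                 normalize = TRUE)$grid), 1)
})

test_that("uniform occupancy is multinomially flat", {
  set.seed(2)
  n <- 2e5
  o <- occupancy_map(runif(n, 0, 25), runif(n, 0, 15), bin_size = 1,
                     normalize = TRUE)
  p0 <- 1 / 375
  sigma <- sqrt(p0 * (1 - p0) / n)
  expect_lt(max(abs(o$grid - p0)), 5 * sigma)
})

test_that("sniff-rate map divides sniff counts by occupancy", {
  occ <- occupancy_map(rep(c(2, 12), each = 50), rep(c(3, 3), each = 50),
                       bin_size = 1)
  rate <- sniff_rate_map(rep(2, 25), rep(3, 25), occ)
  expect_equal(rate$grid[4, 3], 0.5) # 25 sniffs over 50 frames
  expect_equal(rate$grid[4, 13], 0)
  expect_true(is.na(rate$grid[1, 1]))
  # no sniffs: zero map where occupied
  r0 <- sniff_rate_map(numeric(0), numeric(0), occ)
  expect_equal(r0$grid[4, 3], 0)
})

test_that("sniff-rate maps recover planted position-dependent rates", {
  # 10 Hz of sniffing near the port (one inhalation per 8 frames at 80 Hz),
  # 5 Hz far from it: the map-mean ratio is 2
  set.seed(3)
  long <- c(runif(4000, 0, 8), runif(4000, 17, 25))
  lat <- runif(8000, 0, 15)
  near_idx <- seq(1, 4000, by = 8)
  far_idx <- seq(4001, 8000, by = 16)
  occ <- occupancy_map(long, lat, bin_size = 1)
  rmap <- sniff_rate_map(long[c(near_idx, far_idx)], lat[c(near_idx, far_idx)],
                         occ)
  near <- mean(rmap$grid[, 1:8], na.rm = TRUE)
  far <- mean(rmap$grid[, 18:25], na.rm = TRUE)
  expect_equal(near / far, 2, tolerance = 0.25)
  # session generator: investigation sniffing near the port is faster
  s <- simulate_session(session_config(n_trials = 10), seed = 3)
  slong <- unlist(lapply(s$trials, function(tr) tr$trajectory$nose_x))
  slat <- unlist(lapply(s$trials, function(tr) tr$trajectory$nose_y))
  tt <- unlist(lapply(s$trials, function(tr) tr$trajectory$time_s))
  inh <- unlist(lapply(s$trials, function(tr) tr$truth$inhalation_s))
  ii <- vapply(inh, function(t0) which.min(abs(tt - t0)), integer(1))
  socc <- occupancy_map(slong, slat, bin_size = 1)
  smap <- sniff_rate_map(slong[ii], slat[ii], socc)
  expect_gt(mean(smap$grid[, 1:8], na.rm = TRUE),
            mean(smap$grid[, 17:25], na.rm = TRUE))
})

test_that("state occupancy maps split and conserve labeled frames", {
  long <- c(rep(2, 30), rep(20, 20))
  lat <- rep(7, 50)
  lab <- c(rep("investigation", 30), rep("approach", 20))
  m <- state_occupancy_maps(long, lat, lab)
  expect_equal(sum(m$investigation$grid), 30)
  expect_equal(sum(m$approach$grid), 20)
  all_inv <- state_occupancy_maps(long, lat, rep("investigation", 50))
  expect_equal(sum(all_inv$approach$grid), 0)
  norm <- state_occupancy_maps(long, lat, lab, normalize_total = TRUE)
  expect_equal(norm$investigation$grid[8, 3], 1)
})

test_that("I.A.I. hits its endpoint values and is antisymmetric", {
  inv <- occupancy_map(rep(2, 10), rep(2, 10), bin_size = 1)
  app <- occupancy_map(rep(20, 10), rep(2, 10), bin_size = 1)
  ia <- iai(inv, app)
  expect_equal(ia$grid[3, 3], 1)
  expect_equal(ia$grid[3, 21], -1)
  expect_true(is.na(ia$grid[10, 10]))
  expect_equal(iai(5, 5), 0)
  expect_equal(iai(c(2, 0), c(0, 0)), c(1, NA))
  ia_swap <- iai(app, inv)
  expect_equal(ia_swap$grid, -ia$grid)
})

test_that("choice reorientation flips right-choice trials and is an involution", {
  s <- simulate_session(session_config(n_trials = 12), seed = 4)
  r1 <- reorient_by_choice(s)
  r2 <- reorient_by_choice(r1)
  # double flip restores right-choice trajectories
  ch <- vapply(s$trials, function(tr) tr$meta$choice, character(1))
  i_r <- which(ch == "right")[1]; i_l <- which(ch == "left")[1]
  expect_equal(r2$trials[[i_r]]$trajectory$nose_y,
               s$trials[[i_r]]$trajectory$nose_y)
  expect_equal(r1$trials[[i_l]]$trajectory$nose_y,
               s$trials[[i_l]]$trajectory$nose_y)
  expect_equal(r1$trials[[i_r]]$trajectory$nose_y,
               15 - s$trials[[i_r]]$trajectory$nose_y)
  # after reorientation all trials end on the same lateral half
  ends <- vapply(r1$trials, function(tr) tail(tr$trajectory$body_y, 1), numeric(1))
  expect_true(all(ends > 7.5) || all(ends < 7.5))
})

test_that("axis profiles project, respect zones, and localize deltas", {
  u <- occupancy_map(runif(2000, 0, 25), runif(2000, 0, 15), bin_size = 1)
  p_long <- axis_profile(u, "longitudinal")
  expect_equal(sum(p_long$value), 2000)
  expect_equal(nrow(p_long), 25)
  full <- axis_profile(u, "lateral", zone = c(0, 25))
  expect_equal(full$value, axis_profile(u, "lateral")$value)
  d <- occupancy_map(7.2, 3.4, bin_size = 1)
  pd <- axis_profile(d, "lateral", zone = c(5, 10))
  expect_equal(sum(pd$value), 1)
  expect_equal(pd$center_cm[pd$value == 1], 3.5)
  expect_error(axis_profile(d, "lateral", zone = c(-2, 30)), "zone")
})

test_that("correct/incorrect permutation detects planted effects and calibrates", {
  set.seed(5)
  mice <- lapply(1:5, function(m) {
    correct <- rep(c(TRUE, FALSE), each = 10)
    profiles <- t(vapply(seq_len(20), function(i) {
      base <- rep(10, 15)
      if (correct[i]) base[7:9] <- base[7:9] + 4 # midline investigation boost
      base + rnorm(15, 0, 2)
    }, numeric(15)))
    list(profiles = profiles, correct = correct)
  })
  res <- correct_incorrect_permutation(mice, n = 1000, seed = 6)
  expect_lt(max(res$p[7:9]), 0.01)
  expect_gt(min(res$p[c(1:4, 12:15)]), 0.05)
  expect_equal(dim(res$null), c(1000, 15))
  # null calibration: ~5% of bins significant
  set.seed(7)
  fr <- replicate(30, {
    mice0 <- lapply(1:4, function(m)
      list(profiles = matrix(rnorm(20 * 10, 10, 2), 20),
           correct = rep(c(TRUE, FALSE), each = 10)))
    mean(correct_incorrect_permutation(mice0, n = 200,
                                       seed = sample.int(1e6, 1))$p < 0.05)
  })
  expect_lt(abs(mean(fr) - 0.05), 0.035)
  expect_error(correct_incorrect_permutation(mice, n = 0), ">= 1")
  # single-outcome mice are excluded with a warning
  bad <- c(mice, list(list(profiles = matrix(rnorm(50), 5),
                           correct = rep(TRUE, 5))))
  expect_warning(correct_incorrect_permutation(bad, n = 10, seed = 1),
                 "excluded")
})

test_that("stay/switch partition is exhaustive and matches construction", {
  s <- simulate_session(session_config(n_trials = 15), seed = 8)
  sp <- split_stay_switch(s)
  expect_equal(sort(c(sp$stay, sp$switch, sp$excluded)),
               seq_along(s$trials))
  expect_length(intersect(sp$stay, sp$switch), 0)
  # straight-to-port paths always stay
  straight <- s
  straight$trials <- lapply(straight$trials, function(tr) {
    n <- nrow(tr$trajectory)
    tgt <- if (tr$meta$choice == "left") 11.25 else 3.75
    tr$trajectory$nose_x <- seq(0.5, 24, length.out = n)
    tr$trajectory$nose_y <- seq(7.5, tgt, length.out = n)
    tr
  })
  sp2 <- split_stay_switch(straight)
  expect_length(sp2$switch, 0)
})

test_that("session performance summarizes correctness, duration, tortuosity", {
  s <- simulate_session(session_config(n_trials = 12,
                                       choice_rule = "always_correct"),
                        seed = 9)
  perf <- session_performance(s)
  expect_equal(perf$percent_correct, 100)
  expect_lt(perf$binomial_p, 0.001)
  expect_gte(perf$mean_tortuosity, 1)
  expect_gt(perf$mean_duration_s, 0)
  # coin-flip outcomes are rarely significant
  set.seed(10)
  ps <- replicate(40, binom.test(rbinom(1, 200, 0.5), 200, 0.5,
                                 alternative = "greater")$p.value)
  expect_gte(mean(ps > 0.05), 0.9)
})
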