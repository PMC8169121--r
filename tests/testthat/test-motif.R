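# Transition-matrix clustering, motif onsets, and sniff-cycle alignment.

# two 2-motif blocks: per-element within-block probability `within`,
# cross-block probability `cross` (rows sum to 1 when within = 0.5 - cross)
block_matrix <- function(cross = 0.05, within = 0.5 - cross) {
  m <- matrix(cross, 4, 4)
  m[1:2, 1:2] <- within
  m[3:4, 3:4] <- within
  m / rowSums(m)
}

test_that("transition clustering recovers planted blocks with both algorithms", {
  pi_b <- block_matrix(cross = 0.05) # within 0.45, cross 0.05
  truth <- rep(1:2, each = 2)
  for (meth in c("ward", "kmeans")) {
    g <- cluster_transition_matrix(pi_b, method = meth, seed = 1)
    expect_true(all(table(g$group, truth) %in% c(0, 2)))
  }
  # permutation invariance (up to relabeling)
  ord <- c(3, 1, 4, 2)
  g2 <- cluster_transition_matrix(pi_b[ord, ord])
  expect_true(all(table(g2$group, truth[ord]) %in% c(0, 2)))
  # identical rows cluster together
  same <- rbind(c(.5, .5, 0), c(.5, .5, 0), c(0, 0, 1))
  g3 <- cluster_transition_matrix(same)
  expect_equal(g3$group[1], g3$group[2])
  expect_error(cluster_transition_matrix(matrix(1)), ">= 2")
})

test_that("clustering survives a sweep of cross-block probabilities", {
  truth <- rep(1:2, each = 2)
  for (cross in c(0.05, 0.1, 0.15)) {
    for (meth in c("ward", "kmeans")) {
      g <- cluster_transition_matrix(block_matrix(cross = cross), method = meth)
      expect_true(all(table(g$group, truth) %in% c(0, 2)),
                  info = paste(meth, "cross =", cross))
    }
  }
})

test_that("onsets are label changes plus trial starts", {
  on <- motif_onsets(list(c(0L, 0L, 1L, 1L, 0L)), list((0:4) / 80))
  expect_equal(on$frame, c(0L, 2L, 4L))
  expect_equal(on$motif, c(0L, 1L, 0L))
  const <- motif_onsets(list(rep(2L, 10), rep(3L, 5)),
                        list((0:9) / 80, (0:4) / 80))
  expect_equal(nrow(const), 2)
  # onset count = transition count + trial count on Markov labels
  z <- markov_seqs(0.8, 5, 100, seed = 2)
  tt <- lapply(z, function(zz) seq_along(zz) / 80)
  n_trans <- sum(vapply(z, function(zz) sum(diff(zz) != 0), numeric(1)))
  expect_equal(nrow(motif_onsets(z, tt)), n_trans + 5)
})

test_that("onset-time PSTH localizes planted offsets and stays flat under the null", {
  set.seed(3)
  inh <- sort(runif(2000, 0, 200))
  # onsets planted 50 ms after inhalations: PSTH peaks at -50 ms
  psth <- onset_time_psth(inh[seq(1, 2000, 4)] + 0.05, inh,
                          window = 0.2, bin = 0.0125)
  expect_lt(abs(psth$lag_s[which.max(psth$rate)] + 0.05), 0.0126)
  # independent onsets: flat
  ons <- sort(runif(5000, 1, 199))
  flat <- onset_time_psth(ons, inh, window = 0.2, bin = 0.025)
  expect_lt(max(flat$rate) / min(flat$rate), 1.3)
  # onsets exactly at inhalations: delta at lag 0
  delta <- onset_time_psth(inh, inh, window = 0.2, bin = 0.0125)
  expect_lt(abs(delta$lag_s[which.max(delta$rate)]), 0.0126)
})

test_that("phase histogram places onsets in the expected bins", {
  ev <- sniff_events(seq(0, 20, by = 0.2))
  at_inh <- data.frame(trial = 1, motif = 1,
                       time_s = seq(0.2, 19, by = 0.2) + 1e-6, frame = 0)
  h1 <- onset_phase_hist(at_inh, ev, n_bins = 10)$hist
  expect_equal(which.max(h1$count), 1)
  mid <- data.frame(trial = 1, motif = 1,
                    time_s = seq(0.2, 19, by = 0.2) + 0.1, frame = 0)
  h2 <- onset_phase_hist(mid, ev, n_bins = 10)$hist
  expect_lt(abs(h2$phase[which.max(h2$count)] - 0.5), 0.06)
  # uniform onsets: uniform histogram by chi-square
  set.seed(4)
  unif <- data.frame(trial = 1, motif = 1, time_s = runif(4000, 0.1, 19.9),
                     frame = 0)
  h3 <- onset_phase_hist(unif, ev, n_bins = 10)$hist
  expect_gt(suppressWarnings(chisq.test(h3$count)$p.value), 0.01)
  # mean end-of-inhalation phase reported (mid-cycle for the generator waveform)
  g <- gen_sniff_trace(10, 6, sample_rate = 500, seed = 5)
  ev2 <- sniff_events(g$true_events$inhalation_s, g$true_events$exhalation_s)
  r <- onset_phase_hist(unif[1:10, ], ev2)
  expect_equal(r$mean_inhalation_end_phase, 0.5, tolerance = 0.05)
})

test_that("onset modulation test flags locked onsets and not random ones", {
  gs <- lapply(1:10, function(i) gen_sniff_trace(6, 7, sample_rate = 500,
                                                 seed = 40 + i))
  sn <- lapply(gs, function(x) sniff_events(x$true_events$inhalation_s,
                                            x$true_events$exhalation_s))
  locked <- lapply(gs, function(x) {
    inh <- x$true_events$inhalation_s
    (inh + 0.02)[seq(1, length(inh), by = 2)]
  })
  om <- onset_modulation_test(locked, sn, n = 300, seed = 41)
  expect_lt(om$p_time, 0.01)
  expect_true(is.finite(om$mi_time) && is.finite(om$mi_phase))
  set.seed(42)
  rand_on <- lapply(1:10, function(i) sort(runif(20, 0.3, 5.7)))
  om0 <- onset_modulation_test(rand_on, sn, n = 300, seed = 43)
  expect_gt(om0$p_time, 0.05)
  # all-equal histogram has MI zero
  expect_equal(modulation_index(rep(7, 16)), 0)
  expect_error(onset_modulation_test(rand_on[1], sn[1]), "paired")
})

test_that("frame labels map deterministically through the grouping", {
  g <- cluster_transition_matrix(rbind(c(.9, .1), c(.1, .9)))
  seqs <- list(c(1L, 1L, 2L, 2L), c(2L, 1L, 3L, 1L))
  lab <- state_frame_labels(seqs, g)
  expect_equal(lab[[1]][1], lab[[1]][2])
  expect_true(is.na(lab[[2]][3])) # motif 3 not covered by the grouping
  one_group <- g; one_group$group <- c(1L, 1L)
  expect_equal(unique(state_frame_labels(seqs[1], one_group)[[1]]),
               "investigation")
})

test_that("state summary z-scores within mouse and orders groups by speed", {
  frames <- data.frame(
    mouse = rep("m1", 200),
    motif = rep(c(1, 2), each = 100),
    nose_speed = c(rnorm(100, 1, 0.01), rnorm(100, 3, 0.01)),
    sniff_rate = c(rnorm(100, 10, 0.01), rnorm(100, 5, 0.01)))
  s <- state_summary(frames)
  expect_equal(sign(s$norm_speed), c(-1, 1))
  expect_equal(sign(s$norm_rate), c(1, -1))
  one <- state_summary(data.frame(mouse = "m", motif = 1,
                                  nose_speed = rnorm(10)))
  expect_equal(one$norm_speed, 0)
  expect_false("norm_rate" %in% names(one))
})
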