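# Higher-order structure of motif sequences: clustering the transition
# matrix into investigation vs approach groups, motif-onset events, their
# alignment to the sniff cycle in time and phase, and permutation tests of
# onset modulation.

#' Cluster transition-matrix rows into two motif groups
#'
#' Groups motifs by the similarity of their outgoing transition
#' probabilities (Euclidean distance between raw probability rows). The
#' group whose motifs' states the chain tends to occupy early is not
#' identified here; callers label groups by kinematic summaries.
#'
#' @param pi row-stochastic transition matrix over retained motifs
#'   (dimnames, if present, name the motifs).
#' @param method "ward" (agglomerative, Ward linkage; default) or "kmeans"
#'   (k = 2, 100 restarts).
#' @param seed seed for k-means restarts.
#' @return list of class `state_grouping`: `group` (integer 1/2 per motif),
#'   `motif_ids`, `method`, and the linkage object for the Ward route.
#' @export
cluster_transition_matrix <- function(pi, method = c("ward", "kmeans"),
                                      seed = 1) {
  method <- match.arg(method)
  if (nrow(pi) < 2) stop_invalid("need >= 2 motifs to cluster")
  ids <- rownames(pi)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(pi)))
  if (method == "ward") {
    hc <- hclust(dist(pi), method = "ward.D2")
    grp <- cutree(hc, k = 2)
    link <- hc
  } else {
    km <- with_seed(seed, kmeans(pi, centers = 2, nstart = 100))
    grp <- km$cluster
    link <- km
  }
  structure(list(group = as.integer(grp), motif_ids = ids,
                 method = method, linkage = link),
            class = "state_grouping")
}

#' Motif onset events from MAP sequences
#'
#' An onset is any frame whose motif differs from the previous frame's;
#' the first frame of each trial counts as an onset of its motif.
#'
#' @param map_sequences list of per-trial label vectors.
#' @param frame_times list of per-trial frame-time vectors (s), matching
#'   lengths.
#' @return data.frame with `trial`, `motif`, `time_s`, `frame`.
#' @export
motif_onsets <- function(map_sequences, frame_times) {
  out <- list()
  for (i in seq_along(map_sequences)) {
    z <- map_sequences[[i]]; tt <- frame_times[[i]]
    if (length(z) != length(tt)) stop_invalid("labels/times length mismatch")
    on <- c(TRUE, diff(z) != 0)
    on[is.na(on)] <- FALSE
    out[[i]] <- data.frame(trial = i, motif = z[on], time_s = tt[on],
                           frame = which(on) - 1L)
  }
  do.call(rbind, out)
}

#' Motif-onset PSTH of inhalation times
#'
#' Histogram of inhalation times at lags relative to each motif's onsets,
#' normalized to a rate (events per second per onset).
#'
#' @param onsets data.frame from [motif_onsets()] (or a numeric vector of
#'   onset times for a single motif).
#' @param inhalations numeric inhalation times on the same clock.
#' @param window half-window in seconds (default 0.5).
#' @param bin bin width in seconds (default 0.0125, one frame at 80 Hz).
#' @return data.frame with `motif`, `lag_s` (bin centers), `rate`.
#' @export
onset_time_psth <- function(onsets, inhalations, window = 0.5, bin = 0.0125) {
  if (is.numeric(onsets)) onsets <- data.frame(motif = 1L, time_s = onsets)
  if (nrow(onsets) == 0) return(data.frame(motif = integer(0), lag_s = numeric(0), rate = numeric(0)))
  edges <- seq(-window, window, by = bin)
  centers <- head(edges, -1) + bin / 2
  res <- lapply(split(onsets$time_s, onsets$motif), function(ts) {
    lags <- unlist(lapply(ts, function(t0) {
      d <- inhalations - t0
      d[d >= -window & d < window]
    }))
    h <- if (length(lags)) hist(lags, breaks = edges, plot = FALSE)$counts else
      rep(0L, length(centers))
    h / (length(ts) * bin)
  })
  do.call(rbind, lapply(names(res), function(m)
    data.frame(motif = as.integer(m), lag_s = centers, rate = res[[m]])))
}

#' Motif-onset histogram in sniff phase
#'
#' Histogram over \[0, 1) of the sniff phase at each onset; onsets outside
#' a kept sniff are dropped. The mean end-of-inhalation phase is reported
#' alongside when exhalation onsets are available.
#'
#' @param onsets data.frame from [motif_onsets()].
#' @param events `sniff_events` on the same clock.
#' @param n_bins number of phase bins (default 32).
#' @return list: `hist` data.frame (`motif`, `phase` centers, `count`,
#'   `density`), `mean_inhalation_end_phase`.
#' @export
onset_phase_hist <- function(onsets, events, n_bins = 32) {
  ph <- sniff_phase(onsets$time_s, events)
  keep <- !is.na(ph)
  edges <- seq(0, 1, length.out = n_bins + 1)
  centers <- head(edges, -1) + diff(edges) / 2
  res <- lapply(split(ph[keep], onsets$motif[keep]), function(p) {
    h <- hist(p, breaks = edges, plot = FALSE, include.lowest = TRUE)$counts
    data.frame(phase = centers, count = h,
               density = if (sum(h)) h / sum(h) / diff(edges)[1] else h)
  })
  hist_df <- do.call(rbind, lapply(names(res), function(m)
    cbind(motif = as.integer(m), res[[m]])))
  end_ph <- NA_real_
  if (length(events$exhalation_s)) {
    ep <- sniff_phase(events$exhalation_s, events)
    end_ph <- mean(ep, na.rm = TRUE)
  }
  list(hist = hist_df, mean_inhalation_end_phase = end_ph)
}

#' Permutation test of motif-onset modulation in time and phase
#'
#' The observed statistics are the modulation indices of the pooled onset
#' PSTH (time) and phase histogram. The null re-pairs each trial's onset
#' train with another trial's sniff events (random derangement); one-sided
#' p = (1 + #{null >= observed}) / (1 + n).
#'
#' @param onset_trials list of onset-time vectors, one per trial (trial
#'   clock).
#' @param sniff_trials list of `sniff_events`, one per trial.
#' @param n permutations (default 1000).
#' @param window,bin PSTH parameters (seconds).
#' @param n_bins phase-histogram bins.
#' @param seed integer seed.
#' @return list: `mi_time`, `mi_phase`, `p_time`, `p_phase`, `null_time`,
#'   `null_phase`.
#' @export
onset_modulation_test <- function(onset_trials, sniff_trials, n = 1000,
                                  window = 0.2, bin = 0.025, n_bins = 16,
                                  seed = 1) {
  m <- length(onset_trials)
  if (m < 2 || length(sniff_trials) != m) stop_invalid("need >= 2 paired trials")
  edges_t <- seq(-window, window, by = bin)
  edges_p <- seq(0, 1, length.out = n_bins + 1)
  pair_time <- matrix(vector("list", m * m), m, m)
  pair_phase <- matrix(vector("list", m * m), m, m)
  nev <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ons <- onset_trials[[i]]
    ev <- sniff_trials[[j]]
    lags <- unlist(lapply(ons, function(t0) {
      d <- ev$inhalation_s - t0
      d[d >= -window & d < window]
    }))
    ht <- if (length(lags)) hist(lags, breaks = edges_t, plot = FALSE)$counts else
      rep(0L, length(edges_t) - 1L)
    ph <- sniff_phase(ons, ev)
    ph <- ph[!is.na(ph)]
    hp <- if (length(ph)) hist(ph, breaks = edges_p, plot = FALSE,
                               include.lowest = TRUE)$counts else
      rep(0L, n_bins)
    pair_time[[i, j]] <- ht
    pair_phase[[i, j]] <- hp
    nev[i, j] <- length(ons)
  }
  stat_for <- function(pairing) {
    ht <- Reduce(`+`, lapply(seq_len(m), function(i) pair_time[[i, pairing[i]]]))
    hp <- Reduce(`+`, lapply(seq_len(m), function(i) pair_phase[[i, pairing[i]]]))
    c(time = modulation_index(ht), phase = modulation_index(hp))
  }
  obs <- stat_for(seq_len(m))
  null <- with_seed(seed, vapply(seq_len(n), function(k)
    stat_for(derangement(m)), numeric(2)))
  p_time <- (1 + sum(null["time", ] >= obs["time"], na.rm = TRUE)) / (1 + n)
  p_phase <- (1 + sum(null["phase", ] >= obs["phase"], na.rm = TRUE)) / (1 + n)
  list(mi_time = unname(obs["time"]), mi_phase = unname(obs["phase"]),
       p_time = p_time, p_phase = p_phase,
       null_time = null["time", ], null_phase = null["phase", ])
}

#' Relabel frames as investigation or approach
#'
#' Deterministic map from per-frame motif labels to the two-group labels of
#' a [cluster_transition_matrix()] result; motifs not covered by the
#' grouping (e.g. filtered-out rare motifs) become NA.
#'
#' @param map_sequences list of label vectors.
#' @param grouping `state_grouping`.
#' @param labels group names, index by group id (default
#'   c("investigation", "approach")).
#' @return list of character vectors.
#' @export
state_frame_labels <- function(map_sequences, grouping,
                               labels = c("investigation", "approach")) {
  lut <- setNames(labels[grouping$group], grouping$motif_ids)
  lapply(map_sequences, function(z) unname(lut[as.character(z)]))
}

#' Per-motif kinematic and sniff-rate summary
#'
#' Mean nose speed and mean instantaneous sniff rate per motif, z-scored
#' within mouse.
#'
#' @param frames data.frame with columns `mouse`, `motif`, `nose_speed`,
#'   and optionally `sniff_rate` (one row per frame).
#' @return data.frame with per-mouse, per-motif normalized means
#'   (`norm_speed`, `norm_rate`).
#' @export
state_summary <- function(frames) {
  zscore <- function(x) {
    if (length(x) < 2 || sd(x) == 0) return(rep(0, length(x)))
    (x - mean(x)) / sd(x)
  }
  agg <- aggregate(frames[, intersect(c("nose_speed", "sniff_rate"), names(frames)),
                          drop = FALSE],
                   by = list(mouse = frames$mouse, motif = frames$motif),
                   FUN = function(v) mean(v, na.rm = TRUE))
  out <- do.call(rbind, lapply(split(agg, agg$mouse), function(g) {
    g$norm_speed <- zscore(g$nose_speed)
    if ("sniff_rate" %in% names(g)) g$norm_rate <- zscore(g$sniff_rate)
    g
  }))
  rownames(out) <- NULL
  out
}
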