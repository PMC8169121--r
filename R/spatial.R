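# Allocentric spatial statistics over the behavioral arena.
#
# Coordinate frame: the longitudinal axis runs 0 -> 25 cm from the
# initiation-port wall toward the odor ports; the lateral axis runs
# 0 -> 15 cm. Bins tile the arena exactly: 50 x 30 bins at 0.5 cm,
# 25 x 15 at 1 cm (longitudinal x lateral). Maps are stored with lateral
# bins as rows and longitudinal bins as columns.

ARENA_LONG_CM <- 25
ARENA_LAT_CM <- 15

#' Construct a spatial map
#'
#' @param grid numeric matrix, lateral bins x longitudinal bins.
#' @param bin_size bin edge length in cm.
#' @param extent arena rectangle c(long_cm, lat_cm).
#' @param smoothing smoothing record (NULL or the Gaussian sigma in bins).
#' @export
spatial_map <- function(grid, bin_size, extent = c(ARENA_LONG_CM, ARENA_LAT_CM),
                        smoothing = NULL) {
  if (ncol(grid) != round(extent[1] / bin_size) ||
      nrow(grid) != round(extent[2] / bin_size))
    stop_invalid("grid does not tile the arena at this bin size")
  structure(list(grid = grid, bin_size = bin_size, extent = extent,
                 smoothing = smoothing), class = "spatial_map")
}

bin_positions <- function(long, lat, bin_size, extent) {
  ncol_ <- round(extent[1] / bin_size); nrow_ <- round(extent[2] / bin_size)
  ci <- pmin(pmax(floor(long / bin_size) + 1L, 1L), ncol_)
  ri <- pmin(pmax(floor(lat / bin_size) + 1L, 1L), nrow_)
  n_clip <- sum(long < 0 | long > extent[1] | lat < 0 | lat > extent[2],
                na.rm = TRUE)
  list(row = ri, col = ci, n_clipped = n_clip, nrow = nrow_, ncol = ncol_)
}

#' Occupancy map of nose positions
#'
#' 2-D histogram of nose positions over the arena grid. Out-of-arena points
#' are clipped to edge bins; the clipped count is recorded as an attribute.
#'
#' @param long,lat nose coordinates in cm (arena frame).
#' @param bin_size bin size in cm (default 0.5).
#' @param normalize if TRUE, return fraction of frames instead of counts.
#' @param smooth_sigma optional Gaussian smoothing sigma in bins (recorded;
#'   applied to the returned grid).
#' @return `spatial_map`.
#' @export
occupancy_map <- function(long, lat, bin_size = 0.5, normalize = FALSE,
                          smooth_sigma = NULL) {
  ok <- is.finite(long) & is.finite(lat)
  long <- long[ok]; lat <- lat[ok]
  bp <- bin_positions(long, lat, bin_size, c(ARENA_LONG_CM, ARENA_LAT_CM))
  g <- matrix(0, bp$nrow, bp$ncol)
  for (i in seq_along(long)) g[bp$row[i], bp$col[i]] <- g[bp$row[i], bp$col[i]] + 1
  if (normalize && length(long)) g <- g / length(long)
  if (!is.null(smooth_sigma)) g <- gauss_smooth2d(g, smooth_sigma)
  out <- spatial_map(g, bin_size, smoothing = smooth_sigma)
  attr(out, "n_clipped") <- bp$n_clipped
  out
}

#' Sniff-rate map
#'
#' Divides the per-bin inhalation count by the per-bin occupancy count,
#' giving sniffs per frame (multiply by the frame rate for Hz). Bins with
#' zero occupancy are NA.
#'
#' @param sniff_long,sniff_lat positions of the nose at inhalation times (cm).
#' @param occupancy `spatial_map` of frame counts on the same grid.
#' @return `spatial_map` of sniffs per frame.
#' @export
sniff_rate_map <- function(sniff_long, sniff_lat, occupancy) {
  cnt <- occupancy_map(sniff_long, sniff_lat, bin_size = occupancy$bin_size)
  if (!all(dim(cnt$grid) == dim(occupancy$grid)))
    stop_invalid("grid mismatch")
  rate <- cnt$grid / occupancy$grid
  rate[occupancy$grid == 0] <- NA_real_
  spatial_map(rate, occupancy$bin_size, smoothing = occupancy$smoothing)
}

#' Investigation and approach occupancy maps
#'
#' Separate 2-D histograms for frames labeled investigation vs approach
#' (1 cm bins by default). Optionally each bin is normalized to the total
#' labeled occupancy of that bin (inv / (inv + app)).
#'
#' @param long,lat nose positions (cm).
#' @param labels character per-frame labels ("investigation", "approach",
#'   or NA for unlabeled frames, which are dropped).
#' @param bin_size bin size in cm (default 1).
#' @param normalize_total per-bin normalization to inv + app (default FALSE).
#' @return list with `investigation` and `approach` `spatial_map`s.
#' @export
state_occupancy_maps <- function(long, lat, labels, bin_size = 1,
                                 normalize_total = FALSE) {
  keep <- !is.na(labels) & is.finite(long) & is.finite(lat)
  inv <- occupancy_map(long[keep & labels == "investigation"],
                       lat[keep & labels == "investigation"], bin_size)
  app <- occupancy_map(long[keep & labels == "approach"],
                       lat[keep & labels == "approach"], bin_size)
  if (normalize_total) {
    tot <- inv$grid + app$grid
    gi <- inv$grid / tot; ga <- app$grid / tot
    gi[tot == 0] <- NA_real_; ga[tot == 0] <- NA_real_
    inv$grid <- gi; app$grid <- ga
  }
  list(investigation = inv, approach = app)
}

#' Investigation-approach index
#'
#' I.A.I. = (investigation - approach) / (investigation + approach), per
#' bin (both-zero bins are NA). Maps must share a grid. Pass profiles
#' (numeric vectors) to get a profile I.A.I.
#'
#' @param inv,app `spatial_map`s or numeric vectors on the same support.
#' @return `spatial_map` or numeric vector in \[-1, 1\].
#' @export
iai <- function(inv, app) {
  if (inherits(inv, "spatial_map")) {
    if (!all(dim(inv$grid) == dim(app$grid))) stop_invalid("grid mismatch")
    s <- inv$grid + app$grid
    g <- (inv$grid - app$grid) / s
    g[s == 0] <- NA_real_
    out <- inv; out$grid <- g
    return(out)
  }
  s <- inv + app
  out <- (inv - app) / s
  out[s == 0] <- NA_real_
  out
}

#' Flip the lateral axis of right-choice trials
#'
#' Reorients trials with respect to choice: right-choice trials get
#' lateral coordinate y -> arena width - y, so the chosen side always
#' faces the same way. Applying twice is the identity. Trials with missing
#' choice are excluded (recorded in attribute `excluded`).
#'
#' @param session a `session_bundle`.
#' @return reoriented `session_bundle`.
#' @export
reorient_by_choice <- function(session) {
  width <- ARENA_LAT_CM
  excluded <- integer(0)
  keep <- list()
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    ch <- tr$meta$choice
    if (is.null(ch) || is.na(ch)) { excluded <- c(excluded, i); next }
    if (ch == "right") {
      for (col in c("nose_y", "head_y", "body_y"))
        tr$trajectory[[col]] <- width - tr$trajectory[[col]]
    }
    keep[[length(keep) + 1]] <- tr
  }
  session$trials <- keep
  attr(session, "excluded") <- excluded
  session
}

#' Project a spatial map onto an arena axis
#'
#' Sums the map over the orthogonal axis, optionally restricted to a zone
#' (a cm window on the orthogonal coordinate, e.g. the 5-10 cm transition
#' zone when projecting onto the lateral axis).
#'
#' @param map `spatial_map`.
#' @param axis "longitudinal" or "lateral".
#' @param zone optional c(lo, hi) cm window on the orthogonal axis.
#' @return data.frame with `center_cm`, `value`.
#' @export
axis_profile <- function(map, axis = c("longitudinal", "lateral"),
                         zone = NULL) {
  axis <- match.arg(axis)
  bs <- map$bin_size
  long_centers <- (seq_len(ncol(map$grid)) - 0.5) * bs
  lat_centers <- (seq_len(nrow(map$grid)) - 0.5) * bs
  sel_rows <- rep(TRUE, nrow(map$grid)); sel_cols <- rep(TRUE, ncol(map$grid))
  if (!is.null(zone)) {
    if (zone[1] < 0 || zone[2] > max(map$extent)) stop_invalid("zone outside arena")
    if (axis == "longitudinal") sel_rows <- lat_centers >= zone[1] & lat_centers <= zone[2]
    else sel_cols <- long_centers >= zone[1] & long_centers <= zone[2]
  }
  sub <- map$grid[sel_rows, sel_cols, drop = FALSE]
  if (axis == "longitudinal")
    data.frame(center_cm = long_centers[sel_cols],
               value = colSums(sub, na.rm = TRUE))
  else
    data.frame(center_cm = lat_centers[sel_rows],
               value = rowSums(sub, na.rm = TRUE))
}

#' Correct-vs-incorrect permutation test on spatial profiles
#'
#' Observed statistic: grand mean over mice of the per-mouse difference
#' between mean correct-trial and mean incorrect-trial profiles. Null:
#' correct/incorrect labels scrambled within each mouse before re-taking
#' the grand mean (so the null carries both within- and across-mouse
#' variability). Pointwise p = (1 + #{|null| >= |obs|}) / (1 + n).
#'
#' @param mice list; each element a list with `profiles` (trials x bins
#'   matrix) and `correct` (logical per trial). Mice with only one outcome
#'   class are excluded with a warning.
#' @param n permutations (default 1000).
#' @param seed integer seed.
#' @return list: `observed` (bin-wise difference), `null` (n x bins),
#'   `p` (pointwise), `p_max` (family-wise, max-statistic).
#' @export
correct_incorrect_permutation <- function(mice, n = 1000, seed = 1) {
  if (n < 1) stop_invalid("n must be >= 1")
  usable <- vapply(mice, function(m)
    sum(m$correct) >= 1 && sum(!m$correct) >= 1, logical(1))
  if (any(!usable))
    warning(sum(!usable), " mouse/mice with a single outcome class excluded")
  mice <- mice[usable]
  if (length(mice) == 0) stop_invalid("no usable mice")
  diff_for <- function(m, labels) {
    colMeans(m$profiles[labels, , drop = FALSE]) -
      colMeans(m$profiles[!labels, , drop = FALSE])
  }
  observed <- Reduce(`+`, lapply(mice, function(m) diff_for(m, m$correct))) /
    length(mice)
  nb <- length(observed)
  null <- with_seed(seed, {
    t(vapply(seq_len(n), function(k) {
      Reduce(`+`, lapply(mice, function(m) {
        diff_for(m, sample(m$correct))
      })) / length(mice)
    }, numeric(nb)))
  })
  p <- vapply(seq_len(nb), function(j)
    (1 + sum(abs(null[, j]) >= abs(observed[j]))) / (1 + n), numeric(1))
  maxnull <- apply(abs(null), 1, max)
  p_max <- vapply(seq_len(nb), function(j)
    (1 + sum(maxnull >= abs(observed[j]))) / (1 + n), numeric(1))
  list(observed = observed, null = null, p = p, p_max = p_max)
}

#' Split trials by first-turn side
#'
#' Derives the side of the first turn (the first lateral half entered after
#' leaving the initiation-port region) and partitions trials into those
#' where the mouse stayed with the first turn and those where it switched.
#'
#' @param session `session_bundle` with recorded choices.
#' @param long_min longitudinal distance (cm) the mouse must travel before
#'   a turn is scored (default 1).
#' @param lat_margin lateral deviation from the midline (cm) that counts as
#'   a turn (default 1).
#' @return list with `stay` and `switch` trial-index vectors and `excluded`
#'   (trials that never left the port region).
#' @export
split_stay_switch <- function(session, long_min = 1, lat_margin = 1) {
  mid <- ARENA_LAT_CM / 2
  stay <- integer(0); sw <- integer(0); excl <- integer(0)
  left_lat_hi <- session$left_is_high_lat %||% TRUE
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    y <- tr$trajectory$nose_y; x <- tr$trajectory$nose_x
    cand <- which(x > long_min & abs(y - mid) > lat_margin)
    if (length(cand) == 0 || is.na(tr$meta$choice)) { excl <- c(excl, i); next }
    first_side <- if ((y[cand[1]] > mid) == left_lat_hi) "left" else "right"
    if (first_side == tr$meta$choice) stay <- c(stay, i) else sw <- c(sw, i)
  }
  list(stay = stay, switch = sw, excluded = excl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Session performance summary
#'
#' Percent correct, mean trial duration, mean tortuosity, and a binomial
#' test of above-chance performance. 0:0 (odor-omission) trials have no
#' defined correct side and are excluded from the accuracy statistics.
#'
#' @param session `session_bundle`.
#' @return one-row data.frame: `n_trials`, `percent_correct`,
#'   `mean_duration_s`, `mean_tortuosity`, `binomial_p`.
#' @export
session_performance <- function(session) {
  if (length(session$trials) == 0) stop_invalid("empty session")
  correct <- vapply(session$trials, function(tr)
    if (is.null(tr$meta$correct)) NA else tr$meta$correct, logical(1))
  dur <- vapply(session$trials, function(tr)
    tr$meta$end_s - tr$meta$start_s, numeric(1))
  tort <- vapply(session$trials, function(tr)
    tortuosity(tr$trajectory$nose_x, tr$trajectory$nose_y), numeric(1))
  scored <- !is.na(correct)
  pc <- 100 * mean(correct[scored])
  bt <- binom.test(sum(correct[scored]), sum(scored), p = 0.5,
                   alternative = "greater")
  data.frame(n_trials = length(session$trials),
             percent_correct = pc,
             mean_duration_s = mean(dur),
             mean_tortuosity = mean(tort, na.rm = TRUE),
             binomial_p = bt$p.value)
}

#' Pairwise Wilcoxon rank-sum comparison helper
#'
#' @param values numeric outcomes.
#' @param groups group labels.
#' @return data.frame of pairwise group comparisons with rank-sum p-values.
#' @export
compare_groups_ranksum <- function(values, groups) {
  groups <- as.factor(groups)
  levs <- levels(groups)
  out <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) if (i < j) {
    w <- wilcox.test(values[groups == levs[i]], values[groups == levs[j]])
    out[[length(out) + 1]] <- data.frame(group_a = levs[i], group_b = levs[j],
                                         p_value = w$p.value)
  }
  do.call(rbind, out)
}
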