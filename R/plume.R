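# Odor-plume discriminability from gridded PID recordings: mean
# concentration maps and ROC maps for absolute concentration and for the
# local gradient angle, computed over 25 ms chunk means of 2 s trials.

#' Construct a plume grid
#'
#' @param locations data.frame with `row` (1..5 lateral), `col` (1..7
#'   longitudinal), `long_cm`, `lat_cm`.
#' @param trials list; each element a list with `location` (row index into
#'   `locations`), `side` ("left"/"right"), `trace` (numeric PID samples),
#'   `sample_rate` (Hz).
#' @export
plume_grid <- function(locations, trials) {
  lens <- vapply(trials, function(tr) length(tr$trace), 1L)
  if (length(unique(lens)) > 1) stop_invalid("all traces must share a duration")
  structure(list(locations = locations, trials = trials),
            class = "plume_grid")
}

#' Mean concentration map of one stimulus side
#'
#' Per-location mean over all trials and samples of that side.
#'
#' @param grid `plume_grid`.
#' @param side "left" or "right".
#' @return 5 x 7 matrix (lateral rows x longitudinal cols); locations with
#'   no trials are NA.
#' @export
mean_concentration_map <- function(grid, side) {
  out <- matrix(NA_real_, max(grid$locations$row), max(grid$locations$col))
  for (li in seq_len(nrow(grid$locations))) {
    vals <- unlist(lapply(grid$trials, function(tr)
      if (tr$location == li && tr$side == side) mean(tr$trace) else NULL))
    if (length(vals))
      out[grid$locations$row[li], grid$locations$col[li]] <- mean(vals)
  }
  out
}

#' Chunk means of a PID trace
#'
#' Splits a trace into consecutive chunks (default 25 ms, approximately one
#' inhalation) and returns the chunk means; a trailing remainder is
#' dropped.
#'
#' @param trace numeric samples.
#' @param sample_rate Hz.
#' @param chunk chunk length in seconds (default 0.025).
#' @return numeric vector of chunk means.
#' @export
chunk_means <- function(trace, sample_rate, chunk = 0.025) {
  w <- round(chunk * sample_rate)
  if (w < 1 || w > length(trace)) stop_invalid("chunk longer than trace")
  n <- length(trace) %/% w
  colMeans(matrix(trace[seq_len(n * w)], nrow = w))
}

# chunk-mean distributions per location and side
chunk_distributions <- function(grid, chunk = 0.025) {
  lapply(seq_len(nrow(grid$locations)), function(li) {
    by_side <- lapply(c(left = "left", right = "right"), function(sd_) {
      unlist(lapply(grid$trials, function(tr)
        if (tr$location == li && tr$side == sd_)
          chunk_means(tr$trace, tr$sample_rate, chunk) else NULL))
    })
    by_side
  })
}

#' Absolute-concentration discriminability map
#'
#' Per location, compiles the 25 ms chunk means of left and right trials
#' into two distributions and computes the scaled |auROC| = |2 AUC - 1|.
#'
#' @param grid `plume_grid`.
#' @param chunk chunk length in seconds.
#' @return list of class `discriminability_map`: `grid` (5 x 7 matrix of
#'   values in \[0, 1\]), `kind = "absolute"`.
#' @export
auroc_map_absolute <- function(grid, chunk = 0.025) {
  dists <- chunk_distributions(grid, chunk)
  out <- matrix(NA_real_, max(grid$locations$row), max(grid$locations$col))
  for (li in seq_len(nrow(grid$locations))) {
    L <- dists[[li]]$left; R <- dists[[li]]$right
    if (length(L) && length(R))
      out[grid$locations$row[li], grid$locations$col[li]] <- scaled_auroc(L, R)
  }
  structure(list(grid = out, kind = "absolute", levels = NULL),
            class = "discriminability_map")
}

#' Gradient-angle pseudosample distributions
#'
#' Assembles pseudosamples (the j-th chunk mean from every location forms
#' one spatial snapshot), computes the spatial gradient by central
#' differences (one-sided at edges) and the gradient angle per bin, and
#' accumulates per-side angle distributions. Pseudosamples with a missing
#' location are skipped.
#'
#' @param grid `plume_grid`.
#' @param chunk chunk length in seconds.
#' @param pairing "sequential" (default: j-th chunk of j-th trial paired
#'   across locations) or "random".
#' @param seed seed for random pairing.
#' @return list with `left` and `right`: each a 5 x 7 matrix-list of angle
#'   vectors (radians).
#' @export
gradient_pseudosamples <- function(grid, chunk = 0.025,
                                   pairing = c("sequential", "random"),
                                   seed = 1) {
  pairing <- match.arg(pairing)
  nr <- max(grid$locations$row); nc <- max(grid$locations$col)
  res <- list()
  for (sd_ in c("left", "right")) {
    # chunk matrix per location: chunks x 1 vector (pooled across trials)
    chunks_by_loc <- lapply(seq_len(nrow(grid$locations)), function(li) {
      unlist(lapply(grid$trials, function(tr)
        if (tr$location == li && tr$side == sd_)
          chunk_means(tr$trace, tr$sample_rate, chunk) else NULL))
    })
    nmin <- min(vapply(chunks_by_loc, length, 1L))
    if (nmin == 0) stop_invalid("a location has no trials for side ", sd_)
    if (pairing == "random") {
      chunks_by_loc <- with_seed(child_seed(seed, match(sd_, c("left", "right"))),
        lapply(chunks_by_loc, function(v) v[sample.int(length(v))]))
    }
    angles <- array(NA_real_, c(nr, nc, nmin))
    for (j in seq_len(nmin)) {
      field <- matrix(NA_real_, nr, nc)
      for (li in seq_len(nrow(grid$locations)))
        field[grid$locations$row[li], grid$locations$col[li]] <- chunks_by_loc[[li]][j]
      if (any(is.na(field))) next
      g <- grad2d(field)
      angles[, , j] <- atan2(g$gy, g$gx)
    }
    res[[sd_]] <- angles
  }
  res
}

# central differences, one-sided at edges; gx along columns (longitudinal),
# gy along rows (lateral)
grad2d <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 2) {
    gx[, 2:(nc - 1)] <- (f[, 3:nc] - f[, 1:(nc - 2)]) / 2
    gx[, 1] <- f[, 2] - f[, 1]
    gx[, nc] <- f[, nc] - f[, nc - 1]
  }
  if (nr >= 2) {
    gy[2:(nr - 1), ] <- (f[3:nr, ] - f[1:(nr - 2), ]) / 2
    gy[1, ] <- f[2, ] - f[1, ]
    gy[nr, ] <- f[nr, ] - f[nr - 1, ]
  }
  list(gx = gx, gy = gy)
}

#' Gradient-angle discriminability map
#'
#' Scaled |auROC| between the left- and right-trial gradient-angle
#' distributions per bin. Angles are circular; by default each angle is
#' linearized as sin(angle), its lateral component relative to the
#' longitudinal axis, before the ROC (raw radian values available).
#'
#' @param angles output of [gradient_pseudosamples()].
#' @param linearize "sin" (default) or "raw".
#' @return `discriminability_map` with `kind = "gradient"`.
#' @export
auroc_map_gradient <- function(angles, linearize = c("sin", "raw")) {
  linearize <- match.arg(linearize)
  L <- angles$left; R <- angles$right
  nr <- dim(L)[1]; nc <- dim(L)[2]
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    a <- L[r, cc, ]; b <- R[r, cc, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) next
    if (linearize == "sin") { a <- sin(a); b <- sin(b) }
    out[r, cc] <- scaled_auroc(a, b)
  }
  structure(list(grid = out, kind = "gradient", levels = NULL),
            class = "discriminability_map")
}

#' Quantize a discriminability map for display
#'
#' Bins values in \[0, 1\] into at most `levels` equal-width gray levels;
#' idempotent on already-quantized input.
#'
#' @param map `discriminability_map`.
#' @param levels number of levels (default 8).
#' @return quantized `discriminability_map`.
#' @export
quantize_map <- function(map, levels = 8) {
  g <- map$grid
  if (levels < 1) stop_invalid("levels must be >= 1")
  q <- (ceiling(pmax(g, .Machine$double.eps) * levels) - 0.5) / levels
  q[is.na(g)] <- NA_real_
  map$grid <- q
  map$levels <- levels
  map
}
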