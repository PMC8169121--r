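# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed so one user seed can drive several generators.
# Arithmetic in doubles (exact below 2^53) to avoid 32-bit overflow.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_invalid(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper))
  x
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Probability that a random draw from `pos` exceeds a random draw from
#' `neg`, with ties counted one half. This is the standard rank-sum
#' estimator of the auROC.
#'
#' @param pos,neg numeric samples from the two conditions.
#' @return AUC in \[0, 1\].
#' @export
auroc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop_invalid("both samples must be non-empty")
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# |2*AUC - 1|: discriminability scaled to [0, 1].
scaled_auroc <- function(a, b) abs(2 * auroc(a, b) - 1)

# Stratified fold assignment: within each stratum, fold ids are dealt
# round-robin after a seeded shuffle, so class proportions are balanced.
stratified_folds <- function(strata, k, seed = NULL) {
  strata <- as.factor(strata)
  folds <- integer(length(strata))
  with_seed(seed, {
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Exact best-permutation alignment of estimated labels to reference labels
# (maximizes frame agreement). Feasible for small S; every state count used
# in this package's tests is <= 6.
align_labels <- function(ref, est, S) {
  stopifnot(length(ref) == length(est))
  if (S > 8L) stop_invalid("exact permutation alignment supported for S <= 8")
  perms <- permutations_of(S)
  best <- NULL; best_acc <- -1
  for (i in seq_len(nrow(perms))) {
    mapped <- perms[i, est]
    acc <- mean(mapped == ref)
    if (acc > best_acc) { best_acc <- acc; best <- perms[i, ] }
  }
  list(perm = best, accuracy = best_acc, aligned = best[est])
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(i, rest[sub[j, ]])
    }
  }
  out
}

# 2-D Gaussian smoothing with edge renormalization (kernel mass falling
# outside the grid is redistributed, so counts are conserved up to
# normalization). NA cells are ignored and restored as NA.
gauss_smooth2d <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k <- k / sum(k)
  na <- is.na(m)
  m0 <- m; m0[na] <- 0
  w <- matrix(1, nrow(m), ncol(m)); w[na] <- 0
  conv <- function(x) {
    out <- matrix(0, nrow(x), ncol(x))
    for (di in -r:r) for (dj in -r:r) {
      kv <- k[di + r + 1, dj + r + 1]
      si <- pmin(pmax(seq_len(nrow(x)) + di, 1L), nrow(x))
      sj <- pmin(pmax(seq_len(ncol(x)) + dj, 1L), ncol(x))
      out <- out + kv * x[si, sj, drop = FALSE]
    }
    out
  }
  num <- conv(m0); den <- conv(w)
  out <- num / den
  out[na] <- NA_real_
  out
}

# Random derangement (permutation without fixed points) of n >= 2 items,
# by rejection; expected number of tries is e ~ 2.72.
derangement <- function(n) {
  if (n < 2L) stop_invalid("derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

# Multivariate normal log-density rows of X under mean rows MU, covariance Q.
mvn_logdens <- function(X, MU, Q) {
  d <- ncol(Q)
  L <- chol(Q)
  R <- (X - MU) %*% backsolve(L, diag(d))
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + rowSums(R^2))
}
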