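# Decoding trial labels (mouse identity, experimental condition) from
# single-trial empirical motif-transition matrices with a linear
# discriminant and label-shuffle significance.

#' Empirical transition matrix of a single MAP sequence
#'
#' Counts consecutive state pairs n_ab and row-normalizes. Rows with zero
#' outgoing count are imputed uniform and flagged, keeping the feature
#' dimension fixed.
#'
#' @param map_sequence integer labels (1-based), length >= 2.
#' @param S state count.
#' @return list of class `transition_feature`: `pi_hat` (S x S), `counts`,
#'   `undefined_rows` (logical per row).
#' @export
empirical_transition_matrix <- function(map_sequence, S) {
  z <- as.integer(map_sequence)
  if (length(z) < 2) stop_invalid("sequence length must be >= 2")
  if (any(z < 1L | z > S)) stop_invalid("label outside 1..S")
  counts <- matrix(0, S, S)
  for (t in seq_len(length(z) - 1L))
    counts[z[t], z[t + 1L]] <- counts[z[t], z[t + 1L]] + 1
  rs <- rowSums(counts)
  pi_hat <- counts / ifelse(rs == 0, 1, rs)
  undef <- rs == 0
  pi_hat[undef, ] <- 1 / S
  structure(list(pi_hat = pi_hat, counts = counts, undefined_rows = undef),
            class = "transition_feature")
}

#' Flatten transition features into a design matrix
#'
#' @param features list of `transition_feature`s (or of label sequences,
#'   with `S` supplied).
#' @param S state count (needed when raw sequences are passed).
#' @return trials x S^2 numeric matrix.
#' @export
transition_design <- function(features, S = NULL) {
  rows <- lapply(features, function(f) {
    if (!inherits(f, "transition_feature")) f <- empirical_transition_matrix(f, S)
    as.numeric(t(f$pi_hat))
  })
  do.call(rbind, rows)
}

# Pooled-covariance LDA with ridge shrinkage. Transition-probability
# features are exactly collinear (rows sum to 1), so the pooled covariance
# is regularized toward a scaled identity before inversion.
rlda_fit <- function(X, y, lambda = 0.1) {
  y <- as.factor(y)
  classes <- levels(y)
  p <- ncol(X)
  means <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                    numeric(p)))
  Sw <- matrix(0, p, p)
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / max(1, nrow(X) - length(classes))
  gamma <- mean(diag(Sw))
  if (gamma == 0) gamma <- 1
  Sigma <- (1 - lambda) * Sw + lambda * gamma * diag(p)
  Sinv <- solve(Sigma)
  priors <- as.numeric(table(y)[classes]) / length(y)
  list(classes = classes, means = means, Sinv = Sinv, priors = priors)
}

rlda_predict <- function(fit, X) {
  scores <- vapply(seq_along(fit$classes), function(k) {
    mu <- fit$means[k, ]
    drop(X %*% (fit$Sinv %*% mu)) - 0.5 * drop(mu %*% fit$Sinv %*% mu) +
      log(fit$priors[k])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated linear-discriminant decoding
#'
#' Stratified k-fold cross-validation of a shrinkage LDA on flattened
#' empirical transition matrices. Stratification defaults to the class
#' labels but can include finer trial-type strata.
#'
#' @param X trials x features design matrix (see [transition_design()]).
#' @param labels class labels per trial.
#' @param folds number of CV folds (default 5).
#' @param strata optional finer stratification labels.
#' @param lambda shrinkage weight toward the scaled identity (default 0.1).
#' @param seed integer seed (fold assignment).
#' @return list: `confusion` (row-normalized, rows = true class),
#'   `accuracy` (overall), `class_accuracy`, `predicted`, `folds`.
#' @export
lda_decode <- function(X, labels, folds = 5, strata = NULL, lambda = 0.1,
                       seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop_invalid("need >= 2 classes")
  if (is.null(strata)) strata <- labels
  else strata <- interaction(labels, strata, drop = TRUE)
  fid <- stratified_folds(strata, folds, seed = seed)
  pred <- character(length(labels))
  for (f in seq_len(folds)) {
    tr <- fid != f; te <- fid == f
    if (!any(te)) next
    if (nlevels(droplevels(labels[tr])) < nlevels(labels))
      stop_invalid("a class is absent from a training fold; reduce folds")
    fit <- rlda_fit(X[tr, , drop = FALSE], labels[tr], lambda = lambda)
    pred[te] <- rlda_predict(fit, X[te, , drop = FALSE])
  }
  classes <- levels(labels)
  conf <- table(factor(labels, classes), factor(pred, classes))
  conf_norm <- conf / pmax(1, rowSums(conf))
  list(confusion = as.matrix(conf_norm),
       accuracy = mean(pred == as.character(labels)),
       class_accuracy = diag(as.matrix(conf_norm)),
       predicted = pred, folds = fid)
}

#' Label-shuffle significance of decoding accuracy
#'
#' For each CV fold, the training labels are shuffled `n_shuffles` times;
#' each shuffled classifier is evaluated on the unshuffled test fold,
#' building a null accuracy distribution per class. z = (observed - null
#' mean) / null sd per class per fold; z-scores are averaged across folds
#' and converted to a one-sided p by the standard normal tail. Because each
#' fold's z is approximately standard normal under the null, the average of
#' K fold z-scores has standard deviation 1/sqrt(K); the overall p uses
#' that scale (p = 1 - Phi(z_mean * sqrt(K))). A zero-variance null falls
#' back to the exceedance count.
#'
#' @inheritParams lda_decode
#' @param n_shuffles shuffles per fold (default 100).
#' @return list: `z_per_fold` (folds x classes), `z` (fold-averaged per
#'   class), `p` (per class), `observed_class_accuracy`, plus overall
#'   `z_overall`, `p_overall`.
#' @export
shuffle_significance <- function(X, labels, folds = 5, strata = NULL,
                                 n_shuffles = 100, lambda = 0.1, seed = 1) {
  if (n_shuffles < 1) stop_invalid("n_shuffles must be >= 1")
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (is.null(strata)) str_ <- labels
  else str_ <- interaction(labels, strata, drop = TRUE)
  fid <- stratified_folds(str_, folds, seed = seed)
  nclass <- length(classes)
  zf <- matrix(NA_real_, folds, nclass, dimnames = list(NULL, classes))
  zo <- numeric(folds)
  obs_acc <- matrix(NA_real_, folds, nclass)
  exceed <- matrix(0, folds, nclass)
  with_seed(child_seed(seed, 2), {
    for (f in seq_len(folds)) {
      tr <- fid != f; te <- fid == f
      ytr <- labels[tr]; yte <- labels[te]
      fit <- rlda_fit(X[tr, , drop = FALSE], ytr, lambda = lambda)
      pred <- rlda_predict(fit, X[te, , drop = FALSE])
      class_acc <- vapply(classes, function(k)
        if (any(yte == k)) mean(pred[yte == k] == k) else NA_real_, numeric(1))
      obs_acc[f, ] <- class_acc
      nullmat <- matrix(NA_real_, n_shuffles, nclass)
      nullall <- numeric(n_shuffles)
      for (b in seq_len(n_shuffles)) {
        ysh <- ytr[sample.int(length(ytr))]
        fitb <- rlda_fit(X[tr, , drop = FALSE], ysh, lambda = lambda)
        predb <- rlda_predict(fitb, X[te, , drop = FALSE])
        nullmat[b, ] <- vapply(classes, function(k)
          if (any(yte == k)) mean(predb[yte == k] == k) else NA_real_, numeric(1))
        nullall[b] <- mean(predb == as.character(yte))
      }
      mu <- colMeans(nullmat, na.rm = TRUE)
      sg <- apply(nullmat, 2, sd, na.rm = TRUE)
      zf[f, ] <- ifelse(sg > 0, (class_acc - mu) / sg, NA_real_)
      exceed[f, ] <- colSums(sweep(nullmat, 2, class_acc, `>=`), na.rm = TRUE)
      sa <- sd(nullall)
      zo[f] <- if (sa > 0) (mean(pred == as.character(yte)) - mean(nullall)) / sa else NA
    }
  })
  z <- colMeans(zf, na.rm = TRUE)
  k_used <- colSums(is.finite(zf))
  p <- pnorm(z * sqrt(pmax(k_used, 1)), lower.tail = FALSE)
  # zero-variance fallback: exceedance count across all folds' shuffles
  degenerate <- !is.finite(z)
  if (any(degenerate)) {
    pc <- (1 + colSums(exceed)) / (1 + folds * n_shuffles)
    p[degenerate] <- pc[degenerate]
  }
  z_overall <- mean(zo, na.rm = TRUE)
  ko <- sum(is.finite(zo))
  list(z_per_fold = zf, z = z, p = p,
       observed_class_accuracy = colMeans(obs_acc, na.rm = TRUE),
       z_overall = z_overall,
       p_overall = pnorm(z_overall * sqrt(max(ko, 1)), lower.tail = FALSE))
}
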