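# Bayesian auto-regressive hidden Markov model.
#
# Generative model: a hidden state sequence z_t follows a Markov chain with
# row-stochastic transition matrix pi and uniform initial distribution; given
# z_t = z, the observed trajectory evolves as
#     x_t = A_z x_{t-1} + b_z + eps_t,   eps_t ~ N(0, Q_z),
# with the first frame of every trial conditioned on (the AR likelihood runs
# from t = 2). Inference is conjugate Gibbs sampling: Dirichlet rows for pi,
# matrix-normal-inverse-Wishart for (A_z, b_z, Q_z), exact forward-filter
# backward-sample sweeps for the state sequences.

#' Construct AR-HMM parameters
#'
#' @param pi S x S row-stochastic transition matrix.
#' @param A list of S d x d dynamics matrices.
#' @param b list of S length-d drift vectors.
#' @param Q list of S d x d SPD noise covariances.
#' @param init initial state distribution (default uniform).
#' @return an object of class `arhmm_params`.
#' @export
arhmm_params <- function(pi, A, b, Q, init = NULL) {
  S <- nrow(pi)
  d <- nrow(A[[1]])
  if (ncol(pi) != S) stop_invalid("pi must be square")
  if (any(abs(rowSums(pi) - 1) > 1e-8)) stop_invalid("rows of pi must sum to 1")
  if (length(A) != S || length(b) != S || length(Q) != S)
    stop_invalid("A, b, Q must have one element per state")
  if (is.null(init)) init <- rep(1 / S, S)
  structure(list(S = S, d = d, pi = pi, init = init, A = A, b = b, Q = Q),
            class = "arhmm_params")
}

#' Prior hyperparameters for the AR-HMM
#'
#' Defaults follow the conjugate specification used throughout the package:
#' Dirichlet transition rows with uniform mean and total concentration
#' `alpha = 4`; inverse-Wishart noise covariance with identity scale and
#' `d + 2` degrees of freedom; matrix-normal prior on \[A_z, b_z\] with mean
#' \[I, 0\], row covariance Q_z and identity column covariance.
#'
#' @param d trajectory dimension.
#' @param alpha Dirichlet concentration (total mass per row).
#' @param alpha_per_cell if TRUE, put `alpha` in every Dirichlet cell instead
#'   of splitting `alpha` uniformly across the row.
#' @param iw_scale d x d inverse-Wishart scale matrix.
#' @param iw_dof inverse-Wishart degrees of freedom (> d - 1).
#' @param mean_A,mean_b prior means of A_z and b_z.
#' @param col_cov (d+1) x (d+1) column covariance of \[A_z, b_z\].
#' @return an object of class `arhmm_prior`.
#' @export
arhmm_prior <- function(d, alpha = 4, alpha_per_cell = FALSE,
                        iw_scale = diag(d), iw_dof = d + 2,
                        mean_A = diag(d), mean_b = rep(0, d),
                        col_cov = diag(d + 1)) {
  check_scalar(alpha, "alpha", lower = 1e-12)
  if (iw_dof <= d - 1) stop_invalid("iw_dof must exceed d - 1")
  structure(list(d = d, alpha = alpha, alpha_per_cell = alpha_per_cell,
                 iw_scale = iw_scale, iw_dof = iw_dof,
                 M0 = cbind(mean_A, mean_b), col_cov = col_cov),
            class = "arhmm_prior")
}

#' Gibbs sampler configuration
#'
#' @param n_iter total Gibbs iterations (default 300).
#' @param n_burn burn-in iterations discarded (default 200).
#' @param seed integer seed.
#' @export
gibbs_config <- function(n_iter = 300, n_burn = 200, seed = 1) {
  if (n_burn >= n_iter) stop_invalid("n_burn must be < n_iter")
  list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
       seed = as.integer(seed))
}

# T x S matrix of emission log-likelihoods; row 1 is zero because x_1 is
# conditioned on, not modeled.
emission_loglik <- function(params, x) {
  x <- as.matrix(x)
  T_ <- nrow(x); S <- params$S
  logB <- matrix(0, T_, S)
  if (T_ < 2) return(logB)
  xprev <- x[-T_, , drop = FALSE]
  xcur <- x[-1, , drop = FALSE]
  for (s in seq_len(S)) {
    MU <- xprev %*% t(params$A[[s]]) +
      matrix(params$b[[s]], T_ - 1, params$d, byrow = TRUE)
    logB[-1, s] <- mvn_logdens(xcur, MU, params$Q[[s]])
  }
  logB
}

#' Exact joint log-likelihood of trajectories and label sequences
#'
#' Evaluates, for each trial, the sum over t >= 2 of the transition log
#' probability and the state-conditional Gaussian AR log density, and adds
#' the log initial-state probability.
#'
#' @param params `arhmm_params`.
#' @param trials list of T x d trajectory matrices.
#' @param labels list of integer label vectors (1-based), same lengths.
#' @param include_init include the log initial-distribution term
#'   (default TRUE; a uniform initial distribution only shifts the value by
#'   -log(S) per trial).
#' @return scalar log-likelihood.
#' @export
log_joint_likelihood <- function(params, trials, labels, include_init = TRUE) {
  if (length(trials) != length(labels)) stop_invalid("trials/labels length mismatch")
  total <- 0
  for (i in seq_along(trials)) {
    x <- as.matrix(trials[[i]])
    z <- as.integer(labels[[i]])
    T_ <- nrow(x)
    if (T_ < 2) stop_invalid("trial lengths must be >= 2")
    if (length(z) != T_) stop_invalid("labels must match trajectory length")
    if (any(z < 1L | z > params$S)) stop_invalid("label outside 1..S")
    if (ncol(x) != params$d) stop_invalid("trajectory dimension mismatch")
    logB <- emission_loglik(params, x)
    total <- total + sum(log(params$pi[cbind(z[-T_], z[-1])])) +
      sum(logB[cbind(2:T_, z[-1])])
    if (include_init) total <- total + log(params$init[z[1]])
  }
  total
}

#' Sample a state sequence from its exact conditional posterior
#'
#' Forward-filter backward-sample draw from P(z_1:T | x_1:T, theta).
#'
#' @param params `arhmm_params`.
#' @param trial T x d trajectory matrix.
#' @param seed optional seed.
#' @return integer vector of 1-based labels.
#' @export
sample_states <- function(params, trial, seed = NULL) {
  logB <- emission_loglik(params, as.matrix(trial))
  with_seed(seed, {
    u <- runif(nrow(logB))
    as.integer(ffbs_sample_cpp(logB, params$pi, params$init, u))
  })
}

# Exact time-wise posterior state marginals for fixed parameters.
state_marginals <- function(params, trial) {
  logB <- emission_loglik(params, as.matrix(trial))
  forward_backward_cpp(logB, params$pi, params$init)
}

#' Draw model parameters from their conditional posterior
#'
#' Conjugate updates: each transition row is Dirichlet(prior mass +
#' transition counts); each state's (A_z, b_z, Q_z) is drawn from the
#' matrix-normal-inverse-Wishart posterior given the regression statistics
#' of the frames currently assigned to that state. States with no assigned
#' frames draw from the prior.
#'
#' @param trials list of T x d matrices.
#' @param labels list of label vectors.
#' @param S state count.
#' @param prior `arhmm_prior`.
#' @param seed optional seed.
#' @return `arhmm_params` draw.
#' @export
sample_params <- function(trials, labels, S, prior, seed = NULL) {
  d <- prior$d
  # transition counts
  N <- matrix(0, S, S)
  for (z in labels) {
    T_ <- length(z)
    if (T_ >= 2) {
      pairs <- cbind(z[-T_], z[-1])
      for (r in seq_len(nrow(pairs))) N[pairs[r, 1], pairs[r, 2]] <- N[pairs[r, 1], pairs[r, 2]] + 1
    }
  }
  # regression sufficient statistics per state (responses x_t, t >= 2)
  X_by <- vector("list", S); Z_by <- vector("list", S)
  for (i in seq_along(trials)) {
    x <- as.matrix(trials[[i]]); z <- labels[[i]]
    T_ <- nrow(x)
    if (T_ < 2) next
    zt <- z[-1]
    Xc <- x[-1, , drop = FALSE]
    Zc <- cbind(x[-T_, , drop = FALSE], 1)
    for (s in unique(zt)) {
      sel <- zt == s
      X_by[[s]] <- rbind(X_by[[s]], Xc[sel, , drop = FALSE])
      Z_by[[s]] <- rbind(Z_by[[s]], Zc[sel, , drop = FALSE])
    }
  }
  a0 <- if (isTRUE(prior$alpha_per_cell)) prior$alpha else prior$alpha / S
  K0inv <- solve(prior$col_cov)
  with_seed(seed, {
    pi <- t(apply(N, 1, function(row) {
      g <- rgamma(S, shape = a0 + row, rate = 1)
      g / sum(g)
    }))
    A <- vector("list", S); b <- vector("list", S); Q <- vector("list", S)
    for (s in seq_len(S)) {
      X <- X_by[[s]]; Z <- Z_by[[s]]
      n <- if (is.null(X)) 0L else nrow(X)
      if (n == 0L) {
        Szz <- K0inv
        Mn <- prior$M0
        Sn <- matrix(0, d, d)
      } else {
        Szz <- crossprod(Z) + K0inv
        Sxz <- crossprod(X, Z) + prior$M0 %*% K0inv
        Mn <- Sxz %*% solve(Szz)
        Sxx <- crossprod(X) + prior$M0 %*% K0inv %*% t(prior$M0)
        Sn <- Sxx - Mn %*% Szz %*% t(Mn)
        Sn <- (Sn + t(Sn)) / 2
      }
      Psi <- prior$iw_scale + Sn
      nu <- prior$iw_dof + n
      Qs <- draw_inv_wishart(Psi, nu)
      Vn <- solve(Szz)
      Vn <- (Vn + t(Vn)) / 2
      LQ <- t(safe_chol(Qs))
      LV <- t(safe_chol(Vn))
      W <- Mn + LQ %*% matrix(rnorm(d * (d + 1)), d, d + 1) %*% t(LV)
      A[[s]] <- W[, seq_len(d), drop = FALSE]
      b[[s]] <- W[, d + 1]
      Q[[s]] <- Qs
    }
    arhmm_params(pi = pi, A = A, b = b, Q = Q)
  })
}

draw_inv_wishart <- function(Psi, nu) {
  d <- nrow(Psi)
  W <- rWishart(1, df = nu, Sigma = solve(Psi))[, , 1]
  Q <- solve(W)
  (Q + t(Q)) / 2
}

# Cholesky with a tiny jitter retry; posterior scatter matrices can be
# numerically semi-definite.
safe_chol <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) out <- chol(M + 1e-10 * diag(nrow(M)))
  out
}

#' Fit an AR-HMM by Gibbs sampling
#'
#' Alternates exact state-sequence draws (all trials) and conjugate
#' parameter draws. After burn-in, retained draws yield per-frame posterior
#' state marginals (draw frequencies), the posterior-mean parameters, and
#' time-wise MAP label sequences.
#'
#' The joint posterior is multimodal (e.g. a single near-unit-root state
#' can absorb several spatially separated regimes), and a blocked Gibbs
#' chain rarely crosses between modes. `n_restarts` therefore runs
#' independent chains from fresh iid-uniform label initializations and
#' keeps the chain with the highest joint log-likelihood at its final
#' sweep.
#'
#' @param trials list of T x d trajectory matrices (each T >= 2).
#' @param S number of states (motifs).
#' @param prior `arhmm_prior` (default: `arhmm_prior(d)` with package
#'   defaults).
#' @param cfg `gibbs_config`; defaults retain 100 of 300 iterations.
#' @param n_restarts independent chains (default 3); restart seeds are
#'   derived deterministically from `cfg$seed`.
#' @return an `arhmm_fit` with elements `samples` (retained parameter
#'   draws), `posterior_marginals`, `expected_params`, `map_sequences`,
#'   `final_joint_loglik`.
#' @export
gibbs_fit <- function(trials, S, prior = NULL, cfg = gibbs_config(),
                      n_restarts = 3) {
  fits <- lapply(seq_len(n_restarts), function(r) {
    cfg_r <- cfg
    if (r > 1) cfg_r$seed <- child_seed(cfg$seed, 7000 + r)
    gibbs_chain(trials, S, prior, cfg_r)
  })
  lls <- vapply(fits, `[[`, numeric(1), "final_joint_loglik")
  fits[[which.max(lls)]]
}

gibbs_chain <- function(trials, S, prior, cfg) {
  if (length(trials) < 1L) stop_invalid("need at least one trial")
  trials <- lapply(trials, as.matrix)
  if (any(vapply(trials, nrow, 1L) < 2L)) stop_invalid("each trial needs >= 2 frames")
  d <- ncol(trials[[1]])
  if (is.null(prior)) prior <- arhmm_prior(d)
  n_keep <- cfg$n_iter - cfg$n_burn
  Tlens <- vapply(trials, nrow, 1L)
  counts <- lapply(Tlens, function(T_) matrix(0L, T_, S))
  samples <- vector("list", n_keep)
  with_seed(cfg$seed, {
    labels <- lapply(Tlens, function(T_) sample.int(S, T_, replace = TRUE))
    for (it in seq_len(cfg$n_iter)) {
      params <- sample_params(trials, labels, S, prior)
      for (i in seq_along(trials)) {
        logB <- emission_loglik(params, trials[[i]])
        u <- runif(Tlens[i])
        labels[[i]] <- as.integer(ffbs_sample_cpp(logB, params$pi, params$init, u))
      }
      if (it > cfg$n_burn) {
        samples[[it - cfg$n_burn]] <- params
        for (i in seq_along(trials)) {
          idx <- cbind(seq_len(Tlens[i]), labels[[i]])
          counts[[i]][idx] <- counts[[i]][idx] + 1L
        }
      }
    }
  })
  marginals <- lapply(counts, function(m) m / n_keep)
  map_sequences <- lapply(marginals, function(m) max.col(m, ties.method = "first"))
  expected <- average_params(samples)
  final_ll <- log_joint_likelihood(samples[[n_keep]], trials, labels)
  structure(list(S = S, d = d, prior = prior, cfg = cfg,
                 samples = samples, posterior_marginals = marginals,
                 expected_params = expected, map_sequences = map_sequences,
                 final_joint_loglik = final_ll),
            class = "arhmm_fit")
}

# Posterior mean over retained draws; transition rows renormalized to guard
# against rounding.
average_params <- function(samples) {
  S <- nrow(samples[[1]]$pi); d <- samples[[1]]$d
  n <- length(samples)
  pi <- Reduce(`+`, lapply(samples, `[[`, "pi")) / n
  pi <- pi / rowSums(pi)
  A <- lapply(seq_len(S), function(s) Reduce(`+`, lapply(samples, function(p) p$A[[s]])) / n)
  b <- lapply(seq_len(S), function(s) Reduce(`+`, lapply(samples, function(p) p$b[[s]])) / n)
  Q <- lapply(seq_len(S), function(s) Reduce(`+`, lapply(samples, function(p) p$Q[[s]])) / n)
  arhmm_params(pi = pi, A = A, b = b, Q = Q)
}

#' Held-out log-likelihood under a fitted model
#'
#' Marginalizes the hidden states by the forward algorithm (uniform initial
#' distribution, AR emissions from the second frame of each trial).
#'
#' @param params `arhmm_params` (typically `fit$expected_params`).
#' @param trials list of T x d matrices.
#' @return scalar log P(x | theta) summed over trials.
#' @export
heldout_loglik <- function(params, trials) {
  sum(vapply(trials, function(x) {
    logB <- emission_loglik(params, as.matrix(x))
    forward_loglik_cpp(logB, params$pi, params$init)
  }, numeric(1)))
}

#' Number of free parameters of an S-state, d-dimensional AR-HMM
#'
#' S(S-1) transition parameters plus, per state, d^2 for A_z, d for b_z and
#' d(d+1)/2 for the symmetric Q_z.
#'
#' @param S state count.
#' @param d trajectory dimension.
#' @return integer count.
#' @export
n_free_parameters <- function(S, d) {
  if (S < 1 || d < 1) stop_invalid("S and d must be >= 1")
  as.integer(S * (S - 1) + 3 * S * d * (d + 1) / 2)
}

#' Retain motifs by frame usage
#'
#' Keeps motif ids whose share of assigned frames is at least `threshold`
#' (rare-motif exclusion).
#'
#' @param map_sequences list of label vectors.
#' @param threshold minimum frame share (default 0.05).
#' @return integer vector of retained motif ids.
#' @export
usage_filter <- function(map_sequences, threshold = 0.05) {
  z <- unlist(map_sequences)
  if (length(z) == 0L) stop_invalid("empty sequences")
  share <- table(z) / length(z)
  sort(as.integer(names(share)[share >= threshold]))
}

#' Cross-validated model-size scan
#'
#' Splits trials into train/test, fits one AR-HMM per candidate S on the
#' training trials and evaluates the held-out log-likelihood on the test
#' trials.
#'
#' @param trials list of T x d matrices (>= 2 trials).
#' @param S_list candidate state counts.
#' @param prior optional `arhmm_prior`.
#' @param cfg `gibbs_config`.
#' @param split_seed seed for the train/test split.
#' @param train_frac fraction of trials used for fitting (default 0.5).
#' @return data.frame with columns S, heldout_loglik, n_train, n_test.
#' @export
crossval_model_scan <- function(trials, S_list, prior = NULL,
                                cfg = gibbs_config(), split_seed = 1,
                                train_frac = 0.5) {
  if (length(S_list) == 0L) stop_invalid("S_list must be non-empty")
  if (length(trials) < 2L) stop_invalid("need >= 2 trials to split")
  n <- length(trials)
  idx <- with_seed(split_seed, sample.int(n, max(1L, round(train_frac * n))))
  train <- trials[idx]; test <- trials[-idx]
  res <- lapply(S_list, function(S) {
    fit <- gibbs_fit(train, S, prior = prior, cfg = cfg)
    data.frame(S = S, heldout_loglik = heldout_loglik(fit$expected_params, test),
               n_train = length(train), n_test = length(test))
  })
  do.call(rbind, res)
}
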