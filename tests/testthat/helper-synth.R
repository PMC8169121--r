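# Shared fixture builders; everything generated in code at test time.

# Markov-chain label sequences with given self-transition persistence.
markov_seqs <- function(persistence, n, T_, S = 2, seed = 1) {
  p <- matrix((1 - persistence) / (S - 1), S, S)
  diag(p) <- persistence
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    z <- integer(T_)
    z[1] <- sample.int(S, 1)
    for (t in 2:T_) z[t] <- sample.int(S, 1, prob = p[z[t - 1], ])
    z
  })
}

# Trials of sniff-locked kinematics + matched sniff trains.
locked_trial_set <- function(depth, n_trials, dur = 6, rate = 7,
                             noise_sd = 0.05, seed0 = 1) {
  kin <- vector("list", n_trials)
  sn <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    g <- gen_sniff_trace(dur, rate, sample_rate = 1000, seed = seed0 + i)
    kin[[i]] <- gen_sniff_locked_kinematics(g$true_events, depth = depth,
                                            noise_sd = noise_sd, duration = dur,
                                            seed = seed0 + 1000 + i)
    sn[[i]] <- g$true_events$inhalation_s
  }
  list(kin = kin, sniffs = sn)
}

# Small toy AR-HMM with hand-set parameters (S=2, d=1).
toy_params <- function() {
  arhmm_params(pi = matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
               A = list(matrix(0.5), matrix(0.9)),
               b = list(0.5, -0.3),
               Q = list(matrix(0.2), matrix(0.3)))
}

# Exhaustive posterior over label sequences of a toy trial; returns
# time-wise marginals of state 1 and the marginal log-likelihood.
enumerate_posterior <- function(params, x) {
  T_ <- nrow(x)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(params$S)), T_)))
  lp <- apply(seqs, 1, function(z)
    log_joint_likelihood(params, list(x), list(as.integer(z))))
  m <- max(lp)
  w <- exp(lp - m)
  ll <- m + log(sum(w))
  w <- w / sum(w)
  marg <- vapply(seq_len(T_), function(t)
    vapply(seq_len(params$S), function(s) sum(w[seqs[, t] == s]), numeric(1)),
    numeric(params$S))
  list(marginals = t(marg), loglik = ll)
}

# Frame agreement between estimated grouping labels and planted epochs
# after majority mapping.
epoch_agreement <- function(est, truth) {
  ok <- !is.na(est)
  tab <- table(est[ok], truth[ok])
  maj <- colnames(tab)[apply(tab, 1, which.max)]
  names(maj) <- rownames(tab)
  mean(maj[est[ok]] == as.character(truth[ok]))
}

# Brute-force pair-counting AUC oracle: P(pos > neg) + 0.5 P(tie).
auc_paircount <- function(pos, neg) {
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}
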