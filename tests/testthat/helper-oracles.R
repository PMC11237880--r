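# Independent oracles and small fixture builders used across the suite.

# Exhaustive enumeration over all K^T state sequences: exact posterior state
# marginals, log evidence, and the most probable sequence. Independent of
# the package's recursions.
enum_hmm <- function(log_obs, transition, initial) {
  T_len <- nrow(log_obs)
  K <- ncol(log_obs)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(seqs, 1, function(s) {
    v <- log(initial[s[1]]) + log_obs[1, s[1]]
    if (T_len > 1) {
      for (t in 2:T_len) v <- v + log(transition[s[t - 1], s[t]]) +
          log_obs[t, s[t]]
    }
    v
  })
  m <- max(lp)
  logz <- m + log(sum(exp(lp - m)))
  w <- exp(lp - logz)
  gamma <- matrix(0, T_len, K)
  for (t in seq_len(T_len)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(w[seqs[, t] == k])
  }
  list(gamma = gamma, log_evidence = logz,
       best_path = seqs[which.max(lp), ], best_logp = max(lp))
}

# Direct access to the decoding recursion for oracle comparisons on raw
# (log-likelihood, transition, initial) triples.
viterbi_cpp_wrapper <- function(logb, A, p0) {
  brainstates:::viterbi_cpp(logb, log(A), log(p0))
}

# All permutations of 1..n (for brute-force assignment checks).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (i in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = i)
  }
  out
}

# Brute-force maximum-trace matching of a score matrix.
brute_best_match <- function(R) {
  n <- nrow(R)
  best <- -Inf
  for (p in all_perms(n)) {
    v <- sum(R[cbind(seq_len(n), unlist(p))])
    if (v > best) best <- v
  }
  best
}

# Well-separated Gaussian HMM group data with known chains.
make_sep_runs <- function(K, n_runs, T_len, C = 4, separation = 4,
                          stay = 0.85, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(K * C), K, C)
  if (K > 1) {
    d <- as.matrix(dist(mu))
    mu <- mu * separation / min(d[upper.tri(d)])
  }
  A <- brainstates:::make_transition(K, stay)
  chains <- lapply(seq_len(n_runs), function(i)
    simulate_chain(A, rep(1 / K, K), T_len, seed = seed * 1000 + i))
  runs <- lapply(seq_len(n_runs), function(i) {
    ch <- chains[[i]]
    mu[ch, , drop = FALSE] + matrix(rnorm(T_len * C), T_len, C)
  })
  list(runs = runs, chains = chains, means = mu, transition = A, K = K)
}

# Match model states to true states by the confusion matrix of decoded vs
# true paths; returns the permutation p with p[true_state] = model_state.
match_states_by_confusion <- function(true_paths, decoded_paths, K) {
  conf <- matrix(0, K, K)
  for (i in seq_along(true_paths)) {
    tp <- true_paths[[i]]
    dp <- decoded_paths[[i]]
    for (t in seq_along(tp)) conf[tp[t], dp[t]] <- conf[tp[t], dp[t]] + 1
  }
  brainstates:::solve_assignment(-conf)
}

# Decoded-vs-true accuracy after optimal state relabelling.
matched_accuracy <- function(true_paths, decoded_paths, K) {
  p <- match_states_by_confusion(true_paths, decoded_paths, K)
  num <- 0; den <- 0
  for (i in seq_along(true_paths)) {
    num <- num + sum(p[true_paths[[i]]] == decoded_paths[[i]])
    den <- den + length(true_paths[[i]])
  }
  num / den
}
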