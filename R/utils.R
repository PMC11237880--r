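# Internal numeric and validation helpers.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible child seed
#'
#' All randomness in a study flows from one integer seed. Child seeds for
#' individual runs/stages are derived by folding integer or character tags
#' into a 31-bit multiplicative-congruential state (multiplier 48271, the
#' MINSTD generator), so regenerating any single run is stable regardless of
#' generation order.
#'
#' @param seed Parent integer seed.
#' @param ... Integer or character tags identifying the child stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  for (tag in list(...)) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (v in as.numeric(tag)) {
      h <- (h * 48271 + (abs(v) %% m) + 1) %% m
      if (h == 0) h <- 1
    }
  }
  as.integer(h)
}

stop_param <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "brainstates_parameter_error")
}

stop_compute <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "brainstates_computation_error")
}

check_prob_rows <- function(mat, tol = 1e-9, what = "transition matrix") {
  if (any(mat < 0)) stop_param("%s has negative entries", what)
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > tol)) {
    stop_param("%s rows must sum to 1 (max deviation %.3g)", what,
               max(abs(rs - 1)))
  }
  invisible(mat)
}

check_simplex <- function(p, tol = 1e-9, what = "initial distribution") {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    stop_param("%s must be a probability vector summing to 1", what)
  }
  invisible(p)
}

check_spd <- function(S, what = "covariance") {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop_param("%s is not symmetric positive definite (min eigenvalue %.3g)",
               what, min(ev))
  }
  invisible(S)
}

# Draw n multivariate normal rows with mean mu and covariance Sigma using a
# Cholesky factor; standard-normal draws are consumed row-major so output is
# reproducible under a fixed RNG state.
rmvn_chol <- function(n, mu, Sigma) {
  C <- length(mu)
  Z <- matrix(rnorm(n * C), nrow = n)
  Z %*% chol(Sigma) + matrix(mu, n, C, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
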