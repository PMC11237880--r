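# Group-level Gaussian-observation HMM: variational-Bayes inference with a
# Normal-Inverse-Wishart emission posterior and Dirichlet transition/initial
# posteriors, exact forward-backward smoothing, and Viterbi decoding.

as_run_table <- function(data) {
  if (is.matrix(data)) {
    data <- list(data)
  }
  if (is.data.frame(data)) {
    if (!"data" %in% names(data)) {
      stop_param("run table must have a 'data' list-column of matrices")
    }
    tbl <- tibble::as_tibble(data)
    if (!"period" %in% names(tbl)) tbl$period <- 1
    if (!"subject" %in% names(tbl)) tbl$subject <- sprintf("run-%02d", seq_len(nrow(tbl)))
    if (!"run" %in% names(tbl)) tbl$run <- seq_len(nrow(tbl))
    if (!"condition" %in% names(tbl)) tbl$condition <- NA_character_
    if (!"modality" %in% names(tbl)) tbl$modality <- NA_character_
    return(tbl)
  }
  if (is.list(data)) {
    return(tibble::tibble(
      subject = sprintf("run-%02d", seq_along(data)),
      run = seq_along(data),
      condition = NA_character_,
      modality = NA_character_,
      period = vapply(data, function(m) attr(m, "period") %||% 1, 0),
      data = data
    ))
  }
  stop_param("data must be a run tibble, a list of matrices, or a matrix")
}

#' Standardise run amplitudes
#'
#' Scales every channel of every run to mean 0 and standard deviation 1, the
#' amplitude standardisation applied to all HMM inputs. With
#' `scope = "subject"` the centring/scaling statistics are pooled across a
#' subject's runs (per modality) instead of computed per run.
#'
#' @param data A run tibble (as produced by [make_study()]`$runs`), a list of
#'   `T x C` matrices, or a single matrix.
#' @param scope `"run"` (default) or `"subject"`.
#' @return The same structure with standardized `data` matrices.
#' @export
standardize_runs <- function(data, scope = c("run", "subject")) {
  scope <- match.arg(scope)
  single <- is.matrix(data)
  tbl <- as_run_table(data)
  scale_mat <- function(m, centre, scl, label) {
    bad <- which(scl < 1e-12)
    if (length(bad)) {
      stop_compute("zero-variance channel '%s' in run %s",
                   (colnames(m) %||% as.character(seq_len(ncol(m))))[bad[1]],
                   label)
    }
    sweep(sweep(m, 2, centre), 2, scl, "/")
  }
  if (scope == "run") {
    tbl$data <- purrr::pmap(list(tbl$data, tbl$subject, tbl$run),
      function(m, s, r) {
        if (nrow(m) < 2) stop_param("runs need at least 2 samples per channel")
        out <- scale_mat(m, colMeans(m), apply(m, 2, sd),
                         sprintf("%s/%s", s, r))
        attributes(out)[c("period", "duration", "modality")] <-
          attributes(m)[c("period", "duration", "modality")]
        out
      })
  } else {
    key <- paste(tbl$subject, tbl$modality)
    for (k in unique(key)) {
      idx <- which(key == k)
      pooled <- do.call(rbind, tbl$data[idx])
      ctr <- colMeans(pooled)
      scl <- apply(pooled, 2, sd)
      tbl$data[idx] <- lapply(tbl$data[idx], function(m)
        scale_mat(m, ctr, scl, k))
    }
  }
  if (single) tbl$data[[1]] else tbl
}

#' Prior hyperparameters for the variational HMM
#'
#' Dirichlet priors on the transition rows and initial distribution, and a
#' Normal-Inverse-Wishart prior on each state's (mean, covariance). Defaults
#' are weakly informative on standardized data: concentration 1, prior mean
#' 0, mean-precision 0.1, identity scale, and `C + 2` degrees of freedom
#' (the smallest integer dof with a finite covariance mean).
#'
#' @param dirichlet Dirichlet concentration for transition rows and the
#'   initial distribution.
#' @param mean Prior emission mean (scalar or length-`C`).
#' @param mean_precision Scalar precision `kappa0` on the emission mean.
#' @param scale Inverse-Wishart scale matrix (default identity).
#' @param dof Inverse-Wishart degrees of freedom (default `C + 2`).
#' @return A list of class `bs_prior`.
#' @export
hmm_prior <- function(dirichlet = 1, mean = 0, mean_precision = 0.1,
                      scale = NULL, dof = NULL) {
  structure(list(dirichlet = dirichlet, mean = mean,
                 mean_precision = mean_precision, scale = scale, dof = dof),
            class = "bs_prior")
}

kl_dirichlet <- function(a, a0) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((a - a0) * (digamma(a) - digamma(sum(a))))
}

lmvgamma <- function(C, a) {
  C * (C - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(C)) / 2))
}

# E[log |Lambda|] under Wishart(S^-1 scale param form): uses log|S|.
e_logdet_lambda <- function(nu, logdetS, C) {
  sum(digamma((nu + 1 - seq_len(C)) / 2)) + C * log(2) - logdetS
}

# KL( NIW(m, kappa, S, nu) || NIW(m0, kappa0, S0, nu0) ), Normal-Wishart
# parameterisation with W = S^{-1}.
kl_niw <- function(m, kappa, S, nu, m0, kappa0, S0, nu0) {
  C <- length(m)
  R <- chol(S)
  logdetS <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  logdetS0 <- determinant(S0, logarithm = TRUE)$modulus[1]
  elog <- e_logdet_lambda(nu, logdetS, C)
  d <- m - m0
  qf <- drop(t(d) %*% Sinv %*% d)
  kl_n <- 0.5 * (C * kappa0 / kappa + kappa0 * nu * qf - C +
                   C * log(kappa / kappa0))
  logB <- function(ldS, nn) (nn / 2) * ldS - (nn * C / 2) * log(2) -
    lmvgamma(C, nn / 2)
  kl_w <- logB(logdetS, nu) - logB(logdetS0, nu0) +
    ((nu - nu0) / 2) * elog + (nu / 2) * (sum(S0 * Sinv) - C)
  kl_n + kl_w
}

# Expected log observation densities under the NIW posterior, T x K.
expected_log_lik <- function(Y, post) {
  K <- length(post$kappa)
  C <- ncol(Y)
  out <- matrix(0, nrow(Y), K)
  for (k in seq_len(K)) {
    R <- chol(post$S[[k]])
    logdetS <- 2 * sum(log(diag(R)))
    elog <- e_logdet_lambda(post$nu[k], logdetS, C)
    X <- sweep(Y, 2, post$m[k, ])
    W <- forwardsolve(t(R), t(X))
    qf <- colSums(W^2)
    out[, k] <- 0.5 * elog - C / (2 * post$kappa[k]) -
      0.5 * post$nu[k] * qf - (C / 2) * log(2 * pi)
  }
  out
}

#' Exact forward-backward smoothing
#'
#' Computes posterior state probabilities (`gamma`), pairwise transition
#' marginals (`xi`) and the log evidence for one run, given per-sample log
#' observation likelihoods and fixed transition/initial probabilities. All
#' recursions run in log space with per-step log-sum-exp normalisation.
#'
#' @param log_obs_lik `T x K` matrix of log observation likelihoods.
#' @param transition `K x K` row-stochastic transition matrix.
#' @param initial Length-`K` initial distribution.
#' @return A list with `gamma` (`T x K`, rows sum to 1), `xi`
#'   (`(T-1) x K x K` array, each slice sums to 1) and `log_evidence`.
#' @export
forward_backward <- function(log_obs_lik, transition, initial) {
  log_obs_lik <- as.matrix(log_obs_lik)
  if (any(!is.finite(log_obs_lik))) {
    stop_param("log observation likelihoods must be finite")
  }
  K <- ncol(log_obs_lik)
  check_prob_rows(as.matrix(transition))
  check_simplex(initial)
  fb <- forward_backward_cpp(log_obs_lik, log(as.matrix(transition)),
                             log(initial))
  T_len <- nrow(log_obs_lik)
  xi <- array(fb$xi, dim = c(max(T_len - 1, 0), K, K))
  list(gamma = fb$gamma, xi = xi, log_evidence = fb$log_evidence)
}

#' Fit a group-level Gaussian HMM by variational Bayes
#'
#' All runs share one set of state parameters (means, covariances, transition
#' matrix, initial distribution); posterior state probability courses are
#' returned per run. Inference alternates exact forward-backward E-steps
#' with conjugate coordinate updates of the Dirichlet and
#' Normal-Inverse-Wishart posteriors, and records the variational free
#' energy (negative evidence lower bound; lower is better) once per cycle.
#' The trace is guaranteed non-increasing. Runs are chained with the initial
#' distribution re-applied at every run boundary, so no transitions are
#' counted across runs. Initialisation is a seeded k-means hard assignment of
#' the pooled samples (computed on a canonically row-sorted copy of the
#' pooled matrix, making the fit invariant to run order).
#'
#' @param data A run tibble, list of `T x C` matrices, or single matrix.
#'   Inputs are assumed amplitude-standardized (see [standardize_runs()]).
#' @param n_states Number of states `K`.
#' @param prior A [hmm_prior()].
#' @param tol Relative free-energy change declaring convergence.
#' @param max_cycles Maximum variational cycles.
#' @param seed Integer seed controlling initialisation.
#' @return An object of class `bs_hmm`: state `means` (`K x C`), `covs`
#'   (posterior-expected covariances), `transition`, `initial`, per-run
#'   `gamma`, `free_energy_trace`, the full variational `posterior`, and fit
#'   metadata.
#' @export
fit_hmm <- function(data, n_states, prior = hmm_prior(), tol = 1e-5,
                    max_cycles = 500, seed = 1) {
  tbl <- as_run_table(data)
  Y_list <- lapply(tbl$data, as.matrix)
  C <- ncol(Y_list[[1]])
  if (!all(vapply(Y_list, ncol, 0L) == C)) {
    stop_param("all runs must share one channel count")
  }
  K <- as.integer(n_states)
  if (K < 1) stop_param("n_states must be at least 1")
  Ypool <- do.call(rbind, Y_list)
  T_tot <- nrow(Ypool)
  if (K > T_tot) stop_param("n_states (%d) exceeds total samples (%d)", K, T_tot)
  T_runs <- vapply(Y_list, nrow, 0L)
  run_end <- cumsum(T_runs)
  run_start <- run_end - T_runs + 1

  m0 <- rep_len(prior$mean, C)
  kappa0 <- prior$mean_precision
  S0 <- prior$scale %||% diag(C)
  nu0 <- prior$dof %||% (C + 2)
  if (nu0 <= C - 1) stop_param("prior dof must exceed C - 1")
  a0 <- prior$dirichlet

  # ---- initialisation: seeded k-means on canonically ordered pooled data
  ord <- do.call(order, as.data.frame(Ypool))
  set.seed(derive_seed(seed, "init"))
  km <- suppressWarnings(kmeans(Ypool[ord, , drop = FALSE], centers = K,
                                nstart = 3, iter.max = 50))
  z <- integer(T_tot)
  z[ord] <- km$cluster
  gamma_pool <- matrix(0, T_tot, K)
  gamma_pool[cbind(seq_len(T_tot), z)] <- 1
  xi_sum <- matrix(0, K, K)
  init_counts <- rep(0, K)
  for (i in seq_along(Y_list)) {
    s <- run_start[i]; e <- run_end[i]
    init_counts <- init_counts + gamma_pool[s, ]
    if (e > s) {
      zt <- z[s:(e - 1)]; zt1 <- z[(s + 1):e]
      for (t in seq_along(zt)) xi_sum[zt[t], zt1[t]] <- xi_sum[zt[t], zt1[t]] + 1
    }
  }

  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (cycle in seq_len(max_cycles)) {
    # ---- M-step: conjugate posterior updates
    N <- colSums(gamma_pool)
    m <- matrix(0, K, C)
    S <- vector("list", K)
    kappa <- kappa0 + N
    nu <- nu0 + N
    for (k in seq_len(K)) {
      if (N[k] > 1e-12) {
        ybar <- colSums(Ypool * gamma_pool[, k]) / N[k]
        Xc <- sweep(Ypool, 2, ybar)
        S_emp <- t(Xc * gamma_pool[, k]) %*% Xc
        d <- ybar - m0
        S[[k]] <- S0 + S_emp + (kappa0 * N[k] / kappa[k]) * tcrossprod(d)
        m[k, ] <- (kappa0 * m0 + N[k] * ybar) / kappa[k]
      } else {
        S[[k]] <- S0
        m[k, ] <- m0
      }
      S[[k]] <- (S[[k]] + t(S[[k]])) / 2
    }
    a_trans <- a0 + xi_sum
    a_init <- a0 + init_counts
    post <- list(m = m, kappa = kappa, S = S, nu = nu,
                 a_trans = a_trans, a_init = a_init)

    kl <- kl_dirichlet(a_init, rep(a0, K))
    for (j in seq_len(K)) kl <- kl + kl_dirichlet(a_trans[j, ], rep(a0, K))
    for (k in seq_len(K)) {
      kl <- kl + tryCatch(
        kl_niw(m[k, ], kappa[k], S[[k]], nu[k], m0, kappa0, S0, nu0),
        error = function(e) stop_compute(
          "emission covariance collapsed for state %d; use a stronger prior (larger scale or dof)", k))
    }

    # ---- E-step with expected log parameters
    elog_trans <- digamma(a_trans) - digamma(rowSums(a_trans))
    elog_init <- digamma(a_init) - digamma(sum(a_init))
    logB <- tryCatch(expected_log_lik(Ypool, post),
                     error = function(e) stop_compute(
                       "emission covariance collapsed; use a stronger prior (larger scale or dof)"))
    logZ_sum <- 0
    xi_sum <- matrix(0, K, K)
    init_counts <- rep(0, K)
    for (i in seq_along(Y_list)) {
      s <- run_start[i]; e <- run_end[i]
      fb <- forward_backward_cpp(logB[s:e, , drop = FALSE],
                                 matrix(elog_trans, K, K),
                                 as.numeric(elog_init))
      gamma_pool[s:e, ] <- fb$gamma
      if (e > s) xi_sum <- xi_sum + matrix(colSums(fb$xi), K, K)
      init_counts <- init_counts + fb$gamma[1, ]
      logZ_sum <- logZ_sum + fb$log_evidence
    }
    fe <- kl - logZ_sum
    trace <- c(trace, fe)
    if (cycle > 1) {
      prev <- trace[cycle - 1]
      if (abs(prev - fe) <= tol * abs(prev)) { converged <- TRUE; break }
    }
  }

  covs <- lapply(seq_len(K), function(k) post$S[[k]] / (post$nu[k] - C - 1))
  gamma_runs <- lapply(seq_along(Y_list), function(i)
    gamma_pool[run_start[i]:run_end[i], , drop = FALSE])
  structure(list(
    n_states = K,
    channels = colnames(Y_list[[1]]) %||% sprintf("ch%02d", seq_len(C)),
    means = post$m,
    covs = covs,
    transition = post$a_trans / rowSums(post$a_trans),
    initial = post$a_init / sum(post$a_init),
    gamma = gamma_runs,
    run_info = tbl[c("subject", "run", "condition", "modality", "period")],
    free_energy = trace[length(trace)],
    free_energy_trace = trace,
    posterior = post,
    prior = list(dirichlet = a0, mean = m0, mean_precision = kappa0,
                 scale = S0, dof = nu0),
    tol = tol, max_cycles = max_cycles, seed = seed,
    converged = converged, cycles = length(trace)
  ), class = "bs_hmm")
}

#' @export
print.bs_hmm <- function(x, ...) {
  cat(sprintf("<bs_hmm> K = %d states, %d channels, %d runs\n", x$n_states,
              length(x$channels), nrow(x$run_info)))
  cat(sprintf("  free energy %.3f after %d cycles (%s)\n", x$free_energy,
              x$cycles, if (x$converged) "converged" else "max cycles"))
  invisible(x)
}

#' Variational free energy of a fitted model on a dataset
#'
#' Re-runs the E-step with the model's variational posterior held fixed and
#' returns `KL(q(theta) || p(theta)) - sum(log evidence)`. Evaluated on the
#' training data this equals the final entry of the fit's free-energy trace.
#' The per-run log evidence sum and the KL term are attached as attributes
#' (`"log_evidence"`, `"kl"`).
#'
#' @param model A [fit_hmm()] object.
#' @param data A run tibble, list of matrices, or single matrix with the same
#'   channel count as the training data.
#' @return The free energy (scalar, lower is better).
#' @export
free_energy <- function(model, data) {
  tbl <- as_run_table(data)
  Y_list <- lapply(tbl$data, as.matrix)
  C <- length(model$channels)
  if (!all(vapply(Y_list, ncol, 0L) == C)) {
    stop_param("data has a different channel count than the model (%d)", C)
  }
  post <- model$posterior
  K <- model$n_states
  pr <- model$prior
  kl <- kl_dirichlet(post$a_init, rep(pr$dirichlet, K))
  for (j in seq_len(K)) {
    kl <- kl + kl_dirichlet(post$a_trans[j, ], rep(pr$dirichlet, K))
  }
  for (k in seq_len(K)) {
    kl <- kl + kl_niw(post$m[k, ], post$kappa[k], post$S[[k]], post$nu[k],
                      pr$mean, pr$mean_precision, pr$scale, pr$dof)
  }
  elog_trans <- digamma(post$a_trans) - digamma(rowSums(post$a_trans))
  elog_init <- digamma(post$a_init) - digamma(sum(post$a_init))
  logZ <- 0
  for (Y in Y_list) {
    logB <- expected_log_lik(Y, post)
    fb <- forward_backward_cpp(logB, matrix(elog_trans, K, K),
                               as.numeric(elog_init))
    logZ <- logZ + fb$log_evidence
  }
  structure(kl - logZ, log_evidence = logZ, kl = kl)
}

mvn_log_density <- function(Y, mu, Sigma) {
  C <- ncol(Y)
  R <- chol(Sigma)
  X <- sweep(Y, 2, mu)
  W <- forwardsolve(t(R), t(X))
  -0.5 * colSums(W^2) - sum(log(diag(R))) - (C / 2) * log(2 * pi)
}

#' Viterbi decoding of runs under a fitted model
#'
#' Decodes each run to its most probable state sequence using the
#' posterior-expected parameters (posterior mean vectors, expected
#' covariances, and posterior-mean transition/initial probabilities). Ties
#' are broken toward the lower state index.
#'
#' @param model A [fit_hmm()] object.
#' @param data A run tibble, list of matrices, or single matrix (standardized
#'   like the training inputs).
#' @return A tibble with one row per run: `subject`, `run`, `condition`,
#'   `period`, `path` (integer list-column) and `log_prob`.
#' @export
viterbi_paths <- function(model, data) {
  tbl <- as_run_table(data)
  K <- model$n_states
  out <- purrr::map(tbl$data, function(Y) {
    Y <- as.matrix(Y)
    if (nrow(Y) < 1) stop_param("cannot decode an empty run")
    if (ncol(Y) != length(model$channels)) {
      stop_param("run channel count does not match the model")
    }
    logB <- vapply(seq_len(K), function(k)
      mvn_log_density(Y, model$means[k, ], model$covs[[k]]), numeric(nrow(Y)))
    logB <- matrix(logB, nrow = nrow(Y))
    viterbi_cpp(logB, log(model$transition), log(model$initial))
  })
  tibble::tibble(
    subject = tbl$subject, run = tbl$run, condition = tbl$condition,
    period = tbl$period,
    path = purrr::map(out, "path"),
    log_prob = purrr::map_dbl(out, "log_prob")
  )
}

#' Binarise state probability courses at an activation threshold
#'
#' A state is deemed active at a time point when its posterior probability
#' exceeds the threshold (default 0.8, i.e. ">80% likelihood"). With a
#' threshold of at least 0.5, at most one state is active per time point.
#'
#' @param gamma `T x K` state probability matrix.
#' @param threshold Probability threshold in (0, 1).
#' @return Logical `T x K` matrix.
#' @export
threshold_activation <- function(gamma, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) {
    stop_param("threshold must lie strictly in (0, 1)")
  }
  as.matrix(gamma) > threshold
}
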