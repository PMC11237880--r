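test_that("standardisation gives exact zero mean, unit SD, and is idempotent", {
  set.seed(1)
  runs <- list(matrix(rnorm(200, 3, 5), 50, 4), matrix(rnorm(200, -1, 2), 50, 4))
  std <- standardize_runs(runs)
  for (m in std$data) {
    expect_lt(max(abs(colMeans(m))), 1e-10)
    expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-10)
  }
  twice <- standardize_runs(std)
  expect_equal(twice$data, std$data, tolerance = 1e-12)
  bad <- list(cbind(rnorm(20), rep(2, 20)))
  colnames(bad[[1]]) <- c("good", "flat")
  expect_error(standardize_runs(bad), "flat",
               class = "brainstates_computation_error")
})

test_that("forward-backward handles degenerate and symmetric cases", {
  lb <- matrix(rnorm(6), 6, 1)
  fb <- forward_backward(lb, matrix(1, 1, 1), 1)
  expect_equal(as.numeric(fb$gamma), rep(1, 6))
  expect_equal(fb$log_evidence, sum(lb))
  lb2 <- matrix(rep(rnorm(5), 3), 5, 3)
  fb2 <- forward_backward(lb2, matrix(1 / 3, 3, 3), rep(1 / 3, 3))
  expect_equal(fb2$gamma, matrix(1 / 3, 5, 3))
  expect_error(forward_backward(matrix(c(1, NA), 1), matrix(1), 1),
               class = "brainstates_parameter_error")
})

test_that("forward-backward matches exhaustive enumeration (fixed small case)", {
  set.seed(71)
  A <- matrix(runif(4), 2); A <- A / rowSums(A)
  p0 <- c(0.3, 0.7)
  lb <- matrix(rnorm(6), 3, 2)
  fb <- forward_backward(lb, A, p0)
  oracle <- enum_hmm(lb, A, p0)
  expect_lt(max(abs(fb$gamma - oracle$gamma)), 1e-12)
  expect_equal(fb$log_evidence, oracle$log_evidence, tolerance = 1e-12)
  # xi consistency: marginalising over the second index reproduces gamma
  ximarg <- apply(fb$xi, c(1, 2), sum)
  expect_lt(max(abs(ximarg - fb$gamma[1:2, ])), 1e-9)
  expect_equal(apply(fb$xi, 1, sum), rep(1, 2), tolerance = 1e-9)
})

test_that("variational fit recovers well-separated states with a monotone trace", {
  dat <- make_sep_runs(K = 2, n_runs = 10, T_len = 300, C = 3,
                       separation = 5, seed = 42)
  std <- standardize_runs(dat$runs)
  fit <- fit_hmm(std, 2, seed = 7)
  expect_true(all(diff(fit$free_energy_trace) <= 1e-8))
  paths <- viterbi_paths(fit, std)
  expect_gt(matched_accuracy(dat$chains, paths$path, 2), 0.95)
  # matched means agree with the empirical standardized state means
  p <- match_states_by_confusion(dat$chains, paths$path, 2)
  pooled <- do.call(rbind, std$data)
  truechain <- unlist(dat$chains)
  for (k in 1:2) {
    emp <- colMeans(pooled[truechain == k, , drop = FALSE])
    expect_lt(max(abs(fit$means[p[k], ] - emp)), 0.1)
  }
})

test_that("single-state fit recovers the standardized moments", {
  set.seed(8)
  runs <- list(matrix(rnorm(9000), 3000, 3), matrix(rnorm(9000), 3000, 3))
  fit <- fit_hmm(standardize_runs(runs), 1, seed = 2)
  expect_lt(max(abs(fit$means)), 0.02)
  expect_lt(max(abs(fit$covs[[1]] - diag(3))), 0.02)
  expect_true(all(diff(fit$free_energy_trace) <= 1e-8))
})

test_that("free energy evaluation matches the trace and is additive over runs", {
  dat <- make_sep_runs(K = 2, n_runs = 4, T_len = 150, C = 3, seed = 3)
  std <- standardize_runs(dat$runs)
  fit <- fit_hmm(std, 2, seed = 5)
  fe <- free_energy(fit, std)
  expect_equal(as.numeric(fe), fit$free_energy_trace[fit$cycles],
               tolerance = 1e-6)
  dup <- standardize_runs(c(dat$runs, dat$runs))
  fe2 <- free_energy(fit, dup)
  expect_equal(attr(fe2, "log_evidence"), 2 * attr(fe, "log_evidence"),
               tolerance = 1e-6)
  expect_error(free_energy(fit, list(matrix(rnorm(40), 10, 4))),
               class = "brainstates_parameter_error")
})

test_that("run order does not change the fitted parameters", {
  dat <- make_sep_runs(K = 3, n_runs = 6, T_len = 120, C = 3, seed = 12)
  std <- standardize_runs(dat$runs)
  f1 <- fit_hmm(std, 3, seed = 4)
  rev_tbl <- std[rev(seq_len(nrow(std))), ]
  f2 <- fit_hmm(rev_tbl, 3, seed = 4)
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$transition, f2$transition, tolerance = 1e-6)
})

test_that("VB emission means agree with an independent EM mixture fit", {
  withr::local_package("mclust")   # Mclust resolves helpers via attachment
  dat <- make_sep_runs(K = 3, n_runs = 8, T_len = 250, C = 3,
                       separation = 5, seed = 33)
  std <- standardize_runs(dat$runs)
  fit <- fit_hmm(std, 3, seed = 6)
  pooled <- do.call(rbind, std$data)
  em <- mclust::Mclust(pooled, G = 3, modelNames = "VVV", verbose = FALSE)
  em_means <- t(em$parameters$mean)
  R <- cor(t(fit$means), t(em_means))
  p <- brainstates:::solve_assignment(-R)
  expect_true(all(R[cbind(1:3, p)] > 0.99))
})

test_that("viterbi matches enumeration and limiting regimes", {
  set.seed(19)
  for (i in 1:5) {
    K <- 2; T_len <- sample(4:8, 1)
    A <- matrix(runif(K * K), K); A <- A / rowSums(A)
    p0 <- runif(K); p0 <- p0 / sum(p0)
    mu <- matrix(rnorm(K * 2, sd = 2), K, 2)
    Y <- matrix(rnorm(T_len * 2), T_len, 2)
    model <- structure(list(n_states = K, channels = c("a", "b"), means = mu,
                            covs = replicate(K, diag(2), simplify = FALSE),
                            transition = A, initial = p0), class = "bs_hmm")
    vp <- viterbi_paths(model, Y)
    logb <- vapply(1:K, function(k)
      brainstates:::mvn_log_density(Y, mu[k, ], diag(2)), numeric(T_len))
    oracle <- enum_hmm(logb, A, p0)
    expect_equal(vp$log_prob, oracle$best_logp, tolerance = 1e-10)
    expect_equal(vp$path[[1]], as.integer(oracle$best_path))
  }
  # near-deterministic emissions with uniform transitions: per-sample argmax
  mu <- rbind(c(-10, 0), c(10, 0))
  Y <- mu[c(1, 2, 1, 1, 2), ] + matrix(rnorm(10, sd = 0.1), 5, 2)
  model <- structure(list(n_states = 2, channels = c("a", "b"), means = mu,
                          covs = replicate(2, diag(2), simplify = FALSE),
                          transition = matrix(0.5, 2, 2),
                          initial = c(0.5, 0.5)), class = "bs_hmm")
  expect_equal(viterbi_paths(model, Y)$path[[1]], c(1L, 2L, 1L, 1L, 2L))
  # identity transitions: constant path at the best single state
  model$transition <- diag(2)
  expect_equal(length(unique(viterbi_paths(model, Y)$path[[1]])), 1L)
  expect_error(viterbi_paths(model, matrix(numeric(0), 0, 2)),
               class = "brainstates_parameter_error")
})

test_that("activation thresholding follows the 80% rule", {
  g <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.79, 0.21))
  act <- threshold_activation(g, 0.8)
  expect_equal(act, rbind(c(TRUE, FALSE), c(FALSE, FALSE), c(FALSE, FALSE)))
  expect_true(all(rowSums(threshold_activation(g, 0.5)) <= 1))
  expect_error(threshold_activation(g, 1.2),
               class = "brainstates_parameter_error")
})
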