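test_that("the double-gamma kernel has the canonical shape", {
  h <- double_gamma_hrf(step = 0.01)
  expect_equal(h$values[1], 0)
  expect_equal(max(h$values), 1)
  # dense-grid argmax: mode of the shape-6 gamma, barely moved by the
  # undershoot
  expect_lt(abs(h$time[which.max(h$values)] - 5.0), 0.1)
  late <- h$values[h$time >= 13 & h$time <= 30]
  expect_true(all(late < 0))
  expect_error(double_gamma_hrf(0.01, length = 10),
               class = "brainstates_parameter_error")
  expect_error(double_gamma_hrf(0.01, peak_delay = 0.5),
               class = "brainstates_parameter_error")
})

test_that("regressors convolve at the native rate and sample on the TR grid", {
  # 10 min of a 40 Hz course -> 300 volumes
  reg <- build_regressor(rep(1, 24000), rate = 40, tr = 2)
  expect_equal(length(reg), 300)
  # steady state equals the kernel mass
  h <- double_gamma_hrf(step = 1 / 40)
  expect_equal(reg[300], sum(h$values) * h$step, tolerance = 1e-9)
  expect_equal(build_regressor(rep(0, 4000), 40, 2), rep(0, 50))
  expect_error(build_regressor(rep(1, 24000), 40, 2, n_out = 400),
               class = "brainstates_parameter_error")
})

test_that("first-level OLS is exact on noiseless data and calibrated on noise", {
  set.seed(31)
  x <- rnorm(120)
  xd <- x - mean(x)                                    # fitted design column
  Y <- cbind(3 * x, rnorm(120))
  Y[, 2] <- Y[, 2] - xd * sum(Y[, 2] * xd) / sum(xd * xd)  # orthogonalise
  fit <- first_level_glm(Y, x)
  est <- fit$estimates[fit$estimates$term == "x1", ]
  expect_equal(est$estimate[1], 3, tolerance = 1e-10)
  expect_lt(abs(est$estimate[2]), 1e-10)
  expect_equal(fit$df, 118)
  neg <- fit$contrasts[fit$contrasts$contrast == "negative", ]
  pos <- fit$contrasts[fit$contrasts$contrast == "positive", ]
  expect_equal(neg$statistic, -pos$statistic)
  # Monte-Carlo: unbiased betas, SE calibrated within 10%
  beta <- 0.7
  Ymc <- sapply(1:200, function(i) beta * x + rnorm(120))
  fmc <- first_level_glm(Ymc, x)
  emc <- fmc$estimates[fmc$estimates$term == "x1", ]
  expect_lt(abs(mean(emc$estimate) - beta), 2 * sd(emc$estimate) / sqrt(200))
  expect_equal(sd(emc$estimate), mean(emc$se), tolerance = 0.10)
  expect_error(first_level_glm(Ymc, cbind(x, 2 * x)),
               class = "brainstates_parameter_error")
})

test_that("scaling the data scales betas but not t statistics", {
  set.seed(32)
  x <- rnorm(80)
  Y <- matrix(0.5 * x + rnorm(80 * 3), 80, 3)
  f1 <- first_level_glm(Y, x)
  f2 <- first_level_glm(10 * Y, x)
  e1 <- f1$estimates[f1$estimates$term == "x1", ]
  e2 <- f2$estimates[f2$estimates$term == "x1", ]
  expect_equal(e2$estimate, 10 * e1$estimate, tolerance = 1e-10)
  expect_equal(e2$statistic, e1$statistic, tolerance = 1e-10)
})

test_that("subject-level averaging is a fixed-effects mean per condition", {
  set.seed(33)
  x <- rnorm(60)
  mk <- function(b) first_level_glm(matrix(b * x + rnorm(60, sd = 1e-8)), x)
  fits <- tibble::tibble(
    subject = c("s1", "s1", "s1"), condition = c("EO", "EO", "EC"),
    fit = list(mk(1), mk(3), mk(5)))
  maps <- subject_level_average(fits)
  expect_equal(maps$estimate[maps$condition == "EO"], 2, tolerance = 1e-6)
  expect_equal(maps$estimate[maps$condition == "EC"], 5, tolerance = 1e-6)
  expect_error(subject_level_average(fits[0, ]),
               class = "brainstates_parameter_error")
})

test_that("group tests flag no targets on null or identical-condition maps", {
  subs <- sprintf("s%02d", 1:8)
  maps <- tidyr::expand_grid(subject = subs, condition = c("EO", "EC"),
                             target = c("t1", "t2"))
  maps$term <- "x1"
  maps$estimate <- 0
  maps$n_runs <- 2
  class(maps) <- c("bs_subject_maps", class(maps))
  g <- group_level_test(maps, "EO")
  expect_true(all(!g$significant))
  # identical EO and EC values per subject/target: all differences are zero,
  # so the paired contrast has no variance and is flagged missing
  set.seed(9)
  key <- paste(maps$subject, maps$target)
  vals <- stats::setNames(rnorm(length(unique(key))), unique(key))
  maps$estimate <- as.numeric(vals[key])
  g2 <- group_level_test(maps, "EO-EC")
  expect_true(all(is.na(g2$statistic)))
  expect_true(all(!g2$significant))
})

test_that("noiseless voxel round trip recovers the loading map exactly", {
  set.seed(35)
  K <- 3
  gam <- matrix(runif(150 * K), 150, K)
  gam <- gam / rowSums(gam)
  beta <- matrix(rnorm(12 * K), 12, K)
  vox <- simulate_voxel_bold(gam, beta, tr = 2, ar1 = list(coef = 0, sd = 0))
  X <- vapply(seq_len(K), function(k)
    build_regressor(gam[, k], rate = 0.5, tr = 2), numeric(150))
  fit <- first_level_glm(vox, X, targets_in_rows = TRUE)
  est <- tidyr::pivot_wider(
    fit$estimates[fit$estimates$term != "intercept",
                  c("target", "term", "estimate")],
    names_from = "term", values_from = "estimate")
  expect_lt(max(abs(as.matrix(est[, -1]) - beta)), 1e-6)
})

test_that("AR(1) prewhitening estimates the residual autocorrelation", {
  set.seed(36)
  x <- rnorm(400)
  e <- as.numeric(stats::filter(rnorm(400), 0.5, method = "recursive"))
  fit <- first_level_glm(matrix(2 * x + e), x, prewhiten = TRUE)
  expect_lt(abs(fit$rho - 0.5), 0.15)
  est <- fit$estimates[fit$estimates$term == "x1", ]
  expect_equal(est$estimate, 2, tolerance = 0.2)
})
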