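test_that("simulate_chain honours absorbing dynamics, determinism and stationarity", {
  expect_equal(simulate_chain(diag(2), c(1, 0), 5, seed = 1), rep(1L, 5))
  a <- simulate_chain(matrix(0.25, 4, 4), rep(0.25, 4), 50, seed = 9)
  b <- simulate_chain(matrix(0.25, 4, 4), rep(0.25, 4), 50, seed = 9)
  expect_identical(a, b)
  # doubly stochastic symmetric chain: stationary occupancy 1/2
  A <- matrix(0.5, 2, 2)
  ch <- simulate_chain(A, c(0.5, 0.5), 1e5, seed = 3)
  expect_equal(mean(ch == 1), 0.5, tolerance = 0.01 / 0.5)
  expect_error(simulate_chain(matrix(c(0.6, 0.2, 0.5, 0.8), 2), c(1, 0), 5, 1),
               class = "brainstates_parameter_error")
  expect_error(simulate_chain(diag(2), c(1, 0), 0, 1),
               class = "brainstates_parameter_error")
})

test_that("fMRI emission matches the state Gaussians", {
  truth <- list(state_means = rbind(c(-1, 0, 2), c(3, 1, -2)),
                state_covs = list(diag(3) * 1e-12, diag(3) * 1e-12))
  ch <- rep(c(1L, 2L), 10)
  y <- simulate_fmri_run(ch, truth, tr = 2, seed = 4)
  expect_lt(max(abs(y - truth$state_means[ch, ])), 1e-4)
  expect_equal(attr(y, "duration"), 40)
  # law of large numbers on per-state channel means
  truth2 <- list(state_means = rbind(c(-2, 1), c(2, -1)),
                 state_covs = list(diag(2), diag(2)))
  ch2 <- rep(c(1L, 2L), each = 1e4)
  y2 <- simulate_fmri_run(ch2, truth2, seed = 5)
  for (k in 1:2) {
    se <- 1 / sqrt(1e4)
    expect_lt(max(abs(colMeans(y2[ch2 == k, ]) - truth2$state_means[k, ])),
              3 * se)
  }
  ch300 <- simulate_chain(matrix(0.5, 2, 2), c(0.5, 0.5), 300, 1)
  expect_equal(attr(simulate_fmri_run(ch300, truth2, tr = 2, seed = 1),
                    "duration"), 600)
  expect_error(simulate_fmri_run(c(1L, 3L), truth2, seed = 1),
               class = "brainstates_parameter_error")
})

test_that("EEG emission carries a state-scaled alpha tone", {
  amp <- matrix(1.3, 1, 6)
  y <- simulate_eeg_run(rep(1L, 2000), amp, carrier = 10, raw_rate = 200,
                        noise_sd = 0, seed = 2)
  env <- hilbert_envelope(bandpass_alpha(y, 200), 200)
  interior <- 301:1700
  expect_equal(mean(env[interior, 1]), 1.3, tolerance = 0.02)
  expect_equal(nrow(y), 200 * 10)   # 10 s at 200 Hz
  expect_error(simulate_eeg_run(rep(1L, 10), amp, carrier = 120,
                                raw_rate = 200, seed = 1),
               class = "brainstates_parameter_error")
  # zero amplitudes: envelope carries no state information. The band-limited
  # envelope is autocorrelated over ~1/bandwidth, so the null comparison is
  # made on per-block envelope means (independent units), not raw samples.
  ch <- rep(rep(c(1L, 2L), each = 100), 10)
  y0 <- simulate_eeg_run(ch, matrix(0, 2, 6), noise_sd = 1, seed = 7)
  env0 <- hilbert_envelope(bandpass_alpha(y0, 200), 200)
  block <- rep(seq_len(20), each = 100)[seq_along(ch)]
  bm <- tapply(env0[, 1], block, mean)
  bs <- tapply(ch, block, function(x) x[1])
  tt <- t.test(bm[bs == 1], bm[bs == 2])
  expect_gt(tt$p.value, 0.01)
})

test_that("parcel BOLD is the HRF-filtered state course plus AR(1) noise", {
  beta <- matrix(0, 5, 2)
  v0 <- simulate_voxel_bold(rep(1L, 100), beta, ar1 = list(coef = 0, sd = 0))
  expect_equal(v0, matrix(0, 5, 100))
  beta1 <- matrix(c(1, 0), 1, 2)
  v1 <- simulate_voxel_bold(rep(1L, 100), beta1, tr = 2,
                            ar1 = list(coef = 0, sd = 0))
  reg <- build_regressor(rep(1, 100), rate = 0.5, tr = 2)
  expect_equal(as.numeric(v1), reg)
  expect_error(simulate_voxel_bold(rep(1L, 10), beta1, tr = 2,
                                   ar1 = list(coef = 0, sd = 0)),
               class = "brainstates_parameter_error")
  expect_error(simulate_voxel_bold(rep(1L, 100), beta1, tr = 2,
                                   ar1 = list(coef = 1.2, sd = 1)),
               class = "brainstates_parameter_error")
})

test_that("make_study reproduces the acquisition design and is reproducible", {
  mf <- study_manifest()
  st <- make_study(mf, effect_profile("null"), seed = 11, voxels = FALSE,
                   eeg = FALSE)
  fm <- st$runs[st$runs$modality == "fmri", ]
  expect_equal(length(unique(fm$subject)), 21)
  expect_equal(nrow(fm), 21 * 4)
  expect_true(all(vapply(fm$data, function(m) all(dim(m) == c(300, 13)), TRUE)))
  expect_equal(unique(fm$condition[fm$run == 1]), "EO")
  expect_equal(unique(fm$condition[fm$run == 2]), "EC")

  mf2 <- study_manifest(n_subjects = 2, n_volumes = 30)
  a <- make_study(mf2, effect_profile("null", n_states = 3), seed = 5)
  b <- make_study(mf2, effect_profile("null", n_states = 3), seed = 5)
  expect_identical(a$runs$data, b$runs$data)
  expect_identical(a$truth$chain_paths$path, b$truth$chain_paths$path)

  # chain/observation consistency: nearest-mean decoding of near-noiseless
  # observations reproduces the stored chains
  tr3 <- ground_truth(mf2, effect_profile("null", n_states = 3),
                      state_covs = replicate(3, diag(13) * 1e-10,
                                             simplify = FALSE), seed = 5)
  stn <- make_study(mf2, effect_profile("null", n_states = 3), truth = tr3,
                    seed = 5, voxels = FALSE, eeg = FALSE)
  for (i in seq_len(nrow(stn$runs))) {
    y <- stn$runs$data[[i]]
    dec <- apply(y, 1, function(row)
      which.min(colSums((t(tr3$state_means) - row)^2)))
    expect_identical(as.integer(dec), stn$truth$chain_paths$path[[i]])
  }
})

test_that("raising one state's EC stay probability raises its EC occupancy in every subject", {
  eff <- effect_profile("null", n_states = 5, stay = 0.90)
  ec_stay <- rep(0.90, 5); ec_stay[5] <- 0.97
  eff$transition$EC <- brainstates:::make_transition(5, ec_stay)
  mf <- study_manifest(n_subjects = 12, n_volumes = 300)
  st <- make_study(mf, eff, seed = 21, voxels = FALSE, eeg = FALSE,
                   fmri = FALSE)
  cp <- st$truth$chain_paths
  fo5 <- vapply(cp$path, function(p) mean(p == 5), 0)
  by_subj <- tapply(fo5, list(cp$subject, cp$condition), mean)
  expect_true(all(by_subj[, "EC"] - by_subj[, "EO"] > 0))
})

test_that("stationary_dist solves pi = pi A", {
  A <- brainstates:::make_transition(4, c(0.7, 0.8, 0.9, 0.6))
  p <- stationary_dist(A)
  expect_equal(as.numeric(p %*% A), as.numeric(p), tolerance = 1e-12)
  expect_equal(sum(p), 1)
})
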