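tone <- function(freq, rate, dur, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(dur * rate - 1)) / rate + phase)
}

test_that("alpha bandpass preserves the passband and rejects the stopband", {
  rate <- 200
  mid <- tone(10, rate, 20)
  out <- bandpass_alpha(mid, rate)
  interior <- 1001:3000
  expect_equal(max(abs(out[interior])), 1, tolerance = 0.05)
  low <- bandpass_alpha(tone(2, rate, 20), rate)
  expect_lt(max(abs(low[interior])), 0.01)
  # stated stopband attenuation: >= 40 dB at 5 and 15 Hz
  for (f in c(5, 15)) {
    res <- bandpass_alpha(tone(f, rate, 20), rate)
    expect_lt(20 * log10(max(abs(res[interior]))), -40)
  }
  dc <- bandpass_alpha(rep(3, 1000), rate)
  expect_lt(abs(mean(dc[301:700])), 3e-6)   # interior, clear of edge ringing
  expect_error(bandpass_alpha(mid, rate = 20),
               class = "brainstates_parameter_error")
})

test_that("the Hilbert envelope tracks instantaneous amplitude", {
  rate <- 200
  x <- tone(10, rate, 10, amp = 2.5)
  env <- hilbert_envelope(x, rate)
  interior <- 201:1800
  expect_true(all(abs(env[interior] - 2.5) / 2.5 < 0.02))
  expect_equal(hilbert_envelope(rep(0, 100)), rep(0, 100),
               ignore_attr = TRUE)
  # amplitude step a -> 2a localised within 0.25 s
  xs <- c(tone(10, rate, 5), tone(10, rate, 5, amp = 2))
  es <- hilbert_envelope(xs, rate)
  crossing <- which(es > 1.5)[1]
  expect_lt(abs(crossing - 5 * rate) / rate, 0.25)
  expect_error(hilbert_envelope(c(1, NA)),
               class = "brainstates_parameter_error")
})

test_that("TR epoching yields 80-sample epochs that tile the run", {
  rate <- 200
  x <- matrix(rnorm(rate * 600 / 10 * 6), ncol = 6)   # 60 s, 6 channels
  ep <- epoch_downsample(x, rate, tr = 2, target_rate = 40)
  expect_equal(dim(ep)[2], 80)
  expect_equal(dim(ep)[1], 30)
  # concatenating epochs reconstructs the downsampled series
  rec <- do.call(rbind, lapply(seq_len(dim(ep)[1]), function(e) ep[e, , ]))
  expect_equal(rec, unname(attr(ep, "series")), ignore_attr = TRUE)
  # a 600 s run at the acquisition grid gives 300 epochs
  long <- matrix(0, 600 * rate, 1)
  expect_equal(dim(epoch_downsample(long, rate))[1], 300)
  expect_error(epoch_downsample(x, rate, target_rate = 37),
               class = "brainstates_parameter_error")
  expect_error(epoch_downsample(x[1:100, ], rate),
               class = "brainstates_parameter_error")
})

test_that("Welch band power matches the analytic tone power", {
  rate <- 40
  ep <- array(0, dim = c(1, 80, 6),
              dimnames = list(NULL, NULL, c("Oz", "O1", "O2", "POz", "PO3", "PO4")))
  for (cc in 1:6) ep[1, , cc] <- tone(10, rate, 2)
  attr(ep, "rate") <- rate
  p <- welch_alpha_power(ep)
  expect_equal(p, 0.5, tolerance = 0.10)         # a^2 / 2 for unit amplitude
  ep2 <- ep; for (cc in 1:6) ep2[1, , cc] <- tone(10, rate, 2, amp = 2)
  attr(ep2, "rate") <- rate
  expect_equal(welch_alpha_power(ep2) / p, 4, tolerance = 0.05)
  epz <- ep; epz[1, , ] <- 0; attr(epz, "rate") <- rate
  expect_equal(welch_alpha_power(epz), 0)
  expect_error(welch_alpha_power(ep, channels = c("Oz", "Pz")), "Pz",
               class = "brainstates_parameter_error")
})

test_that("two independent power estimators agree for an in-band tone", {
  rate <- 200
  x <- tone(10, rate, 20, amp = 1.4)
  filt <- bandpass_alpha(x, rate)
  env <- hilbert_envelope(filt, rate)
  ep <- epoch_downsample(matrix(filt, ncol = 1), rate, tr = 2)
  dimnames(ep)[[3]] <- "Oz"
  welch <- welch_alpha_power(ep, channels = "Oz")
  env_power <- mean(env[401:3600]^2) / 2
  expect_equal(mean(welch[3:8]), env_power, tolerance = 0.10)
})

test_that("regressor normalisation is an exact z-score and affine invariant", {
  set.seed(2)
  x <- runif(50, 3, 9)
  z <- normalize_regressor(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(normalize_regressor(2.5 * x + 7), z, tolerance = 1e-12)
  expect_equal(normalize_regressor(-x), -z, tolerance = 1e-12)
  expect_error(normalize_regressor(rep(4, 10)),
               class = "brainstates_computation_error")
})

test_that("alpha condition test shares the paired engine", {
  pw <- tibble::tibble(subject = rep(c("s1", "s2"), each = 2),
                       condition = rep(c("EO", "EC"), 2),
                       value = c(5, 3, 7, 3))
  ct <- alpha_condition_test(pw)
  expect_equal(ct$statistic, 3.0, tolerance = 1e-12)
  expect_equal(ct$df, 1)
  pw0 <- dplyr::mutate(pw, value = c(5, 4, 3, 4))
  expect_equal(alpha_condition_test(pw0)$statistic, 0)
})

test_that("stronger generator alpha amplitudes yield strictly larger extracted power", {
  # three-level staircase through the full feature chain
  powers <- vapply(c(0.6, 1.2, 2.4), function(a) {
    y <- simulate_eeg_run(rep(1L, 6000), matrix(a, 1, 6), carrier = 10,
                          raw_rate = 200, noise_sd = 0.3, seed = 17)
    colnames(y) <- c("Oz", "O1", "O2", "POz", "PO3", "PO4")
    mean(alpha_power_course(y, 200)$alpha_power)
  }, 0)
  expect_true(all(diff(powers) > 0))
})

test_that("EC-scaled alpha amplitudes are detected by the paired pipeline test", {
  mf <- study_manifest(n_subjects = 18, n_volumes = 15)
  hits <- 0
  for (i in 1:5) {
    st <- make_study(mf, effect_profile("reactive"), seed = 400 + i,
                     voxels = FALSE, fmri = FALSE)
    eeg <- st$runs[st$runs$modality == "eeg", ]
    pw <- dplyr::bind_rows(lapply(seq_len(nrow(eeg)), function(j) {
      tibble::tibble(subject = eeg$subject[j], condition = eeg$condition[j],
                     value = mean(alpha_power_course(
                       eeg$data[[j]], st$manifest$eeg_rate)$alpha_power))
    }))
    ct <- alpha_condition_test(pw)
    if (ct$p_value < 0.05 && ct$difference < 0) hits <- hits + 1
  }
  expect_equal(hits, 5)   # EC > EO in every replicate
})

test_that("alpha course length matches the paired BOLD run", {
  mf <- study_manifest(n_subjects = 1, n_volumes = 20)
  st <- make_study(mf, effect_profile("null"), seed = 3, voxels = FALSE)
  eeg <- st$runs[st$runs$modality == "eeg", ]
  pc <- alpha_power_course(eeg$data[[1]], mf$eeg_rate)
  expect_equal(nrow(pc), mf$n_volumes)
  env <- eeg_envelope_features(eeg$data[[1]], mf$eeg_rate)
  expect_equal(nrow(env), mf$n_volumes * mf$tr * 40)
})
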