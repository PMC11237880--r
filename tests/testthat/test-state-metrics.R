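test_that("fractional occupancy counts states and sums to one", {
  expect_equal(fractional_occupancy(c(1, 1, 2, 2), 2), c(0.5, 0.5))
  expect_equal(fractional_occupancy(c(1, 1, 1, 2, 3, 3, 3, 3, 3, 3), 3),
               c(0.3, 0.1, 0.6))
  set.seed(4)
  p <- sample.int(5, 997, replace = TRUE)
  expect_equal(sum(fractional_occupancy(p, 5)), 1, tolerance = 1e-12)
})

test_that("lifetimes and intervals follow the visit structure", {
  lt <- state_lifetimes(c(1, 1, 1, 2), 2, K = 2)
  expect_equal(lt[["1"]], 6)
  expect_equal(lt[["2"]], 2)
  expect_equal(state_lifetimes(rep(3L, 17), 0.5, K = 3)[["3"]], 8.5)
  alt <- state_lifetimes(rep(c(1L, 2L), 3), 1, K = 2)
  expect_equal(alt[["1"]], rep(1, 3))
  iv <- state_intervals(c(1, 2, 2, 1), 2, K = 2)
  expect_equal(iv[["1"]], 4)
  expect_equal(iv[["2"]], numeric(0))  # single visit
  expect_equal(state_intervals(c(1, 2, 1, 2, 1), 2, K = 2)[["1"]], c(2, 2))
})

test_that("lifetime mass equals occupancy times duration, and visits bracket intervals", {
  set.seed(11)
  p <- simulate_chain(brainstates:::make_transition(3, 0.8), rep(1 / 3, 3),
                      400, seed = 2)
  fo <- fractional_occupancy(p, 3)
  lt <- state_lifetimes(p, 2, K = 3)
  iv <- state_intervals(p, 2, K = 3)
  for (k in 1:3) {
    expect_equal(sum(lt[[k]]), fo[k] * 400 * 2, tolerance = 1e-12)
    expect_equal(length(lt[[k]]), length(iv[[k]]) + 1)
  }
})

test_that("switching rate counts state changes per sample", {
  expect_equal(switching_rate(rep(4L, 50)), 0)
  expect_equal(switching_rate(c(1, 2, 1, 2)), 1.0)
  set.seed(3)
  u <- sample.int(4, 1e4, replace = TRUE)
  expect_equal(switching_rate(u), 0.75, tolerance = 0.02 / 0.75)
  expect_error(switching_rate(1L), class = "brainstates_parameter_error")
})

test_that("first-quarter restriction keeps floor(T/4) samples", {
  paths <- tibble::tibble(subject = "s1", run = 1, condition = "EO",
                          period = 2, path = list(rep(c(1L, 2L), 150)))
  q <- restrict_first_quarter(paths)
  expect_equal(length(q$path[[1]]), 75)        # 150 s = 2.5 min at TR 2 s
  const <- tibble::tibble(subject = "s1", run = 1, condition = "EO",
                          period = 2, path = list(rep(2L, 40)))
  expect_equal(fractional_occupancy(restrict_first_quarter(const)$path[[1]], 3),
               c(0, 1, 0))
  mixed <- tibble::tibble(subject = "s1", run = 1, condition = "EO",
                          period = 2,
                          path = list(c(rep(3L, 10), rep(c(1L, 2L), 15))))
  expect_equal(fractional_occupancy(restrict_first_quarter(mixed)$path[[1]], 3),
               c(0, 0, 1))
})

test_that("paired contrasts reproduce the closed-form t and Bonferroni scaling", {
  # two subjects with EO-EC differences 2 and 4: t = 3, d = 3/sqrt(2)
  met <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 2),
    run = rep(1:2, 2),
    condition = rep(c("EO", "EC"), 2),
    state = 1L,
    fo = c(5, 3, 7, 3),
    switching_rate = c(5, 3, 7, 3)
  )
  ct <- compare_conditions(met, "fractional_occupancy", m_comparisons = 1)
  expect_equal(ct$statistic, 3.0, tolerance = 1e-12)
  expect_equal(ct$df, 1)
  expect_equal(ct$difference, 3)
  expect_equal(ct$cohens_d, 3 / sqrt(2), tolerance = 1e-12)
  expect_true(ct$conf.low <= ct$difference & ct$difference <= ct$conf.high)
  ct6 <- compare_conditions(met, "fractional_occupancy", m_comparisons = 6)
  expect_equal(ct6$p_adjusted, pmin(1, ct6$p_value * 6))
  sw <- compare_conditions(met, "switching_rate")
  expect_equal(sw$statistic, 3.0, tolerance = 1e-12)

  # equal condition means with nonzero difference variance: t exactly 0
  met0 <- dplyr::mutate(met, fo = c(5, 4, 3, 4))
  ct0 <- compare_conditions(met0, "fractional_occupancy")
  expect_equal(ct0$statistic, 0)
  expect_equal(ct0$difference, 0)
  # zero-variance differences are an error
  metz <- dplyr::mutate(met, fo = c(4, 2, 7, 5))
  expect_error(compare_conditions(metz, "fractional_occupancy"),
               class = "brainstates_computation_error")
})

test_that("state_metrics assembles a consistent per-run table", {
  paths <- tibble::tibble(
    subject = c("s1", "s1"), run = 1:2, condition = c("EO", "EC"),
    period = 2,
    path = list(c(1L, 1L, 2L, 2L, 1L, 3L), c(3L, 3L, 3L, 1L, 2L, 2L)))
  met <- state_metrics(paths, 3)
  expect_equal(nrow(met), 6)
  per_run_fo <- tapply(met$fo, met$run, sum)
  expect_true(all(abs(per_run_fo - 1) < 1e-9))
  expect_equal(met$switching_rate[met$run == 1], rep(3 / 5, 3))
  expect_equal(met$switching_rate_per_s, met$switching_rate / 2)
})
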