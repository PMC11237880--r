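# Haemodynamic mapping: double-gamma HRF, regressor construction, and
# first/subject/group-level GLMs on parcel matrices.

#' Canonical double-gamma haemodynamic response kernel
#'
#' `h(t) = g(t; shape = peak_delay, scale = 1) -
#'  ratio * g(t; shape = undershoot_delay, scale = 1)` with each `g` a gamma
#' density, sampled on a regular grid and normalised to unit peak height.
#' The positive lobe peaks near 5 s (the mode of the shape-6 gamma) and is
#' followed by a shallow undershoot.
#'
#' @param step Grid step in seconds (the regressor's native period).
#' @param peak_delay Shape of the positive lobe (seconds, scale 1).
#' @param undershoot_delay Shape of the undershoot lobe.
#' @param ratio Undershoot amplitude ratio.
#' @param length Kernel support in seconds (at least 32 s).
#' @return A list of class `bs_hrf` with `time`, `values`, `step` and the
#'   parameters.
#' @export
#' @examples
#' h <- double_gamma_hrf(step = 0.1)
#' h$values[1] # 0 at t = 0
double_gamma_hrf <- function(step, peak_delay = 6, undershoot_delay = 16,
                             ratio = 1 / 6, length = 32) {
  if (step <= 0) stop_param("step must be positive")
  if (peak_delay <= 1 || undershoot_delay <= 1) {
    stop_param("gamma shapes must exceed 1 for a zero-onset kernel")
  }
  if (length <= undershoot_delay) {
    stop_param("kernel length must exceed the undershoot delay")
  }
  tt <- seq(0, length, by = step)
  h <- dgamma(tt, shape = peak_delay, scale = 1) -
    ratio * dgamma(tt, shape = undershoot_delay, scale = 1)
  h <- h / max(h)
  structure(list(time = tt, values = h, step = step,
                 peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 ratio = ratio, length = length), class = "bs_hrf")
}

# Causal same-length convolution approximating the continuous integral:
# (x * h)(t_i) = sum_j x[i - j] h[j] * dt, zero pre-history.
convolve_causal <- function(x, kernel, step) {
  T_len <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open") * step
  full[seq_len(T_len)]
}

#' Build a TR-grid haemodynamic regressor from a state course
#'
#' Convolves a state probability (or activation/power) course with the
#' double-gamma kernel at the course's native rate, then samples the result
#' at the fMRI volume instants `0, tr, 2 tr, ...`.
#'
#' @param course Numeric course at the native rate.
#' @param rate Native sampling rate of `course` in Hz.
#' @param tr fMRI sampling period in seconds.
#' @param hrf Optional [double_gamma_hrf()]; built at `step = 1/rate` when
#'   `NULL`.
#' @param n_out Expected output length (number of volumes); defaults to
#'   `floor(duration / tr)`. A mismatch with a paired fMRI run is an error.
#' @return Numeric regressor of length `n_out`.
#' @export
build_regressor <- function(course, rate, tr = 2, hrf = NULL, n_out = NULL) {
  if (rate < 1 / tr) stop_param("course rate must be at least the TR rate")
  if (is.null(hrf)) hrf <- double_gamma_hrf(step = 1 / rate)
  if (abs(hrf$step - 1 / rate) > 1e-9) {
    stop_param("hrf kernel step (%.4g s) does not match the course rate", hrf$step)
  }
  conv <- convolve_causal(as.numeric(course), hrf$values, hrf$step)
  duration <- length(course) / rate
  n_vol <- n_out %||% floor(duration / tr + 1e-9)
  idx <- round((seq_len(n_vol) - 1) * tr * rate) + 1
  if (any(idx > length(conv))) {
    stop_param("regressor length %d does not fit the course duration %.1f s",
               n_vol, duration)
  }
  conv[idx]
}

#' First-level GLM of target series on regressors
#'
#' Ordinary least squares of every target (parcel/voxel) series on the given
#' regressors plus an intercept. Regressors are demeaned before fitting.
#' Positive and negative mean-activation contrasts are the `+t` and `-t`
#' maps for each regressor. Optional AR(1) prewhitening estimates a common
#' lag-1 autocorrelation from the pooled OLS residuals and refits on
#' quasi-differenced data.
#'
#' @param Y `T x V` matrix of target series (targets in columns), or `V x T`
#'   with `targets_in_rows = TRUE`.
#' @param X `T x p` matrix (or vector) of regressors, without intercept.
#' @param targets_in_rows Set `TRUE` when `Y` is `V x T`.
#' @param prewhiten Apply AR(1) prewhitening before the final fit.
#' @return A list of class `bs_glm`: tibble `estimates` (target, term,
#'   estimate, se, statistic, df), `contrasts` (positive/negative t maps),
#'   and fit metadata.
#' @export
first_level_glm <- function(Y, X, targets_in_rows = FALSE, prewhiten = FALSE) {
  Y <- as.matrix(Y)
  if (targets_in_rows) Y <- t(Y)
  X <- as.matrix(X)
  if (nrow(X) != nrow(Y)) stop_param("Y and X must share the time dimension")
  p <- ncol(X)
  terms <- colnames(X) %||% sprintf("x%d", seq_len(p))
  X <- sweep(X, 2, colMeans(X))
  D <- cbind(intercept = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])
    stop_param("design is rank deficient; collinear column(s): %s",
               paste(colnames(D)[drop_cols], collapse = ", "))
  }
  df <- nrow(D) - ncol(D)
  if (df < 1) stop_param("need more samples than design columns")
  rho <- NA_real_
  if (prewhiten) {
    res0 <- qr.resid(qrD, Y)
    num <- sum(res0[-1, ] * res0[-nrow(res0), ])
    den <- sum(res0^2)
    rho <- num / den
    W <- function(M) M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
    D <- W(D); Y <- W(Y)
    qrD <- qr(D)
    df <- nrow(D) - ncol(D)
  }
  beta <- qr.coef(qrD, Y)                      # (p+1) x V
  res <- qr.resid(qrD, Y)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrD))
  se <- sqrt(outer(diag(XtXinv), sigma2))      # (p+1) x V
  tstat <- beta / se
  V <- ncol(Y)
  targets <- colnames(Y) %||% sprintf("t%03d", seq_len(V))
  est <- tibble::tibble(
    target = rep(targets, each = p + 1),
    term = rep(c("intercept", terms), V),
    estimate = as.numeric(beta),
    se = as.numeric(se),
    statistic = as.numeric(tstat),
    df = df
  )
  contr <- dplyr::filter(est, .data$term != "intercept")
  contrasts <- dplyr::bind_rows(
    dplyr::mutate(contr, contrast = "positive"),
    dplyr::mutate(contr, contrast = "negative",
                  estimate = -.data$estimate, statistic = -.data$statistic)
  )
  structure(list(estimates = est, contrasts = contrasts, df = df,
                 terms = terms, level = "first", rho = rho,
                 prewhiten = prewhiten), class = "bs_glm")
}

#' Average first-level results within subject and condition
#'
#' Fixed-effects averaging of run-level regression coefficients across the
#' runs of each condition, per subject.
#'
#' @param fits A tibble with columns `subject`, `condition` and `fit` (a
#'   list-column of [first_level_glm()] results).
#' @return A tibble `subject, condition, target, term, estimate` of class
#'   `bs_subject_maps`.
#' @export
subject_level_average <- function(fits) {
  if (!all(c("subject", "condition", "fit") %in% names(fits))) {
    stop_param("fits must have subject, condition and fit columns")
  }
  if (nrow(fits) == 0) stop_param("no runs to average")
  long <- tidyr::unnest(
    dplyr::mutate(fits,
                  est = purrr::map(.data$fit, function(f)
                    dplyr::filter(f$estimates, .data$term != "intercept"))),
    "est")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$subject, .data$condition, .data$target,
                    .data$term),
    estimate = mean(.data$estimate), n_runs = dplyr::n(), .groups = "drop")
  class(out) <- c("bs_subject_maps", class(out))
  out
}

#' Group-level test of subject condition maps
#'
#' One-sample t test per target for a single-condition mean map (`"EO"`,
#' `"EC"`), or a paired t test per target for the condition contrasts
#' (`"EO-EC"`, `"EC-EO"`). p values are Bonferroni-corrected across targets.
#'
#' @param maps A [subject_level_average()] tibble.
#' @param contrast One of `"EO"`, `"EC"`, `"EO-EC"`, `"EC-EO"`.
#' @param term Which regressor's maps to test (default: the only one).
#' @param alpha Familywise significance level.
#' @return A tibble `target, estimate, statistic, df, p_value, p_adjusted,
#'   significant`; targets with zero variance across subjects are returned
#'   with `NA` statistics.
#' @export
group_level_test <- function(maps, contrast = c("EO", "EC", "EO-EC", "EC-EO"),
                             term = NULL, alpha = 0.05) {
  contrast <- match.arg(contrast)
  if (is.null(term)) {
    term <- unique(maps$term)
    if (length(term) > 1) stop_param("several terms present; pick one")
  }
  maps <- dplyr::filter(maps, .data$term == !!term)
  wide <- tidyr::pivot_wider(maps[c("subject", "condition", "target", "estimate")],
                             names_from = "condition", values_from = "estimate")
  if (contrast %in% c("EO", "EC")) {
    wide$value <- wide[[contrast]]
  } else if (contrast == "EO-EC") {
    wide$value <- wide$EO - wide$EC
  } else {
    wide$value <- wide$EC - wide$EO
  }
  by_target <- split(wide$value, wide$target)
  n_sub <- length(unique(wide$subject))
  if (n_sub < 3) stop_param("group-level test needs at least 3 subjects")
  m <- length(by_target)
  res <- purrr::map(by_target, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || sd(v) < 1e-14) {
      return(tibble::tibble(estimate = mean(v), statistic = NA_real_,
                            df = length(v) - 1, p_value = NA_real_))
    }
    tt <- t.test(v)
    tibble::tibble(estimate = mean(v), statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  })
  out <- dplyr::bind_cols(tibble::tibble(target = names(by_target)),
                          dplyr::bind_rows(res))
  out$p_adjusted <- pmin(1, out$p_value * m)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}
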