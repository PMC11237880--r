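# Viterbi-path state metrics and EO-vs-EC paired contrasts.

#' Fractional occupancy of each state along a path
#'
#' @param path Integer state sequence in `1..K`.
#' @param K Number of states.
#' @return Length-`K` vector summing to 1.
#' @export
fractional_occupancy <- function(path, K) {
  if (length(path) == 0) stop_param("path must be nonempty")
  tabulate(path, nbins = K) / length(path)
}

#' State lifetimes (visit durations)
#'
#' One duration per maximal constant run of the path, in seconds.
#' Boundary-truncated first/last visits are included by default.
#'
#' @param path Integer state sequence.
#' @param sampling_period Sampling period in seconds.
#' @param K Number of states.
#' @param drop_boundary Exclude the first and last (possibly truncated) visits.
#' @return A list of `K` numeric vectors of durations.
#' @export
state_lifetimes <- function(path, sampling_period, K = max(path),
                            drop_boundary = FALSE) {
  if (sampling_period <= 0) stop_param("sampling_period must be positive")
  r <- rle(as.integer(path))
  keep <- rep(TRUE, length(r$lengths))
  if (drop_boundary && length(r$lengths) > 0) {
    keep[c(1, length(keep))] <- FALSE
  }
  out <- lapply(seq_len(K), function(k)
    r$lengths[keep & r$values == k] * sampling_period)
  names(out) <- as.character(seq_len(K))
  out
}

#' State interval times (gaps between consecutive visits)
#'
#' For each state visited at least twice, the durations of the gaps between
#' consecutive visits, in seconds; states with fewer than two visits yield
#' empty vectors.
#'
#' @inheritParams state_lifetimes
#' @return A list of `K` numeric vectors of durations.
#' @export
state_intervals <- function(path, sampling_period, K = max(path)) {
  if (sampling_period <= 0) stop_param("sampling_period must be positive")
  r <- rle(as.integer(path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # gap in samples between the end of one visit and the start of the next
  out <- lapply(seq_len(K), function(k) {
    vis <- which(r$values == k)
    if (length(vis) < 2) return(numeric(0))
    (starts[vis[-1]] - ends[vis[-length(vis)]] - 1) * sampling_period
  })
  names(out) <- as.character(seq_len(K))
  out
}

#' State switching rate
#'
#' Fraction of consecutive sample pairs at which the path changes state
#' (transitions per sample; divide by the sampling period for a per-second
#' rate).
#'
#' @param path Integer state sequence of length at least 2.
#' @return Scalar in `[0, 1]`.
#' @export
switching_rate <- function(path) {
  if (length(path) < 2) stop_param("switching rate needs at least 2 samples")
  mean(diff(as.integer(path)) != 0)
}

#' Restrict decoded paths to the first quarter of each run
#'
#' Keeps the first `floor(T / 4)` samples of every path (2.5 min of a
#' 10-min run), after which all state metrics apply unchanged.
#'
#' @param paths A [viterbi_paths()] tibble (or any tibble with a `path`
#'   list-column).
#' @return The same tibble with truncated paths.
#' @export
restrict_first_quarter <- function(paths) {
  paths$path <- lapply(paths$path, function(p) {
    if (length(p) < 4) stop_param("runs need at least 4 samples")
    p[seq_len(floor(length(p) / 4))]
  })
  paths
}

#' Per-run state metrics table
#'
#' Computes fractional occupancy, lifetimes, interval times (descriptive)
#' and the switching rate for every run's decoded path.
#'
#' @param paths A [viterbi_paths()] tibble with `subject`, `run`,
#'   `condition`, `period` and `path`.
#' @param K Number of states.
#' @param drop_boundary Passed to [state_lifetimes()].
#' @return A tibble of class `bs_metrics` keyed (subject, run, condition,
#'   state) with columns `fo`, `lifetimes` and `intervals` (list-columns of
#'   durations in seconds), `mean_lifetime`, `mean_interval`, `n_visits`,
#'   and the per-run `switching_rate` (per sample) and
#'   `switching_rate_per_s`.
#' @export
state_metrics <- function(paths, K, drop_boundary = FALSE) {
  rows <- purrr::pmap(
    list(paths$subject, paths$run, paths$condition, paths$period, paths$path),
    function(subject, run, condition, period, path) {
      fo <- fractional_occupancy(path, K)
      lt <- state_lifetimes(path, period, K, drop_boundary)
      iv <- state_intervals(path, period, K)
      sw <- switching_rate(path)
      tibble::tibble(
        subject = subject, run = run, condition = condition, state = seq_len(K),
        fo = fo,
        lifetimes = lt,
        intervals = iv,
        mean_lifetime = vapply(lt, function(x) mean(x)[1], 0),
        mean_interval = vapply(iv, function(x) if (length(x)) mean(x) else NA_real_, 0),
        n_visits = vapply(seq_len(K), function(k)
          sum(rle(as.integer(path))$values == k), 0),
        switching_rate = sw,
        switching_rate_per_s = sw / period
      )
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bs_metrics", class(out))
  out
}

# Paired t with Cohen's d and noncentral-t CI for d. `diffs` are per-subject
# paired differences (first condition minus second).
paired_contrast_row <- function(diffs, m = 1, conf = 0.95,
                                degenerate = c("error", "na")) {
  degenerate <- match.arg(degenerate)
  n <- length(diffs)
  if (n < 2) stop_param("paired contrast needs at least 2 subjects")
  if (sd(diffs) < 1e-14) {
    if (degenerate == "error") {
      stop_compute("zero-variance paired differences; t undefined")
    }
    return(tibble::tibble(
      difference = mean(diffs), statistic = NA_real_, df = n - 1,
      p_value = NA_real_, p_adjusted = NA_real_, conf.low = NA_real_,
      conf.high = NA_real_, cohens_d = NA_real_, d_conf.low = NA_real_,
      d_conf.high = NA_real_))
  }
  tt <- t.test(diffs, conf.level = conf)
  d <- mean(diffs) / sd(diffs)
  tval <- unname(tt$statistic)
  # CI for d: invert the noncentral t distribution of t = d * sqrt(n)
  ncp_bounds <- vapply(c(1 - (1 - conf) / 2, (1 - conf) / 2), function(pr) {
    # pnt warns about precision in the far tails; the CI is insensitive there
    f <- function(ncp) suppressWarnings(pt(tval, df = n - 1, ncp = ncp)) - pr
    lo <- tval - 10 - 10 * abs(tval); hi <- tval + 10 + 10 * abs(tval)
    tryCatch(stats::uniroot(f, c(lo, hi))$root, error = function(e) NA_real_)
  }, 0)
  tibble::tibble(
    difference = mean(diffs),
    statistic = tval,
    df = n - 1,
    p_value = tt$p.value,
    p_adjusted = pmin(1, tt$p.value * m),
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    cohens_d = d,
    d_conf.low = ncp_bounds[1] / sqrt(n),
    d_conf.high = ncp_bounds[2] / sqrt(n)
  )
}

#' Paired EO-vs-EC contrasts of state metrics
#'
#' Same-condition runs are averaged within subject first; each state's
#' fractional occupancy (or the per-run switching rate, once) is then
#' compared between conditions with a paired t test, reported as
#' EO minus EC with Bonferroni-adjusted p values, 95% CIs and Cohen's d.
#'
#' @param metrics A [state_metrics()] tibble.
#' @param metric `"fractional_occupancy"` or `"switching_rate"`.
#' @param m_comparisons Bonferroni multiplier; defaults to the number of
#'   states for fractional occupancy and 1 for the switching rate.
#' @param conditions The two condition labels, first minus second.
#' @param degenerate `"error"` (default) aborts on zero-variance paired
#'   differences; `"na"` reports such states with `NA` statistics instead
#'   (used by the pipeline driver, where a never-visited state should not
#'   abort the experiment).
#' @return A tibble of class `bs_contrast`, one row per state (or a single
#'   row for the switching rate).
#' @export
compare_conditions <- function(metrics,
                               metric = c("fractional_occupancy",
                                          "switching_rate"),
                               m_comparisons = NULL,
                               conditions = c("EO", "EC"),
                               degenerate = c("error", "na")) {
  metric <- match.arg(metric)
  degenerate <- match.arg(degenerate)
  if (metric == "switching_rate") {
    per_run <- dplyr::distinct(metrics, .data$subject, .data$run,
                               .data$condition, .data$switching_rate)
    subj <- dplyr::summarise(
      dplyr::group_by(per_run, .data$subject, .data$condition),
      value = mean(.data$switching_rate), .groups = "drop")
    m <- m_comparisons %||% 1
    diffs <- paired_differences(subj, conditions)
    out <- dplyr::mutate(paired_contrast_row(diffs, m, degenerate = degenerate),
                         metric = metric, .before = 1)
  } else {
    subj <- dplyr::summarise(
      dplyr::group_by(metrics, .data$subject, .data$condition, .data$state),
      value = mean(.data$fo), .groups = "drop")
    K <- max(metrics$state)
    m <- m_comparisons %||% K
    out <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
      diffs <- paired_differences(dplyr::filter(subj, .data$state == k),
                                  conditions)
      dplyr::mutate(paired_contrast_row(diffs, m, degenerate = degenerate),
                    metric = metric, state = k, .before = 1)
    }))
  }
  class(out) <- c("bs_contrast", class(out))
  out
}

# Subject-level paired differences cond1 - cond2; errors if a subject lacks
# a condition.
paired_differences <- function(subj_values, conditions) {
  wide <- tidyr::pivot_wider(subj_values, names_from = "condition",
                             values_from = "value")
  for (cond in conditions) {
    if (!cond %in% names(wide) || any(is.na(wide[[cond]]))) {
      stop_param("every subject needs at least one %s run", cond)
    }
  }
  wide[[conditions[1]]] - wide[[conditions[2]]]
}
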