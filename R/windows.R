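# Sliding-window fractional-occupancy time courses and cross-modal
# correlation of group-mean courses.

#' Windowed fractional occupancy of a decoded path
#'
#' Tiles the run with windows defined in seconds from run start (so courses
#' from different sampling grids share one window grid) and computes the
#' fractional occupancy of every state inside each window. The trailing
#' partial window is dropped.
#'
#' @param path Integer state path, or a `T x K` gamma matrix with
#'   `weights = TRUE` for probability-weighted occupancy.
#' @param period Sampling period of the path in seconds.
#' @param K Number of states.
#' @param window_length Window length in seconds (default 10).
#' @param overlap Window overlap in seconds (default 0).
#' @param weights Treat `path` as a gamma matrix and average probabilities.
#' @return A matrix of class `bs_fo_course` (`windows x K`, rows sum to 1)
#'   with attributes `window_length`, `overlap`, `window_start` (s).
#' @export
windowed_fo <- function(path, period, K, window_length = 10, overlap = 0,
                        weights = FALSE) {
  if (window_length < period) {
    stop_param("window_length (%.3g s) is shorter than one sample (%.3g s)",
               window_length, period)
  }
  if (overlap >= window_length) stop_param("overlap must be below the window length")
  w <- as.integer(round(window_length / period))
  step <- as.integer(round((window_length - overlap) / period))
  if (step < 1) stop_param("window step is below one sample")
  T_len <- if (weights) nrow(path) else length(path)
  n_win <- (T_len - w) %/% step + 1
  if (n_win < 1) stop_param("run shorter than one window")
  out <- matrix(0, n_win, K)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1) * step + 1):((i - 1) * step + w)
    out[i, ] <- if (weights) colMeans(path[idx, , drop = FALSE]) else
      fractional_occupancy(path[idx], K)
  }
  structure(out, class = c("bs_fo_course", class(out)),
            window_length = window_length, overlap = overlap,
            window_start = (seq_len(n_win) - 1) * (window_length - overlap),
            level = "run")
}

#' Group-average windowed occupancy with confidence band
#'
#' Pointwise mean across subjects' courses for one aligned run, with a 95%
#' t-based confidence band.
#'
#' @param courses List of [windowed_fo()] matrices on identical window grids
#'   (one per subject).
#' @param conf Confidence level.
#' @return A list of class `bs_group_fo`: `mean` (`windows x K`), `lower`,
#'   `upper`, `n`, and the window grid attributes.
#' @export
group_average_fo <- function(courses, conf = 0.95) {
  dims <- vapply(courses, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_param("courses must share one window grid and state count")
  }
  n <- length(courses)
  arr <- simplify2array(courses)          # W x K x n
  mu <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), sd) / sqrt(n)
  tcrit <- if (n > 1) qt(1 - (1 - conf) / 2, df = n - 1) else 0
  structure(list(mean = mu, lower = mu - tcrit * se, upper = mu + tcrit * se,
                 n = n,
                 window_start = attr(courses[[1]], "window_start"),
                 window_length = attr(courses[[1]], "window_length")),
            class = "bs_group_fo")
}

#' Cross-modal correlation of windowed occupancy courses
#'
#' Pearson correlation, over windows, between every pair of one modality's
#' and the other modality's group-mean state occupancy courses for the same
#' run, with two-sided p values from the t transform and Bonferroni
#' correction over all cells.
#'
#' @param fmri_course `windows x K_f` group-mean course.
#' @param eeg_course `windows x K_e` group-mean course on the same window
#'   grid.
#' @param m Bonferroni multiplier (default: number of cells).
#' @return A tibble of class `bs_crossmodal`: `fmri_state`, `eeg_state`,
#'   `r`, `p_value`, `p_adjusted`, `n_windows`. Zero-variance cells carry
#'   `NA`.
#' @export
crossmodal_correlation <- function(fmri_course, eeg_course, m = NULL) {
  A <- if (is.list(fmri_course)) fmri_course$mean else unclass(fmri_course)
  B <- if (is.list(eeg_course)) eeg_course$mean else unclass(eeg_course)
  if (nrow(A) != nrow(B)) {
    stop_param("courses must be on the same window grid (got %d vs %d windows)",
               nrow(A), nrow(B))
  }
  W <- nrow(A)
  if (W < 3) stop_param("need at least 3 windows to correlate")
  Kf <- ncol(A); Ke <- ncol(B)
  m <- m %||% (Kf * Ke)
  grid <- expand.grid(fmri_state = seq_len(Kf), eeg_state = seq_len(Ke))
  sda <- apply(A, 2, sd); sdb <- apply(B, 2, sd)
  if (any(sda < 1e-14) || any(sdb < 1e-14)) {
    warn("zero-variance windowed course; its correlations are undefined")
  }
  res <- purrr::pmap(grid, function(fmri_state, eeg_state) {
    x <- A[, fmri_state]; y <- B[, eeg_state]
    if (sda[fmri_state] < 1e-14 || sdb[eeg_state] < 1e-14) {
      return(tibble::tibble(r = NA_real_, p_value = NA_real_))
    }
    r <- cor(x, y)
    tval <- r * sqrt((W - 2) / max(1 - r^2, 1e-300))
    tibble::tibble(r = r, p_value = 2 * pt(-abs(tval), df = W - 2))
  })
  out <- dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(res))
  out$p_adjusted <- pmin(1, out$p_value * m)
  out$n_windows <- W
  class(out) <- c("bs_crossmodal", class(out))
  out
}
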