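# State-wise weighted multitaper spectral estimation.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the DPSS, ordered by decreasing eigenvalue
#' and sign-fixed so each taper's mean lobe is nonnegative. Each taper has
#' unit energy.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k = max(1, floor(2 * nw - 1))) {
  if (k > n) stop_param("cannot build %d tapers of length %d", k, n)
  W <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- i[-1] * (n - i[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(seq_len(n - 1), 2:n)] <- off
  A[cbind(2:n, seq_len(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
  }
  tapers
}

# Multitaper one-sided PSD of one window (density scaling).
multitaper_psd <- function(x, rate, tapers) {
  n <- length(x)
  nf <- n %/% 2 + 1
  acc <- numeric(nf)
  for (j in seq_len(ncol(tapers))) {
    P <- Mod(fft(x * tapers[, j]))^2 / rate
    P <- P[seq_len(nf)]
    P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
    if (n %% 2 == 1) P[nf] <- 2 * P[nf]
    acc <- acc + P
  }
  list(freq = (seq_len(nf) - 1) * rate / n, psd = acc / ncol(tapers))
}

#' State-wise weighted multitaper spectra
#'
#' Segments the series into non-overlapping windows, estimates a multitaper
#' PSD per window and channel, and forms each state's spectrum as the
#' weighted average of window PSDs with weights equal to the window-mean
#' state probability: windows where a state is more likely active
#' contribute more. With `K = 1` this reduces exactly to the unweighted
#' multitaper PSD.
#'
#' @param series `T x C` matrix at `rate` Hz.
#' @param gamma `T x K` state probability matrix aligned with `series`.
#' @param rate Sampling rate in Hz.
#' @param window_length Window length in seconds (default 2, one TR).
#' @param time_bandwidth DPSS time-bandwidth product (default 3, giving 5
#'   tapers).
#' @return A tibble of class `bs_spectra`: `frequency`, `state`, `channel`,
#'   `psd` (units^2/Hz), with taper settings as attributes. States with zero
#'   total weight are omitted (reported missing with a warning).
#' @export
weighted_multitaper <- function(series, gamma, rate, window_length = 2,
                                time_bandwidth = 3) {
  series <- as.matrix(series)
  gamma <- as.matrix(gamma)
  if (nrow(series) != nrow(gamma)) {
    stop_param("series and gamma must be aligned in time")
  }
  L <- as.integer(round(window_length * rate))
  n_tapers <- max(1, floor(2 * time_bandwidth - 1))
  if (L < 2 * n_tapers) {
    stop_param("window too short for %d tapers", n_tapers)
  }
  K <- ncol(gamma)
  C <- ncol(series)
  n_win <- nrow(series) %/% L
  if (n_win < 1) stop_param("series shorter than one window")
  tapers <- dpss_tapers(L, time_bandwidth, n_tapers)
  nf <- L %/% 2 + 1
  psd_arr <- array(0, dim = c(n_win, nf, C))
  weights <- matrix(0, n_win, K)
  freq <- NULL
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * L + 1):(w * L)
    weights[w, ] <- colMeans(gamma[idx, , drop = FALSE])
    for (cc in seq_len(C)) {
      sp <- multitaper_psd(series[idx, cc], rate, tapers)
      psd_arr[w, , cc] <- sp$psd
      freq <- sp$freq
    }
  }
  chan <- colnames(series) %||% sprintf("ch%02d", seq_len(C))
  rows <- list()
  for (k in seq_len(K)) {
    tw <- sum(weights[, k])
    if (tw <= 0) {
      warn(sprintf("state %d has zero total weight; spectrum undefined", k))
      next
    }
    for (cc in seq_len(C)) {
      spec <- colSums(psd_arr[, , cc, drop = FALSE][, , 1] * weights[, k]) / tw
      rows[[length(rows) + 1]] <- tibble::tibble(
        frequency = freq, state = k, channel = chan[cc], psd = spec)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "window_length") <- window_length
  attr(out, "time_bandwidth") <- time_bandwidth
  attr(out, "n_tapers") <- n_tapers
  attr(out, "rate") <- rate
  class(out) <- c("bs_spectra", class(out))
  out
}
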