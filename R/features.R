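# EEG alpha-band features: zero-phase bandpass, Hilbert envelope,
# TR-epoching with downsampling, Welch band power, regressor normalisation,
# and the EO/EC alpha-power contrast.

#' Zero-phase alpha bandpass filter
#'
#' Order-6 Butterworth bandpass applied forward and backward
#' ([signal::filtfilt()]), giving zero phase delay, passband ripple below
#' 1 dB across 7-13 Hz, and two-pass stopband attenuation of at least 40 dB
#' at 5 and 15 Hz. DC offsets are removed by the passband itself.
#'
#' @param x `T x C` matrix (or vector) of raw series.
#' @param rate Sampling rate in Hz (must exceed `2 * high`).
#' @param low,high Band edges in Hz.
#' @param order Butterworth order per pass.
#' @return Filtered series of the same shape.
#' @export
bandpass_alpha <- function(x, rate, low = 7, high = 13, order = 6) {
  if (rate <= 2 * high) {
    stop_param("sampling rate %.1f Hz violates Nyquist for a %.1f Hz band edge",
               rate, high)
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  if (vec) out <- drop(out)
  out
}

# Analytic signal via the FFT construction (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal per channel. The first and last 0.5 s
#' are edge-affected and flagged through the `"edge"` attribute (a logical
#' vector marking unreliable samples).
#'
#' @param x Filtered `T x C` matrix (or vector).
#' @param rate Sampling rate in Hz (used only to flag edges).
#' @return Nonnegative envelope series of the same shape, with attribute
#'   `"edge"`.
#' @export
hilbert_envelope <- function(x, rate = NULL) {
  if (any(!is.finite(x))) stop_param("input must be finite")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  env <- apply(x, 2, function(col) Mod(analytic_signal(col)))
  env <- matrix(env, nrow(x), ncol(x), dimnames = dimnames(x))
  edge <- rep(FALSE, nrow(x))
  if (!is.null(rate)) {
    ne <- min(nrow(x), ceiling(rate / 2))
    edge[seq_len(ne)] <- TRUE
    edge[seq(nrow(x) - ne + 1, nrow(x))] <- TRUE
  }
  if (vec) env <- drop(env)
  attr(env, "edge") <- edge
  env
}

#' Epoch a series by the TR and downsample
#'
#' Decimates the series to `target_rate` (the raw rate must be an integer
#' multiple; alpha-band content is far below the 20 Hz target Nyquist, so
#' plain decimation after bandpassing is alias-free) and splits it into
#' consecutive TR epochs of `tr * target_rate` samples. Trailing samples
#' short of a full epoch are dropped.
#'
#' @param x `T x C` matrix (or vector) at `rate` Hz.
#' @param rate Raw sampling rate in Hz.
#' @param tr Epoch length in seconds.
#' @param target_rate Output rate in Hz.
#' @return An `epochs x samples x channels` array with attributes `rate`
#'   and `series` (the concatenated downsampled matrix).
#' @export
epoch_downsample <- function(x, rate, tr = 2, target_rate = 40) {
  x <- as.matrix(x)
  fac <- rate / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
    stop_param("target_rate must divide the raw rate (%.1f / %.1f)", rate,
               target_rate)
  }
  down <- x[seq(1, nrow(x), by = as.integer(round(fac))), , drop = FALSE]
  spe <- as.integer(round(tr * target_rate))
  n_epochs <- nrow(down) %/% spe
  if (n_epochs < 1) stop_param("run shorter than one TR epoch")
  used <- down[seq_len(n_epochs * spe), , drop = FALSE]
  arr <- array(0, dim = c(n_epochs, spe, ncol(x)),
               dimnames = list(NULL, NULL, colnames(x)))
  for (cc in seq_len(ncol(x))) {
    arr[, , cc] <- matrix(used[, cc], nrow = n_epochs, ncol = spe, byrow = TRUE)
  }
  attr(arr, "rate") <- target_rate
  attr(arr, "series") <- used
  arr
}

# One-sided Welch power spectral density (Hann window, density scaling):
# integrating the PSD over frequency recovers signal power.
welch_psd <- function(x, rate, seg_length = 1, overlap = 0.5) {
  n <- length(x)
  L <- as.integer(round(seg_length * rate))
  if (L > n) stop_param("Welch segment (%d samples) exceeds the epoch (%d)", L, n)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  scale <- rate * sum(w^2)
  nf <- L %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    P <- Mod(fft(seg))^2 / scale
    P <- P[seq_len(nf)]
    P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
    if (L %% 2 == 1) P[nf] <- 2 * P[nf]
    acc <- acc + P
  }
  list(freq = (seq_len(nf) - 1) * rate / L, psd = acc / length(starts))
}

#' Per-epoch Welch alpha power averaged over posterior channels
#'
#' Welch's method per channel (1 s Hann segments, 50% overlap), integrated
#' over the alpha band and averaged across the selected channels, one
#' scalar per TR epoch.
#'
#' @param epochs An [epoch_downsample()] array.
#' @param band Integration band in Hz.
#' @param channels Channel labels to use; all must be present.
#' @return Numeric vector, one band power (units^2) per epoch.
#' @export
welch_alpha_power <- function(epochs, band = c(7, 13),
                              channels = c("Oz", "O1", "O2", "POz", "PO3", "PO4")) {
  rate <- attr(epochs, "rate")
  have <- dimnames(epochs)[[3]]
  if (is.null(have)) {
    if (dim(epochs)[3] != length(channels)) {
      stop_param("unnamed channels: expected %d, found %d", length(channels),
                 dim(epochs)[3])
    }
    idx <- seq_along(channels)
  } else {
    missing <- setdiff(channels, have)
    if (length(missing)) stop_param("channel '%s' not present", missing[1])
    idx <- match(channels, have)
  }
  vapply(seq_len(dim(epochs)[1]), function(e) {
    mean(vapply(idx, function(cc) {
      sp <- welch_psd(epochs[e, , cc], rate)
      df <- sp$freq[2] - sp$freq[1]
      sum(sp$psd[sp$freq >= band[1] & sp$freq <= band[2]]) * df
    }, 0))
  }, 0)
}

#' Normalise an alpha-power regressor
#'
#' Demeans and scales one run's course to unit standard deviation, removing
#' between-subject differences in absolute alpha power.
#'
#' @param course Numeric course.
#' @return Z-scored course.
#' @export
normalize_regressor <- function(course) {
  s <- sd(course)
  if (s < 1e-14) stop_compute("zero-variance course cannot be normalised")
  (course - mean(course)) / s
}

#' Alpha-power time course of one raw EEG run
#'
#' The full feature chain at the BOLD sampling rate: bandpass 7-13 Hz,
#' epoch by the TR and downsample to 40 Hz, Welch alpha power per epoch
#' averaged over the posterior channels.
#'
#' @param run `T x C` raw EEG matrix.
#' @param rate Raw sampling rate in Hz.
#' @param tr TR in seconds.
#' @param band Alpha band in Hz.
#' @param channels Posterior channel set.
#' @param normalize Z-score the course (as done before GLM use).
#' @return A tibble `epoch, alpha_power`.
#' @export
alpha_power_course <- function(run, rate, tr = 2, band = c(7, 13),
                               channels = colnames(run), normalize = FALSE) {
  filt <- bandpass_alpha(run, rate, band[1], band[2])
  ep <- epoch_downsample(filt, rate, tr = tr)
  p <- welch_alpha_power(ep, band = band, channels = channels)
  if (normalize) p <- normalize_regressor(p)
  tibble::tibble(epoch = seq_along(p), alpha_power = p)
}

#' Alpha-envelope HMM inputs of one raw EEG run
#'
#' Bandpass, Hilbert envelope, then decimation to the envelope grid
#' (default 40 Hz): the amplitude courses used as the EEG model's
#' observation channels.
#'
#' @inheritParams alpha_power_course
#' @param target_rate Envelope sampling rate in Hz.
#' @return A `T' x C` envelope matrix with attribute `period`.
#' @export
eeg_envelope_features <- function(run, rate, tr = 2, band = c(7, 13),
                                  target_rate = 40) {
  filt <- bandpass_alpha(run, rate, band[1], band[2])
  env <- hilbert_envelope(filt, rate)
  ep <- epoch_downsample(env, rate, tr = tr, target_rate = target_rate)
  out <- attr(ep, "series")
  attr(out, "period") <- 1 / target_rate
  attr(out, "modality") <- "eeg"
  out
}

#' Paired EO-vs-EC test of subject mean alpha power
#'
#' Averages each subject's per-epoch alpha power within condition and
#' compares the two conditions with a paired t test (EO minus EC), with
#' Cohen's d and confidence intervals.
#'
#' @param power A tibble with columns `subject`, `condition` and `value`
#'   (mean alpha power per subject and condition, or per run: runs are
#'   averaged within subject first).
#' @param conditions The two condition labels, first minus second.
#' @return A one-row [compare_conditions()]-style tibble.
#' @export
alpha_condition_test <- function(power, conditions = c("EO", "EC")) {
  subj <- dplyr::summarise(
    dplyr::group_by(power, .data$subject, .data$condition),
    value = mean(.data$value), .groups = "drop")
  if (length(unique(subj$subject)) < 2) {
    stop_param("need at least 2 subjects")
  }
  diffs <- paired_differences(subj, conditions)
  out <- dplyr::mutate(paired_contrast_row(diffs), metric = "alpha_power",
                       .before = 1)
  class(out) <- c("bs_contrast", class(out))
  out
}
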