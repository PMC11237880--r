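# ggplot2 visualisations of the main result types.

#' Plot state mean activation patterns
#'
#' Heatmap of posterior-expected state means per channel.
#'
#' @param object A [fit_hmm()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bs_hmm <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$channel,
                                   y = factor(.data$state),
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "state", fill = "mean",
                  title = "State mean activation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a group-mean windowed occupancy course
#'
#' One line per state with its 95% confidence band, over window start time.
#'
#' @param object A [group_average_fo()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bs_group_fo <- function(object, ...) {
  K <- ncol(object$mean)
  df <- tibble::tibble(
    time = rep(object$window_start, K),
    state = factor(rep(seq_len(K), each = length(object$window_start))),
    fo = as.numeric(object$mean),
    lower = as.numeric(object$lower),
    upper = as.numeric(object$upper)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$fo,
                                   colour = .data$state,
                                   fill = .data$state)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from run start (s)", y = "fractional occupancy") +
    ggplot2::theme_minimal()
}

#' Plot a cross-modal correlation matrix
#'
#' Tile map of the windowed-occupancy correlations between the two models'
#' states, with Bonferroni-significant cells marked.
#'
#' @param object A [crossmodal_correlation()] tibble.
#' @param alpha Significance level for the marks.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bs_crossmodal <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      sig = !is.na(.data$p_adjusted) & .data$p_adjusted < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$eeg_state),
                                   y = factor(.data$fmri_state),
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$sig, "*", "")),
                       size = 6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "EEG state", y = "fMRI state", fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot state spectra
#'
#' Channel-averaged power spectral density per state.
#'
#' @param object A [weighted_multitaper()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bs_spectra <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$frequency, .data$state),
    psd = mean(.data$psd), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$psd,
                                   colour = factor(.data$state))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD ~ (units^2 / Hz)),
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot model-selection metrics over state number
#'
#' Free energy and mean repeat reliability against the number of states.
#'
#' @param object A [scan_states()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bs_selection <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    td[c("k", "free_energy", "mean_reliability")],
    cols = c("free_energy", "mean_reliability"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "number of states", y = NULL) +
    ggplot2::theme_minimal()
}
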