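# broom-style tidiers for fitted objects.

#' Tidy a fitted HMM
#'
#' One row per state and channel with the posterior-expected mean and the
#' channel's marginal SD.
#'
#' @param x A [fit_hmm()] object.
#' @param ... Unused.
#' @return A tibble `state, channel, mean, sd`.
#' @export
tidy.bs_hmm <- function(x, ...) {
  K <- x$n_states
  C <- length(x$channels)
  tibble::tibble(
    state = rep(seq_len(K), each = C),
    channel = rep(x$channels, K),
    mean = as.numeric(t(x$means)),
    sd = as.numeric(t(vapply(x$covs, function(S) sqrt(diag(S)), numeric(C))))
  )
}

#' Glance at a fitted HMM
#'
#' @param x A [fit_hmm()] object.
#' @param ... Unused.
#' @return A one-row tibble with state count, channel and run counts, free
#'   energy, cycles and convergence flag.
#' @export
glance.bs_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states,
    n_channels = length(x$channels),
    n_runs = nrow(x$run_info),
    free_energy = x$free_energy,
    cycles = x$cycles,
    converged = x$converged
  )
}

#' Tidy a model-selection report
#'
#' @param x A [scan_states()] report.
#' @param ... Unused.
#' @return A tibble, one row per (k, repeat), with free energy, mean max
#'   fractional occupancy and the k-level mean repeat reliability joined on.
#' @export
tidy.bs_selection <- function(x, ...) {
  dplyr::left_join(x$fits, reliability_by_k(x), by = "k")
}

#' Tidy a first-level GLM
#'
#' @param x A [first_level_glm()] object.
#' @param ... Unused.
#' @return The per-target estimate table.
#' @export
tidy.bs_glm <- function(x, ...) x$estimates

#' Glance at a first-level GLM
#'
#' @param x A [first_level_glm()] object.
#' @param ... Unused.
#' @return A one-row tibble with residual df, term count and AR(1) rho.
#' @export
glance.bs_glm <- function(x, ...) {
  tibble::tibble(df = x$df, n_terms = length(x$terms),
                 prewhitened = x$prewhiten, rho = x$rho)
}
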