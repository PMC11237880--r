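# State-number scan, selection metrics (free energy, max fractional
# occupancy, repeat reliability) and the selection decision rule.

# Hungarian algorithm (augmenting-path/potentials form) for the linear sum
# assignment problem, minimising total cost. Returns for each row the
# assigned column. No installed package in the stack provides this.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop_param("assignment needs a square cost matrix")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1            # columns are offset by 1; column 1 is the virtual one
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1
  ans
}

#' Match states across two fits and score repeat reliability
#'
#' Concatenates each repeat's per-run state probability courses, correlates
#' every state pair across repeats, matches states one-to-one by maximising
#' the total Pearson correlation (optimal linear assignment), and returns
#' the matched pairs and their mean correlation. Zero-variance courses
#' contribute r = 0 with a warning.
#'
#' @param gammas_a,gammas_b Lists of per-run `T x K` gamma matrices (or
#'   single matrices) from two fits with identical run structure and `K`.
#' @return A list with `pairs` (tibble: state_a, state_b, r) and `mean_r`.
#' @export
repeat_reliability <- function(gammas_a, gammas_b) {
  if (is.matrix(gammas_a)) gammas_a <- list(gammas_a)
  if (is.matrix(gammas_b)) gammas_b <- list(gammas_b)
  A <- do.call(rbind, gammas_a)
  B <- do.call(rbind, gammas_b)
  if (!all(dim(A) == dim(B))) {
    stop_param("gamma sets must share run structure and state count")
  }
  K <- ncol(A)
  sda <- apply(A, 2, sd); sdb <- apply(B, 2, sd)
  if (any(sda < 1e-14) || any(sdb < 1e-14)) {
    warn("zero-variance state course; its correlations are set to 0")
  }
  R <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      R[i, j] <- if (sda[i] < 1e-14 || sdb[j] < 1e-14) 0 else
        cor(A[, i], B[, j])
    }
  }
  match <- solve_assignment(-R)
  r <- R[cbind(seq_len(K), match)]
  list(pairs = tibble::tibble(state_a = seq_len(K), state_b = match, r = r),
       mean_r = mean(r))
}

#' Per-run maximum fractional occupancy
#'
#' The largest share of a run occupied by any single state; values near 1
#' flag a degenerate, dynamics-poor model.
#'
#' @param paths A [viterbi_paths()] tibble (or list of integer paths).
#' @param K Number of states.
#' @return Numeric vector, one value in `(0, 1]` per run.
#' @export
max_fractional_occupancy <- function(paths, K) {
  plist <- if (is.data.frame(paths)) paths$path else paths
  if (length(plist) == 0) stop_param("paths must be nonempty")
  vapply(plist, function(p) max(fractional_occupancy(p, K)), 0)
}

#' Scan state numbers and repeats for model selection
#'
#' Fits the group HMM for every state number in `k_range`, `repeats` times
#' each with deterministically derived seeds, and records the three
#' selection metrics: variational free energy, per-run maximum fractional
#' occupancy (from Viterbi paths), and pairwise repeat reliability of the
#' state probability courses. Individual fit failures are recorded, not
#' fatal.
#'
#' @param data Standardized run tibble or list of matrices.
#' @param k_range Integer vector of state numbers (default `2:15`).
#' @param repeats Fits per state number (default 5).
#' @param base_seed Seed from which all fit seeds derive.
#' @param keep_models Keep the fitted `bs_hmm` objects in the report.
#' @param ... Passed to [fit_hmm()] (`prior`, `tol`, `max_cycles`).
#' @return A list of class `bs_selection` with `fits` (tibble: k, repeat,
#'   free_energy, mean_max_fo, converged, error), `reliability` (tibble:
#'   k, repeat_a, repeat_b, mean_r), `models` (optional), and `k_range`.
#' @export
scan_states <- function(data, k_range = 2:15, repeats = 5, base_seed = 1,
                        keep_models = TRUE, ...) {
  tbl <- as_run_table(data)
  fits <- list(); rel <- list(); models <- list()
  for (k in k_range) {
    for (r in seq_len(repeats)) {
      seed <- derive_seed(base_seed, "scan", k, r)
      fit <- tryCatch(fit_hmm(tbl, n_states = k, seed = seed, ...),
                      error = function(e) e)
      key <- sprintf("k%02d_r%d", k, r)
      if (inherits(fit, "error")) {
        fits[[key]] <- tibble::tibble(
          k = k, rep = r, free_energy = NA_real_, mean_max_fo = NA_real_,
          converged = NA, error = conditionMessage(fit))
        models[[key]] <- NULL
      } else {
        paths <- viterbi_paths(fit, tbl)
        fits[[key]] <- tibble::tibble(
          k = k, rep = r, free_energy = fit$free_energy,
          mean_max_fo = mean(max_fractional_occupancy(paths, k)),
          converged = fit$converged, error = NA_character_)
        models[[key]] <- fit
      }
    }
    ok <- which(!vapply(sprintf("k%02d_r%d", k, seq_len(repeats)),
                        function(key) is.null(models[[key]]), TRUE))
    if (length(ok) < 2 && repeats >= 2) {
      warn(sprintf("fewer than 2 successful repeats at K = %d", k))
    }
    if (length(ok) >= 2) {
      for (a in ok) {
        for (b in ok) {
          if (b <= a) next
          rr <- repeat_reliability(models[[sprintf("k%02d_r%d", k, a)]]$gamma,
                                   models[[sprintf("k%02d_r%d", k, b)]]$gamma)
          rel[[length(rel) + 1]] <- tibble::tibble(
            k = k, repeat_a = a, repeat_b = b, mean_r = rr$mean_r)
        }
      }
    }
  }
  structure(list(
    fits = dplyr::bind_rows(fits),
    reliability = if (length(rel)) dplyr::bind_rows(rel) else
      tibble::tibble(k = integer(), repeat_a = integer(),
                     repeat_b = integer(), mean_r = numeric()),
    models = if (keep_models) models else NULL,
    k_range = k_range, repeats = repeats, base_seed = base_seed
  ), class = "bs_selection")
}

#' Mean repeat reliability per state number
#'
#' @param report A [scan_states()] report.
#' @return A tibble `k, mean_reliability`.
#' @export
reliability_by_k <- function(report) {
  dplyr::summarise(dplyr::group_by(report$reliability, .data$k),
                   mean_reliability = mean(.data$mean_r), .groups = "drop")
}

#' Apply the model-selection decision rule
#'
#' Selects the largest state number whose mean repeat reliability reaches
#' the floor, then the repeat with the lowest mean per-run maximum
#' fractional occupancy at that state number. Free energy is reported for
#' context but is not a hard criterion.
#'
#' @param report A [scan_states()] report.
#' @param reliability_floor Minimum acceptable mean repeat reliability.
#' @return A list with `k`, `rep`, `rationale`, and the chosen model (when
#'   kept in the report).
#' @export
select_model <- function(report, reliability_floor = 0.8) {
  byk <- reliability_by_k(report)
  ok <- dplyr::filter(byk, .data$mean_reliability >= reliability_floor)
  if (nrow(ok) == 0) {
    best <- byk[which.max(byk$mean_reliability), ]
    stop_compute(
      "no state number reaches reliability %.2f; best is K = %d at %.3f",
      reliability_floor, best$k, best$mean_reliability)
  }
  k_sel <- max(ok$k)
  cand <- dplyr::filter(report$fits, .data$k == k_sel, is.na(.data$error))
  rep_sel <- cand$rep[which.min(cand$mean_max_fo)]
  rationale <- sprintf(
    "K = %d is the largest state number with mean repeat reliability %.3f >= %.2f; repeat %d has the lowest mean max fractional occupancy (%.3f)",
    k_sel, ok$mean_reliability[ok$k == k_sel], reliability_floor, rep_sel,
    min(cand$mean_max_fo))
  model <- report$models[[sprintf("k%02d_r%d", k_sel, rep_sel)]]
  list(k = k_sel, rep = rep_sel, rationale = rationale, model = model)
}
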