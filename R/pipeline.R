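# End-to-end study driver: simulate -> features -> HMMs -> selection ->
# metrics/contrasts -> windows/cross-modal -> spectra -> GLM.

#' Configuration for an end-to-end experiment
#'
#' Defaults follow the emulated acquisition and analysis: 7-13 Hz alpha
#' band, TR 2 s, 10 s non-overlapping windows, state numbers 2-15 with five
#' repeats, repeat-reliability floor 0.8, activation threshold 0.8 and
#' familywise alpha 0.05. The manifest and state scan can be scaled down
#' for desk-scale runs.
#'
#' @param manifest A [study_manifest()].
#' @param effect An [effect_profile()].
#' @param band Alpha band edges in Hz.
#' @param window_length Sliding window length in seconds.
#' @param k_range State numbers to scan.
#' @param repeats Repeats per state number.
#' @param reliability_floor Model-selection reliability floor.
#' @param activation_threshold Gamma activation threshold.
#' @param alpha Familywise significance level.
#' @param first_quarter Also compare metrics within the first quarter of
#'   each run.
#' @param gamma_fo Use probability-weighted (rather than Viterbi) windowed
#'   occupancy.
#' @param prewhiten AR(1) prewhitening in first-level GLMs.
#' @param envelope_rate EEG envelope sampling rate in Hz.
#' @param glm_states EEG states to map through the BOLD GLM (`"all"` or a
#'   vector of state indices).
#' @param tol Relative free-energy convergence tolerance for all fits.
#' @param max_cycles Maximum variational cycles per fit.
#' @return A list of class `bs_config`.
#' @export
experiment_config <- function(manifest = study_manifest(),
                              effect = effect_profile(),
                              band = c(7, 13),
                              window_length = 10,
                              k_range = 2:15,
                              repeats = 5,
                              reliability_floor = 0.8,
                              activation_threshold = 0.8,
                              alpha = 0.05,
                              first_quarter = TRUE,
                              gamma_fo = FALSE,
                              prewhiten = FALSE,
                              envelope_rate = 40,
                              glm_states = "all",
                              tol = 1e-5,
                              max_cycles = 500) {
  structure(list(manifest = manifest, effect = effect, band = band,
                 window_length = window_length, k_range = k_range,
                 repeats = repeats, reliability_floor = reliability_floor,
                 activation_threshold = activation_threshold, alpha = alpha,
                 first_quarter = first_quarter, gamma_fo = gamma_fo,
                 prewhiten = prewhiten, envelope_rate = envelope_rate,
                 glm_states = glm_states, tol = tol,
                 max_cycles = max_cycles), class = "bs_config")
}

run_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop_compute("stage '%s' failed: %s", name, conditionMessage(e))
  })
  log[[name]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(result = res, log = log)
}

#' Run the full synthetic EO/EC experiment
#'
#' Generates (or accepts) a study, extracts EEG alpha features, fits and
#' selects both HMMs, computes Viterbi state metrics with EO-vs-EC paired
#' contrasts (whole-run and first-quarter), sliding-window occupancy
#' courses with cross-modal correlations per run, EEG state spectra, and
#' the state-regressor and alpha-power BOLD GLMs. Deterministic given
#' (`config`, `seed`).
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for the whole experiment.
#' @param study Optional pre-built [make_study()] object (takes precedence
#'   over `config$manifest`/`config$effect`).
#' @param out_dir Optional directory; when given, all report tables are
#'   written as TSV/JSON.
#' @return A list of class `bs_experiment` with the stage outputs and a
#'   `log` of stage timings.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1,
                           study = NULL, out_dir = NULL) {
  log <- list()
  mf <- config$manifest
  if (is.null(study)) {
    st <- run_stage("simulate", log, make_study(mf, config$effect, seed = seed))
    study <- st$result; log <- st$log
  }
  mf <- study$manifest
  tr <- mf$tr

  # ---- EEG features
  st <- run_stage("features", log, {
    eeg_runs <- dplyr::filter(study$runs, .data$modality == "eeg")
    feats <- purrr::map(eeg_runs$data, function(m) {
      filt <- bandpass_alpha(m, mf$eeg_rate, config$band[1], config$band[2])
      env <- hilbert_envelope(filt, mf$eeg_rate)
      ep <- epoch_downsample(env, mf$eeg_rate, tr = tr,
                             target_rate = config$envelope_rate)
      env40 <- attr(ep, "series")
      attr(env40, "period") <- 1 / config$envelope_rate
      filt_ep <- epoch_downsample(filt, mf$eeg_rate, tr = tr,
                                  target_rate = config$envelope_rate)
      power <- welch_alpha_power(filt_ep, band = config$band,
                                 channels = mf$eeg_channels)
      list(envelope = env40, filtered = attr(filt_ep, "series"),
           power = power)
    })
    env_tbl <- dplyr::mutate(
      eeg_runs[c("subject", "run", "condition", "modality")],
      period = 1 / config$envelope_rate,
      data = purrr::map(feats, "envelope"))
    power_tbl <- tidyr::unnest(
      dplyr::mutate(eeg_runs[c("subject", "run", "condition")],
                    alpha_power = purrr::map(feats, "power")),
      "alpha_power")
    list(envelopes = env_tbl, power = power_tbl,
         filtered = purrr::map(feats, "filtered"))
  })
  features <- st$result; log <- st$log

  # ---- alpha power EO vs EC
  st <- run_stage("alpha_test", log, {
    subj <- dplyr::summarise(
      dplyr::group_by(features$power, .data$subject, .data$condition),
      value = mean(.data$alpha_power), .groups = "drop")
    alpha_condition_test(subj)
  })
  alpha_test <- st$result; log <- st$log

  # ---- HMMs with model selection
  fit_branch <- function(runs_tbl, label) {
    std <- standardize_runs(runs_tbl)
    scan <- scan_states(std, k_range = config$k_range,
                        repeats = config$repeats,
                        base_seed = derive_seed(seed, label),
                        tol = config$tol, max_cycles = config$max_cycles)
    sel <- select_model(scan, config$reliability_floor)
    paths <- viterbi_paths(sel$model, std)
    metrics <- state_metrics(paths, sel$k)
    contrasts <- dplyr::bind_rows(
      compare_conditions(metrics, "fractional_occupancy", degenerate = "na"),
      compare_conditions(metrics, "switching_rate", degenerate = "na"))
    fq <- NULL
    if (config$first_quarter) {
      fq_metrics <- state_metrics(restrict_first_quarter(paths), sel$k)
      fq <- dplyr::bind_rows(
        compare_conditions(fq_metrics, "fractional_occupancy",
                           degenerate = "na"),
        compare_conditions(fq_metrics, "switching_rate", degenerate = "na"))
    }
    list(standardized = std, scan = scan, selection = sel, paths = paths,
         metrics = metrics, contrasts = contrasts,
         first_quarter_contrasts = fq)
  }
  st <- run_stage("fmri_hmm", log,
                  fit_branch(dplyr::filter(study$runs,
                                           .data$modality == "fmri"), "fmri"))
  fmri <- st$result; log <- st$log
  st <- run_stage("eeg_hmm", log, fit_branch(features$envelopes, "eeg"))
  eeg <- st$result; log <- st$log

  # ---- sliding windows and cross-modal correlation, per run index
  st <- run_stage("windows", log, {
    win_of <- function(branch, run_idx) {
      idx <- which(branch$paths$run == run_idx)
      lapply(idx, function(i) {
        if (config$gamma_fo) {
          windowed_fo(branch$selection$model$gamma[[i]],
                      branch$paths$period[i], branch$selection$k,
                      config$window_length, weights = TRUE)
        } else {
          windowed_fo(branch$paths$path[[i]], branch$paths$period[i],
                      branch$selection$k, config$window_length)
        }
      })
    }
    runs_idx <- sort(unique(study$runs$run))
    per_run <- purrr::map(runs_idx, function(r) {
      gf <- group_average_fo(win_of(fmri, r))
      ge <- group_average_fo(win_of(eeg, r))
      list(run = r, fmri = gf, eeg = ge,
           crossmodal = crossmodal_correlation(gf, ge))
    })
    names(per_run) <- sprintf("run%d", runs_idx)
    per_run
  })
  windows <- st$result; log <- st$log

  # ---- EEG state spectra (state-weighted multitaper on the filtered series)
  st <- run_stage("spectra", log, {
    series <- do.call(rbind, features$filtered)
    gam <- do.call(rbind, eeg$selection$model$gamma)
    n <- min(nrow(series), nrow(gam))
    weighted_multitaper(series[seq_len(n), , drop = FALSE],
                        gam[seq_len(n), , drop = FALSE],
                        rate = config$envelope_rate, window_length = tr)
  })
  spectra <- st$result; log <- st$log

  # ---- BOLD GLMs: EEG state regressors and the conventional alpha regressor
  glm_res <- NULL
  if (!is.null(study$voxels)) {
    st <- run_stage("glm", log, {
      ke <- eeg$selection$k
      states <- if (identical(config$glm_states, "all")) seq_len(ke) else
        config$glm_states
      n_vol <- mf$n_volumes
      state_glms <- purrr::map(states, function(k) {
        fits <- purrr::pmap(
          study$voxels, function(subject, run, condition, data) {
            i <- which(eeg$paths$subject == subject & eeg$paths$run == run)
            reg <- build_regressor(eeg$selection$model$gamma[[i]][, k],
                                   rate = config$envelope_rate, tr = tr,
                                   n_out = n_vol)
            tibble::tibble(subject = subject, condition = condition,
                           fit = list(first_level_glm(
                             data, matrix(reg, ncol = 1),
                             targets_in_rows = TRUE,
                             prewhiten = config$prewhiten)))
          })
        maps <- subject_level_average(dplyr::bind_rows(fits))
        list(state = k, maps = maps,
             group = list(EO = group_level_test(maps, "EO", alpha = config$alpha),
                          EC = group_level_test(maps, "EC", alpha = config$alpha),
                          `EC-EO` = group_level_test(maps, "EC-EO",
                                                     alpha = config$alpha)))
      })
      alpha_fits <- purrr::pmap(
        study$voxels, function(subject, run, condition, data) {
          pw <- features$power[features$power$subject == subject &
                                 features$power$run == run, ]
          reg <- build_regressor(normalize_regressor(pw$alpha_power),
                                 rate = 1 / tr, tr = tr, n_out = n_vol)
          tibble::tibble(subject = subject, condition = condition,
                         fit = list(first_level_glm(
                           data, matrix(reg, ncol = 1),
                           targets_in_rows = TRUE,
                           prewhiten = config$prewhiten)))
        })
      alpha_maps <- subject_level_average(dplyr::bind_rows(alpha_fits))
      list(states = state_glms, alpha = list(
        maps = alpha_maps,
        group = list(EO = group_level_test(alpha_maps, "EO", alpha = config$alpha),
                     EC = group_level_test(alpha_maps, "EC", alpha = config$alpha),
                     `EC-EO` = group_level_test(alpha_maps, "EC-EO",
                                                alpha = config$alpha))))
    })
    glm_res <- st$result; log <- st$log
  }

  bundle <- structure(list(
    study = study, features = features, alpha_test = alpha_test,
    fmri = fmri, eeg = eeg, windows = windows, spectra = spectra,
    glm = glm_res, config = config, seed = seed, log = log
  ), class = "bs_experiment")
  if (!is.null(out_dir)) write_experiment(bundle, out_dir)
  bundle
}

#' Write an experiment's report tables
#'
#' Persists every figure-analog table of a [run_experiment()] bundle as
#' TSV (metrics, contrasts, selection scan, windowed courses, cross-modal
#' matrices, spectra, group GLM maps) plus a `summary.json` with the
#' selected models, seed and stage log.
#'
#' @param bundle A `bs_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    x <- dplyr::select(tibble::as_tibble(x),
                       -dplyr::where(function(col) is.list(col)))
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  wt(bundle$alpha_test, "alpha_test.tsv")
  for (b in c("fmri", "eeg")) {
    br <- bundle[[b]]
    wt(br$scan$fits, sprintf("%s_scan.tsv", b))
    wt(br$scan$reliability, sprintf("%s_reliability.tsv", b))
    wt(br$metrics, sprintf("%s_metrics.tsv", b))
    wt(br$contrasts, sprintf("%s_contrasts.tsv", b))
    if (!is.null(br$first_quarter_contrasts)) {
      wt(br$first_quarter_contrasts, sprintf("%s_contrasts_q1.tsv", b))
    }
  }
  for (rn in names(bundle$windows)) {
    w <- bundle$windows[[rn]]
    for (b in c("fmri", "eeg")) {
      m <- w[[b]]$mean
      colnames(m) <- sprintf("state%02d", seq_len(ncol(m)))
      readr::write_tsv(tibble::as_tibble(m),
                       file.path(dir, sprintf("windows_%s_%s.tsv", rn, b)),
                       progress = FALSE)
    }
    wt(w$crossmodal, sprintf("crossmodal_%s.tsv", rn))
  }
  wt(bundle$spectra, "spectra.tsv")
  if (!is.null(bundle$glm)) {
    for (sg in bundle$glm$states) {
      for (ct in names(sg$group)) {
        wt(sg$group[[ct]],
           sprintf("glm_state%02d_%s.tsv", sg$state, gsub("-", "_", ct)))
      }
    }
    for (ct in names(bundle$glm$alpha$group)) {
      wt(bundle$glm$alpha$group[[ct]],
         sprintf("glm_alpha_%s.tsv", gsub("-", "_", ct)))
    }
  }
  jsonlite::write_json(list(
    seed = bundle$seed,
    fmri_k = bundle$fmri$selection$k, fmri_rep = bundle$fmri$selection$rep,
    eeg_k = bundle$eeg$selection$k, eeg_rep = bundle$eeg$selection$rep,
    fmri_rationale = bundle$fmri$selection$rationale,
    eeg_rationale = bundle$eeg$selection$rationale,
    stage_seconds = bundle$log
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
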