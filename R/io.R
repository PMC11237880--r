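# Plain-text interchange: TSV run matrices, JSON manifests, JSON models.

run_filename <- function(subject, run, modality) {
  sprintf("%s_run-%d_%s.tsv", subject, run, modality)
}

#' Write a study to a directory of TSV matrices plus JSON metadata
#'
#' Each run becomes one TSV (time x channels, header row of channel
#' labels); parcel BOLD matrices are written time x parcel. `manifest.json`
#' records subjects, run order, conditions, sampling periods and file
#' paths; `truth.json` (when present) records the ground-truth parameters
#' and integer chain paths.
#'
#' @param study A [make_study()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- study$runs
  files <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    f <- run_filename(runs$subject[i], runs$run[i], runs$modality[i])
    m <- as.matrix(runs$data[[i]])
    colnames(m) <- colnames(m) %||% sprintf("ch%02d", seq_len(ncol(m)))
    readr::write_tsv(tibble::as_tibble(m), file.path(dir, f),
                     progress = FALSE)
    files[i] <- f
  }
  vox_files <- NULL
  if (!is.null(study$voxels)) {
    vox_files <- character(nrow(study$voxels))
    for (i in seq_len(nrow(study$voxels))) {
      f <- run_filename(study$voxels$subject[i], study$voxels$run[i], "bold")
      m <- t(study$voxels$data[[i]])
      colnames(m) <- sprintf("p%03d", seq_len(ncol(m)))
      readr::write_tsv(tibble::as_tibble(m), file.path(dir, f),
                       progress = FALSE)
      vox_files[i] <- f
    }
  }
  manifest <- list(
    subjects = study$manifest$subjects,
    conditions = study$manifest$conditions,
    tr = study$manifest$tr,
    n_volumes = study$manifest$n_volumes,
    eeg_rate = study$manifest$eeg_rate,
    eeg_channels = study$manifest$eeg_channels,
    fmri_channels = study$manifest$fmri_channels,
    seed = study$seed,
    runs = tibble::tibble(
      subject = runs$subject, run = runs$run, condition = runs$condition,
      modality = runs$modality, period = runs$period, file = files),
    voxel_runs = if (!is.null(vox_files)) tibble::tibble(
      subject = study$voxels$subject, run = study$voxels$run,
      condition = study$voxels$condition, file = vox_files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(study$truth)) {
    tr <- study$truth
    truth <- list(
      n_states = tr$n_states,
      transition_by_condition = lapply(tr$transition_by_condition, unclass),
      initial_by_condition = tr$initial_by_condition,
      state_means = unclass(tr$state_means),
      state_covs = lapply(tr$state_covs, unclass),
      eeg_amplitudes = unclass(tr$eeg_amplitudes),
      carrier = tr$carrier, noise_sd = tr$noise_sd,
      seed = tr$seed,
      chain_paths = tibble::tibble(
        subject = tr$chain_paths$subject, run = tr$chain_paths$run,
        condition = tr$chain_paths$condition,
        path = lapply(tr$chain_paths$path, as.integer))
    )
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a study directory written by [write_study()]
#'
#' Validates that every referenced file exists, that matrices match the
#' manifest's sample and channel counts, and that conditions are EO/EC.
#'
#' @param dir Directory containing `manifest.json`, or the path to the
#'   manifest itself.
#' @return A list of class `bs_study` (without generative parameters unless
#'   `truth.json` is present).
#' @export
load_study <- function(dir) {
  manifest_path <- if (grepl("[.]json$", dir)) dir else
    file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_param("manifest not found at %s", manifest_path)
  }
  root <- dirname(manifest_path)
  mf <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!all(mf$runs$condition %in% c("EO", "EC"))) {
    bad <- setdiff(unique(mf$runs$condition), c("EO", "EC"))
    stop_param("unknown condition '%s' in manifest", bad[1])
  }
  runs <- tibble::as_tibble(mf$runs)
  runs$data <- lapply(seq_len(nrow(runs)), function(i) {
    path <- file.path(root, runs$file[i])
    if (!file.exists(path)) stop_param("missing run file %s", runs$file[i])
    m <- as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE))
    expected_t <- if (runs$modality[i] == "fmri") mf$n_volumes else
      mf$n_volumes * mf$tr * mf$eeg_rate
    expected_c <- if (runs$modality[i] == "fmri")
      length(mf$fmri_channels) else length(mf$eeg_channels)
    if (nrow(m) != expected_t || ncol(m) != expected_c) {
      stop_param("run %s/%d (%s): expected %d x %d, found %d x %d",
                 runs$subject[i], runs$run[i], runs$modality[i], expected_t,
                 expected_c, nrow(m), ncol(m))
    }
    attr(m, "period") <- runs$period[i]
    attr(m, "modality") <- runs$modality[i]
    m
  })
  runs$file <- NULL
  voxels <- NULL
  if (!is.null(mf$voxel_runs)) {
    vr <- tibble::as_tibble(mf$voxel_runs)
    vr$data <- lapply(seq_len(nrow(vr)), function(i) {
      path <- file.path(root, vr$file[i])
      if (!file.exists(path)) stop_param("missing voxel file %s", vr$file[i])
      t(as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                  progress = FALSE)))
    })
    vr$file <- NULL
    voxels <- vr
  }
  truth <- NULL
  truth_path <- file.path(root, "truth.json")
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(
      n_states = tj$n_states,
      transition_by_condition = lapply(tj$transition_by_condition, as.matrix),
      initial_by_condition = tj$initial_by_condition,
      state_means = as.matrix(tj$state_means),
      state_covs = lapply(tj$state_covs, as.matrix),
      eeg_amplitudes = as.matrix(tj$eeg_amplitudes),
      carrier = tj$carrier, noise_sd = tj$noise_sd, seed = tj$seed,
      chain_paths = tibble::as_tibble(tj$chain_paths)
    )
    class(truth) <- "bs_truth"
  }
  manifest <- structure(list(
    subjects = mf$subjects, conditions = mf$conditions, tr = mf$tr,
    n_volumes = mf$n_volumes, eeg_rate = mf$eeg_rate,
    eeg_channels = mf$eeg_channels, fmri_channels = mf$fmri_channels
  ), class = "bs_manifest")
  structure(list(runs = runs, voxels = voxels, truth = truth,
                 manifest = manifest, seed = mf$seed),
            class = "bs_study")
}

#' Serialise a fitted HMM to JSON
#'
#' Writes the state parameters, transition/initial probabilities, prior and
#' posterior hyperparameters and the free-energy trace to one JSON file;
#' optionally writes per-run gamma and Viterbi-path TSVs next to it.
#'
#' @param model A [fit_hmm()] object.
#' @param path Output JSON path.
#' @param gamma_dir Optional directory for per-run `gamma_*.tsv` files.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, gamma_dir = NULL) {
  obj <- list(
    n_states = model$n_states, channels = model$channels,
    means = unclass(model$means), covs = lapply(model$covs, unclass),
    transition = unclass(model$transition), initial = model$initial,
    free_energy = model$free_energy,
    free_energy_trace = model$free_energy_trace,
    posterior = list(m = unclass(model$posterior$m),
                     kappa = model$posterior$kappa,
                     S = lapply(model$posterior$S, unclass),
                     nu = model$posterior$nu,
                     a_trans = unclass(model$posterior$a_trans),
                     a_init = model$posterior$a_init),
    prior = list(dirichlet = model$prior$dirichlet, mean = model$prior$mean,
                 mean_precision = model$prior$mean_precision,
                 scale = unclass(model$prior$scale), dof = model$prior$dof),
    tol = model$tol, max_cycles = model$max_cycles, seed = model$seed,
    converged = model$converged, cycles = model$cycles,
    run_info = model$run_info
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(gamma_dir)) {
    dir.create(gamma_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(model$gamma)) {
      g <- model$gamma[[i]]
      colnames(g) <- sprintf("state%02d", seq_len(ncol(g)))
      readr::write_tsv(tibble::as_tibble(g),
                       file.path(gamma_dir, sprintf("gamma_%s_run-%d_%s.tsv",
                                                    model$run_info$subject[i],
                                                    model$run_info$run[i],
                                                    model$run_info$modality[i] %||% "x")),
                       progress = FALSE)
    }
  }
  invisible(path)
}

#' Read a fitted HMM from JSON
#'
#' @param path JSON path written by [write_model()].
#' @return A `bs_hmm` object (without per-run gamma).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # a JSON list of K matrices simplifies to a (K, C, C) array
  mat_list <- function(x) {
    if (is.list(x)) return(lapply(x, as.matrix))
    lapply(seq_len(dim(x)[1]), function(k) as.matrix(x[k, , ]))
  }
  structure(list(
    n_states = obj$n_states, channels = obj$channels,
    means = as.matrix(obj$means), covs = mat_list(obj$covs),
    transition = as.matrix(obj$transition), initial = obj$initial,
    gamma = NULL,
    run_info = tibble::as_tibble(obj$run_info),
    free_energy = obj$free_energy,
    free_energy_trace = obj$free_energy_trace,
    posterior = list(m = as.matrix(obj$posterior$m),
                     kappa = obj$posterior$kappa,
                     S = mat_list(obj$posterior$S),
                     nu = obj$posterior$nu,
                     a_trans = as.matrix(obj$posterior$a_trans),
                     a_init = obj$posterior$a_init),
    prior = list(dirichlet = obj$prior$dirichlet, mean = obj$prior$mean,
                 mean_precision = obj$prior$mean_precision,
                 scale = as.matrix(obj$prior$scale), dof = obj$prior$dof),
    tol = obj$tol, max_cycles = obj$max_cycles, seed = obj$seed,
    converged = obj$converged, cycles = obj$cycles
  ), class = "bs_hmm")
}
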