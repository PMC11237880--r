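#' Describe an eyes-open / eyes-closed study design
#'
#' Captures the acquisition layout of a concurrent multichannel study: how
#' many subjects, the per-subject run order of eyes-open (EO) and eyes-closed
#' (EC) conditions, the BOLD repetition time and run length, and the EEG grid.
#' Defaults reproduce the emulated design: 21 subjects, four 10-minute runs
#' alternating EO, EC, EO, EC, 300 volumes at TR = 2 s, 13 network channels,
#' and six posterior EEG channels carried on a 200 Hz raw grid.
#'
#' @param n_subjects Number of subjects.
#' @param conditions Ordered run conditions, each `"EO"` or `"EC"`.
#' @param tr BOLD sampling period in seconds.
#' @param n_volumes BOLD samples per run.
#' @param eeg_rate Raw EEG sampling rate in Hz.
#' @param eeg_channels EEG channel labels.
#' @param fmri_channels Network (parcel/IC) channel labels.
#' @return A list of class `bs_manifest`.
#' @export
#' @examples
#' m <- study_manifest(n_subjects = 2, n_volumes = 50)
#' m$conditions
study_manifest <- function(n_subjects = 21,
                           conditions = c("EO", "EC", "EO", "EC"),
                           tr = 2,
                           n_volumes = 300,
                           eeg_rate = 200,
                           eeg_channels = c("Oz", "O1", "O2", "POz", "PO3", "PO4"),
                           fmri_channels = c("vis_occ_pole", "vis_medial",
                                             "vis_lateral", "auditory",
                                             "dmn_ant", "dmn_post", "precuneus",
                                             "salience", "smn_sup", "smn_inf",
                                             "dan", "fpn_l", "fpn_r")) {
  if (!all(conditions %in% c("EO", "EC"))) {
    stop_param("conditions must be 'EO' or 'EC'")
  }
  if (tr <= 0 || eeg_rate <= 0) stop_param("sampling periods must be positive")
  if (n_subjects < 1 || n_volumes < 1) {
    stop_param("n_subjects and n_volumes must be at least 1")
  }
  if (abs(eeg_rate * tr - round(eeg_rate * tr)) > 1e-9) {
    stop_param("tr must be an integer number of EEG samples")
  }
  structure(list(
    subjects = sprintf("sub-%02d", seq_len(n_subjects)),
    conditions = conditions,
    tr = tr,
    n_volumes = n_volumes,
    eeg_rate = eeg_rate,
    eeg_channels = eeg_channels,
    fmri_channels = fmri_channels
  ), class = "bs_manifest")
}

make_transition <- function(K, stay) {
  stay <- rep_len(stay, K)
  A <- matrix(0, K, K)
  for (j in seq_len(K)) {
    A[j, ] <- if (K == 1) 1 else (1 - stay[j]) / (K - 1)
    A[j, j] <- stay[j]
  }
  A
}

# Per-sample leave rate that yields stationary occupancy `target` for one
# state when all other states keep leave rate `base_out` and off-diagonal
# mass is spread uniformly (stationary occupancy is then proportional to
# 1 / leave-rate).
leave_rate_for_fo <- function(target, K, base_out) {
  (1 - target) / ((K - 1) * (1 / base_out) * target)
}

#' Stationary distribution of a transition matrix
#'
#' @param transition Row-stochastic `K x K` matrix (irreducible).
#' @return Length-`K` probability vector `p` with `p %*% transition = p`.
#' @export
stationary_dist <- function(transition) {
  ev <- eigen(t(as.matrix(transition)))
  i <- which.min(abs(ev$values - 1))
  p <- Re(ev$vectors[, i])
  p / sum(p)
}

#' Condition-effect profiles for synthetic studies
#'
#' Builds the condition-dependent pieces of the generator: per-condition
#' transition matrices, per-condition initial distributions, an optional
#' post-eye-closure transient, and an EC alpha-amplitude scaling.
#'
#' The `"reactive"` profile raises the stay probability of the last
#' (high-alpha) state during EC so its stationary occupancy rises by ~0.11,
#' lowers the stay probability of state 1 (the low-alpha state) so its EC
#' occupancy falls, starts EC runs in the high-alpha state with an elevated
#' stay probability over the first quarter of the run (an occupancy spike
#' that decays over ~2.5 min), and scales EC alpha amplitudes by 1.5. The
#' `"null"` profile makes EO and EC statistically identical. `"fo_shift"`
#' injects a pure stationary-occupancy shift of `delta` into `shift_state`
#' during EC, with no transient and no amplitude change.
#'
#' @param kind `"reactive"`, `"null"` or `"fo_shift"`.
#' @param n_states Number of latent states `K`.
#' @param stay Baseline per-TR stay probability of every state (default
#'   0.85: mean state lifetime `tr / (1 - stay)` of about 13 s at TR = 2 s,
#'   inside the observed lifetime range).
#' @param delta Stationary fractional-occupancy shift for `"fo_shift"`.
#' @param shift_state State receiving the shift (default: last state).
#' @param amp_scale_ec EC multiplier on EEG state amplitudes.
#' @return A list of class `bs_effect`.
#' @export
effect_profile <- function(kind = c("reactive", "null", "fo_shift"),
                           n_states = 5, stay = 0.85, delta = 0.1,
                           shift_state = n_states, amp_scale_ec = 1.5) {
  kind <- match.arg(kind)
  K <- n_states
  A_eo <- make_transition(K, stay)
  base_out <- 1 - stay
  eff <- list(kind = kind, n_states = K,
              transition = list(EO = A_eo, EC = A_eo),
              initial = list(EO = rep(1 / K, K), EC = rep(1 / K, K)),
              transient = NULL,
              amp_scale = c(EO = 1, EC = 1))
  if (kind == "reactive") {
    stay_ec <- rep(stay, K)
    # high-alpha state: stationary EC occupancy 1/K + 0.1125 for K = 5
    stay_ec[K] <- 1 - leave_rate_for_fo(1 / K + 0.1125, K, base_out)
    stay_ec[1] <- 1 - leave_rate_for_fo(1 / K - 0.075, K, base_out)
    eff$transition$EC <- make_transition(K, stay_ec)
    eff$initial$EC <- c(rep(0, K - 1), 1)
    stay_boost <- stay_ec
    stay_boost[K] <- 0.97
    eff$transient <- list(EC = list(transition = make_transition(K, stay_boost),
                                    fraction = 0.25))
    eff$amp_scale <- c(EO = 1, EC = amp_scale_ec)
  } else if (kind == "fo_shift") {
    stay_ec <- rep(stay, K)
    stay_ec[shift_state] <-
      1 - leave_rate_for_fo(1 / K + delta, K, base_out)
    eff$transition$EC <- make_transition(K, stay_ec)
    # start at stationarity so the injected stationary shift equals the
    # expected realized occupancy shift from the first sample
    eff$initial$EO <- stationary_dist(eff$transition$EO)
    eff$initial$EC <- stationary_dist(eff$transition$EC)
  }
  structure(eff, class = "bs_effect")
}

#' Ground truth for a synthetic study
#'
#' Collects the generative counterparts of the model parameters: the latent
#' state count, per-condition transition matrices and initial distributions
#' (taken from an [effect_profile()]), per-state network means and
#' covariances, per-state EEG alpha amplitudes, the voxel/parcel loading map,
#' and noise settings. Per-run latent chains are appended by [make_study()].
#'
#' @param manifest A [study_manifest()].
#' @param effect An [effect_profile()].
#' @param n_states Number of latent states.
#' @param separation Minimum pairwise Euclidean distance between state mean
#'   vectors, in units of the (unit) channel noise SD.
#' @param state_means Optional `K x C` mean matrix; drawn if `NULL`.
#' @param state_covs Optional list of `K` SPD covariance matrices
#'   (default: identity).
#' @param eeg_amplitudes Optional `K x 6` nonnegative alpha amplitudes;
#'   default is a geometric ramp from 0.5 to 2.2 so the last state is the
#'   high-alpha state.
#' @param carrier Alpha carrier frequency in Hz.
#' @param noise_sd Broadband EEG noise SD.
#' @param n_parcels Number of BOLD parcels driven by the state course.
#' @param parcels_per_state Parcels loading on each state.
#' @param parcel_beta Loading weight of each planted parcel.
#' @param ar1 List with elements `coef` and `sd` for parcel AR(1) noise.
#' @param seed Integer seed controlling the drawn means.
#' @return A list of class `bs_truth`.
#' @export
ground_truth <- function(manifest = study_manifest(),
                         effect = effect_profile(),
                         n_states = effect$n_states,
                         separation = 3,
                         state_means = NULL,
                         state_covs = NULL,
                         eeg_amplitudes = NULL,
                         carrier = 10,
                         noise_sd = 0.5,
                         n_parcels = 200,
                         parcels_per_state = 6,
                         parcel_beta = 0.8,
                         ar1 = list(coef = 0.3, sd = 1),
                         seed = 1) {
  K <- n_states
  C <- length(manifest$fmri_channels)
  if (is.null(state_means)) {
    set.seed(derive_seed(seed, "state-means"))
    state_means <- matrix(rnorm(K * C), K, C)
    if (K > 1) {
      d <- as.matrix(stats::dist(state_means))
      state_means <- state_means * separation / min(d[upper.tri(d)])
    }
  }
  dimnames(state_means) <- list(NULL, manifest$fmri_channels)
  if (is.null(state_covs)) {
    state_covs <- replicate(K, diag(C), simplify = FALSE)
  }
  lapply(state_covs, check_spd)
  for (cond in names(effect$transition)) {
    check_prob_rows(effect$transition[[cond]], 1e-12,
                    sprintf("%s transition matrix", cond))
    check_simplex(effect$initial[[cond]], 1e-12,
                  sprintf("%s initial distribution", cond))
  }
  if (is.null(eeg_amplitudes)) {
    levels <- if (K == 1) 1 else 0.5 * (2.2 / 0.5)^((seq_len(K) - 1) / (K - 1))
    eeg_amplitudes <- outer(levels, rep(1, length(manifest$eeg_channels)))
  }
  if (any(eeg_amplitudes < 0)) stop_param("eeg_amplitudes must be nonnegative")
  beta_map <- matrix(0, n_parcels, K)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * parcels_per_state + 1):(k * parcels_per_state)
    idx <- idx[idx <= n_parcels]
    beta_map[idx, k] <- parcel_beta
  }
  structure(list(
    n_states = K,
    transition_by_condition = effect$transition,
    initial_by_condition = effect$initial,
    transient = effect$transient,
    amp_scale = effect$amp_scale,
    state_means = state_means,
    state_covs = state_covs,
    eeg_amplitudes = eeg_amplitudes,
    carrier = carrier,
    noise_sd = noise_sd,
    beta_map = beta_map,
    ar1 = ar1,
    chain_paths = NULL,
    seed = seed
  ), class = "bs_truth")
}

#' Simulate a first-order Markov chain
#'
#' @param transition `K x K` row-stochastic transition matrix.
#' @param initial Length-`K` initial distribution.
#' @param length Number of samples to draw.
#' @param seed Integer seed; identical seeds give identical chains.
#' @return Integer vector of states in `1..K`.
#' @export
#' @examples
#' simulate_chain(diag(2), c(1, 0), 5, seed = 1)
simulate_chain <- function(transition, initial, length, seed) {
  transition <- as.matrix(transition)
  if (length < 1) stop_param("chain length must be at least 1")
  check_prob_rows(transition, 1e-9)
  check_simplex(initial, 1e-9)
  set.seed(seed)
  u <- runif(length)
  cum <- t(apply(transition, 1, cumsum))
  if (nrow(transition) == 1) cum <- matrix(1, 1, 1)
  sample_chain_cpp(u, cum, cumsum(initial))
}

# Chain over consecutive segments with different transition matrices; each
# segment continues from the last state of the previous one (its first sample
# is a transition under the new regime's matrix).
sample_chain_segments <- function(segments, initial, seed) {
  set.seed(seed)
  n_total <- sum(vapply(segments, `[[`, 0, "length"))
  u <- runif(n_total)
  path <- integer(0)
  offset <- 0
  init <- initial
  for (seg in segments) {
    if (seg$length < 1) next
    cum <- t(apply(seg$transition, 1, cumsum))
    if (nrow(seg$transition) == 1) cum <- matrix(1, 1, 1)
    p <- sample_chain_cpp(u[(offset + 1):(offset + seg$length)], cum,
                          cumsum(init))
    path <- c(path, p)
    init <- seg$transition[p[seg$length], ]
    offset <- offset + seg$length
  }
  path
}

#' Simulate one fMRI-like network run from a latent chain
#'
#' At each TR the 13-channel observation is drawn from the multivariate
#' Gaussian of the active state (`state_means` row, `state_covs` matrix).
#'
#' @param chain Integer state sequence on the TR grid.
#' @param truth A [ground_truth()] (or any list with `state_means`,
#'   `state_covs`).
#' @param tr Sampling period in seconds.
#' @param seed Integer seed.
#' @return A `T x C` numeric matrix with attributes `period`, `duration` (s)
#'   and `modality`.
#' @export
simulate_fmri_run <- function(chain, truth, tr = 2, seed = 1) {
  K <- nrow(truth$state_means)
  if (any(chain < 1 | chain > K)) stop_param("chain values must lie in 1..K")
  lapply(truth$state_covs, check_spd)
  C <- ncol(truth$state_means)
  T_len <- length(chain)
  set.seed(seed)
  Z <- matrix(rnorm(T_len * C), T_len, C)
  Y <- truth$state_means[chain, , drop = FALSE]
  for (k in unique(chain)) {
    idx <- which(chain == k)
    Y[idx, ] <- Y[idx, ] + Z[idx, , drop = FALSE] %*% chol(truth$state_covs[[k]])
  }
  colnames(Y) <- colnames(truth$state_means)
  structure(Y, period = tr, duration = T_len * tr, modality = "fmri")
}

#' Simulate one EEG-like posterior alpha run from a latent chain
#'
#' Each channel carries a sinusoid at the alpha carrier frequency whose
#' amplitude is set by the active state, with a per-run random phase per
#' channel and additive white broadband noise.
#'
#' @param chain Integer state sequence on the raw-rate grid.
#' @param state_amplitudes `K x C` nonnegative amplitude matrix.
#' @param carrier Carrier frequency in Hz, inside `(0, raw_rate / 2)`.
#' @param raw_rate Sampling rate in Hz.
#' @param noise_sd SD of the additive white noise.
#' @param seed Integer seed.
#' @param channels Optional channel labels.
#' @return A `T x C` numeric matrix with attributes `period`, `duration`,
#'   `modality`.
#' @export
simulate_eeg_run <- function(chain, state_amplitudes, carrier = 10,
                             raw_rate = 200, noise_sd = 0.5, seed = 1,
                             channels = NULL) {
  if (carrier <= 0 || carrier >= raw_rate / 2) {
    stop_param("carrier must lie strictly inside (0, Nyquist = %.1f Hz)",
               raw_rate / 2)
  }
  if (any(state_amplitudes < 0)) stop_param("state amplitudes must be >= 0")
  K <- nrow(state_amplitudes)
  if (any(chain < 1 | chain > K)) stop_param("chain values must lie in 1..K")
  C <- ncol(state_amplitudes)
  T_len <- length(chain)
  set.seed(seed)
  phi <- runif(C, 0, 2 * pi)
  tt <- (seq_len(T_len) - 1) / raw_rate
  Y <- matrix(0, T_len, C)
  amp <- state_amplitudes[chain, , drop = FALSE]
  for (cc in seq_len(C)) {
    Y[, cc] <- amp[, cc] * sin(2 * pi * carrier * tt + phi[cc])
  }
  Y <- Y + noise_sd * matrix(rnorm(T_len * C), T_len, C)
  colnames(Y) <- channels %||% colnames(state_amplitudes)
  structure(Y, period = 1 / raw_rate, duration = T_len / raw_rate,
            modality = "eeg")
}

#' Simulate parcel BOLD signals driven by a state course
#'
#' Each parcel is a weighted sum of HRF-convolved state courses plus AR(1)
#' noise: `y_v = sum_k beta[v, k] * (h * course_k) + e_v`.
#'
#' @param course Either an integer state path (expanded to one indicator
#'   course per state) or a `T x K` matrix of state probability courses, on
#'   the TR grid.
#' @param beta_map `V x K` loading matrix.
#' @param tr Sampling period of the course in seconds.
#' @param hrf An [double_gamma_hrf()] kernel sampled at step `tr`; built
#'   internally when `NULL`.
#' @param ar1 List with `coef` (|coef| < 1) and `sd`; `sd = 0` disables noise.
#' @param seed Integer seed.
#' @return A `V x T` matrix (parcels in rows).
#' @export
simulate_voxel_bold <- function(course, beta_map, tr = 2, hrf = NULL,
                                ar1 = list(coef = 0.3, sd = 1), seed = 1) {
  if (is.null(dim(course))) {
    K <- ncol(beta_map)
    if (any(course < 1 | course > K)) stop_param("chain values must lie in 1..K")
    course <- outer(course, seq_len(K), `==`) * 1
  }
  course <- as.matrix(course)
  K <- ncol(course)
  if (ncol(beta_map) != K) stop_param("beta_map must have one column per state")
  if (abs(ar1$coef) >= 1) stop_param("AR(1) coefficient must satisfy |coef| < 1")
  if (is.null(hrf)) hrf <- double_gamma_hrf(step = tr)
  if (length(hrf$values) > nrow(course)) {
    stop_param("HRF kernel (%d samples) is longer than the run (%d samples)",
               length(hrf$values), nrow(course))
  }
  T_len <- nrow(course)
  X <- vapply(seq_len(K),
              function(k) convolve_causal(course[, k], hrf$values, hrf$step),
              numeric(T_len))
  signal <- X %*% t(beta_map)            # T x V
  if (ar1$sd > 0) {
    set.seed(seed)
    V <- nrow(beta_map)
    E <- matrix(rnorm(T_len * V, sd = ar1$sd), T_len, V)
    E <- apply(E, 2, function(e) as.numeric(stats::filter(e, ar1$coef,
                                                          method = "recursive")))
    signal <- signal + E
  }
  t(signal)
}

#' Generate a complete synthetic EO/EC study
#'
#' For every subject and run, one latent state chain is sampled on the TR
#' grid under the condition's transition matrix (with the optional
#' post-eye-closure transient), then (a) emitted as a 13-channel fMRI-like
#' Gaussian series on the TR grid, (b) expanded by index replication to the
#' EEG raw grid and emitted as a 6-channel amplitude-modulated alpha
#' oscillation, and (c) convolved with the HRF to drive parcel BOLD
#' matrices. Both modalities therefore share one latent occupancy course by
#' construction. All randomness derives from `seed` via per-run child seeds.
#'
#' @param manifest A [study_manifest()].
#' @param effect An [effect_profile()].
#' @param truth Optional pre-built [ground_truth()]; built from `manifest`,
#'   `effect` and `seed` when `NULL`.
#' @param seed Integer study seed.
#' @param voxels Generate parcel BOLD matrices (set `FALSE` to skip).
#' @param eeg Generate EEG runs (set `FALSE` to skip).
#' @param fmri Generate fMRI emission series (set `FALSE` to keep only the
#'   latent chains, e.g. for chain-level calibration studies).
#' @return A list of class `bs_study` with elements `runs` (tibble: subject,
#'   run, condition, modality, period, data), `voxels` (tibble of `V x T`
#'   matrices), `truth` (with `chain_paths` filled in), `manifest` and `seed`.
#' @export
#' @examples
#' st <- make_study(study_manifest(n_subjects = 2, n_volumes = 40),
#'                  effect_profile("null", n_states = 3), seed = 7)
#' st$runs
make_study <- function(manifest = study_manifest(),
                       effect = effect_profile(),
                       truth = NULL, seed = 1, voxels = TRUE, eeg = TRUE,
                       fmri = TRUE) {
  if (is.null(truth)) {
    truth <- ground_truth(manifest = manifest, effect = effect, seed = seed)
  }
  if (length(truth$eeg_amplitudes[1, ]) != length(manifest$eeg_channels)) {
    stop_param("eeg_amplitudes columns must match manifest eeg_channels")
  }
  K <- truth$n_states
  n_tr <- manifest$n_volumes
  per_tr <- as.integer(round(manifest$eeg_rate * manifest$tr))
  rows <- list()
  vox_rows <- list()
  chains <- list()
  for (s in seq_along(manifest$subjects)) {
    for (r in seq_along(manifest$conditions)) {
      cond <- manifest$conditions[r]
      chain_seed <- derive_seed(seed, "chain", s, r)
      trans <- truth$transient[[cond]]
      if (!is.null(trans)) {
        n1 <- floor(n_tr * trans$fraction)
        chain <- sample_chain_segments(
          list(list(transition = trans$transition, length = n1),
               list(transition = truth$transition_by_condition[[cond]],
                    length = n_tr - n1)),
          truth$initial_by_condition[[cond]], chain_seed)
      } else {
        chain <- simulate_chain(truth$transition_by_condition[[cond]],
                                truth$initial_by_condition[[cond]],
                                n_tr, chain_seed)
      }
      chains[[length(chains) + 1]] <- tibble::tibble(
        subject = manifest$subjects[s], run = r, condition = cond,
        path = list(chain))
      if (fmri) {
        fmri_run <- simulate_fmri_run(chain, truth, tr = manifest$tr,
                                      seed = derive_seed(seed, "fmri", s, r))
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = manifest$subjects[s], run = r, condition = cond,
          modality = "fmri", period = manifest$tr, data = list(fmri_run))
      }
      if (eeg) {
        amp <- truth$eeg_amplitudes * truth$amp_scale[[cond]]
        eeg_run <- simulate_eeg_run(rep(chain, each = per_tr), amp,
                                    carrier = truth$carrier,
                                    raw_rate = manifest$eeg_rate,
                                    noise_sd = truth$noise_sd,
                                    seed = derive_seed(seed, "eeg", s, r),
                                    channels = manifest$eeg_channels)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = manifest$subjects[s], run = r, condition = cond,
          modality = "eeg", period = 1 / manifest$eeg_rate,
          data = list(eeg_run))
      }
      if (voxels) {
        vox <- simulate_voxel_bold(chain, truth$beta_map, tr = manifest$tr,
                                   ar1 = truth$ar1,
                                   seed = derive_seed(seed, "bold", s, r))
        vox_rows[[length(vox_rows) + 1]] <- tibble::tibble(
          subject = manifest$subjects[s], run = r, condition = cond,
          data = list(vox))
      }
    }
  }
  truth$chain_paths <- dplyr::bind_rows(chains)
  structure(list(
    runs = dplyr::bind_rows(rows),
    voxels = if (voxels) dplyr::bind_rows(vox_rows) else NULL,
    truth = truth,
    manifest = manifest,
    effect = effect,
    seed = seed
  ), class = "bs_study")
}

#' @export
print.bs_study <- function(x, ...) {
  cat(sprintf("<bs_study> %d subjects x %d runs, %d latent states, seed %d\n",
              length(x$manifest$subjects), length(x$manifest$conditions),
              x$truth$n_states, x$seed))
  print(dplyr::count(x$runs, .data$modality, .data$condition))
  invisible(x)
}
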