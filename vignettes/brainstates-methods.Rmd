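---
title: "Modelling eyes-open/eyes-closed brain-state dynamics with Gaussian HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling eyes-open/eyes-closed brain-state dynamics with Gaussian HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
```

## The model

`brainstates` treats a multichannel resting-state recording as a sequence of
visits to a small number of recurring **brain states**. Observations
$y_t \in \mathbb{R}^C$ (13 network BOLD courses at TR = 2 s, or 6 posterior
alpha-envelope channels at 40 Hz) are modelled with a hidden Markov model
whose hidden chain $z_t \in \{1,\dots,K\}$ follows a first-order Markov
process with transition matrix $A$ and initial distribution $\pi$, and whose
observation model is multivariate Gaussian per state:

$$y_t \mid z_t = k \;\sim\; \mathcal{N}(\mu_k, \Sigma_k).$$

A state is therefore a pattern of mean channel activity together with a
between-channel covariance. Inference is **group-level**: all runs of all
subjects share one set of $(\mu_k, \Sigma_k, A, \pi)$, while the posterior
state probability course $\gamma_t^{(r)}$ (the *gamma*) is computed per run.
Runs are chained with $\pi$ re-applied at each run boundary, so no
transitions are counted across runs; the recordings are separate scans and a
cross-run transition has no physical meaning.

### Variational inference

Parameters are inferred by variational Bayes with conjugate priors:
Dirichlet (concentration 1) on each transition row and on $\pi$, and a
Normal–Inverse-Wishart prior on each $(\mu_k, \Sigma_k)$ with prior mean 0,
mean-precision $\kappa_0 = 0.1$, identity scale and $C + 2$ degrees of
freedom — weakly informative on amplitude-standardized inputs, and just
informative enough that a state which momentarily loses all its
responsibility keeps a proper covariance instead of collapsing. The E-step
is an exact forward–backward smoother run with the expected log-parameters;
the M-step is the closed-form conjugate update. The variational free energy
(the negative evidence lower bound; lower = better) is recorded after every
cycle and is non-increasing by construction — the test suite asserts this on
every fit it makes. Iteration stops when the relative free-energy change
falls below `tol` ($10^{-5}$) or after `max_cycles` (500).

Two details matter for reproducibility:

* **Initialisation** is a seeded k-means hard assignment of the pooled
  samples. k-means itself depends on row order, so it is run on a
  canonically row-sorted copy of the pooled matrix; the fitted parameters
  are then invariant to the order in which runs are supplied.
* **All recursions run in log space** with log-sum-exp normalisation at
  every step (implemented in C++), so arbitrarily long runs cannot
  underflow.

Decoding uses the Viterbi algorithm on the posterior-expected parameters
(posterior mean vectors, expected covariances, posterior-mean transition
probabilities); decoding from posterior samples would make every downstream
metric stochastic. Ties are broken toward the lower state index. All state
metrics — fractional occupancy, lifetimes, interval times, switching rate —
are computed from the Viterbi path; thresholded gammas (`threshold_activation`,
default 0.8) are available but are not the default path to the metrics.

### Standardisation

Every channel of every run is scaled to mean 0, SD 1 before model fitting
(`standardize_runs()`). Whether the original analysis standardized per run
or per subject-concatenation is not documented for this class of pipeline;
per run is the default here because it also removes slow between-run gain
drifts, and a `scope = "subject"` flag provides the alternative.

## Model selection

`scan_states()` fits every state number in `k_range` (default 2–15)
`repeats` times (default 5) and records three quantities per fit: the free
energy, the per-run maximum fractional occupancy (a high value means one
state swallows a run — a degenerate, dynamics-poor solution), and the
repeat reliability. Reliability correlates the concatenated gamma courses
of two repeats after matching states one-to-one by maximising total Pearson
correlation with an exact assignment solver (a small Hungarian
implementation, tested against brute-force permutation search). Gammas
rather than binarized Viterbi courses are correlated because they retain
the model's uncertainty.

`select_model()` applies the decision rule: the largest $K$ whose mean
repeat reliability reaches the floor (default 0.8), then the repeat with
the lowest mean max-FO at that $K$. Free energy is reported for context
only — it decreases almost monotonically with $K$ and cannot pick the state
number by itself.

## EEG features and spectra

The alpha pipeline is: zero-phase Butterworth bandpass 7–13 Hz → Hilbert
envelope (FFT analytic signal) → decimation to 40 Hz → TR epochs of 80
samples → Welch band power per epoch (1 s Hann segments, 50 % overlap),
averaged over the posterior channels (Oz, O1, O2, POz, PO3, PO4). The
envelope channels at 40 Hz are the EEG HMM's inputs; the per-epoch band
power, z-scored per run, is the conventional alpha regressor.

The filter is order 6 applied forward–backward. An order-4 design was
considered first but cannot reach 40 dB of stopband attenuation at 15 Hz
even after two passes; order 6 achieves ~42 dB at 15 Hz and far more at
5 Hz while keeping passband ripple below 1 dB, and the tests measure these
attenuations on synthetic tones. Decimation from the raw rate (200 Hz in
the generator) to 40 Hz is plain index decimation: the signal has already
been confined to 7–13 Hz, far below the 20 Hz target Nyquist.

State spectra use a state-weighted multitaper estimate: non-overlapping
2 s windows, DPSS tapers (time-bandwidth 3, 5 tapers, computed as
eigenvectors of the Slepian tridiagonal matrix), each window's PSD weighted
by the window-mean gamma of the state. Weighting whole windows (rather than
individual samples inside the Fourier transform) matches the semantics
"periods where the state is more likely active contribute more" and keeps
the estimator a convex combination of valid PSDs.

## Haemodynamic mapping

State probability courses (and the alpha regressor) are convolved with the
canonical double-gamma HRF
$h(t) = g(t;6,1) - \tfrac{1}{6}\, g(t;16,1)$ (unit peak, 32 s support,
$h(0)=0$, peak near 5 s), at the course's native rate, then sampled at the
volume instants. First-level GLMs are ordinary least squares per parcel
with an intercept and demeaned regressors, with ±contrasts; subject-level
maps are fixed-effects averages over runs per condition; group-level maps
are one-sample (or paired, for EO−EC) t tests per parcel with Bonferroni
correction across parcels. Gamma probabilities (not binarized activations)
are convolved — binarisation discards amplitude information the GLM can
use. No temporal prewhitening is applied by default; an AR(1)
quasi-differencing option exists behind `prewhiten = TRUE` because
scanner-grade analyses implicitly prewhiten, but the synthetic parcels'
AR(1) noise is mild and OLS keeps the round-trip tests exact.

## The synthetic study generator

No public deposition exists for the kind of concurrent EEG–fMRI EO/EC data
this pipeline targets, so `make_study()` generates studies with known
ground truth. The default design mirrors the emulated acquisition: 21
subjects × 4 runs in the order EO, EC, EO, EC; 300 volumes at TR = 2 s;
six posterior EEG channels on a 200 Hz raw grid (the pipeline only needs
content below 20 Hz, so the acquisition-grade 5 kHz rate would only burn
memory).

One latent chain per run is sampled on the TR grid and expanded to the EEG
grid by index replication, so both modalities share their occupancy course
by construction — this is what makes cross-modal correlation targets well
defined. Sampling on the TR grid (rather than sampling at 200 Hz and
decimating) keeps the stated per-TR transition probabilities meaningful;
decimating the replicated chain back to the TR grid reproduces it exactly,
so the two constructions are contract-equivalent.

Generator defaults, chosen once:

* **K = 5 latent states** with a graded alpha-amplitude ladder
  (0.5 → 2.2), the top state being the high-alpha state.
* **Baseline stay probability 0.85 per TR** — mean state lifetime
  $\mathrm{TR}/(1-0.85) \approx 13$ s, inside the lifetime range such
  recordings show. This value was fixed by a design-stage power analysis:
  the condition-contrast calibration (a 0.1 occupancy shift, 20 subjects,
  paired t with Bonferroni) must be detectable with full-length runs,
  which requires runs to contain tens of independent state visits.
* **Condition effects** (`effect_profile("reactive")`): during EC the
  high-alpha state's stay probability rises so its stationary occupancy
  gains ~0.11, state 1 (low alpha) loses occupancy, EC runs start in the
  high-alpha state with an extra stay boost over the first quarter of the
  run — an occupancy spike decaying over ~2.5 min — and all EEG amplitudes
  scale by 1.5. With uniform off-diagonal transitions the stationary
  distribution is proportional to the reciprocal leave-rates, which gives a
  closed form for injecting a chosen occupancy shift.
* The `"fo_shift"` profile starts each chain at its condition's stationary
  distribution, so an injected stationary shift of $\delta$ *is* the
  expected realized occupancy shift (with a uniform start, burn-in eats
  ~10 % of it).
* **Parcel BOLD**: 200 parcels, each latent state loading 0.8 on six of
  them, driven by the HRF-convolved state course plus AR(1) noise
  (coefficient 0.3, SD 1).
* All randomness flows from one study seed through `derive_seed()`, a
  31-bit multiplicative-congruential fold of (stage, subject, run) tags, so
  any single run can be regenerated independently of generation order.

What the generator does **not** emulate: MR gradient/ballistocardiogram
artefacts, volumetric images (parcel matrices stand in for voxels), spatial
ICA and its component-selection step (network series are emitted directly),
1/f EEG background by default (white noise is used; the alpha band is
narrow enough that the distinction barely matters after filtering), head
motion, or drowsiness/sleep intrusions. Passing tests therefore demonstrate
that the *analysis machinery* is correct and calibrated under the stated
generative assumptions — not that real recordings satisfy those
assumptions. Within-condition nonstationarity beyond the first-quarter
transient (whose true functional form is unknown) is limited to that single
boosted-transition segment.

## Test and calibration problem sizes

The suite runs at desk scale, sized so the full suite stays inside a few
minutes of CPU: exact-inference oracles enumerate all $K^T$ sequences for
$K \le 3$, $T \le 8$; parameter recovery uses 20 runs × 500 samples at mean
separation 4; selection behaviour uses 12 runs × 200 samples of true-K = 3
data at separation 2.5 (chosen so that surplus states at K = 6 are
genuinely unstable across repeats — with strongly separated states even
overfit solutions replicate, which is not the phenomenon the selection rule
exists for); the condition-contrast calibration runs 200 null and 200
shifted replicates of 20-subject studies with full-length runs (300
samples), generating latent chains only; the cross-modal study uses 8
subjects × 150 volumes with both models fit at K = 5. The end-to-end
determinism check runs a 3-subject experiment twice and compares report
files byte for byte.

## Known limitations

* The observation model is a static Gaussian per state: no
  time-delay-embedded or autoregressive observation models, so EEG states
  are defined by band-power amplitude only.
* No semi-Markov durations; lifetimes are geometric by construction.
* Group inference on parcels uses Bonferroni-corrected t tests, not
  mixed-effects cluster inference on volumes; spatial inference is out of
  scope.
* The paired contrasts assume every subject contributes both conditions;
  subjects missing a condition are an error, not silently dropped.
* `select_model()` errors when no state number reaches the reliability
  floor rather than guessing; callers can lower the floor explicitly.
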