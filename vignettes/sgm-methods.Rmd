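---
title: "Methods: the spectral graph model pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the spectral graph model pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgmeg)
```

## The model

`sgmeg` implements a linear, closed-form spectral graph model (SGM) of
regional M/EEG power spectra. Each of the N regions of a structural
connectome hosts an excitatory and an inhibitory neural mass whose
impulse responses are Gamma-shaped kernels
$f_\tau(t) = (t/\tau^2)e^{-t/\tau}$ with Fourier transforms
$F_\tau(\omega) = (1 + i\omega\tau)^{-2}$. The local
excitatory-inhibitory loop gives a 2x2 frequency-domain system whose
determinant is $\Delta = ad + bc$ with
$a = i\omega + (g_{ee}/\tau_e)F_e$, $b = (g_{ei}/\tau_e)F_e$,
$c = (g_{ei}/\tau_i)F_i$, $d = i\omega + (g_{ii}/\tau_i)F_i$; the local
transfer function is $H_{loc} = X_e + X_i$ with $X_e = (d-b)/\Delta$,
$X_i = (c+a)/\Delta$ (`local_transfer()`).

Long-range excitatory populations couple through the row-degree
normalized connectivity matrix with conduction delays
$d_{jk}/(1000\,v)$ seconds (distances in mm, speed in m/s), giving the
frequency-dependent complex Laplacian
$L(\omega) = I - \alpha\,C^*(\omega)$,
$C^*_{jk}(\omega) = C^{norm}_{jk} e^{-i\omega d_{jk}/(1000 v)}$
(`complex_laplacian()`). The network transfer operator is

$$G(\omega) = \bigl(i\omega I + \tau_G^{-1} F_G(\omega) L(\omega)\bigr)^{-1},$$

computed either by eigenmode expansion
$G = U\,\mathrm{diag}\{1/(i\omega + \lambda_k F_G/\tau_G)\}\,U^{-1}$
(with optional truncation to the smallest-magnitude modes) or by a
direct linear solve; the two routes are algebraically identical and
cross-checked to 1e-8 in the test suite.

Seven parameters are free — $\tau_e, \tau_i, \tau_G$ (ms), $\alpha$,
$v$ (m/s), $g_{ei}, g_{ii}$ — with $g_{ee} = 1$ fixed for
identifiability. Bounds, the three standard initial guesses, and the
staged gain bounds are those in `sgm_bounds()`,
`sgm_initial_guesses()` and `fit_config()`.

### The noise-drive convention (a deliberate design choice)

The model is driven by white noise entering every region's local
populations. Two conventions exist for the deterministic spectrum used
in fitting:

* **uniform** — apply $G(\omega)H_{loc}$ to the all-ones vector
  (the literal printed form of the closed-form solution);
* **iid** (the package default) — the expected root power under
  *independent* unit-variance noise per region,
  $|X_j| = \sqrt{\sum_k |G_{jk}|^2}\,|H_{loc}|$.

We default to `iid` for two reasons. First, it is the physically
correct expected PSD of the stochastic system being modeled, and it is
exactly the spectrum realized by the surrogate time-series generator
(`gen_timeseries()`), which filters independent per-region noise.
Second, with row-normalized weights the all-ones vector is precisely
the Perron eigenvector of $C^*(\omega\!\to\!0)$, so the uniform drive
excites essentially a single eigenmode; $\tau_G$ then acts through one
effective pole that $\tau_e$ can imitate, and in simulation its
recovery collapses under as little as 1 dB of spectral noise
(rank correlation between true and recovered $\tau_G$ drops to ~0.4,
versus ~0.9 under `iid`). Both conventions are available via
`model_spectrum(..., drive = )`.

### Stability

Substituting $s$ for $i\omega$ in $\Delta$ and clearing the Gamma
denominators yields a degree-6 polynomial; `is_stable()` requires all
roots in the open left half-plane. An independent Euler simulation of
the same convolution system (`simulate_local()`) serves as the
time-domain oracle: the impulse-response envelope must not grow between
the two halves of a 2 s simulation. The two agree on >= 95% of random
in-bounds parameter draws; residual disagreements sit at the stability
boundary where a finite simulation cannot resolve growth rates near
zero.

## Parameter inference

The objective is the sum of the *spectral correlation* (mean over
cortical regions of Pearson r between model and empirical dB spectra)
and the *spatial correlation*
$\tilde x^\top \|C^{norm} + wI\|\,\tilde y / N$ of the z-scored
regional alpha-band (8-12 Hz) raw-power maps, with $w = 10$ and
$\|\cdot\|$ row normalization. We z-score with the population (1/N)
convention so that the statistic reduces *exactly* to the Pearson
correlation when the smoothing matrix is the identity — making
"correlation" literal and giving a clean identity test. Model-side
band power is $\sum |X|^2$ over grid points in the band; empirical dB
values are de-logged ($10^{dB/10}$) first.

Optimization is bounded generalized simulated annealing
(`sa_anneal()`): Cauchy visiting moves scaled by a geometrically
cooled temperature, Metropolis acceptance, restart from the incumbent
every 20 iterations, and a final bounded L-BFGS-B polish — the same
anneal-plus-local-search structure as SciPy's dual annealing, which the
procedure follows. Three initial guesses are run per stage; if the best
result of a stage is unstable, the neural-gain bounds are tightened
(0.7/2.0 to 0.5/1.5 to 0.4/1.5) and the stage repeated, up to three
stages; if no stage ends stable, the best stable candidate evaluated
anywhere is accepted, and an explicit failure is returned if none was
ever seen (this fallback is our own definition; the staged-bounds
procedure as usually described leaves the case unspecified). Restarts are run within every stage, and
`polish_mode = "best"` (default) polishes only the winning restart;
`"each"` reproduces the costlier per-restart polish. Chains are seeded
deterministically from `(seed, subject, stage, start)`, so fits are
exactly reproducible.

Production settings are `maxiter = 500` iterations; the test suite
uses desk-scale profiles (maxiter 8-100, documented per test), which
on noiseless 20-node problems still recover $\tau_G$ to a few percent.

`progressive_refit()` re-fits each subject while freeing parameters one
at a time in a given importance order, all others held at the cohort
grand mean; the per-step mean spectral correlation quantifies how much
each parameter buys.

## Empirical spectral features

* `compute_psd_db()` — Welch-style segment-averaged amplitude spectra
  (2 s Hann segments, 50% overlap; clinical M/EEG pipelines often say
  only "FFT", and segment averaging is the standard variance-reduction
  choice), interpolated to the analysis grid, in dB.
* `acf_timescale()` — the intrinsic timescale: band-pass filter
  (default 1-35 Hz, the analysis band; the original band is not
  stated), per-region normalized autocorrelation, **mean ACF across
  regions first**, then the first $e^{-1}$ crossing with linear
  interpolation. Averaging order matters (a constructed two-region
  counterexample is in the tests).
* `parameterize_spectrum()` — aperiodic component
  $\mathrm{offset} - \mathrm{exponent}\cdot\log_{10} f$ fitted in
  log10-power space (so a $1/f^2$ spectrum has exponent 2), robustly
  (refit on the lower residual half); iterative Gaussian peak
  extraction above a 2-SD relative threshold with bandwidth
  (2 Gaussian SDs) at least 2 Hz; joint refit; the two lowest center
  frequencies become `first_cf`/`second_cf`, and a single peak is
  duplicated into the second slot. Zero peaks are flagged, not silent.

## Cohort statistics and classification

`group_compare()` fits `value ~ group + age` per parameter by OLS
(the estimand of the original mixed-model call in this single
observation-per-subject design), reports LS-means at the pooled mean
age with 95% CIs, Bonferroni correction over the 7-parameter family,
and Cohen's D on raw values (patient minus control; a flag switches to
age-residualized values). `regress_cognition()` provides the
univariate (Bonferroni x3) and multivariate (with age) regressions of
MMSE/CDR on $\tau_G, \tau_e, g_{ii}$.

`classify_cohort()` runs a random forest (100 trees, Gini CART,
`mtry = floor(sqrt(p))`, bootstrap — the common library defaults) under
repeated nested stratified 5-fold cross-validation; the inner 5-fold
grid tunes only the depth cap over {unbounded, 2, 3, 4} by mean inner
AUROC with ties to shallower trees; reported metrics are means over
repeats x outer folds at a 0.5 probability threshold, and importances
are mean decrease in impurity averaged over all outer-fold forests.
The forest is implemented in compiled code with its own RNG, so reports
are bit-reproducible given the seed. The default test profile uses 10
repeats; 100 (the production setting) is a config value.

## The synthetic world

`gen_connectome()` embeds regions uniformly in a 140 mm sphere,
takes Euclidean distances, applies an exponential distance rule
`exp(-d/40 mm)` thresholded to the target density (default 0.35),
keeps the strongest edge of any region the threshold would isolate, and
marks a fixed 79% subset cortical (the 68/86 proportion).

`gen_cohort()` draws each subject's parameters truncated-normal within
bounds and rejection-samples to stability. Group means default to the
reported control/patient values ($\tau_G$ 7.50/13.90 ms, $\tau_e$
11.88/15.01 ms, $g_{ii}$ 0.26/0.46) with SDs 3 ms / 3 ms / 0.15; the
other four parameters are group-invariant at mid-bound, with SDs chosen
once as roughly 5-10% of each bound range ($\tau_i$ 10 ms, $\alpha$
0.1, $v$ 1.5 m/s, $g_{ei}$ 0.05). Ages are drawn from the reported
group distributions (65.07 +/- 9.92 / 62.73 +/- 8.64 years). MMSE is
linear in the true $\tau_G$ (intercept 30, slope -0.6 per ms, noise SD
3, clipped to [0, 30]) — the only cognition-parameter link, because
that is the only cognition association the generator is designed to
carry; patients additionally get CDR = -1 + 0.42 $\tau_G$ + noise
(SD 2), clipped at 0. These coefficients place the patient group near
the reported MMSE/CDR means (22.1 and 4.9).

Spectra are the SGM forward prediction plus i.i.d. Gaussian noise in
dB. The default noise SD is **1 dB**, derived from first principles:
typical resting MEG protocols analyze 60 s epochs at 600 Hz, and a
Welch estimate
with 2 s Hann segments at 50% overlap averages ~59 segments, giving a
log-PSD standard error of $10/\ln(10)/\sqrt{59} \approx 0.56$ dB; 1 dB
allows for residual artifacts. What i.i.d. dB noise does *not* emulate
is structured model mismatch — the dominant error source against real
recordings (where spectral correlations are ~0.7-0.8) — so a green
synthetic recovery test establishes estimator correctness under the
model, not robustness to misspecification.

`gen_timeseries()` colors independent complex-Gaussian FFT bin
amplitudes by the full network transfer matrix and inverse-transforms,
yielding real series whose auto- and cross-spectra follow the model
(responses above 100 Hz, where the model is negligible, are zeroed for
speed).

## Numerical choices and degenerate inputs

* Frequencies in Hz at the interface, $\omega = 2\pi f$ internally;
  time constants in ms at the interface, seconds internally; distances
  mm; speed m/s.
* Eigenvalues sorted by ascending magnitude, ties by phase, so mode
  truncation is deterministic.
* Degrees are computed from the raw non-negative weights, never from
  the delayed complex matrix, keeping normalization
  frequency-independent.
* Zero-variance spectra, constant power maps, empty bands, isolated
  regions, single-class labels, and all-missing cognition columns
  raise informative errors rather than propagating NaN.
* The spatial smoother is built from the *full* row-normalized
  connectome restricted to cortical regions (+ $wI$), so cortical
  regions whose only connections are subcortical remain usable.
* The annealing objective returns a worst-case penalty (4, outside the
  attainable [-2, 2] range of a correlation sum) for non-finite or
  degenerate model responses, keeping the optimizer total.

## Known limitations

* One template connectome; no individual-connectome or spatially
  varying parameter support (matching the global, spatially-invariant
  premise of the model).
* The synthetic world cannot certify behavior under real model
  mismatch, sensor artifacts, or source-leakage correlations.
* The stability criterion addresses the local 2x2 system; network-level
  instabilities (possible in principle for extreme coupling) are
  caught only by the non-finite-response guard.
* HDF5 and YAML interfaces were descoped (CSV/JSON only) to stay
  within the guaranteed dependency set.
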