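---
title: "Methods: oscillation metrics, reliability, and the synthetic validation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillation metrics, reliability, and the synthetic validation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assrtools)
```

`assrtools` implements an analysis pipeline for single-channel auditory-cortex
ECoG experiments built around the auditory steady-state response (ASSR):
1 s click trains at 10/20/40/80 Hz separated by 1 s inter-stimulus intervals,
~100 trials per session, sampled at 2 kHz with 1--1000 Hz bandpass and a 50 Hz
notch. This vignette documents the estimators, their tunable parameters, the
generative model behind the synthetic cohorts, and the numerical and design
choices a maintainer should know about.

## Spontaneous spectra

Spontaneous activity is measured in the stimulation-free part of each epoch,
`t` in [-0.9, -0.2) s relative to train onset: this keeps a 0.2 s guard after
the previous train's offset and before the next onset. `psd_multitaper()`
demeans each 0.7 s segment, tapers it with discrete prolate spheroidal
(Slepian) sequences, combines eigenspectra with concentration weights summing
to one, and averages across trials. The one-sided density is calibrated so
that its integral over [0, fs/2] equals the segment variance; for
unit-variance white noise at 2 kHz the density is `1/(fs/2) = 1e-3` uV^2/Hz,
which the test suite verifies against a plain periodogram oracle and an
independent multitaper implementation.

The default half-bandwidth is W = 2.9 Hz (time-bandwidth product NW close
to 2 on the 0.7 s window, 3 tapers = 2NW - 1). The delta band (2--4 Hz) sits
at the resolution limit of this window; its variance is controlled by
averaging across the ~100 trials of a session, but single-session delta
estimates are the noisiest of the band set. W and the taper count are
arguments, not constants.

Band summaries are means (not integrals) of the density over half-open bins
`[low, high)`: delta 2--4, theta 4--8, alpha 8--12, beta 12--30, low gamma
30--45, high gamma 55--90 Hz, with 45--55 Hz always excluded because the
acquisition notch leaves residual mains power. The literature this design
follows is inconsistent about high gamma (45--90 in one place, 55--90 with
the 45--55 exclusion elsewhere); the package defaults to 55--90 and exposes
the wide variant as `default_bands("wide")`, which combined with the
exclusion gives the same bins.

## ASSR metrics

`morlet_tfr()` convolves each trial with L2-normalized complex Morlet
wavelets, 7 cycles at every frequency. Seven cycles gives roughly +/- 6 Hz
spectral support at 40 Hz and ~175 ms temporal support, compatible with the
0.2--0.9 s analysis window; at 10 Hz the ~700 ms support forces the
edge-handling rule: any time-frequency bin whose wavelet half-support
(`n_cycles/(2f)` seconds) crosses the epoch edge is flagged, and flagged bins
are excluded from every window average. Whether published ASSR averages
include edge-contaminated bins is generally unknowable; flag-and-exclude is
this package's documented choice. Output times are decimated to 5 ms.

Three metrics are extracted per session from the band `[f-2, f+2]` Hz around
the stimulation rate (endpoints inclusive on the integer frequency grid) and
the window 0.2--0.9 s after onset:

* **PLF** (phase-locking factor, inter-trial phase coherence): at each bin,
  the magnitude of the across-trial mean unit phasor, then averaged over
  bins. Amplitude-invariant by construction. With `N` uniformly random
  phases its expectation is `sqrt(pi/(4N))` — about 0.089 at N = 100 — so
  PLF values must always be read against this floor.
* **Induced power ratio**: per trial, mean power in the stimulation window
  divided by mean power in the 0.1--0.5 s pre-onset baseline, averaged
  across trials. The per-trial-ratio convention follows the order of
  operations in the underlying experimental literature; because the
  baseline mean in the denominator is itself noisy (few effectively
  independent wavelet samples in 0.4 s), this estimator carries a positive
  bias of roughly `1/dof` — about +10--20% at these window sizes — on
  stationary data. The bias cancels in within-animal contrasts. The
  unbiased ratio-of-means variant is available via
  `aggregate = "ratio_of_means"` for sensitivity analyses.
* **Evoked power**: trials are averaged sample-wise first, then transformed;
  only phase-locked activity survives averaging, and with uniform phases the
  expectation drops by the incoherent-averaging factor 1/N. The
  evoked/induced contrast is therefore the pipeline's phase-sensitivity
  dissociation, and an acceptance test verifies it directly. Units are uV^2
  under the discrete L2 wavelet normalization; evoked power of the trial
  average is computed by averaging the complex TFR coefficients (the
  transform is linear), which is exact and avoids a second convolution.

Harmonic responses (e.g. 80 Hz during 40 Hz trains) reuse the same machinery
on the band `[2f-2, 2f+2]` Hz.

## Reliability and inference

`icc_a1()` implements the single-measurement, absolute-agreement intraclass
correlation from the two-way decomposition (rows = animals, columns = days):

ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))

with F = MSR/MSE on (n-1, (n-1)(k-1)) degrees of freedom and the McGraw-Wong
confidence interval (Satterthwaite denominator df). Negative estimates are
reported as computed, not floored, for transparency in small-sample
simulations. Categories: poor < 0.5, moderate [0.5, 0.75), good
[0.75, 0.90), excellent >= 0.90; the published band notation is ambiguous at
the joins, so joins are assigned upward and the rule is centralized in
`classify_icc()`. Reliability tables analyse raw metric values by default
with a `log10` option; the test suite cross-checks the estimator against an
independent ANOVA route and against `pingouin`'s implementation.

`route_test()` reproduces the standard decision tree: Shapiro-Wilk at
alpha = 0.05 (on the differences for paired designs, on each sample
otherwise) routes to Student t tests or to Wilcoxon matched-pairs /
Mann-Whitney U. All tests are two-sided; rank tests use exact p-values when
feasible (combined n <= 20 without ties unpaired; <= 25 nonzero differences
paired, zeros dropped) and the tie-corrected normal approximation otherwise.
No multiplicity correction is applied, matching the per-band reporting
convention of the field. Drug effects are within-animal deltas,
`KET - SAL`, so a negative delta is a reduction under ketamine; sex
comparisons average each animal's metric across baseline days before an
unpaired test.

## The synthetic cohort generator

No public recordings accompany the study design this package targets, so
validation rests on a generator whose ground truth is known exactly.
Per session:

* **Background**: spectral shaping of random-phase noise. The one-sided
  target density is `c/f^chi` (default chi = 1) plus one Gaussian bump per
  band whose peak is the band's target density. Amplitudes are deterministic
  (square root of the target density) and only phases are random, so each
  epoch's variance equals the integral of its target density exactly — a
  property the tests assert. Bump SD is band width / 6: wide bumps bleed
  across band edges and couple neighbouring bands' drug effects (an early
  width/4 choice let the beta bump contaminate low gamma enough to dilute
  its ketamine effect), while width/6 keeps > 97% of each bump's mass inside
  its band. A narrow 50 Hz bump (default 5 uV^2/Hz) models the post-notch
  mains residual, so the 45--55 Hz exclusion is exercised; the notch filter
  itself is not simulated because epochs represent post-acquisition-filter
  signals.
* **Entrainment**: inside [0, 1) s, `A sin(2 pi f t + phi)` plus a 2f
  harmonic at `harmonic_amp_frac` (default 0.3) of the amplitude, under
  10 ms raised-cosine ramps; `phi` is drawn per trial from a von Mises
  distribution with concentration kappa. The von Mises choice gives the
  closed-form large-trial PLF target `I1(kappa)/I0(kappa)`
  (`expected_plf()`), which links the generator to the estimator in the
  acceptance suite.
* **Hierarchy**: animal, day and session Gaussian effects on the log scale,
  applied as a common multiplier to band densities, entrainment amplitude
  and kappa. On the log scale the intended ICC of any session metric is
  exactly `sigma_a^2 / (sigma_a^2 + sigma_d^2 + sigma_r^2)`. Defaults
  (0.50, 0.08, 0.15) put that ratio at ~0.88, matching the good-to-excellent
  test-retest reliability reported for these measures in vivo; the split is
  a calibration choice, not a measured fact, and all three are arguments.
  The day effect is shared across animals within a day (it is what the
  absolute-agreement column variance sees).
* **Drug sessions**: saline and ketamine sessions follow the baseline
  period, with administration order counterbalanced across animals (half
  receive saline first), so the shared day effect cancels out of group-mean
  drug deltas exactly as a counterbalanced in-vivo design intends — without
  it, the day effect is confounded with condition and can flip the weaker
  band deltas at desk scale.
* **Ketamine**: phenomenological multipliers — per-band density factors
  below one for delta/theta/alpha/beta and above one for the gamma bands
  (defaults follow the observed direction and rough magnitude of
  subanaesthetic NMDA-antagonist effects), and reductions of the
  drug-paradigm entrainment amplitude and kappa. No pharmacokinetics, no
  interneuron circuit model; conditions are labels.
* **Determinism**: every session has its own RNG stream keyed by
  (seed, animal, day, rate, condition), so identical specs reproduce
  bit-identical datasets and any session can be regenerated independently.

Defaults mirror the emulated study scale: 35 males, 33 females, five
baseline days, four train rates, 100 trials per session, with saline and
ketamine sessions (40 Hz paradigm) after the baseline period. What the
generator does **not** emulate: non-stationarity within sessions, estrous
hormone dynamics (only generic day-level variance), movement or electrode
artifacts, 1/f knee structure, and real click-evoked transients (the
stimulus is the entrained sinusoid the analysis measures, not a click train
through an unknown neural transfer function). Passing tests therefore
demonstrate estimator correctness and pipeline integrity under the model's
assumptions, not robustness to every pathology of real recordings.

## Validation studies and their sizing

Because simulation-based checks are statistical, each validation study was
sized so that a correct implementation passes with high probability — a
power analysis, not a tuned threshold:

* **PLF--kappa link**: the 1000-trial PLF estimate has Monte-Carlo SD around
  `sqrt((1-R^2)/2000)` (~0.02 at kappa = 0.5), comparable to the 0.03
  acceptance band, so the comparison is made on the mean of four independent
  1000-trial estimates.
* **ICC recovery** (`icc_recovery_study()`): 30 animals by 5 days, log
  beta-band power measured from 8-trial sessions. Spectral measurement
  noise (~0.007 log-variance) attenuates the recovered ICC by a known
  factor `sigma_tot^2 / (sigma_tot^2 + sigma_meas^2)` (~3% here), which
  sits well inside the +/- 0.08 acceptance band.
* **Directional pattern study** (`pattern_spec()`, `check_pattern_seed()`):
  a desk-scale cohort (14 + 14 animals, one baseline day, 20 and 40 Hz
  paradigms, 18 trials) with stronger male 40 Hz entrainment, the ketamine
  band multipliers, and ketamine-reduced 40 Hz amplitude and concentration
  (both 0.6, chosen so the configured log-effects exceed three standard
  errors of the corresponding group-mean deltas under the generator's
  session-level variability). Each seed is scored on: male > female group
  means for the three 40 Hz metrics; no sex difference in 20 Hz metrics or
  any spontaneous band; sign-correct group-mean band deltas in both sexes;
  reduced 40 Hz PLF/induced/evoked in both sexes; and — in a sex-equal
  companion cohort — no sex difference in any delta metric. The "no
  difference" checks use alpha = 0.001 because a seed must pass the
  conjunction of roughly a dozen null tests; at alpha = 0.05 the joint
  false-positive rate alone (~1 - 0.95^12) would fail most seeds of a
  correct implementation. The delta sex-difference null is evaluated on the
  sex-equal companion because multiplicative drug effects on sex-different
  baselines necessarily produce sex-different raw deltas — the null is only
  well-defined when the generative sex difference is off.
* **`run_e2e_validation()`** compares estimated PLF against
  `expected_plf(kappa)` of each session's realized concentration (all
  conditions, so the drug-induced kappa reduction is exercised), the
  recovered ICC of log beta power against the variance-ratio target, and
  group-mean band-delta signs against the configured multipliers. The PLF
  check is a large-amplitude limit: `validation_config()` therefore uses
  entrained amplitudes that dominate the in-band background. The
  sign check is restricted to the spontaneous bands, whose configured
  effects are strong; session-level variability makes sign checks on the
  weaker default ASSR multipliers uninformative at this scale.

## Numerical notes and degenerate inputs

* Half-open windows everywhere: the sample at exactly t = 0 is
  post-stimulus; band bins satisfy `low <= f < high`; the ASSR analysis
  bands are endpoint-inclusive on the integer wavelet grid, matching the
  printed "8--12, 18--22, 38--42, 78--82 Hz" convention.
* DPSS tapers come from the classical symmetric tridiagonal eigenproblem;
  concentrations are the exact sinc-kernel quadratic forms and are checked
  (warning below 0.90). Tapers are cached per (length, W, count).
* Wavelets are truncated at `n_cycles/(2f)` half-support (capped at the
  epoch length) and FFT convolution uses 5-smooth transform lengths.
* `expected_plf()` switches to the asymptotic expansion
  `1 - 1/(2k) - 1/(8k^2)` above kappa = 1e4, where R's Bessel functions
  lose accuracy.
* Zero-magnitude TFR coefficients contribute zero unit vectors to PLF;
  all-zero trials make the induced ratio error out (zero baseline), naming
  the trial. Constant ratings matrices, incomplete designs and n or k < 2
  are hard errors in `icc_a1()`; ICC = 1 exactly returns the degenerate CI
  (1, 1). Paired comparisons with zero-variance differences are degenerate
  errors rather than infinite t statistics.
* EDF I/O quantizes to the 16-bit digital range over a symmetric physical
  range covering the data; round trips are exact to that quantization.
  Bundles store float32 little-endian, trial-major; analysis is always in
  double precision.

## Known limitations

* The multitaper delta band on a 0.7 s window has ~1 Hz resolution and two
  usable bins; treat single-session delta power with caution.
* The induced-ratio default is biased upward on stationary data (documented
  above); cross-condition contrasts are unaffected but absolute ratios
  should be compared only within a fixed window configuration.
* PLF is bounded, so heavy animal-level heterogeneity compresses
  between-animal variance near the ceiling and its ICC is not a clean
  variance ratio (the generator's log-scale ICC statement applies to power
  metrics).
* The EDF writer covers plain continuous recordings (no EDF+ annotations,
  no discontinuous records).
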