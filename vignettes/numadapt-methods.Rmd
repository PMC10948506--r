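---
title: "Models and methods behind numadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numadapt)
```

## The scientific problem

Temporal numerosity adaptation is the bias in estimating how many events
occurred in a sequence after exposure to a more numerous (underestimation) or
less numerous (overestimation) adaptor sequence. The experimental paradigm
this package models is a blocked design: each trial presents an 8-s adaptor
of either 64 flashes (High, ~8 Hz) or 16 flashes (Low, ~2 Hz), a 1-s gap,
and a 4-s test sequence of 14, 16, 18, 20 or 22 flashes whose numerosity the
participant reports verbally. 350 trials are split into 10 blocks of 35 with
the adaptor condition constant within a block and the block order
counterbalanced across participants. Flashes are evenly spaced up to a
+/-15% jitter of the inter-flash interval, so a test of `n` flashes over 4 s
*frequency-tags* the EEG at `n/4` Hz (3.5--5.5 Hz).

Three readouts are computed from 30-channel EEG epochs spanning
[-500, 4500) ms around test onset at 500 Hz:

1. **ERPs** to the test onset: epochs trimmed to [-100, 200) ms, baseline
   [-100, 0) ms removed, averaged over numerosities 14--20 only (at 22
   flashes the second flash lands inside the window), compared pointwise
   between conditions over a posterior cluster.
2. **ssVEPs**: selective averaging per condition x numerosity, single-sided
   FFT amplitude of the [0, 4000) ms window, amplitude extracted at the
   tagging bin and averaged across numerosities but never across conditions.
3. **ISPC connectivity**: surface-Laplacian filtering, condition x
   numerosity averaging, narrowband Hilbert phase at the tagging frequency,
   and inter-site phase clustering `|mean(exp(i(phi_a - phi_b)))|` for all
   435 channel pairs, averaged over numerosities.

Group inference uses paired sign-flip permutation tests (15,000 permutations,
statistic: paired t), Benjamini-Hochberg FDR across channels or pairs, a
2 x 5 repeated-measures ANOVA with Greenhouse-Geisser correction for the
behavioral estimates, Bonferroni post-hocs, the adaptation percentage
`100 (mean estimate | Low - mean estimate | High)/true N`, and a Spearman
correlation linking individual ssVEP modulation to behavioral adaptation.

## Window and time conventions

All times are in ms with 0 = test onset; all sample windows are half-open
`[start, stop)`. The FFT window is exactly [0, 4000) ms (2000 samples), so
the bin width is 0.25 Hz and every tagging frequency falls on an exact bin;
this removes spectral-leakage ambiguity and makes the tagging readout an
identity for a noise-free bin-aligned sinusoid (a property the test suite
asserts at 1e-9).

## The preprocessing chain

* **Band-pass filter.** Hamming-windowed linear-phase FIR, 1--40 Hz
  passband, -6 dB points at 0.5 and 40.5 Hz, applied forward with explicit
  group-delay compensation (net zero phase) and reflection padding. Because
  the lower transition band sits next to DC, the realized -6 dB point of a
  windowed design drifts from the requested cutoff; `fir_bandpass_design()`
  calibrates the requested cutoffs by root-finding so the realized -6 dB
  points land exactly on 0.5/40.5 Hz. The default order (1650 at 500 Hz,
  from the 1-Hz transition width) yields <0.2% passband ripple and ~40 dB
  DC attenuation. Epochs must be at least as long as the filter.
* **Average reference** (a projection; per-sample channel mean becomes 0).
* **Spherical-spline interpolation** of bad channels and the
  **surface Laplacian** share one basis implementation (Perrin-style,
  order m = 4, regularization 1e-5, 50 Legendre terms), so the two can
  never drift apart numerically.
* **Epoch rejection**: an epoch is removed iff any channel's peak-to-peak
  amplitude exceeds 150 uV. This deterministic rule stands in for manual
  artifact inspection and independent-component removal, which are
  judgment calls that cannot be reproduced from a specification; the
  fractions removed by the original manual procedure are therefore not
  modeled targets. When the threshold would empty a condition x numerosity
  cell (selective averaging needs every cell), the pipeline keeps that
  participant's epochs unrejected and warns.

## The synthetic generator

The generator exists so that every analysis stage can be verified against
known ground truth. Its defaults are the study conditions: 16 participants,
the blocked design above, behavioral gains 1.075 (Low) and 0.925 (High)
whose difference is the ~15% headline adaptation effect, a 1.3 High/Low
ssVEP amplitude ratio at sensors POz, O2, C3, Cz, and narrowband phase
coupling at pairs C3-CP5, CP5-CP6, CP5-POz, C3-PO7 with strengths 0.6
(High) vs 0.2 (Low).

**Behavior.** `estimate = round(max(0, N * gain_c * s_p + eps))` with a
per-participant gain `s_p ~ N(1, 0.05)`, trial noise `eps ~ N(0, 1.2)`
flashes, and rounding half away from zero (verbal integer reports; the
symmetric rule makes the noise-free examples exact). In the noise-free limit
the expected adaptation percentage is exactly `100 (gain_low - gain_high)`.

**EEG.** Each trial is a sum of:

* **1/f background noise** (10 uV RMS per channel, exponent 1), split
  between channel-independent noise and six very smooth shared spatial
  sources (90% of variance) standing in for volume-conducted far fields --
  the spatial structure the surface Laplacian is designed to suppress, and
  the reason the Laplacian demonstrably decorrelates the simulated data.
* A **stimulus-locked ssVEP sinusoid** at the trial's tagging frequency,
  active during [0, 4000) ms, cosine phase, with amplitude exactly 1 uV
  (Low) or 1.3 uV (High) at the effect sensors. Away from them the
  topography is the minimum-leakage field around a 6-degree Gaussian
  falloff: a small quadratic program jointly penalizes scalp amplitude
  (what the tagging-bin readout sees) and current source density (what the
  Laplacian-filtered connectivity readout sees) at the non-effect
  electrodes, so the evoked response stays focal in both analysis domains
  and the generator's ground truth is a sensor-resolved effect set.
* **Entrained narrowband sources** at the tagging frequency, which carry
  the phase-coupling manipulation (next section).

**Montage.** The paper-style 30-channel set with idealized 10-10 spherical
positions computed analytically (spherical interpolation along the
nasion-inion, ear-to-ear, and outer-ring arcs in 10% steps). Digitized
positions were never available; the idealization affects spline constants,
not pipeline logic.

## How the coupling manipulation is built

Three design problems shape the narrowband source model, and each is solved
structurally rather than by brute force:

1. **The connectivity readout must not confound the amplitude readout.**
   The narrowband sources are synthesized on the DFT grid of the [0, 4000)
   ms window with the coefficient at the exact tagging bin set to zero:
   they surround the tagging frequency (so they dominate the Hilbert-band
   phase) while contributing nothing -- identically zero -- to the
   tagging-bin amplitude. The ssVEP and ISPC manipulations are orthogonal
   by construction.
2. **The coupling must survive the surface Laplacian.** Scalp-level
   injection at single electrodes fails: adjacent coupled electrodes (C3,
   CP5, CP6 are neighbors) get spatially differenced by the Laplacian,
   which is precisely its job. The sources are therefore defined in
   current-source-density space -- focal cortical sources under the member
   electrodes -- and mapped to the scalp by the pseudo-inverse of the
   Laplacian operator (its forward field), with per-mode scalp gain capped
   so near-singular smooth modes cannot blow up scalp amplitudes. The
   analysis then recovers the injected correlation structure almost
   exactly (one irreducible null-mode projection remains; its leaked
   correlations are <0.1 and ISPC responds only quadratically to
   correlations near its noise floor, so the leak is invisible).
3. **The pair graph caps the achievable coupling.** With CP5 in three pairs
   and C3 in two, a uniform pair correlation of 0.6 is mathematically
   infeasible (`I + 0.6 A` is not positive definite; the limit is
   `1/lambda_max(A)` = 0.54 for this graph). The channel-wise sources are
   drawn with target covariance `I + w A` via its Cholesky factor, with
   `w` capped at `0.95/lambda_max(A)` (~0.51). Every channel keeps unit
   band variance and non-coupled pairs keep exactly zero correlation.

The sources are **stimulus-entrained**: one realization per numerosity,
reproducible across trials and across the two adaptation conditions (the
test sequences are identical; the adaptor changes only the coupling
weight). Selective trial averaging therefore preserves them, and the paired
High-Low contrast isolates exactly what the adaptor manipulates. Part of
the source variance (`nb_common_frac = 0.45`) is stimulus-determined --
shared by all participants of the same simulated experiment (keyed by
`nb_common_seed`, redrawn per experiment) -- the rest is individual. The
stimulus-determined block is orthonormalized over the analysis window, so
the covariance imposed on it is realized exactly in every experiment rather
than up to the (large, because the band-time product is small) finite-sample
error of a random draw: what the generator injects is known ground truth,
not ground truth plus sampling noise. Source strength is expressed on the
montage's local CSD scale (Laplacian row norms), keeping the
source-to-background ratio uniform across the scalp.

### Why the analysis band is wider than the tagging spacing

The Hilbert band half-width is 2 Hz by default. A +/-0.5 Hz band looks
natural (the tagging frequencies are 0.5 Hz apart) but is a statistical
dead end for ISPC over a 3-s valid window: the number of effective phase
samples is roughly bandwidth x time, so +/-0.5 Hz yields ~3 effective
samples, an ISPC null floor of ~0.5, and -- together with the 0.54
correlation ceiling above -- no corridor left for the coupling effect to
live in. Nothing separates adjacent tagging frequencies inside a condition
x numerosity average (each average contains a single tagging frequency),
so the band need only exclude broadband noise; +/-2 Hz gives ~12 effective
phase samples and a null floor near 0.3. The 500-ms edge exclusion at each
end of the test window removes filter and Hilbert edge artifacts. The
forward-backward second-order Butterworth response is applied as `|H|^2` in
the frequency domain, fused with the Hilbert half-spectrum mask; its
boundary behavior differs from time-domain filtering only inside the
excluded margins.

### Reference handling in the simulation pipeline

The recorded-EEG chain re-references to the channel average because a
recording reference must be removed. The generator emits reference-free
potentials: re-referencing them only injects the focal ssVEP topography's
spatial mean -- scaled by the condition ratio -- into every channel, which
is a real (and instructive) average-reference artifact but makes the
generator's ground truth no longer sensor-resolved. The simulation
pipeline (`run_group_experiment()`) therefore skips re-referencing; the
operation keeps its contract, unit tests, and place in the CLI chain for
recorded-style data. The ISPC arm is reference-invariant either way
(a reference shift is spatially constant and the Laplacian of a constant
is zero).

## Statistics

* `paired_permutation_test()`: paired t on within-participant differences;
  null by random sign flips of each participant's difference vector
  (condition-label exchange within participant); exhaustive enumeration
  whenever `2^n <= n_permutations`; Monte-Carlo p `(1 + c)/(B + 1)` so p is
  never zero; all features share one set of flips, as channel-wise EEG
  permutation tests do.
* `fdr_bh()`: step-up adjusted p values with enforced monotonicity,
  verified against the brute-force definition in the tests.
* `rm_anova_gg()`: two-way within-subject decomposition on per-participant
  cell means (trials are collapsed first, standard psychophysics practice);
  Greenhouse-Geisser epsilon from the covariance of orthonormal contrast
  scores, `eps = tr(S)^2 / ((k-1) tr(S^2))`; corrected p values on
  `(eps df1, eps df2)` with uncorrected df reported; partial eta squared
  per effect against its own error stratum. Cross-checked against an
  independent implementation (`car`) to 1e-6 in the tests.
* `adaptation_percentage()`: per participant and numerosity first, then
  the unweighted numerosity mean per participant, then the group mean --
  the per-range-then-average order matches how per-range adaptation curves
  are reported.
* `spearman_correlation()`: Pearson correlation of mid-ranks with the
  two-sided t approximation. The brain-behavior analysis pairs each
  participant's overall adaptation percentage with the (High - Low)
  numerosity-averaged tagging amplitude averaged over the significant
  sensor set.

## Problem sizes and what the tests do and do not show

EEG simulations in the test suite run at a desk-scale profile: 8 trials per
condition x numerosity cell (2 blocks x 40 trials) instead of the full 35,
with 16 participants. The recovery checks -- FDR-significant sensor set
equal to the injected {POz, O2, C3, Cz}, FDR-significant pair set equal to
the injected {C3-CP5, CP5-CP6, CP5-POz, C3-PO7} -- are run over 20 seeded
replicate experiments, and error-rate checks over null experiments with no
injected effect.

What passing these tests shows: the full pipeline (generator ->
preprocessing -> spectral/connectivity readouts -> permutation + FDR
inference) recovers known ground truth with controlled error rates at
realistic signal-to-noise. One asymmetry between the two arms is worth
understanding: the sensor comparison recovers the exact effect set almost
every run because the 26 null channels share volume-conducted tagging-bin
noise and behave like a handful of effective tests, whereas the surface
Laplacian deliberately decorrelates the 435 pair statistics, so
Benjamini-Hochberg with four discoveries faces hundreds of nearly
independent null tests at an adaptive threshold of `5q/435` and admits an
occasional isolated false-positive pair (on the order of one run in five)
-- the designed behavior of FDR control, not a pipeline defect. All four
injected pairs are themselves recovered in essentially every run, and under
the global null the family discovery rate stays at the FDR level. What it does not show: the generator omits
eye-movement and muscle artifacts, real volume-conduction physics (its
forward model is the spline pseudo-inverse, not a head model), non-unit
electrode impedance structure, and any single-trial variability of the
entrained response beyond the stationary model above; conclusions about
real recordings still require real recordings.

## Numerical choices

* Round-half-away-from-zero for verbal estimates (symmetric, makes the
  stated examples exact).
* FFT normalization: `|X0|/N` at DC, `2|Xk|/N` elsewhere, so a bin-aligned
  sinusoid of amplitude A reads A; Parseval is asserted in the tests under
  this convention.
* Spline constants m = 4, lambda = 1e-5, 50 Legendre terms (standard
  Perrin parameterization); the interpolation and Laplacian tests pin the
  constant-field, linearity, idempotence and smooth-field accuracy
  properties.
* Epoch store: a single RDS file per participant with the array, event
  table, labels and sampling attributes; behavioral tables are plain CSV.
* Permutation p-value convention `(1 + c)/(B + 1)`; exhaustive enumeration
  below `2^n <= B` uses the exact proportion.

## Known limitations

* The ~0.51 feasibility cap means the nominal High coupling strength 0.6
  is not exactly realizable over this pair graph; the generator documents
  and applies the cap rather than silently renormalizing per pair.
* An idealized montage stands in for digitized positions; Laplacian
  constants (not logic) depend on it.
* The ERP module simulates no genuine evoked morphology beyond the ssVEP
  onset; ERP comparisons are validated on constructed data and null
  simulations, mirroring the null ERP finding the design anticipates.
* The CLI's full-chain defaults are desk-scale; full-scale runs (35
  trials/cell) are a configuration change, not a code path change.
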