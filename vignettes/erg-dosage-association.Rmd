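---
title: "ERG component simulation and kinship-adjusted dosage association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERG component simulation and kinship-adjusted dosage association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergdose)
```

`ergdose` implements, end to end, the analysis design of a
twin-cohort study linking full-field electroretinogram (ERG) waveform
parameters to allelic dosage at a biallelic myopia-risk locus: a
cellular-component forward model of the ERG, a synthetic twin cohort, the
ISCEV-style measurement chain, and a kinship linear mixed model. Because
individual-level data for this kind of study are access-controlled, the
synthetic generator *is* the study population: all claims the test suite
makes are claims about the pipeline's behaviour on data whose
ground truth is known exactly.

## The forward model

A single-flash response is the sum of six labelled components on a
uniform grid (0.5 ms sampling, −20 to +250 ms; the 20 ms pre-flash span
feeds baseline estimation):

| component | form | role |
|---|---|---|
| rod / cone PIII | `−R_max (1 − e^{−I·S·(t−d)²})` | a-wave trough |
| rod / cone ON PII | unit-peak gamma bump with onset delay | b-wave |
| cone OFF | difference of two gamma bumps | a-wave trough + b-wave shoulder |
| oscillatory potentials | damped sinusoid | wavelets on the rising b-wave |

The PIII form is the standard saturating a-wave model: negative-going,
magnitude nondecreasing in time and flash strength, with no recovery
term. That last property has a structural consequence: a measured
"a-wave" grows with the window end, so troughs must be protected from
the rising PII. We therefore give every PII kernel a hard synaptic onset
(`rod_pii_onset`, `cone_pii_onset`) and place the rod-PII onset (28 ms,
shared by the oscillatory potentials) exactly at the upper edge of the
a-wave search window. Dark-adapted and rod-isolated a-wave troughs are
then purely photoreceptor-driven, which is what makes the CRAO
rod-isolated a-wave ratio exactly 1 rather than approximately 1.

Pathway amplitudes saturate hyperbolically with flash strength
(`I/(I + I₅₀)`). Two half-saturations matter scientifically:

* the OFF **negative** lobe saturates like an a-wave generator
  (`off_i50 = 6`), giving the postreceptoral share of the cone-driven
  a-wave;
* the OFF **positive** lobe is band-pass in flash strength
  (`I/(I+off_pos_i50) · off_pos_sat/(off_pos_sat+I)`, defaults 1 and 5),
  so the OFF contribution to the b-wave is prominent for the standard
  light-adapted 3 cd·m⁻²·s flash but minor for bright flashes delivered
  on the blue background. This single mechanism produces the clinical
  dissociation the lesion demonstrations check: with ON-bipolar signals
  removed (cCSNB), the bright-flash blue-background b-wave collapses
  (ratio < 0.1) while the standard light-adapted flash keeps a clear
  OFF-driven b-wave (ratio > 0.3).

Backgrounds: the dim blue rod-saturating field multiplies every
rod-pathway component by `1 − rod_suppression`; the default
`rod_suppression = 1` is the idealized mode in which the subtraction
identity (dark − blue = rod component) is exact. Values below 1 simulate
incomplete rod saturation, the caveat attached to subtraction-based rod
isolation. The white photopic background applies a single cone
adaptation scalar (`white_cone_adapt = 0.5`); a value below 1 is
required because the light-adapted standard-flash a-wave must stay small
(~24 µV scale) while the dark-adapted cone PIII must be deep enough to
dominate the bright-flash cone response.

The 30-Hz flicker response is modelled directly in its periodic steady
state as a 30 Hz sinusoid whose peak-to-trough amplitude is a stated
linear combination of the cone-pathway amplitudes; the rod pathway
contributes nothing.

**Calibration.** The amplitude gains were tuned once and frozen in
`default_gains()`, so that noiseless baseline (dosage-0) responses land
within ±10% of three anchors: dark-adapted 3.0 cd·m⁻²·s a-wave ≈ 150 µV,
light-adapted 3.0 b-wave ≈ 102.5 µV, cone-driven a-wave at
67 cd·m⁻²·s ≈ 56 µV. The calibration test asserts exactly these three
anchors; other printed parameters of the protocol (dim-flash b-wave,
flicker amplitude, rod-isolated amplitude gradation) come out
recognizably ERG-like but are not asserted numerically.

**Waveform-shape signature.** With the full OFF complement the rising
limb of the light-adapted flash response is smooth (the gradient stays
positive across 18–32 ms); when the OFF gain is reduced, a gradient
change — a local dip around 25 ms — emerges. We deliberately implement
the direction in which the *reduced*-OFF waveform carries the
inflection, matching the clinical observation that risk-allele
homozygotes (lower OFF amplitudes) show the ~25 ms gradient change.

## The synthetic cohort

`cohort_spec()` defaults describe the emulated study: 93 twin pairs
(≈186 analyzed subjects), 95% female, ages ~ Normal(64.2, 9.7) truncated
to [18, 95], risk-allele frequency 0.5296 (the value implied by a
37/101/48 dosage split), and a 50/50 MZ/DZ mix (the registry's split is
not public; 50% is a neutral default). Genotypes: founders and
singletons are Hardy–Weinberg draws; MZ co-twins copy; DZ co-twins get
two explicit Mendelian parental transmissions, so their dosage
correlation is exactly 0.5 in expectation and testable in closed form.

The dosage acts multiplicatively on `off_bipolar_gain` only:
`gain × (1 + d · off_effect)`. The default `off_effect = −0.35` was
chosen so that, with the model's postreceptoral share of the
bright-flash cone a-wave (~22%), the dosage-2/dosage-0 amplitude ratio
reproduces the ~0.85 gradient such studies report, and so that the
cone-driven association is well powered (analytically ≈ 0.9) at
n = 186 while rod parameters remain exactly null. Between-subject
variability is a mean-one lognormal multiplier on all amplitude gains
(`subject_sd = 0.2` on the log scale, matching ~20% cross-sectional
coefficients of variation), with a family-shared multiplier
(`family_sd = 0.1`) inducing within-family correlation and a small
inter-eye deviation (`eye_sd = 0.03`).

What the generator does **not** emulate: electrode drift between
sessions, pupil-size and pre-retinal optics, age- or axial-length-
dependent amplitudes, LD structure or more than one locus, amplifier
bandwidth, and photoreceptor recovery kinetics. Passing tests therefore
demonstrate the correctness and calibration of the *pipeline*, not that
real cohorts will show these effect sizes.

## Measurement chain

Baseline is the arithmetic mean over [−20, 0) ms. Artifact rejection
removes sweeps exceeding 1,000 µV absolutely or whose RMS deviation from
the pointwise median sweep exceeds median + 5·MAD, never removing all
sweeps (the best sweep is kept and flagged). Sweeps are averaged within
eye; parameters are measured per eye and the two eyes' values averaged
(trace-level eye averages exist for display). The a-wave is
baseline-to-trough (reported positive, window 3–28 ms), the b-wave
trough-to-peak (window 10–80 ms; baseline plays the trough's role for
the dim flash, which reports no a-wave), flicker is mean peak-to-trough
over complete cycles after discarding the first. Ties at plateau extrema
go to the earliest sample, for determinism. Rod isolation subtracts the
blue-background response from the dark response to the identical flash
and refuses mismatched flash strengths.

## The mixed model

`fit_lmm()` fits `y = Xβ + u + ε`, `u ~ N(0, σ_g²K)`, by spectral REML:
one symmetric eigendecomposition of `K`, rotation of `y` and `X`, a
100-point log-grid profile over `λ = σ_g²/σ_e² ∈ [10⁻⁵, 10⁵]`, then
golden-section refinement to 10⁻⁶ in log λ. REML (rather than ML) is the
default because variance components feed the standard errors; ML is an
option. The dosage test is a Wald t with `n − rank(X)` degrees of
freedom; a score or likelihood-ratio alternative was considered and not
implemented, keeping the behaviour of the conventional software class
this emulates. Rank-deficient design columns are dropped with a warning
(tiny all-female cohorts make the sex indicator degenerate). `K` must be
symmetric PSD up to a −10⁻⁶ relative ridge; eigenvalues are floored at
zero.

`gls_oracle()` is the verification route: dense `V = λK + I` solves per
grid point. The tests require agreement with the spectral path to 1e−4
relative in β, SE and λ̂ on twin datasets; the restricted likelihood is
additionally cross-checked against a third, literal implementation on a
six-subject system.

Two statistical facts shaped the test design:

* **REML boundary behaviour.** When the true σ_g² is 0 but `K` has twin
  structure, λ̂ follows the usual half-normal boundary distribution —
  about half of finite-n replicates give a small positive λ̂, so GLS
  does not reproduce OLS to 1e−4 on such data. The exact OLS-reduction
  property is therefore asserted on unrelated cohorts (`K = I`), where
  it holds identically for any λ.
* **Wald calibration.** The Wald t is slightly liberal at small n
  (variance-component estimation is unaccounted for). Type-I calibration
  is checked at 60 twin pairs (n = 120) with λ = 2 — two-thirds of trait
  variance familial, consistent with the high reported heritability of
  ERG amplitudes — where the empirical rate sits within 0.05 ± 0.01 over
  2,000 replicates while naive OLS on the same data rejects at roughly
  twice nominal.

## Problem sizes and numerical choices

The test suite and acceptance script use: 2,000 replicates for type-I
calibration; 200 cohorts of 93 pairs for effect recovery and coverage
(bias bounded by 3 Monte-Carlo standard errors, coverage required in
[0.91, 0.98]); 40–50 cohorts for the power/null dissociation; noiseless
single-eye feature extraction (`noiseless_cohort_features()`) for the
simulation studies, which equals the full two-eye chain exactly when
eyes are identical. The subtraction identity is asserted at 10⁻⁹ µV; the
CRAO rod-isolated ratio at 10⁻¹² (the algebra is exact, but the
subtraction re-associates floating-point sums, so bit-identity is not
the right notion); decomposition closure at machine precision. All
randomness flows from one master seed through stage-tagged derived
seeds, and `run_study()` writes numeric tables with 17 significant
digits so that stage-wise runs through intermediate files reproduce the
in-memory run byte for byte.

## Known limitations

The PIII model never recovers, so very long windows would keep deepening
saturated troughs; window ends are part of the measurement definition.
The flicker model is a stated steady-state amplitude, not a
superposition of flash kernels, so flicker waveform *shape* carries no
information. The OFF kernel's band-pass positive lobe is a
phenomenological stand-in for push-pull ON/OFF interactions. Group-level
summary tables from a single simulated cohort need not be monotone in
dosage (sampling noise at n ≈ 45 per group); only expectations are. And
no claim of numerical equivalence with any external mixed-model software
is made — the contract is internal: spectral fitter ≡ dense oracle.
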