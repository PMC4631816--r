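---
title: "Simulating and decoding body-part category responses in MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding body-part category responses in MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package models

`megdecode` implements the full analysis chain for a time-resolved MEG
category-decoding experiment: epochs time-locked to pictures of feet,
hands, mouths and objects are cleaned, averaged, source-localized, and
decoded in sliding time windows, with a random-class relabelling serving
as the null against which categorical decoding is judged. Because no
recordings ship with the package, the first-class citizen is a
forward-modelled generator whose ground truth every later stage is
validated against.

```{r, eval = FALSE}
library(megdecode)
report <- run_pipeline(default_config("smoke"), seed = 7)
```

## The generator

**Geometry.** Sensors sit on a helmet-like spherical cap 2 cm above a
9 cm conductor sphere, sources on a cortical shell at 0.85 of the head
radius, both laid out by a golden-spiral rule with a small seeded
angular jitter. Channels are tagged `frontal` (most anterior quarter;
these are later discarded, 160 → 120), `occipitotemporal`, or `other`;
vertices are tagged `EBA-like` (posterior-lateral extrastriate patch),
`early-visual`, or `background`. The default sizes — 160 channels, 4004
vertices, 560 trials of 14 images, 1 kHz sampling over -500..499 ms —
are the experimental design the package emulates.

**Forward model.** The field of a current dipole in a homogeneous
conducting sphere (Sarvas closed form), projected onto the radial sensor
orientations. This is the standard analytic MEG head model; it makes
inverse recovery testable (the radial-dipole silence and the
pseudo-inverse limit are exact properties a test can assert). Dipole
orientations are oblique unit normals with a guaranteed tangential
component, since purely radial dipoles are invisible.

**Evoked template.** Each body category activates `n_active` vertices in
the EBA-like patch; a fraction `overlap` (default 0.5) of them is shared
across the three body categories and the rest are category-unique. This
mirrors the two-part finding the analysis is designed to detect: a
common body-sensitive response plus category-specific variance. Object
images activate a separate early-visual set. The time course is two
half-cosines joined at `peak_ms` (default 190 ms), identically zero
outside 100–300 ms, full width at half maximum 100 ms. A fixed
per-image gain (SD 10%) gives each image an identity of its own without
adding category structure — exactly what the random-class scheme is
meant to be sensitive to. Setting `category_effect = 0` removes the
category-unique amplitudes and (together with `image_gain_sd = 0`)
yields a label-free null generator.

**Units and calibration.** Sensors are in tesla, dipoles in nA·m.
Source amplitudes are calibrated per subject so the noiseless evoked
field peaks at `target_peak_T` (default 100 fT) at the best channel — a
typical extrastriate evoked-field magnitude. The noise defaults
(300 fT white sensor noise per sample, 20 background dipoles per trial
with 1/f spectra at 2 nA·m, 5% per-channel gain jitter per subject) were
chosen once so that single-trial decoding is clearly above chance but
below ceiling; they are deliberately a *calibration*, because the
experiment reports no single-trial SNR to copy. What the simulator does
not emulate: real cortical folding and BEM conductor geometry, eye-blink
and cardiac artifacts, head movement, and trial-to-trial latency jitter
of the evoked response. Passing tests therefore demonstrate the
correctness and calibration of the *analysis chain*, not performance on
real recordings.

## Preprocessing choices

The chain is notch → band-pass → baseline → channel selection →
artifact rejection.

* Filters are zero-phase (forward–backward IIR): the experiment's
  conclusions hinge on latencies, and causal filtering would delay them
  by several ms. A `zero_phase = FALSE` switch exists because the
  original acquisition chain may well have been causal.
* The band-pass is an order-6 Butterworth (3 poles per edge). An
  order-4 design run forward–backward attenuates 50 Hz by only ~19.5 dB,
  just short of the 20 dB the pipeline promises for line-adjacent
  interference; one extra pole pair buys a comfortable margin without
  meaningful passband distortion at 1–30 Hz.
* Edge handling: each trace is extended by 400 samples of Burg
  linear-prediction forecast before filtering and cropped afterwards,
  and the filter state is initialized to the steady state of the first
  sample. Plain reflection padding leaves a curvature kink at the epoch
  edges that rings through a high-Q notch (Q = 30) and leaks in-band
  through the band-pass; linear prediction continues oscillatory content
  smoothly, so a pure sinusoid passes essentially transient-free, and it
  falls back to constant extension on degenerate traces.
* Artifact rejection is a peak-to-peak threshold (default 3 pT) — the
  simplest criterion consistent with "apparent artifacts were removed",
  and the generator only produces amplitude artifacts anyway.
* The "frontal" exclusion is geometric (most anterior quarter of
  channels) because no channel list exists for the emulated system; with
  160 channels exactly 120 remain.

## Evoked peaks

The body-sensitive peak is the *most negative signed value* across
retained channels in 140–240 ms (not the largest magnitude) — the
component of interest is a negativity, and taking magnitudes would let
the opposite field pole capture the peak. Ties break to the earliest
time, then the lowest channel index. One peak channel is fixed per
subject (from the pooled body-category average) and all categories are
read from it; a `per_category` flag switches to independent channels,
since either reading of the original procedure is defensible. Peak
latency and amplitude are compared across categories by classical
one-way ANOVA; on generators with identical category amplitude and
latency the p-values are uniform (checked as a property test), matching
the null result expected when categories share one evoked component.

The `field_map` dipolarity index is defined in this package as
`2·min(max, -min)/(max - min)`, clamped to [0, 1]: 1 for a balanced
ingoing/outgoing two-pole map, 0 for a single-signed map, invariant
under sign flips.

## Source estimation

The hierarchical Bayesian estimator used with the original data is out
of scope; what the analysis actually requires is a *linear inverse
filter applied per trial*, which an L2 minimum-norm inverse reproduces
structurally: `W = Gᵀ(GGᵀ + λ_eff C̃)⁻¹`, with `C̃` the baseline noise
covariance shrunk 10% toward its diagonal and normalized to unit mean
diagonal. `λ_eff` scales the dimensionless `λ` (default 0.1) by
`mean(diag(GGᵀ))` and divides by the data SNR estimated from the
response window (140–240 ms) against baseline power — stronger responses
are regularized less. The limits are exact and tested: `λ → 0` gives
pseudo-inverse recovery on an orthogonal toy gain, `λ → ∞` shrinks all
estimates to zero.

Currents are averaged in consecutive non-overlapping 20-ms windows
(half-open `[start, start+20)`, labelled by centre). F-maps compare the
window at 180–200 ms by default. ANOVAs run on *signed* current values
(`use_abs` switches to magnitudes): the fixed-orientation inverse
preserves polarity, and signed values retain more information; the
original description does not say which was used.

## Decoding

Features are per-channel means in 20-ms windows slid by 10 ms over
-100..500 ms — 59 windows. The classifier is three one-vs-rest linear
soft-margin SVMs reduced to explicit weight vectors and biases, with
argmax prediction: this matches the described decision rule ("weighted
sum plus bias for each class, maximum wins") literally, rather than
one-vs-one voting. The binary margin problems are solved by libsvm
(`e1071`); `C = 1`. Features are z-scored per window using training-fold
statistics only. Folds are stratified by class with a fixed seed; trials
of the same image can appear in both training and test folds, which is
inherent to the design being emulated and noted as a caveat for
interpreting absolute accuracies. Random-class partitions (4 images per
class, never category-pure) are redrawn `n_random` times (default 20)
and their accuracies averaged; object trials are excluded throughout.
Significance: two-sided binomial tests of pooled correct counts against
1/3 per scheme, and a paired two-sided t-test of categorical vs random
accuracy across subjects, per window, with 95% t-based confidence
intervals.

## Numerical and degenerate-input conventions

* All randomness flows through explicit seeds; sub-seeds are drawn from
  a master seed, and every container records enough metadata to
  reproduce itself (`run_pipeline` reports are byte-identical under the
  same seed and config).
* A flat evoked yields amplitude 0 with a warning; an all-rejected epoch
  set warns; a zero baseline yields a zero covariance with a warning;
  zero between-group variance yields F = 0, p = 1 rather than NaN.
* The amplitude calibration divides by the peak noiseless field and
  falls back to scale 1 when the template amplitude is zero.

## Problem sizes used in the shipped checks

The package's own validation runs at reduced scale, chosen once as
representative: the null-calibration check uses 8-channel/16-vertex
subjects with 120 body trials over 50 seeds; the scheme-separation check
uses 20 cohorts of 9 subjects at 16 channels/48 vertices, 10 repetitions
(120 body trials, enough for the paired t-test to retain its power at
the p < 0.01 level), 25 windows (20-ms step over -100..400 ms), 5 folds
and 2 random partitions; F-map recovery uses 20 nine-subject cohorts at
32 channels/64 vertices with subject-averaged maps. These sizes keep the
suite desk-scale while leaving every statistical property intact; the
full-scale design (160/4004/560/9) runs through exactly the same code
via `default_config("full")`.

## Known limitations

* The spherical-head forward model and shell source space cannot
  reproduce subject-specific anatomy; F-map localization is assessed
  against the simulated vertex sets, not against anatomical regions.
* The minimum-norm inverse is not the hierarchical Bayesian estimator
  whose sparsity priors shaped the original current maps; blur is wider,
  which the localization test acknowledges by scoring top-decile overlap
  (Jaccard) rather than exact recovery.
* Decoding accuracies on synthetic data are calibration-dependent and
  are not comparable in absolute terms with accuracies on real
  recordings; only their structure (chance under the null, categorical >
  random, onset after ~100 ms) is meaningful.
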