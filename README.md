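# megdecode

Time-resolved decoding of body-part categories from simulated MEG evoked
fields.

## The problem

Viewing images of body parts (feet, hands, mouths) evokes a
body-sensitive MEG response over occipitotemporal cortex roughly 190 ms
after stimulus onset. The scientific question this package addresses is
whether that response carries *category* information — can foot vs hand
vs mouth be told apart trial by trial — or only a generic body signal.
The analysis logic: record epochs around picture onset, clean them,
extract the evoked peak, localize category variance on the cortex with
per-vertex ANOVAs on estimated currents, and decode the category from
sliding-window sensor features, comparing a *categorical* labelling
against a *random-class* null labelling that carries image identity but
no category structure.

No recordings are available, so the package is built around its own
forward-modelled generator: `megdecode` simulates multi-subject epoch
sets (560 trials: 14 images x 40 presentations; 4 foot, 4 hand, 4 mouth,
2 object images; 1 kHz, -500..500 ms) in which each body category
activates a partially shared, partially category-unique set of cortical
dipoles inside a spherical-conductor head model, plus 1/f background
dipole noise and sensor noise. Every analysis stage is then exercised,
and validated, against that known ground truth.

## The model in brief

* **Forward model** — Sarvas closed form for a current dipole in a
  homogeneous conducting sphere; radial magnetometer pickup. A gain
  matrix `G` (channels x vertices, T per A·m) maps dipole moments to
  sensor fields; purely radial dipoles are silent.
* **Preprocessing** — zero-phase 60 Hz notch (biquad, Q = 30), zero-phase
  1–30 Hz Butterworth band-pass, baseline correction over -500..-100 ms,
  removal of the frontal channel quarter (160 → 120 channels),
  peak-to-peak artifact rejection.
* **Evoked analysis** — per-category trial averages; the "maximum
  negative component" peak (channel, latency, amplitude) in 140–240 ms;
  one-way ANOVA of peak latency/amplitude across categories.
* **Source analysis** — minimum-norm inverse
  `W = Gᵀ(GGᵀ + λC)⁻¹` with shrunk baseline noise covariance `C`;
  per-trial currents averaged in 20-ms windows; per-vertex one-way ANOVA
  F-maps (foot/hand/mouth and all pairs), averaged across subjects.
* **Decoding** — per-channel mean amplitudes in 20-ms windows slid by
  10 ms over -100..500 ms (59 windows); one-vs-rest linear SVMs
  (argmax of `w_k·x + b_k`); stratified 10-fold cross-validation;
  categorical vs random 3-class schemes; binomial tests against chance
  (1/3), paired t-tests categorical vs random across subjects.

## Worked example

```r
library(megdecode)

report <- run_pipeline(default_config("smoke"), seed = 7)
report
#> Pipeline report (seed 7, config 23522f97)
#> F-map [foot/hand/mouth] at 190 ms: 16 vertices, max F = 4.232
```

The smoke preset simulates one subject with a tiny 8-channel,
16-vertex geometry and only 28 trials; the F-map line reports that at
the 180–200 ms current window the largest category ANOVA F across the
16 vertices is 4.2 — the category-specific vertices stand out even in a
single tiny subject. A 9-subject cohort at a more interesting scale:

```r
cfg <- default_config("smoke")
cfg$geometry <- list(n_channels = 16, n_vertices = 48, head_radius = 0.09)
cfg$stimuli  <- list(repetitions = 5)
cfg$template$n_active <- 6
cfg$n_subjects <- 9
report <- run_pipeline(cfg, seed = 11)
report$significance
#> Decoding significance over 9 subjects, 59 windows
#>   peak categorical accuracy 55.8% at 190 ms (binomial p = 4.5e-26)
#>   random-scheme accuracy there 35.4% (paired p = 0.00015)
```

Categorical decoding rises above chance (33.3%) once the evoked
response begins, peaks inside the body-sensitive window (here 55.8% at
190 ms), and clearly exceeds the random-class accuracy (35.4%), whose
small rise above chance reflects per-image amplitude identity rather
than category structure — the simulated analogue of the finding that
the body-sensitive response carries category information. The
peak-latency/amplitude ANOVA across categories stays null
(`report$peak_anova`: latency p = 0.22, amplitude p = 0.069), matching
the expectation that all body categories share one evoked component.

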