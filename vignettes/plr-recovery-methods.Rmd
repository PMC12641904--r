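---
title: "Methods: dark-adaptation recovery of the pupillary light reflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dark-adaptation recovery of the pupillary light reflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

The pupillary light reflex (PLR) constricts the pupil when retinal
illumination rises. After light adaptation, the response an eye can mount
to a renewed bright stimulus depends on how long it has just spent in
darkness: photopigment regenerates during the dark interval, so longer
darkness yields a larger constriction when the light returns. Retinal
disease that impairs the pigment-epithelium recycling machinery — age-related
macular degeneration (AMD) above all — slows this recovery.

`pupilrecover` implements that measurement end to end. The stimulation
schedule alternates a 3 s bright screen with darkness whose duration grows
by 100 ms per cycle across 50 cycles (100 ms up to 5 s), followed by three
long probe cycles (7, 10, 15 s of darkness) and ten repeats of the first
cycle. `build_protocol()` constructs this schedule exactly; a closing 3 s
bright epoch is appended so the last dark interval also has a measurable
light re-onset. Epochs are half-open integer-millisecond intervals
`[onset, onset + duration)`, which removes every boundary ambiguity at
transitions; the screen luminances (150 nits bright, < 1 nit dark) are
carried as metadata only, since the analysis uses a two-level light/dark
description.

The per-cycle statistic is the **constriction amplitude**: the maximum
pupil diameter 0–100 ms after light re-onset (the eye has not yet reacted)
minus the minimum diameter 100–200 ms after re-onset (the trough of the
early constriction). Both windows are half-open, so the 100 ms sample is
counted exactly once. Plotting amplitude against the preceding dark
duration over the 50 ramp cycles gives the **recovery curve**, whose rise
rate is the quantity of clinical interest.

## The synthetic cohort

No raw recordings ship with the package, so every downstream stage is
exercised on simulated data. The generator is a forward model with one
interpretable knob per physiological ingredient:

* **Recovery law.** `amplitude_law()` is a saturating exponential,
  `A(d) = A_inf (1 - e^{-d/tau})`: the simplest law that is monotone,
  zero at zero dark duration, and saturating, and the natural reduced form
  of first-order photopigment regeneration kinetics. `tau` is the single
  parameter separating the groups: the default control time constant is
  1.2 s and the AMD value 2.4 s, i.e. AMD recovers at half the rate. The
  asymptote declines linearly with age (default 0.008 mm/year in controls,
  0.003 mm/year in AMD), so age lowers amplitudes in both groups and the
  decline is attenuated in AMD — an age-by-group interaction with a
  positive sign under treatment coding.
* **Trace model.** `simulate_recording()` samples at 200 Hz. In darkness
  the diameter relaxes toward `baseline + dark_gain` (defaults 4 mm + 2 mm)
  with an 0.8 s time constant; at re-onset the trace follows
  `baseline + (D_pre - baseline) e^{-t/tau_dil} - A(d) g(t)` with the
  unimodal kernel `g(t) = (t/peak) e^{1 - t/peak}`. The kernel peaks at
  150 ms — inside the 100–200 ms trough window and exactly on the 5 ms
  sample grid, so on noise-free traces without dark dilation the extracted
  amplitude equals `A(d)` to machine precision; the tests exploit this.
* **Nuisance processes.** Additive white measurement noise (0.03 mm SD), a
  slow hippus sinusoid (0.1 mm at 0.2 Hz, random phase), and blink gaps at
  a 0.2 Hz Poisson rate lasting 100–300 ms. Blinks are flagged invalid with
  the diameter set to a sentinel rather than dropped, keeping the sample
  grid uniform the way eye-tracker validity flags do.
* **Between-subject variability.** The scale parameters (`tau`, asymptote,
  baseline, dark gain) are jittered per subject by a lognormal with log-SD
  0.1. Ages are drawn from a common N(75, 7²) for both groups — the cohorts
  are age-matched by construction. Defaults are 14 AMD + 14 control
  subjects, one recorded eye each.

These values are fixed choices representing a plausible elderly cohort on
a consumer 200 Hz video pupillometer; only their orderings and signs (AMD
slower, amplitude rising and saturating, age lowering amplitudes) carry
scientific content, since the real instrument reports arbitrary units.

What the generator does **not** emulate: consensual responses of the
fellow eye, gaze-dependent foreshortening, pupil-size-dependent noise,
non-stationary hippus, or any structural difference between early and
advanced disease. Passing tests therefore demonstrate that the pipeline
recovers what this model family encodes — not that the model family
exhausts real pupillometry data.

`simulate_cohort_amplitudes()` is a second entry point that draws
cycle-wise amplitudes directly from the recovery law plus Gaussian noise
(0.05 mm SD), skipping trace synthesis. Replication studies (type-I error,
power, classifier nulls) use it: the trace-to-amplitude layer is validated
separately and exactly, so re-simulating 70,500 samples per subject inside
a 200-replicate loop would only add time, not information.

## Preprocessing

The cleaning rules are package decisions, pinned in `cleaning_config()`
and logged per run: velocity-based artifact rejection at 50 mm/s (both
endpoints of an impossible first difference are rejected, and affected
runs widened by one sample), linear interpolation of gaps up to 300 ms
(never at the recording edges), and a 25 ms centered moving average.
Cycles whose ROI windows remain less than 80% valid are marked missing
rather than imputed — the primary statistic is never fabricated. The full
pipeline marks its output, so cleaning twice is the identity.

## The mixed models

Two linear mixed-effects specifications are fitted by maximum likelihood
with `lme4`:

```
amplitude ~ 1 + Time + Group + (1 | Group)
amplitude ~ 1 + Age + Time + Group + Age:Group + (1 | Group)
```

`Time` is the preceding dark duration in milliseconds, `Group` a treatment
contrast with Control as reference, `Age` centered at the cohort mean. ML
rather than REML is used because information criteria are compared across
models with different fixed effects, which is only coherent under ML. The
two-level `(1 | Group)` random intercept is kept as specified although it
is confounded with the fixed group effect; its variance is routinely
estimated at the boundary (zero) and reported as such, with a per-subject
random intercept available as a sensitivity refit (`random = "subject"`).
Marginal (Type-III) F-tests use residual degrees of freedom
`n - rank(X)`; every term is single-df, so each F equals the squared
coefficient t-statistic, and coefficient p-values use the same df for
consistency.

Calibration is checked by simulation. Null data for the type-I-error check
are drawn from the model's own linear form (iid Gaussian residuals around
`X beta` with a zero group coefficient): that is the error structure under
which the fitted model's nominal level is defined. Power and
sign-recovery use the full generator defaults, between-subject jitter
included. The test suite runs 200 replicates of each; estimates on a
1,400-row default cohort take well under a second per fit.

## The classifier

Subjects are classified AMD vs control from their 50-point recovery curve
(optionally plus age) with a small 1-D convolutional network, written
directly on R matrices inside the package: two valid-convolution blocks
(16 and 32 filters, kernel 5, ReLU) each followed by width-2 max-pooling,
a 32-unit dense ReLU layer with dropout 0.3, and a 2-unit softmax head;
Adam (learning rate 1e-3, batch 4) minimises categorical cross-entropy
with one-hot labels, and early stopping (patience 10, at most 200 epochs)
monitors the loss on a stratified 25% split carved from the training fold.
The backward pass is verified against finite differences in the tests.
All hyperparameters sit in `cv_config()`.

Evaluation is stratified five-fold cross-validation. Folds are dealt
per class cyclically with a rotated start, giving sizes 6,6,6,5,5 for
14 + 14 subjects and class balance within one everywhere.
Standardization uses training-fold statistics only; held-out subjects
never influence scaling or early stopping. Sensitivity takes AMD as the
positive class. Both the mean of per-fold accuracies and the pooled
confusion-matrix accuracy are reported and labeled, since they differ for
unequal folds. Everything is reproducible from one seed; numerics are
plain R, so there is no backend nondeterminism.

## Numerical choices and degenerate inputs

* All protocol arithmetic is integer milliseconds; sample times are exact
  multiples of 5 ms, so window membership is never subject to float fuzz.
* Max-pooling ties take the earlier position; an odd-length pooled axis
  drops its final element.
* Zero-variance features standardize to zero (scale forced to 1).
* Negative extracted amplitudes are kept: clipping would bias group means
  upward asymmetrically.
* A one-group cohort errors at the model stage ("design error"); a subject
  with more than 40% missing cycles is excluded from classification with a
  warning; missing cycles below that are linearly interpolated across dark
  duration.
* Per-stage seeds in `run_pipeline()` are derived from the global seed and
  the stage name, so stages can be reproduced in isolation.

## Scope and limitations

The package is an analysis library: its interface is the R functions,
`run_pipeline()` for orchestration, and the acceptance script; there is no
shell subcommand layer. The long-dark tail cycles and the repeat block are
extracted and reported but excluded from the default model input, which
follows the 50-points-per-eye analysis design; amplitudes are modeled in
native millimetres (a baseline normalization is available but off by
default). Real recordings, if supplied as long-format CSV, flow through
the identical path after `read_recording()`, but the statistical
guarantees demonstrated here are guarantees about the generator's model
family, at the simulated sample sizes (28 subjects, 50 cycles, 200
replicates for calibration loops), not about any clinical population.
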