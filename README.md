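# pupilrecover

Analysis of **pupillary light reflex (PLR) recovery after light
adaptation** — the functional signature of dark adaptation that is slowed
in age-related macular degeneration (AMD). The package is for
ophthalmic-research and pupillometry groups who want the full measurement
chain as tested, reproducible code: stimulus schedule, pupil-trace
simulation, blink/artifact cleaning, amplitude extraction, mixed-effects
inference, and a cross-validated curve classifier.

## The method

A tested eye alternates between a bright screen (3 s, 150 nits) and
darkness whose duration grows by 100 ms per cycle over 50 cycles, then
three long probes (7/10/15 s dark) and ten repeats of the first cycle.
For each cycle the **constriction amplitude** is

```
amplitude = max D(t), t in [0, 100) ms  -  min D(t), t in [100, 200) ms
```

with `t` measured from light re-onset and `D` the pupil diameter. Amplitude
versus preceding dark duration `d` is the **recovery curve**; it rises and
saturates, and the package's generative model for it is the first-order
photopigment-regeneration form

```
A(d) = A_inf(age, group) * (1 - exp(-d / tau_group)),
```

where `tau` is the recovery time constant (doubled in the simulated AMD
group) and `A_inf` declines linearly with age. Group differences are
tested with linear mixed models fitted by maximum likelihood,

```
amplitude ~ 1 + Time + Group + (1|Group)
amplitude ~ 1 + Age + Time + Group + Age:Group + (1|Group)
```

with marginal (Type-III) F-tests on residual degrees of freedom, and
subjects are classified AMD vs control from their 50-point curves by a
small 1-D CNN (conv-ReLU-maxpool ×2, dense, dropout, softmax; Adam,
categorical cross-entropy, early stopping) under stratified five-fold
cross-validation.

## Worked example

```r
library(pupilrecover)

sim <- simulate_cohort_amplitudes(cohort_config(seed = 2026))  # 14 AMD + 14 controls
fit <- fit_lmm(sim$table)
fit
#> <plr_lmm_fit> base variant, ML, amplitude ~ 1 + Time + Group + (1 | Group)
#>   note: random-intercept variance at the boundary (zero)
#>                estimate        se      t         p
#> (Intercept)  0.38326000 8.373e-03  45.77 3.33e-280
#> Time         0.00015542 2.564e-06  60.62  0.00e+00
#> GroupAMD    -0.17229000 7.399e-03 -23.28 1.35e-101
#>   n = 1400 (0 dropped), AIC -1553.7, BIC -1527.5, sigma 0.13843, RE sd 0.00000

cross_validate(build_features(sim$table), cv_config(seed = 2026))
#> <plr_cv_result> 5 folds (amplitudes only)
#>  fold n  accuracy sensitivity specificity
#>     1 5 1.0000000   1.0000000           1
#>     2 6 1.0000000   1.0000000           1
#>     3 6 1.0000000   1.0000000           1
#>     4 6 0.8333333   0.6666667           1
#>     5 5 1.0000000   1.0000000           1
#>   mean accuracy 96.7% (sd 7.5%), sensitivity 0.933, specificity 1.000
#>   pooled accuracy 96.4% over 28 held-out subjects
```

Reading the fit: the positive `Time` coefficient (amplitude per ms of
preceding darkness) is the recovery itself; the negative `GroupAMD`
coefficient says the simulated AMD group constricts ~0.17 mm less at any
given dark duration, the direct consequence of its slower recovery
constant. The two-level group random intercept is confounded with the
fixed group effect and lands on the boundary, which the fit reports.
The CV result shows per-fold and aggregate diagnostic metrics with AMD as
the positive class.

Full-trace simulation and the end-to-end pipeline:

```r
res <- run_pipeline(run_config(out_dir = "run1", seed = 1))
plot_recovery(res$table, "run1/recovery.png")
```

`run_pipeline()` writes protocol JSON, recordings/subjects/amplitudes CSV,
fit and CV JSON, and a manifest with MD5 checksums; identical
configurations reproduce identical artifacts.

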