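# olarena

Analysis toolkit for **object-location (OL) spatial memory tasks in a
circular virtual arena**, written for researchers studying spatial
navigation and memory in aging and amnestic mild cognitive impairment
(aMCI).

In these tasks a participant encodes four object locations in a 50
virtual-meter (vm) arena that contains both an arena wall (allocentric,
boundary-based cue) and a discrete landmark, an obelisk at
(−10.5, 10.5) (egocentric cue), and later recalls each location over 16
cued trials — 8 with only the wall visible, 8 with only the obelisk.
The package covers the whole analysis chain, plus a synthetic-cohort
simulator so every stage can be exercised without participant data:

* **Geometry** — arena configuration, radial (inner circle, 25% of the
  area, vs outer annulus) and quadrant-pair partitions, radial clipping
  (`arena_config()`, `radial_region()`, `quadrant_region()`,
  `clip_to_arena()`).
* **Recall scoring** — per-trial Euclidean error; landmark and centre
  *attractor indices* (d_target − d_response)/d_target, measuring
  response displacement toward a reference point; object-location
  *binding errors* (nearest-neighbour swaps); reference-frame *switch
  labels* (`score_cohort()`, `binding_errors()`, `switch_labels()`).
* **Path metrics** — step/total distances, mean distance to landmark
  and centre, Welch t contrasts (`path_summary()`, `welch_t()`).
* **Point-pattern density** — area-normalised densities, inner/outer
  and quadrant density ratios, exact two-sided binomial tests against
  the area-based null, group comparisons (`radial_density_report()`,
  `quadrant_density_report()`, `compare_group_densities()`).
* **Inference** — linear mixed-effects ANOVAs with Satterthwaite
  type-III F tests and Cohen's f = √(F·df₁/df₂); trial-course
  polynomial models; Poisson binding models; logistic diagnosis models
  with odds ratios; ROC with the Youden-index cutoff
  (`fit_error_mixed_anova()`, `fit_binding_poisson()`,
  `fit_logistic_diagnosis()`, `roc_youden()`).
* **Simulation** — biased-random-walk encoding and attractor-shrinkage
  recall with parameterised HC-like and aMCI-like phenotypes
  (`behavior_profile()`, `simulate_cohort()`).
* **Pipeline** — CSV session formats with validation, and an
  end-to-end runner that writes scores, density reports, model tables
  and a summary (`read_sessions()`, `run_pipeline()`); a thin CLI lives
  in `inst/cli/olarena.R`.

See the methods vignette (`vignettes/arena-methods.Rmd`) for the models,
conventions and simulator calibration.

## Worked example

```r
library(olarena)

coh <- simulate_cohort(cohort_spec(n_per_group = 20, seed = 42))
scores <- score_cohort(coh)
fit_error_mixed_anova(scores)
#> Model: mixed ANOVA: error
#> F tests (Satterthwaite df):
#>       term df_num df_den F_value      p      f
#>      group      1     38   4.382 0.0430 0.3396
#>        cue      1    598   0.345 0.5572 0.0240
#>  group:cue      1    598   4.593 0.0325 0.0876
```

The simulated aMCI group recalls less accurately than HC: the group
F test at 1 and 38 denominator df is significant (p = .043) with an
effect size f ≈ 0.34; the cue main effect is null in this replicate,
with a group × cue interaction reflecting the aMCI profile's stronger
egocentric-condition bias.

```r
radial_density_from_counts(57, 263)
#> Density report (radial partition), n = 320
#>  label count     area density proportion
#>  inner    57  490.874   0.116      0.178
#>  outer   263 1472.622   0.179      0.822
#> Density ratio (inner/outer): 0.65
#> Exact binomial p (p0 = 0.25): 0.00239
```

From region counts alone (here 57 of 320 recall points in the inner
circle), the report gives per-area densities, the inner-to-outer
density ratio (0.65 — a preference for the outer ring beyond its area
share), and the exact binomial p against the 25% area null.

```r
cm <- participant_cue_means(scores)
roc_youden(cm$error_ego, cm$group, positive = "aMCI")
#> ROC analysis: AUC = 0.81
#> Youden-optimal cutoff: 24.914
#>   sensitivity 0.75  specificity 0.85  accuracy 0.8
```

Mean egocentric-condition error classifies the simulated groups with
AUC 0.81; calling "aMCI" above 24.9 vm gives sensitivity 0.75 and
specificity 0.85.

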