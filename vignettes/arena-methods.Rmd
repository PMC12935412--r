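---
title: "Methods: object-location memory analysis in a circular virtual arena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object-location memory analysis in a circular virtual arena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its geometry

`olarena` analyses landmark- and boundary-based object-location (OL)
memory tasks run in a circular virtual arena of radius 25 virtual
meters (vm). During *encoding*, a participant starting at the centre
collects four objects — cat (−5, −14), chair (−4, 20), bike (18, 10),
carrot (5, 17) — four times each, while both the arena wall (the
allocentric, world-centred cue) and a discrete intra-arena landmark, an
obelisk at (−10.5, 10.5), are visible. During *recall*, the participant
navigates to each remembered location under 16 cued trials, 8 per cue
condition: in the *allocentric* condition only the wall is visible; in
the *egocentric* condition only the obelisk. Positions are sampled at
1 Hz. An invisible wall constrains all movement to the arena.

Two region partitions drive the spatial analyses:

* **radial**: an inner circle of radius 12.5 vm (exactly 25% of the
  arena area; the boundary belongs to the inner region) versus the
  outer annulus (75%);
* **quadrant pair**: the upper-left quadrant (x < 0, y > 0, containing
  the obelisk) versus the diametrically opposite lower-right quadrant.
  Points exactly on an axis form a probability-zero set; they are
  labelled `other` and excluded from quadrant counts rather than being
  double-counted, and their number is reported (`n_excluded`).

Out-of-arena points can only arise from malformed input; they are never
dropped silently — density reports count them in `n_excluded`, and the
session reader flags them per participant (aborting in strict mode).

## Per-trial recall measures

For a cued object with encoded location $t$ and response $r$:

* **error** $= \lVert r - t \rVert$ (vm);
* **landmark attractor index**
  $= (d_\mathrm{target} - d_\mathrm{responseLM}) / d_\mathrm{target}$,
  where $d_\mathrm{target} = \lVert t - L \rVert$ and
  $d_\mathrm{responseLM} = \lVert r - L \rVert$ for landmark $L$.
  It is 1 when the response sits on the landmark, 0 when the response
  is as far from the landmark as the target, and negative beyond that.
  The centre attractor index is the analogue with the arena centre as
  reference. Note the sign convention follows the formula as written:
  *positive* values always mean the response lies nearer the reference
  point (landmark or centre) than the target does. Both indices are
  undefined (an error) when the target coincides with the reference;
* **binding error**: the response is nearer to some *other* object's
  encoded location than to the cued one (nearest-neighbour assignment
  with a strict minimum; exact ties are flagged `binding_ambiguous` and
  conservatively counted as binding errors). No distance threshold is
  imposed — a far response still has a nearest object — matching the
  swap-error notion used for object-location binding. A per-participant
  × cue count of these flags feeds the Poisson model;
* **switch label**: trial $i \ge 2$ is labelled by the cue transition
  from trial $i-1$ (`no_switch`, `ego_to_allo`, `allo_to_ego`); the
  first trial has no transition and is excluded from switching models.
  Presentation order must be recorded (`trial_index`); data without it
  are rejected for this analysis only.

## Path metrics and density analyses

Path metrics are defined per 1 Hz sample: step distances between
consecutive samples, their sum (total distance) and mean (mean step
distance), and the mean distance of all samples — including the first —
from the landmark and from the arena centre. Irregular timestamps are
accepted with a warning; metrics remain per-sample. Group contrasts on
these per-participant summaries use Welch's t test. Sessions whose path
file was not saved are skipped with the number used reported.

Density analyses count points per region, divide by region area
(points / vm²), and form density ratios (inner/outer, or
upper-left/lower-right; the quadrants have equal area, so there the
density ratio equals the count ratio). Observed counts are tested
against the null area proportions (0.25 inner; 0.5 between the two
quadrants) with an exact two-sided binomial test using the
minimum-likelihood ("small-p sum") convention of `stats::binom.test`,
which reproduces the conventional published values for these designs.
Group comparisons report both the difference of density ratios and
their ratio. Encoding-path analyses pool all path samples across
participants within a group; this treats autocorrelated samples as
independent in the binomial test, which is the field's convention for
these group-level percentages — the p-values should be read
descriptively. A per-participant variant is available through
`radial_density_report()` on single-session points for sensitivity
checks.

## The inferential layer

* **Error model**: `error ~ group * cue + (1 | participant)`, REML,
  type-III F tests with Satterthwaite denominator degrees of freedom
  (chosen because it reproduces denominator df of the expected
  magnitude, n − 2, for a between-participant factor). Cohen's
  $f = \sqrt{F \cdot df_1 / df_2}$ accompanies each F test. Optional
  covariates (including raw product interactions such as `age:gender`)
  can be added; no centring is applied, and no multiplicity correction
  is performed — all p-values are raw.
* **Trial-course model**: adds orthogonal polynomial terms in the trial
  index (degree 2 by default — a curvature check without overfitting 16
  trials; configurable) and their interactions with group and cue.
* **Attractor models**: each index separately, group as fixed effect,
  random intercepts for participants and objects.
* **Binding model**: Poisson log-linear model of per-participant × cue
  binding counts with group, cue and their interaction.
* **Diagnosis model**: logistic regression of group membership (aMCI as
  the positive class) on per-participant mean errors within cue (or
  within switch condition), reporting coefficients, odds ratios and
  Wald 95% CIs; predictors enter per-unit (no standardisation).
  Perfect separation is detected; a ridge-penalised fit (`glmnet`,
  $\alpha = 0$, small $\lambda$) is returned and flagged, without Wald
  inference.
* **ROC / Youden**: AUC by pairwise rank concordance with half credit
  for ties; the operating cutoff maximises $J = \text{sens} +
  \text{spec} - 1$, calling positive when score ≥ cutoff; among tied
  cutoffs the smallest is reported with a tie flag.

Group factors are coded with HC as the reference level whenever both
`HC` and `aMCI` labels occur, so "group effect" coefficients are the
aMCI contrast regardless of locale collation.

## The synthetic cohort simulator

No raw data accompany tasks of this kind, so the package ships a
generative stand-in that makes every pipeline stage testable end to
end. It is a *phenomenological* drift-plus-noise model, not a cognitive
one: its dials reproduce group-level behavioural signatures, and no
claim is made that its parameters map onto mechanisms.

**Encoding** is a biased random walk at 1 Hz: the heading is the unit
vector toward the current target, plus `thigmotaxis_weight` times the
outward radial unit vector, plus `landmark_approach_weight` (signed;
negative = avoidance) times the unit vector toward the landmark, with
Gaussian heading noise; steps have fixed length `step_speed` and are
clipped to the arena. A target within `capture_radius` (1 vm — exact
contact is a measure-zero event for a noisy walk) counts as collected.
If the summed drift nearly cancels (norm < 0.3, possible only under a
strong outward bias opposing an inward target), the step falls back to
the pure target direction so the walk cannot stall at the wall.

**Recall** responses are the target shrunk toward the cue's attractor
(arena centre under the allocentric cue, landmark under the egocentric
cue) by the profile's attraction fraction, plus isotropic Gaussian
noise, clipped to the arena. Each participant's noise SD is the profile
value times a lognormal multiplier (`between_subject_cv`), giving
stable individual differences. Response time is simulated as the
straight-walk time plus lognormal jitter and is carried as a nuisance
covariate only. Every per-participant seed derives deterministically
from the master seed and is recorded, so cohorts are byte-reproducible.

### Default profiles and how they were chosen

The shipped `HC` and `aMCI` profiles encode the study conditions the
package targets, chosen once and then frozen:

| parameter | HC | aMCI | rationale |
|---|---|---|---|
| step_speed (vm/s) | 2 | 2 | typical virtual navigation speed; groups do not differ in encoding path length |
| heading_noise_sd (rad) | 0.35 | 0.45 | mildly noisier navigation in aMCI |
| thigmotaxis_weight | 0.42 | 0.46 | reproduces mean distance-to-centre ≈ 14.5 vs 15.5 vm and pooled inner-region encoding proportions ≈ 36% vs 29% |
| landmark_approach_weight | 0.03 | −0.10 | HC orient slightly toward the obelisk, aMCI away (centrifugal pattern); gives mean distance-to-landmark ≈ 18.7 vs 19.8 vm |
| recall_noise_sd (vm) | 31 | 31 | with clipping, yields group mean errors ≈ 21.3 / 23.9 vm and trial-level SD ≈ 11.7 |
| center_attraction | 0.05 | 0.48 | aMCI allocentric responses drawn toward the centre |
| landmark_attraction | 0.05 | 0.68 | aMCI egocentric responses drawn toward the obelisk; the larger egocentric pull makes egocentric error the discriminating predictor |
| between_subject_cv | 0.30 | 0.30 | participant-level mean-error SD ≈ 3.5 vm, so the group effect size is near f ≈ 0.33 at n = 40 + 40 |

Noise is deliberately equal across groups: the error gap and the
attractor-index contrast are then driven by the attraction dials, so
the simulated aMCI deficit is a *systematic spatial bias*, not mere
imprecision — matching the qualitative picture the analyses are built
to detect.

### What the simulator does and does not emulate

It reproduces, at the study size of 40 + 40: the group gap in mean
recall error (≈ 21.3 vs 23.9 vm) with power ≈ 0.9 for the mixed-model
group test; the outer-ring encoding bias of the aMCI profile (detected
in essentially every replicate); the positive egocentric-error
coefficient in the diagnosis model; and encoding distance-to-landmark /
distance-to-centre contrasts of realistic magnitude. The aMCI−HC
attractor-index contrast is positive in expectation but small relative
to between-participant noise, so single cohorts show it inconsistently
(about three replicates in four); tests of this signature therefore
average across replicates.

It does **not** emulate: recall-phase navigation paths (only response
points); the strong centre-ward *magnitudes* of real recall densities
(the simulator's large response noise plus boundary clipping pushes
responses outward, so inner-region recall proportions are smaller than
in real cohorts, although the group *direction* is preserved);
learning or fatigue across trials (the trial-course model's null
calibration relies on this); object-specific memorability; and any
vestibular or embodied cue. Passing pipeline tests on simulated cohorts
therefore demonstrates the statistical machinery recovers planted
effects of realistic size — not that the simulator is a model of
patients.

## Numerical choices and degenerate inputs

* Boundary conventions: the inner circle is closed (`d ≤ 12.5` is
  inner); clipped points may land within 1e-9 of the wall and are
  classified as in-arena.
* Attractor indices error out when the target coincides with the
  reference point (undefined normalisation).
* `welch_t` requires two values per sample and errors on two
  zero-variance samples; the pipeline records such contrasts as `NA`
  rather than aborting (this arises for mean step distance when the
  simulator's fixed step speed leaves almost no variance).
* Binomial tests require 0 < p0 < 1 and integer counts.
* Mixed-model singular fits (zero random-effect variance, common under
  a null) are reported as warnings, not errors.
* Youden ties take the smallest cutoff, flagged; ROC calls positive at
  score ≥ cutoff.

## Problem sizes used in the shipped checks

The test suite exercises the recovery and calibration properties at
sizes chosen to make the checks sharp but routine to run: 100
replicates of full 40 + 40 cohorts for the signature-recovery study,
500 replicates of 15 + 15 recall-only cohorts (encoding walks are not
needed for the error model) for the null calibration of the group test,
10⁵-point uniform samples for the density-ratio null, and exhaustive
enumeration up to n = 12 for the binomial and AUC oracles.

## Known limitations

Binomial tests on pooled path samples inherit the independence caveat
above. The Satterthwaite approximation, not Kenward–Roger, is the only
denominator-df method offered. The logistic model's Wald CIs are
first-order; profile-likelihood CIs are not implemented. The simulator
draws trial order uniformly rather than from the task software's actual
randomisation, and models the response distribution as clipped
Gaussian, which cannot reproduce heavy-tailed guessing behaviour.
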