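---
title: "Calibrating ENMO cut points for children's sedentary and stationary behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating ENMO cut points for children's sedentary and stationary behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmocut)
```

## The problem

Hip- and wrist-worn accelerometers cannot observe posture directly, yet most
of what matters about children's sedentary behaviour is postural: sitting or
lying with low energy expenditure. A thigh-worn inclinometer (an
activPAL-style logger) can classify posture second by second and serves as
the criterion, but it is a second device that most field studies do not
deploy. The practical compromise is a *cut point*: a raw-acceleration
threshold below which a second of wrist or hip data is declared sedentary
(sit/lie) or stationary (sit/lie/stand). `enmocut` implements the whole
calibration-and-validation pipeline for such cut points in children aged
9-10, and ships a synthetic-data generator calibrated to the published
per-station summary statistics so that every stage runs, and is tested,
without any recordings.

## Signal reduction

Raw tri-axial samples (100 Hz, +/-8 g dynamic range) are reduced to the
Euclidean-norm-minus-one metric,

$$\mathrm{ENMO}_i = \max\!\left(\sqrt{x_i^2 + y_i^2 + z_i^2} - 1,\, 0\right),$$

in g, then averaged over 1 s epochs and expressed in mg (1 mg = $10^{-3}$ g,
1 g = 9.81 m/s^2^). Two numerical choices deserve stating because they change
results:

* **Clipping happens per sample, before epoch averaging.** Clipping the
  epoch mean instead would systematically lower quiet-epoch values.
* **Trailing partial epochs are dropped, never padded.** Padding would
  fabricate low-acceleration samples.

Epoch $t$ covers the half-open interval $[t, t+1)$ s, the same convention the
posture expansion uses, so synchronization is an exact inner join on the
integer second.

For calibration data each 300 s activity station is trimmed by 30 s at both
ends (transitional movements) and the central 240 s are analysed. For
stations of other lengths the rule generalizes by centring: trim, then take
the central `central_s` seconds of what remains (a 310 s station yields
seconds [35, 275)). Autocalibration of gain/offset is deliberately a no-op
hook: over the short protocol recordings it has nothing to estimate, and the
synthetic signals are exactly calibrated by construction.

## Posture events and coding schemes

Event logs (start, duration, code 0 sit/lie, 1 stand, 2 step) are expanded
to one code per whole second. When a transition falls inside a second, that
*duplicate second* receives the posture transitioned **into**; with three or
more postures in one second the last-entered wins (the transitive extension
of the two-posture rule). The expansion reports the duplicate count; its
correctness is tested against a 1 ms brute-force accumulator.

Two binary schemes are derived: *sedentary* (positive iff code 0) and
*stationary* (positive iff code 0 or 1). Stationary labels dominate
sedentary labels pointwise by construction.

## Threshold calibration

Seconds are pooled across participants per device x scheme (a
per-participant weighting option exists but is off by default, matching the
pooled design). The classification rule is **strictly less than**: a second
is positive iff its ENMO lies *below* the threshold. Candidate thresholds
are every unique observed ENMO value plus $+\infty$; sensitivity is then
non-decreasing and specificity non-increasing in the threshold, and the
operating point maximizing Youden's $J = \mathrm{sens} + \mathrm{spec} - 1$
is selected. Ties in $J$ break toward the **smallest** threshold -- the
conservative choice that claims the least sedentary time; the statistical
package used for the original tables does not document its tie rule, so the
published 32.6-60.7 mg thresholds are properties of that study's recordings,
not reproduction targets.

AUC is computed in rank form (identical to trapezoidal integration over this
ROC): $P(\mathrm{ENMO}_{pos} < \mathrm{ENMO}_{neg}) + \tfrac12 P(\text{tie})$,
with DeLong's distribution-free asymptotic variance for the 95% CI --
standard, and exactly cross-checked against `pROC` in the tests. Degenerate
single-class groups become failed rows and the cohort run continues.
Thresholds are reported to 0.1 mg.

## Free-living validation

Only whole clock hours between 07:00 and 21:00 with *zero* non-wear minutes
enter the analysis; a one-minute removal invalidates its whole hour, and a
removal spanning an hour boundary invalidates both hours. Estimate minutes
per participant-day are below-threshold seconds / 60; criterion minutes come
from the posture codes. The agreement battery is:

* paired two-sided t-test; **Cohen's d = mean difference / pooled SD of the
  two measurements**, $\sqrt{(s_e^2 + s_c^2)/2}$. The alternative
  (difference / SD of differences) is inconsistent with the published effect
  sizes (a 33 min bias with group SDs ~132 and ~143 min printed as d = 0.25),
  so the pooled-SD form is used.
* Bland-Altman bias with 95% limits of agreement (bias +/- 1.96 SD of
  differences) and a t-based CI of the bias.
* MPE/MAPE with the sign convention **(criterion - estimate)/criterion x
  100**, so overestimation gives a negative MPE -- fixed by the published
  tables, where overestimating monitors carry negative MPE. |MPE| <= MAPE
  always, with equality iff all errors share a sign.
* Pearson r.
* Equivalence in two-one-sided-tests presentation: the zone is criterion
  mean x (1 +/- 0.10) and the estimate is equivalent iff the 90% t-CI of its
  mean lies wholly inside the zone. The cited methodological source gives no
  formulas; this is the stated implementation.

No multiplicity correction is applied to the battery (the original analysis
corrected only its ANOVAs, which are out of scope here).

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed to the
published summary statistics, not tuned.

* **Per-second ENMO is gamma-distributed** with each station's per-placement
  (mean, SD) in mg. The published per-station SDs exceed their means, which
  rules out a normal model on the non-negative ENMO scale; the gamma has the
  right support and skew. Targets are the ActiGraph rows of the published
  station table (e.g. hip resting 8.9 (12.4) mg); GENEActiv devices add a
  +1.44 mg latent-mean offset, the one brand effect the source quantifies
  globally. Activity-specific brand x placement interactions (eta-squared
  <= 0.006) are not modelled.
* **Signal synthesis plants the truth.** Each second's 100 samples share one
  magnitude $1 + e_t/1000$ g along a per-bout random gravity direction, so
  the pipeline must recover the planted $e_t$ exactly (tested at 1e-9 g). A
  `sub_unit` option emits $1 - e_t/1000$ magnitudes to exercise negative
  clipping.
* **Protocol**: seven 300 s stations, TV viewing always first (as in the
  protocol, to keep the screen from distracting later stations), the rest in
  seeded random order, then >= 600 s of recess as alternating 5-60 s
  stand/step bouts. Recess has no published quantitative structure; the
  alternation is a minimal model of intermittent play. Station windows are
  trimmed/centred; recess is used in full.
* **Posture-log imperfections**: with probability 0.05 per transition the
  boundary shifts into the following second (the published logs contained 28
  duplicate seconds in ~28 h, roughly one per twenty transitions); with
  probability 0.02 a sit bout is logged as standing (the logger's documented
  sit-as-stand failure mode, ~30 min of ~28 h).
* **Free-living days** alternate sit/lie and non-sedentary bouts
  (semi-Markov, exponential lengths, sit mean 300 s; bout-length data are
  not published, so these are exposed parameters, not assertions). The sit
  time fraction is 0.666 = 466.3/700 published minutes; within non-sedentary
  time, standing takes 0.549 = (594.6 - 466.3)/(700 - 466.3) -- both derived
  once from the published free-living decomposition. Sit bouts reuse a
  random seated station's profile, standing reuses standing-with-phone,
  stepping reuses walking. Non-wear bouts (Poisson, mean 1/day, 45-120 min)
  zero the wrist signal and enter the wear log; the thigh logger keeps
  running.

What the generator does *not* emulate: within-bout autocorrelation,
between-participant random effects (exposed as an open question in the
design; default off in the sense that the pooled SD absorbs it), limb
kinematics, device miscalibration, sleep, and the possibility that
free-living standing is more active than standing-with-a-phone. The last
point matters for interpreting the tests: because the planted
standing-with-phone wrist distribution is ENMO-indistinguishable from the
seated ones, ~95% of simulated standing seconds fall below the sedentary cut
point, and simulated free-living sedentary estimates overshoot the criterion
by ~15-20% -- farther than the ~5% overshoot observed in the real validation,
where standing was evidently more dynamic. Consequently the end-to-end
simulation reproduces the *direction* of every published result (sedentary
overestimation with negative MPE, one-directional stationary underestimation
with MPE = MAPE, r near 1, and no group-level equivalence under the 10%
zone) but not the published magnitudes, and a test asserting group-level
sedentary equivalence under these conditions fails honestly: with the
planted overlap, equivalence is unattainable just as it was unattained in
the original study. The separate end-to-end test with well-separated planted
distributions shows the machinery itself achieves equivalence when the
classes are separable.

## Problem sizes and determinism

The shipped tests and the acceptance script run the calibration study at 27
participants x 5 monitors x ~45 min at 100 Hz, and validation at 20
free-living days x 2 wrist monitors x 14 h at 100 Hz -- the study's own
design sizes. Module tests use smaller sampling rates (2-25 Hz) where the
planted-value algebra is rate-invariant. All generators take explicit seeds;
participant- and day-level seeds are derived from the base seed with a
modular hash kept below 2^31.

## Worked example

```{r example, eval = FALSE}
pars <- cohort_params(n_participants = 27)
cal <- run_calibration_study(params = pars, seed = 42)
cal$thresholds          # 10 rows: 5 monitors x 2 schemes

val <- run_freeliving_validation(cal$thresholds, n_days = 20,
                                 params = pars, seed = 7)
val$reports             # the agreement battery per brand x scheme
plot_bland_altman(val$minutes$criterion_min[val$minutes$scheme == "sedentary" &
                                            val$minutes$brand == "AG"],
                  val$minutes$estimate_min[val$minutes$scheme == "sedentary" &
                                           val$minutes$brand == "AG"])
```

## Known limitations

* Proprietary binary device formats are out of scope; CSV is the
  interchange format, as in the original processing chain.
* The published thresholds depend on the original recordings and are not
  reproducible from summary statistics; this package reproduces the
  *procedure* and validates it against planted ground truth.
* The hip placement inverts the sedentary signal ordering (standing with a
  phone is the *stillest* hip activity), which caps the sedentary-scheme AUC
  well below the stationary-scheme AUC -- visible in both the published and
  the simulated tables.
* One record per participant-day is assumed in the agreement battery. The
  per-day outputs carry both minutes and percentages of wear time, so
  percent summaries can be formed either as means of per-day percentages or
  as ratios of mean minutes; the published table does not say which it used.
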