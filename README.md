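# enmocut

Raw-acceleration (ENMO) cut points for classifying children's **sedentary**
(sit/lie) and **stationary** (sit/lie/stand) behaviour from hip- and
wrist-worn accelerometers, calibrated against a thigh-worn posture logger
and validated on free-living days.

Field studies of 9- to 10-year-olds typically deploy one ActiGraph (AG) or
GENEActiv (GA) monitor and no posture logger. `enmocut` implements the
pipeline that turns a lab calibration protocol into deployable thresholds,
and quantifies how those thresholds behave in free living:

1. **Signal reduction** — 100 Hz tri-axial g to per-sample
   ENMO = max(√(x²+y²+z²) − 1, 0), clipped per sample, averaged into 1 s
   epochs in mg; 30 s trimming and central-4-min extraction per activity
   station.
2. **Criterion labels** — posture event logs expanded to second-by-second
   codes (duplicate seconds take the posture transitioned *into*), coded
   as sedentary (sit/lie vs stand/step) or stationary (sit/lie/stand vs
   step), inner-joined with the epoch series on the integer second.
3. **Calibration** — ROC curves under the rule *positive iff ENMO <
   threshold* over all observed thresholds; Youden-optimal cut point per
   monitor × scheme (smallest threshold on ties); AUC in Mann–Whitney rank
   form with DeLong 95% CI.
4. **Validation** — valid-hour filtering (whole 07:00–21:00 clock hours
   with zero non-wear), strict below-threshold classification, and the
   agreement battery: paired t / Cohen's d (pooled-SD), Bland–Altman bias
   and 95% limits of agreement, Pearson r, MPE/MAPE with the
   (criterion − estimate)/criterion sign convention, and 10%-zone
   equivalence testing with a 90% t-CI.
5. **Synthetic cohorts** — a generator calibrated to the published
   per-station means/SDs (gamma per-second ENMO, planted and exactly
   recoverable), the seven-station protocol with recess, and semi-Markov
   free-living days with a 0.666 sit fraction and hour-level non-wear — so
   the entire pipeline runs and is tested with no recordings.

## Worked example

```r
library(enmocut)

pars <- cohort_params(n_participants = 6)
cal  <- run_calibration_study(params = pars, seed = 42)
cal$thresholds
#>  brand         placement     scheme sensitivity specificity   auc threshold_mg
#>     AG               hip  sedentary        0.99        0.49 0.650         50.1
#>     AG    wrist_dominant  sedentary        0.92        0.40 0.707         64.6
#>     GA    wrist_dominant  sedentary        0.91        0.42 0.708         61.5
#>     AG wrist_nondominant  sedentary        0.91        0.49 0.694         48.9
#>     GA wrist_nondominant  sedentary        0.90        0.49 0.698         52.7
#>     AG               hip stationary        1.00        0.99 1.000         50.1
#>     AG    wrist_dominant stationary        0.90        0.84 0.946         51.6
#>     GA    wrist_dominant stationary        0.89        0.86 0.947         51.7
#>     AG wrist_nondominant stationary        0.92        0.92 0.978         49.1
#>     GA wrist_nondominant stationary        0.91        0.93 0.976         52.2

val <- run_freeliving_validation(cal$thresholds, n_days = 6,
                                 params = pars, seed = 7)
val$reports[, c("label", "criterion_mean", "estimate_mean", "mpe", "mape",
                "r", "equivalent")]
#>         label criterion_mean estimate_mean    mpe  mape    r equivalent
#>  AG sedentary         476.62        560.82 -16.90 16.90 0.99      FALSE
#> AG stationary         608.55        561.02   7.78  7.78 1.00      FALSE
#>  GA sedentary         476.62        563.11 -17.34 17.34 0.99      FALSE
#> GA stationary         608.55        562.17   7.62  7.62 1.00      FALSE
```

Reading the output: one Youden cut point per monitor × scheme. The hip's
sedentary AUC is lowest because standing with a phone is the *stillest* hip
activity, inverting the signal ordering, while adding stand to the positive
class (stationary scheme) makes the classes nearly separable (AUC ≈ 0.95–1).
In free living the sedentary cut points overestimate sitting (negative MPE:
still standing seconds fall below the threshold) and the stationary cut
points underestimate (positive MPE = MAPE, i.e. all error in one
direction — arm movement while standing pushes seconds above the
threshold); correlations with the criterion stay near 1 and neither
direction achieves 10%-zone group-level equivalence under these simulated
conditions. A command-line wrapper with `simulate` / `calibrate` /
`validate` / `report` subcommands is in `inst/cli/enmocut.R`, and the
methods vignette (`vignettes/enmo-cutpoints.Rmd`) documents the model and
every numerical choice.

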