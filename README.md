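# motib

Simulation and analysis of sustained inattentional blindness in multiple
object tracking (MOT) displays.

In a sustained inattentional blindness task, participants count how many
times the objects of one colour bounce off the edges of a display while an
unexpected object — a cross drifting across the screen at the vertical
midline for several seconds — goes unnoticed by roughly half of them. The
open question this package targets is *when* noticing happens: whether
detection accumulates stochastically while the object is visible, so that
longer exposure means more noticing, or is triggered by a discrete event
(onset, offset, or crossing fixation), so that the noticing rate is flat
across exposures while location reports cluster around the triggering
event.

`motib` is for researchers who want that inferential logic as tested,
runnable machinery rather than prose: it simulates the display, generates
synthetic cohorts under competing observer models, screens and analyses
them exactly the way such experiments are analysed, and asks whether the
generating model can be recovered.

## What's inside

* **Display engine** — seeded simulation of the 700 × 600 px MOT display:
  eight tracked objects on 45° diagonals with speeds on the reflecting
  {66, 132, 198} px/s walk (long-run mean exactly 132 px/s), exact edge
  reflection with per-event bounce logging, and the unexpected object's
  occluder-to-occluder kinematics (always gone at 13 s, 2 s before trial
  end). `condition_catalog()` holds all eleven conditions of the three
  designs; occluders + travel always sum to the display width.
* **Observer models** — four generative accounts of noticing
  (`onset_window`, `offset_window`, `fixation_cross`, `constant_hazard`
  with P(notice) = 1 − e^(−λT)), plus report noise: placement error and
  motion extrapolation, von Mises hue reports, 9-option menus, bounce-count
  error, screening covariates and Farnsworth D-15 arrangements.
  `generate_cohort()` emits a complete subject table from one seed.
* **Screening** — the standard exclusion pipeline (strict 50% bounce-error
  rule over ≥2 trials, age, vision, technical problems, prior experience)
  plus moment-of-inertia D-15 scoring (`score_d15()`, confusion index,
  strict 1.78 threshold), with a per-rule accounting table.
* **Analysis** — percentile-bootstrap proportions and differences
  (`rate_with_ci()`, `difference_with_ci()`), localization distance tables
  and onset-side fractions on full-scale coordinates, circular error
  summaries (circular mean, angular deviation √(2(1−R))), the variance
  ratio, and the Monte-Carlo chance null for random colour responding.
* **Evaluation** — model signatures (rate-vs-exposure slope, anchor
  affinities), a rule-based classifier that returns `"undetermined"` rather
  than guessing, maximum-likelihood hazard recovery with a lack-of-fit
  check, and `run_pipeline()` to drive everything from a config list.

## Worked example

Simulate a cohort for the two-exposure design with a no-object control
(onset-triggered observers, detection probability 0.45), screen it, and
analyse noticing and localization:

```r
library(motib)

cohort   <- generate_cohort("E1", noticing_model("onset_window", p_detect = 0.45),
                            n_per_condition = 125, seed = 2024)
screened <- apply_exclusions(cohort)
screened
#> Exclusion report: 312 recruited, 138 excluded, 174 retained
#>   bounce counts erred by more than 50% on two or more trials 89
#>   reported being younger than 18                          0
#>   needed vision correction but was not wearing it         26
#>   reported a technical problem                            44
#>   prior experience with inattentional blindness tasks     11

retained <- screened$retained
noticed  <- classify_noticer(retained)
rate_with_ci(noticed[retained$condition_id == "long_5s"], seed = 1)
#> 54.7% (95% CI = 42.2-67.2), n = 64
rate_with_ci(noticed[retained$condition_id == "short_2.67s"], seed = 2)
#> 43.3% (95% CI = 31.3-55.2), n = 67
difference_with_ci(noticed[retained$condition_id == "long_5s"],
                   noticed[retained$condition_id == "short_2.67s"], seed = 3)
#> 11.4% (95% CI = -5.5-28.3), n = 64/67

location_analyses(retained)$onset_side
#> # A tibble: 2 x 3
#>   noticed     n onset_side_fraction
#>   <chr>   <int>               <dbl>
#> 1 yes        64               0.969
#> 2 no         67               0.433
```

The pattern is the onset account's fingerprint: similar rates across
exposures (the bootstrap interval on the difference spans zero) while
noticers overwhelmingly place the object on the onset side of fixation and
non-noticers split evenly. Feed the retained cohort to
`compute_signature()` / `classify_model()` to recover the generating model,
or swap in `noticing_model("constant_hazard", hazard_per_s = 0.3)` to see
the rate climb with exposure instead.

The chance benchmark for colour reports — subjects picking a hue uniformly
at random on the wheel:

```r
colour_chance_null(1000, 100, seed = 4)
#> mean angular deviation 77.4 deg; 95% of batches in 72.9-80.4
```

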