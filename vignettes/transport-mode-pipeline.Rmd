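---
title: "Minute-level transport mode detection: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minute-level transport mode detection: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(modesense)
```

# The problem

Epidemiological mobility studies increasingly equip participants with a GPS
receiver, a hip-worn tri-axial accelerometer, and a chest heart-rate sensor
for about a week, and then need to know, for every minute, whether the
participant was at a fixed visited location (an *activity place*) or
travelling, and by which mode: walking, biking, public transport, or a
private motorized vehicle. `modesense` implements this five-class
minute-level classification pipeline end to end, together with the two
methodological refinements that matter most in practice:

1. **Participant-level validation.** A random forest's internal out-of-bag
   (OOB) error mixes minutes from the same participants across the train and
   test roles of each tree. Because a person's sensor signature is highly
   self-similar (their resting heart rate, their count intensity, their
   walking speed, the episode they are currently in), this *naive OOB* rate
   overstates how well the model will do on a new person. The honest figure
   comes from leave-one-participant-out cross-validation (LOOCV): all
   minutes of one participant are held out, a forest is grown on everyone
   else, and the split is repeated once per participant.
2. **Post-hoc homogenization.** Minute-level predictions inside a trip are
   sporadically wrong; a moving-majority output filter over a window of
   `b` minutes on each side removes isolated misclassifications, while too
   large a window erases genuinely short episodes (short walks especially).

Because raw cohorts of this kind cannot be shared (GPS traces identify
people), the package ships a seeded synthetic-cohort generator with the
statistical structure the analysis depends on, so every stage is testable
and every reported phenomenon is reproducible from code alone.

# The prediction model

Forests are bagged classification trees (100 trees by default, Gini
splitting, `floor(sqrt(p))` features tried per node — library defaults,
single-threaded for reproducibility; the `ranger` engine is used). Each tree
is grown on a bootstrap resample of the training minutes of the same size as
the training set; on average a fraction `1 - 1/e ≈ 63%` of distinct minutes
are in-bag and `1/e ≈ 37%` are out-of-bag (`bootstrap_inclusion_fraction()`
verifies this by simulation). Per-minute, per-class *vote shares* — the
fraction of trees voting for each class — are exposed explicitly
(`tree_vote_shares()`, `oob_vote_shares()`), because both evaluation regimes
and the class-imbalance correction operate on them.

**Prevalence cutoff correction.** Activity places dominate follow-up time
(roughly 93% of minutes), so an unweighted arg-max over vote shares
systematically under-predicts rare classes. `weighted_classify()` instead
maximizes `votes_c / prevalence_c`, i.e. it moves each class's decision
cutoff to its observed training prevalence, applied at the aggregation step
only (trees are grown unweighted). With uniform prevalence this reduces
exactly to the unweighted arg-max. Ties go to the first class in the fixed
order `activity_place, bike, private_motorized, public_transport, walk`.
The expected trade is that rare-class recall (bike above all) rises while
majority-class recall falls; both weighted and unweighted predictions are
always emitted, and the report tables follow the convention that overall
rows are unweighted while mode-specific rows are weighted.

# The predictor catalogue (51 + 55 + 12 + 2)

`feature_catalogue()` fixes the minute-level predictor list:

* **GPS (51)**: fixes failing the quality rule HDOP < 6, VDOP < 7, PDOP < 8
  (strict inequalities) are discarded; the seven summary statistics — mean,
  median, sample SD, min, max, 10th and 90th percentile (linear
  interpolation) — are computed over the retained fixes of each minute for
  speed, elevation, the three DOPs, and satellites in view and used
  (7 × 7 = 49), plus the retained-fix count and the fraction of raw fixes
  passing the filter. Latitude/longitude are carried in the fix stream but
  not summarized as predictors; the speed and quality statistics capture the
  behaviourally relevant information without tying the model to geography.
* **Accelerometer (55)**: per count-processing variant (standard and
  low-frequency extension), seven summaries of vector-magnitude counts and
  of METs, the step sum, and the counts of MVPA and sedentary 5-s epochs
  (17 × 2 = 34), plus per-axis seven-statistic summaries for the standard
  variant (21). METs come from an affine vector-magnitude equation
  (`METs = 0.000863 · VM_cpm + 0.668876`, counts scaled to counts/min before
  application); energy expenditure is also emitted as
  `kcal/min = METs × 3.5 × weight / 200`, so both parameterizations are
  available. MVPA is METs ≥ 3; sedentary is axis-1 < 100 counts/min. All
  coefficients and cut-points are arguments, since conventions differ
  between labs.
* **Heart rate (12)**: per-minute HRV statistics of the RR-interval series —
  mean and median RR, SDNN, RMSSD, SDSD, pNN50, the coefficient of
  variation, and the mean/SD/min/max of per-beat heart rate plus the beat
  count. Minutes with fewer than three intervals have the variability
  measures missing. Frequency-domain HRV is deliberately out of scope: a
  one-minute window cannot support it.
* **Time (2)**: minutes since midnight and a weekend flag.

A minute enters the merged dataset only if all three sensors contributed
data to it, mirroring how multi-device studies lose most raw minutes at the
merge step. The label of a minute is the mode of the episode with the
largest overlap with it (ties to the earlier episode) — for minute-aligned
timetables this is simply the covering episode.

# The synthetic cohort generator

`generate_cohort()` draws, per participant and day, an episode schedule that
tiles a 14-hour waking wear window (devices are removed overnight):
activity-place stays alternate with trips; each trip has `1 + Poisson(0.7)`
stages (≈1.7 on average) with a transport mode drawn from the configured
mode mix (walk 45%, private motorized 25%, public transport 20%, bike 10%;
consecutive stages never repeat a mode). Daily trip counts are
`Poisson(5.1)` and trip durations are gamma-distributed with mean chosen so
that about 6.9% of follow-up time is spent on trips — the calibration
targets of a week-long urban cohort.

Sensor signatures are drawn hierarchically: an episode-level mean (speed,
count intensity, heart-rate elevation) from the mode's signature
distribution, then minute- and sample-level noise around it. The defaults
encode the qualitative structure the classifier must exploit, including its
realistic failure modes:

* speeds near zero at activity places; walking ≈ 4.8 km/h; biking, public
  transport and cars at 13/18/26 km/h with wide episode-level SDs, so urban
  speeds genuinely overlap;
* stop-and-go modes (public transport above all) have large within- and
  between-minute speed dispersion — which is why speed-dispersion summaries
  rank among the most important predictors;
* hip-worn counts are high while walking, low while biking despite high
  effort — biking is instead marked by the largest heart-rate elevation
  (+45 bpm vs +25 walking and ≈+5 motorized), which is what makes heart
  rate informative for biking specifically;
* during public transport, with probability 0.6 an episode is treated as
  underground: DOPs are inflated threefold and satellites in view reduced,
  so many fixes fail the quality filter — degraded GPS quality is itself a
  transit signature;
* the low-frequency-extension variant adds non-negative low-intensity
  counts, most to near-sedentary epochs, and epoch-wise dominates the
  standard variant.

**Participant heterogeneity** is the load-bearing part: Gaussian random
effects on resting heart rate (SD 7 bpm), habitual walking speed
(SD 1.2 km/h) and a multiplicative count intensity (log-SD 0.5) make each
participant's data self-similar. This is what reproduces the naive-OOB
optimism: with the effects switched off the OOB/LOOCV gap shrinks toward
the residual episode-memorization component; with them on it widens.

**Non-wear** is modelled as a few contiguous gap episodes per sensor-day
(Poisson count, exponential durations) calibrated to an expected non-wear
fraction of 0.32 per sensor. We chose block gaps over per-minute dropout
deliberately: independent per-minute dropout would fragment the merged
series into one-to-two-minute contiguity blocks, which no real device
produces and which would make the homogenization stage vacuous. With block
gaps, about 250 of the 840 waking minutes per day survive the three-sensor
merge — the same order of merge loss real multi-device studies report.

What the generator does *not* emulate: street networks and real geography
(latitude/longitude follow a heading-consistent random walk), device-specific
noise spectra, inter-sensor clock drift, traffic conditions, or behavioural
correlation between days. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's logic and the directional phenomena are
correct, not that any particular real-world prediction rate will be
attained.

# Homogenization

`mode_filter()` outputs, for each minute, the modal raw prediction in the
window `[t − b, t + b]`, truncated at the edges of the minute's contiguity
block (a gap of more than one minute, e.g. non-wear or overnight, starts a
new block and the filter never spans it). Three choices were genuinely open
and are fixed as follows:

* **Non-recursive**: the filter reads raw predictions only, never its own
  output, so a forward and a backward pass give identical results; a
  recursive in-place variant would be order-dependent.
* **Ties keep the raw centre label** — the least-surprise option, and it
  makes `b = 0` exactly the identity.
* **Truncated edge windows** (no padding): the first and last minutes of a
  block use what exists.

Two consequences are worth knowing: under sporadic independent flip noise
inside long constant segments, accuracy improves with `b` (for `b = 1` the
exact improvement is computable by enumerating the 3-window outcomes); and
any genuine run of length `L ≤ b` flanked by `b` minutes of another mode is
erased entirely — the reason walking recall peaks at moderate bandwidths
and falls at `b = 5`.

# Rates and reports

`prediction_rates()` computes, in percent: the overall rate; the *overall
transport* rate — exact-mode agreement restricted to minutes whose true
class is a transport mode (the stricter of the two possible readings; the
binary trip-vs-place accuracy is also emitted as a supplementary cell); and
per-class recall. Cells with zero denominator are missing, never zero.
Cross-iteration summaries report the median with the 2.5th and 97.5th
percentiles, formatted `median (p2.5–p97.5)` with integer rounding for
display only; CSV outputs keep full precision. `build_report_tables()`
assembles the three standard views: split-regime comparison (naive OOB vs
held-out test, before/after prevalence correction, without heart rate),
with/without heart rate, and the bandwidth sweep.

# Numerical and reproducibility choices

* Percentiles everywhere are linear-interpolation order statistics
  (`type = 7`); SDs are sample SDs (n − 1).
* One master seed drives everything; LOOCV iteration `i` uses
  `seed + i`, the pipeline's forest stage `seed + 1000 + i`. Forests are
  single-threaded, so reruns are byte-identical; the run manifest records
  seeds, versions, and MD5 hashes of every output.
* Rows with any missing feature are dropped before training and counted;
  in merged data such rows arise only from degenerate minutes (a single
  valid GPS fix has no SD; fewer than three beats have no HRV).
* A one-tree forest leaves in-bag rows with no OOB vote; such rows are
  flagged and excluded from rates, with the exclusion count reported.

# Problem sizes used by the test-suite

The package's own checks run on deliberately desk-scale cohorts, chosen as
the smallest sizes at which each phenomenon is stable: schedule calibration
on 60 participants × 7 days (timetables only); the split-bias and weighting
experiments on 20 participants × 2 days, LOOCV with 100-tree forests,
repeated over three seeds with heterogeneity on and off; pipeline smoke and
determinism runs on 5–6 participants with 50-tree forests. The full-scale
default configuration (126 participants × 7 days) runs the identical code
path, only longer.

# Known limitations

* The simulator's class structure is stationary within mode; it does not
  generate multimodal within-trip behaviour such as walking inside a
  transit station during a single labelled transit stage.
* Heart-rate wear in real cohorts is far sparser than GPS/accelerometer
  wear; the generator treats the three sensors symmetrically.
* The MET equation and the MVPA/sedentary cut-points are conventions; users
  comparing against a different calibration should pass their own
  coefficients to `accel_epoch_derivations()`.
* LOOCV retrains one forest per participant per feature set; at the default
  cohort scale this is hours of single-core work — the code is written so
  iterations can be distributed trivially if needed.
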