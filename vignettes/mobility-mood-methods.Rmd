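---
title: "Methods: from duty-cycled GPS and EMA to lagged mobility-mood models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from duty-cycled GPS and EMA to lagged mobility-mood models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Smartphone digital phenotyping studies of mood disorders collect two streams
per participant: passively sensed GPS, recorded on a battery-saving duty
cycle (here, 1 minute of recording per 10-minute period), and actively
reported ecological momentary assessment (EMA) — four ordinal 1–5 mood items
(fatigue, depressed, manic, irritability) prompted twice daily at 12:45 and
17:00, with the 12:45 response used for analysis. The scientific question is
bidirectional and day-lagged: does a change in mobility from one day to the
next predict the next day's mood, and does a change in mood predict the next
day's mobility?

mobimood implements the full chain — raw-fix ingestion, trajectory cleaning
and imputation, eight daily mobility features, EMA reduction, and the lagged
marginal models — together with a synthetic cohort generator that plants
known couplings so the whole chain can be validated without access to any
participant data.

## GPS preprocessing

Five steps, all in local study time (a fixed UTC+8 offset; day boundaries at
local midnight):

1. **Accuracy filter.** Keep fixes with reported accuracy strictly below
   51 m. The threshold is a parameter (`accuracy_threshold`); retention is
   logged.
2. **10-second binning.** The day is an 8640-cell grid of half-open
   intervals $[t, t+10)$ anchored at local midnight; each occupied cell gets
   the mean latitude/longitude of its fixes. Averaging within cells damps
   the speed spikes caused by GPS drift; unoccupied cells are explicit
   `missing` cells, so the grid is always a partition of the day.
3. **Motion states.** For adjacent observed cells the displacement is
   computed; a displacement strictly exceeding $\sqrt{10}$ m over the 10-s
   step marks the touching cells `moving`, otherwise `pause`. An observed
   cell with no observed neighbour is `undefined` (it keeps its observed
   position but is excluded from the imputation donor pool, and takes no
   part in pause aggregation).
4. **Pause events.** Maximal runs of pause cells are bouts; bouts separated
   by at most 300 s and strictly less than 60 m merge into one pause event
   with a duration-weighted centroid.
5. **Imputation.** See below.

Distances use the spherical Mercator projection with a cosine-of-latitude
correction: both points are projected, the Euclidean distance taken, and the
result multiplied by $\cos(\bar\varphi)$ of the mean latitude. Raw Mercator
lengths are inflated by $1/\cos\varphi$ (about 10% at 25° N); the correction
keeps meters locally true while retaining the projection's planar geometry.
Agreement with the haversine great-circle distance is within 0.5% for pairs
under 10 km at Taipei's latitude (asserted against an independent oracle in
the tests).

### Trajectory imputation

Each missing cell is filled in `n_sim = 10` independent realizations; daily
features are computed per realization and averaged. Rules, in order:

* **Agreeing flanks.** An interior gap whose flanking observed positions lie
  within 60 m of each other is bridged as a pause at the mean flank
  position. We apply this at *any* gap length, not only below 300 s: under
  the study's duty cycle every off-window lasts 600 s, so a length cap would
  route essentially all stationary home time into stochastic donor
  resampling and inflate daily travel severalfold. Flank agreement — not gap
  length — is the informative signal under duty-cycled sampling. The cost is
  that a round trip completed entirely inside one off-window (at walking
  speed, at most a few hundred meters out and back) is imputed as a stay;
  this is a conscious bias toward under- rather than over-estimated travel.
* **Short disagreeing gaps** (≤ 300 s) are bridged as a linear flight.
* **Long disagreeing gaps** are filled by hot-deck resampling of observed
  *bouts* — whole flight or pause segments from the same participant-day,
  preferring the same half of the day (00:00–12:00 / 12:00–24:00) — chained
  until the gap is covered, then sheared linearly so the walk connects the
  two flanks. Resampling whole bouts rather than single 10-s steps preserves
  the flight/pause composition of observed behaviour; step-level resampling
  behaves like a jittery random walk and overstates path length.
* **Day-edge gaps** (one flank only) are held as a pause at the nearest
  observed position.

Observed cells are never altered. Everything is seeded: one master seed
yields per-participant, per-day, per-realization sub-seeds, so pipelines are
bit-reproducible.

## Daily mobility features

Study-level location clusters are discovered once per participant from all
pause events (duration-weighted k-means with deterministic farthest-point
seeding; k grows until every pause lies within `d_max` = 500 m of its
centroid), so homestay and entropy are comparable across days. Home is the
cluster holding the most pause time in the 00:00–06:00 window over the whole
study, ties broken by all-day pause time.

Per realization, then averaged over realizations:

* **location variance** $= \log(\mathrm{var(lat)} + \mathrm{var(lon)})$ over
  all points of the day (degrees² inside the log; the scale-stable
  convention of the feature literature). Computed on all points, not pause
  points only — the alternative is available behind a switch in the
  underlying feature function if a study needs it.
* **speed mean / variance** over moving cells only (speed = displacement /
  10 s); pause jitter never contaminates speed.
* **total distance**: sum of 10-s displacements over steps adjacent to at
  least one moving cell. Steps between two pause cells are sub-threshold
  sensor jitter (< $\sqrt{10}$ m each) that would otherwise accumulate to
  kilometers per day; excluding them is the same drift-damping argument that
  motivates 10-s binning.
* **transition time**: moving cells / non-missing cells.
* **number of clusters**: distinct study-level clusters visited that day.
* **normalized entropy**: $-\sum_i p_i \ln p_i / \ln k$ with $p_i$ the share
  of the day's pause time in cluster $i$ and $k$ the clusters visited;
  defined 0 when $k \le 1$. Pause time is the time base because transit time
  belongs to no location.
* **homestay**: pause time in the home cluster / total non-missing time.

Days below 10% observed coverage that cannot be imputed are emitted with
`NA` features and a reason code, never silently dropped.

## EMA handling

The analysis series keeps the 12:45 response; an absent 12:45 response makes
the date missing, with no fallback to 17:00. Between-prompt agreement is
summarised by the intraclass correlation, two-way mixed effects, absolute
agreement, single measures — the form standard for repeated administrations
of one instrument; it is computed within participant over dates with both
prompts and then averaged across participants (the pooled-then-averaged
convention; the alternative of pooling all pairs jointly differs only when
participants have very unequal prompt-pair counts). Because it is an
absolute-agreement form it penalises a constant offset between the prompts,
which the tests assert on constructed examples. Ordinal values enter all
models as numeric 1–5.

## Statistics

**Weekly polyserial correlation.** Each participant contributes one weekly
mean per GPS feature and the rounded mean mood category from their first
7-day window with at least 4 valid days in both series (an all-weeks average
is available behind a switch). The polyserial correlation between the
continuous feature and the latent normal variable under the ordinal mood is
estimated in two steps: thresholds fixed at inverse-normal cumulative
proportions of the ordinal margin, then one-dimensional maximum likelihood
for $\rho$; the two-step form is stable when outer categories are sparse.
The p-value uses the observed-information standard error.

**Day-pair lag models.** For consecutive calendar days $(d, d+1)$ within a
participant, the feature-to-mood model regresses day-2 mood on
$\{\Delta\text{feature}, \text{age}, \text{sex}, \text{feature}_{day1}\}$,
and the mood-to-feature model regresses the day-2 feature on
$\{\Delta\text{mood}, \text{age}, \text{sex}, \text{mood}_{day1}\}$
(identity link; raw day-2 outcomes, matching the covariate list). Pairs with
any missing element are dropped (complete-pair analysis) with counts logged.
Estimation is by generalized estimating equations with the participant as
cluster and an AR(1) working correlation $\alpha^{|t-s|}$ indexed by
calendar day, so calendar gaps decay correctly; $\alpha$ is estimated by
moment matching on lag-1 residual products. Sex is coded 1 = male,
0 = female (a convention choice; the delta-term inference is unaffected).

Inference uses the robust sandwich with two small-sample safeguards that are
the package's convention throughout: the Mancl–DeRouen leverage correction
of the meat, and a $t$ reference with (clusters − 1) degrees of freedom.
With tens rather than hundreds of independent clusters, the plain
Liang–Zeger estimator with normal quantiles is anticonservative — in the
package's own null-calibration experiment it rejected a true-zero delta term
in 11–13% of replicates at the 5% level, versus at most 8% after the
correction. With many clusters the two versions coincide for all practical
purposes.

**Power.** Fisher-z calculations:
$n = \left((z_{1-\alpha/2}+z_{\text{power}})/\operatorname{atanh}\rho\right)^2 + 3$,
rounded to the nearest integer — the convention that reproduces the standard
published values (29 at $\rho = 0.5$, power .80; 38 at power .90; note that
the ceiling convention would give 30 for the first). Achieved power is
$\Phi(\operatorname{atanh}\rho\sqrt{n-3} - z_{1-\alpha/2})$, ignoring the
negligible far tail.

## The synthetic cohort generator

The generator's defaults are the study conditions: 38 participants
(10 healthy controls, 11 bipolar, 17 major depressive disorder), 180 daily
follow-up days, homes scattered within ~2 km of 25.04° N 121.56° E (a
deliberately non-equatorial latitude, where a missing cosine correction in
the distance code is immediately visible), four candidate sites per
participant at 0.5–4 km, a 60 s on / 600 s off duty cycle sampled at
0.2 fixes/s, and 6.5% EMA missingness at the analysis prompt.

Each day is an alternating pause/flight path: home until a habitual leave
time, site visits with flights at 1.4 m/s (walking) or 8 m/s (vehicle,
legs over 1.2 km), home for the night. True daily features are computed
analytically from the event-level schedule (flights integrated as linear
segments), so ground truth involves no discretization. The observation model
renders fixes only inside on-windows and adds *exponentially correlated*
position error (stationary SD 10 m, time constant 600 s): GPS error is a
slowly wandering bias, and white noise of realistic amplitude would make
every 10-s step exceed the motion threshold, which no real trace does.
Accuracy values are lognormal with median 15 m and sdlog 0.702, placing
~95% of draws below 47.6 m and ~99% below 76 m — the shape reported for
this class of device data.

Mood is a latent AR(1) (parameter 0.3, innovation SD 0.6) around a
group-specific trait, driven by the standardized day-to-day changes of the
true features, and thresholded to the ordinal 1–5 scale (a noisier second
thresholding gives the 17:00 prompt). The planted couplings carry the
directions of interest: increasing homestay worsens fatigue, depressed and
irritable mood (+0.4, +0.4, +0.25 per SD of change); increasing location
variance lowers depressed mood (−0.4); and yesterday's latent depressed or
fatigued mood raises today's homestay target (+0.3 each, on the logit) and
shrinks today's dispersal (−0.3, −0.15 on the log scale), which lowers
location variance. Coupling operates on *true* features, so recovery error
in the validation experiments isolates the estimation pipeline. Effect sizes
were chosen once so that *sign* recovery is the criterion — the study's
coefficient magnitudes belong to its own non-deposited data and are not
targets.

What the generator does not emulate: hospitalization-driven dropout,
COVID-era mobility shocks, device heterogeneity beyond the fixes-per-burst
parameter, indoor positioning pathologies, and non-random EMA missingness.
Passing tests therefore show that the pipeline recovers structure of this
kind from data of this shape — not that every artifact of real deployments
is handled.

## Validation experiments and problem sizes

* **Sign recovery**: 20 independent cohorts at the default 38 × 180 scale;
  in each, the four planted pathways (homestay→depressed,
  location-variance→depressed, depressed→location-variance,
  fatigue→homestay) are fit on the patient group and must carry the planted
  sign at p < .05. The experiment runs at the generator's feature level —
  true features plus coupled moods through day pairs and the GEE — which
  isolates statistical recovery; measurement fidelity of the GPS stage is
  established separately by the feature oracles, the truth-tracking
  correlations (> 0.9 for homestay, location variance and distance on a
  rendered cohort), and the imputation-benefit experiment.
* **Null calibration**: 100 cohorts of 15 × 60 with all couplings zero; the
  delta-term must reject at most 10% of the time per model at the 5% level.
* **Imputation benefit**: 20 rendered days; the mean absolute error of total
  distance from the 10-realization average must beat the observed-cells-only
  estimate. Typical result: the imputed estimate lands within ~20% of truth
  while the observed-only estimate captures roughly the duty cycle's ~9%.
* **Closed-form anchors**: required n of 29/38, achieved power 0.70 at
  $\rho = 0.364$, $n = 45$, adherence 93.5% from 4803/5137 person-days, and
  the entropy/distance oracles.

These sizes keep the whole suite within a few minutes on one CPU while
leaving the statistical conclusions comfortably away from their thresholds.

## Numerical and degenerate-input choices

* Thresholds are strict where the protocol says "exceeds" or "<": exactly
  $\sqrt{10}$ m is not moving; accuracy exactly 51 is filtered out; flank
  distance exactly 60 m does not merge.
* Entropy is defined 0 when at most one cluster is visited; the 0/0 of a
  one-cluster day never occurs.
* A constant ordinal margin makes the polyserial undefined and is reported
  as such, never coerced.
* The location-variance log never sees zero variance in practice because
  sensor noise provides a floor; the generator mirrors this by adding the
  noise variance to its analytic ground truth.
* k-means seeding is deterministic (farthest-point from the heaviest
  pause), so cluster discovery has no RNG dependence.
* A day with zero observed cells is unimputable: features are `NA` with a
  reason code, and the QC report counts it.
* GEE non-convergence raises a warning with the fit still returned for
  inspection; the iteration cap is 50 with a relative tolerance of 1e-8.

## Known limitations

* The imputation's stay-biased treatment of agreeing flanks underestimates
  short round trips made entirely within one off-window.
* Transition time is mildly inflated on imputed days (donor shear can turn
  borderline steps into moving ones); distance and homestay are much less
  affected.
* The weekly correlation uses the first qualifying week by default; the
  study's exact windowing is not stated, and the all-weeks switch changes
  participant weights.
* The polyserial standard error is a large-sample quantity; below a few
  dozen participants the p-values are approximate.
* The ICC averages per-participant estimates equally, which differs from a
  jointly pooled estimate when follow-up lengths are very unequal.
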