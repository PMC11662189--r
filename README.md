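# mobimood

Digital phenotyping of mobility and mood from smartphone GPS and ecological
momentary assessment (EMA), for researchers studying mood disorders with
passively sensed data.

Smartphones in naturalistic studies record GPS on a battery-saving duty
cycle (here: 1 minute of fixes per 10-minute period) and prompt short
ordinal mood questionnaires twice a day. mobimood turns those two raw
streams into the bidirectional, day-lagged association between mobility and
mood:

* **Preprocessing** — accuracy filtering (< 51 m), collapsing fixes onto a
  10-second grid, motion-state classification (moving when a 10-s
  displacement exceeds √10 m), pause aggregation (300 s / 60 m rule), and
  seeded hot-deck trajectory imputation averaged over 10 realizations.
  Distances use a cosine-corrected spherical Mercator projection.
* **Eight daily mobility features** — location variance
  log(var(lat)+var(lon)), speed mean and variance, total distance,
  transition time, number of location clusters, normalized entropy
  −Σpᵢ ln pᵢ / ln k over pause time per cluster, and homestay (fraction of
  non-missing time at the inferred home cluster).
* **EMA handling** — the 12:45 prompt forms the analysis series; agreement
  between the two daily prompts is summarised by ICC(A,1) (two-way mixed,
  absolute agreement, single measures).
* **Statistics** — weekly polyserial feature–mood correlations; day-pair
  models fit by GEE with identity link, AR(1) working correlation over
  calendar days, and robust (Mancl–DeRouen corrected) sandwich standard
  errors:

  mood₂ ~ Δfeature + age + sex + feature₁   (feature → mood)
  feature₂ ~ Δmood + age + sex + mood₁     (mood → feature)

  plus Fisher-z power and sample-size calculations,
  n = ((z₁₋α/₂ + z_power)/atanh ρ)² + 3.
* **Synthetic cohort generator** — a seeded home-plus-K-sites semi-Markov
  routine with duty-cycled, drift-noised observation and latent AR(1) mood
  coupled to the true daily features in both directions, so the entire
  pipeline is testable end to end with no participant data.

## Worked example

Generate a small synthetic study on disk, run the full pipeline, and fit
one lag model:

```r
library(mobimood)

cfg <- scenario_config(n_participants = 6, n_days = 21,
                       groups = c(HC = 1, BP = 2, MDD = 3), master_seed = 7)
generate_cohort(cfg, "demo_study")
run <- run_study("demo_study", seed = 1)
print(run)
#> mobimood study run
#>   126 participant-days of features, 6 weekly rows, 89 day pairs
#>   EMA adherence: 93.7% (118/126 person-days)
#>   weekly correlations with p < .05:
#>     location_variance ~ irritability: rho = -0.901 (p = 3.46e-08)
#>     ...

fit_lag_model(run$pairs, "feature_to_mood",
              outcome = "depressed", predictor = "homestay")
#> Day-lag model (feature_to_mood): depressed_2 on d_homestay + age + sex + homestay_1
#>   5 participants, 89 pairs, AR(1) alpha = 0.106
#>   delta-term beta = 3.4128 (robust SE 0.5889, p = 0.00441)
```

The positive delta-term says that a day-over-day increase in homestay goes
with a higher depressed-mood rating the second day — the direction the
generator planted. At this toy scale (6 participants, 3 weeks) only strong
couplings surface; the validation experiments below run at study scale.

Power planning uses the Fisher-z closed forms:

```r
fisher_required_n(0.5, 0.05, 0.80)   #> 29
fisher_required_n(0.5, 0.05, 0.90)   #> 38
round(fisher_power(0.364, 45, 0.05), 2)  #> 0.7
```

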