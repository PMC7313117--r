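# foragetactics

Analysis of alternative foraging tactics in central-place foraging birds
tracked with combined GPS and tri-axial accelerometer loggers, built around
the study design of a breeding colonial raptor: short foraging excursions
from the nest into surrounding farmland, classified at the trip level into a
perch-dominated, energy-sparing *static foraging* (SF) tactic and a
flight-search-dominated, energy-demanding *dynamic foraging* (DF) tactic.

The package covers the full chain from raw fixes to individual-level
inference:

1. **Trip segmentation** — foraging trips are maximal runs of fixes outside
   a 50-m buffer around the nest (and optional roosts), with the field
   rules: the first excursion of a day starting > 2 km from the nest with no
   prior inside-buffer fix is discarded, and urban-only excursions are
   dropped. Descriptors: duration, length, maximum distance, tortuosity
   (length / maximum distance, ≥ 2 for closed trips).
2. **Behavioural annotation** — expectation–maximization clustering of fixes
   in (speed, |turning angle|) space into four modes delimited by low/high
   splits on each axis: *perching* (low/low), *intensive search* (low/high),
   *relocation* (high/low), *extensive search* (high/high), followed by a
   margin-gated majority smoother over a 5-fix window.
3. **Tactic classification** — k-means (best of 100 restarts × 100 Lloyd
   iterations) on each trip's four-mode composition, with the number of
   clusters chosen by a five-index consensus (gap statistic, silhouette,
   Calinski–Harabasz, Davies–Bouldin, Hartigan); the cluster with the higher
   perching centroid is SF.
4. **Energetics** — overall dynamic body acceleration: the static component
   of each 25-Hz axis is a centred 1-s running mean, and per-sample
   ODBA = |dx| + |dy| + |dz| of the dynamic residuals, averaged per trip.
5. **Weather** — hourly records matched nearest-in-time; trip direction TD =
   bearing from the nest to the trip's farthest point; tailwind and
   crosswind components from the mean of departure/return winds:
   `TWC = WS·cos(TD − WD)`, `CWC = |WS·sin(TD − WD)|`.
6. **Mixed models** — binomial GLMMs (logit) of P(DF trip) on standardized
   solar radiation, rain presence, TWC, CWC, time in arable land, breeding
   stage, sex and year, with an individual random intercept; sex-by-weather
   interactions whose 95% CI spans zero are removed in a single step.
   Adjusted repeatability uses the delta-method observation-level variance,
   `R_adj = σ²_id / (σ²_id + 1/(p̄(1−p̄)))`; individual tendencies are the
   conditional modes of the random effect with simulation SDs; behavioural
   reaction norms are tested by 2-df likelihood-ratio tests on random
   slopes, one weather variable at a time.
7. **Fitness correlates** — scaled mass index (SMA allometry on keel
   length), brood-mean daily body mass increase of nestlings (DBMI),
   breeding success and feeding frequency, correlated with individual
   tendency by weighted Pearson correlations (weights = 1/SD of the
   tendency) with 9999-shuffle randomization tests.

Because the original tracking data are not public, the package ships a
**synthetic-study generator** (`simulate_study()`) that emulates the whole
design — trajectories built from tactic-conditional behaviour sequences,
25-Hz accelerometry, hourly weather, nest timelines, morphometrics and
nestling growth — with full ground truth, so every stage can be validated by
parameter and label recovery.

## Worked example

```r
library(foragetactics)

cfg    <- sim_config(n_individuals = 12, trip_count_mu = 14, seed = 11)
report <- run_pipeline(cfg)
print(report)
```

```
Foraging-tactic analysis report
  157 trips from 12 individuals; 59% dynamic foraging
  consensus cluster number: 2
  mean ODBA: SF 0.241 g, DF 0.387 g
  R_adj = 0.060 (LRT chi2 = 1.89, p = 0.17)
  final GLMM coefficients:
                 term estimate  ci_lo  ci_hi
          (Intercept)   -1.019 -2.251  0.212
        z_time_arable   -0.009 -0.415  0.396
            z_stage01    0.862  0.290  1.435
                z_sex   -0.555 -1.399  0.288
             year2017    1.772  0.249  3.295
             year2018    1.816 -0.022  3.654
              z_solar    0.366 -0.083  0.814
       z_rain_present   -0.689 -1.136 -0.241
                z_twc   -0.340 -0.755  0.075
                z_cwc    0.296 -0.164  0.755
 z_sex:z_rain_present    0.468  0.058  0.878
  fitness correlates:
           target  n    r_w p_rand
     residual_smi 12  0.039  0.909
 breeding_success 12 -0.765  0.006
    residual_dbmi  8  0.290  0.531
 device_load_sex0 10  0.218  0.553
  tactic-vs-truth accuracy: 0.975; all key signs recovered: TRUE
```

Reading the output: 157 foraging trips were segmented and classified, 59%
of them dynamic foraging; DF trips cost ~1.6× the ODBA of SF trips (0.387
vs 0.241 g), the energetic signature of flight-search versus perch-hunting.
The final GLMM retains one sex-by-rain interaction whose CI excludes zero;
positive `z_stage01` means DF trips are more frequent during
nestling-rearing. `R_adj` is the fraction of latent-scale variance in tactic
choice attributable to individual identity (small studies often estimate it
imprecisely — see the methods vignette). The last line compares the
recovered tactics against the generator's ground truth: 97.5% of trips were
classified correctly and the substantive generator effects (solar,
crosswind, stage) were recovered with the right signs.

Lower-level functions (`segment_trips()`, `embc_fit()`, `kmeans_tactics()`,
`wind_components()`, `fit_glmm_binomial()`, `adjusted_repeatability()`,
`weighted_corr()`, `randomization_test()`, …) are exported individually and
documented; the methods vignette (`vignettes/foraging-tactics.Rmd`) explains
the models, defaults and their limits.

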