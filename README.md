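# leukoRI

Model-based leukocyte reference intervals (RIs) for wild vertebrate
populations.

Field ecologists and wildlife veterinarians use white blood cell (WBC)
counts and the five-part leukocyte differential (lymphocytes, monocytes,
eosinophils, heterophils, basophils) as inexpensive stress and health
indicators — but deciding whether an individual's value is abnormal
requires reference intervals, and raw-data intervals from one or two
populations confound sex, body size, season, latitude and strong
among-population heterogeneity. `leukoRI` implements a statistical pipeline
that disentangles these sources:

1. **Smear counting** — WBC (cells/µl) estimated from per-field tallies as
   mean cells per field × objective power², with the ≥ 50 fields /
   ≥ 150 leukocytes stopping rule (detection floor 0.7%).
2. **Compositional treatment** — the differential is a 5-part composition;
   it is mapped to 4 Euclidean coordinates by the isometric log-ratio (ilr)
   transform (multiplicative zero replacement below the detection floor).
3. **Cosinor seasonality** — circannual rhythm modeled as
   `MESOR + A·cos(2πt/365 + φ)` in linearized `(cos, sin)` form; amplitude,
   acrophase and calendar peak/trough days are recovered draw-wise.
4. **Bayesian random-intercept LMM** — each response (log-WBC, ilr1–4)
   regressed on the cosinor pair, sex, standardized snout-vent length,
   standardized UTM latitude and the cosinor interactions, with a
   population random intercept; fit by an exact blocked Gibbs sampler
   (conjugate normal/gamma priors), 3 chains, split-R̂/ESS diagnostics.
5. **Reference intervals** — the RI is the mode and 95% prediction interval
   of the back-transformed posterior predictive distribution for a new
   individual in a new population; plus sex contrasts with posterior sign
   probabilities, amplitude-versus-RI exceedance, among-population variance
   fractions σ²ₚₒₚ/(σ²ₚₒₚ+σ²), observed leukocytosis fractions, and the
   H:L stress ratio.

Because no raw cohort is distributed, the package ships a synthetic-cohort
generator replicating the motivating study design (794 lizards — 498 males,
296 females — in 54 populations across a latitudinal gradient, captures
February–October), used for end-to-end parameter-recovery validation.

## Worked example

```r
library(leukoRI)

sim <- simulate_cohort(seed = 1)              # 794 rows, 54 populations
fit <- cosinor_lmm(sim$cohort, "log_wbc",
                   mcmc = mcmc_config(n_chains = 3, n_draws = 2000,
                                      burn_in = 500, seed = 1))
print(fit)
#> Bayesian cosinor mixed model - response: log_wbc
#>    794 individuals, 54 populations, 6000 posterior draws
#> Posterior mean coefficients:
#> intercept     cos_t     sin_t     sex_f   std_svl   std_lat cos_t_sex sin_t_sex
#>    8.5923    0.1920   -0.1913    0.1523    0.0739    0.0727    0.2274   -0.1332
#> cos_t_svl sin_t_svl cos_t_lat sin_t_lat
#>    0.0649   -0.0337    0.0188    0.0085

pp <- posterior_predictive(fit, sex = "male", seed = 2)
reference_interval(back_transform(pp, "log"),
                   variable = "WBC", sex = "male", units = "cells/ul")
#> WBC (male): mode 4030, 95% PI (1762 - 15730) cells/ul  [n = 6000]

sex_contrasts(fit)$mesor          # baseline difference, cells/ul
#> MESOR female-male: 892 +/- 370   P(>0) = 0.99, P(<0) = 0.01

variance_fraction(fit)$mean_pct   # among-population share of residual variance
#> [1] 58.4
```

Reading the output: the intercept is the male MESOR on the log scale
(`exp(8.59) ≈ 5400` cells/µl); the RI is asymmetric about its mode because
the predictive distribution is right-skewed — an individual three times
above baseline can still be healthy; the MESOR contrast says female
baselines exceed males' with posterior probability 0.99; and 58% of the
variation left after sex/size/season/latitude is among-population
heterogeneity, the key argument against single-population reference
intervals. The seed-derived cohort makes every number above exactly
reproducible.

The full pipeline (all five responses, RI table for WBC + the five classes
per sex, contrasts, variance decomposition, convergence report, manifest)
is one call:

```r
run_pipeline(pipeline_config(output_dir = "run1", seed = 1))
```

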