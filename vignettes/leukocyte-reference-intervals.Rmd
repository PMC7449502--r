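---
title: "Estimating leukocyte reference intervals for wild populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leukocyte reference intervals for wild populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukoRI)
```

## The problem

Clinical decisions about wild animals — is this individual's white blood
cell count a sign of disease, or normal? — require reference intervals
(RIs): the range within which a healthy individual's value is expected to
fall. For wild ectotherms such as lacertid lizards, naive RIs computed as
means ± SD of raw counts from one population conflate several systematic
sources of variation: sex, body size (an age proxy), season, latitude, and
strong idiosyncratic differences among populations. `leukoRI` implements a
model-based alternative: RIs are extracted from the posterior predictive
distribution of a Bayesian mixed model that explicitly removes those
effects, so the interval describes the residual "healthy" variation that
applies to a new individual from any population in the species' range.

## The data model

The raw measurement is a stained blood smear scanned at a fixed objective
power. Leukocytes are tallied per microscope field into five classes
(lymphocytes, monocytes, eosinophils, heterophils, basophils) until at
least 50 fields and at least 150 cells have been examined; the 150-cell
floor means a class with true frequency below $100/150 \approx 0.7\%$ can
be missed entirely. Total WBC (cells/µl) is estimated as the mean count per
field times the objective power squared (`estimate_wbc`).

Two transformed responses enter the models:

* **log-WBC** — the concentration is right-skewed and strictly positive.
* **ilr coordinates of the differential.** The five class frequencies are a
  composition: they carry only relative information and sum to one, so they
  cannot be modeled as independent Gaussian responses. The isometric
  log-ratio (ilr) transform maps the 5-part simplex isometrically onto
  $\mathbb{R}^4$; each of the four coordinates is then modeled
  independently.

### ilr basis and zeros

Any orthonormal log-ratio basis gives an equivalent coordinate system. We
use the canonical sequential-binary-partition basis on the fixed class
order (coordinate $k$ balances the geometric mean of the first $k$ classes
against class $k+1$), exposed through `ilr_basis()` and serializable to
plain text. Marginal back-transformed class RIs are insensitive to this
choice, which the test suite checks by refitting under a reversed-order
basis. Sampling zeros (possible below the 0.7% detection floor) are
replaced multiplicatively (`replace_zeros`) with a default
$\delta = 0.65 \times 1/150 \approx 0.0043$, deliberately below the
smallest observable nonzero frequency; non-zero parts are rescaled so the
composition stays closed.

## The model

For one response $y_i$ (log-WBC or one ilr coordinate) of individual $i$ in
population $j(i)$ captured on day-of-year $t_i$:

$$
y_i = \underbrace{\beta_0}_{\text{MESOR}}
 + \beta_c \cos\omega t_i + \beta_s \sin\omega t_i
 + \beta_\text{sex}\,F_i + \beta_\text{svl}\,z^{svl}_i
 + \beta_\text{lat}\,z^{lat}_i
 + (\text{cosinor} \times \{F, z^{svl}, z^{lat}\} \text{ interactions})
 + u_{j(i)} + \varepsilon_i
$$

with $\omega = 2\pi/365$ (day 1 = January 1, 365-day calendar; February 29
folds to day 60), $u_j \sim N(0, \sigma^2_{pop})$,
$\varepsilon_i \sim N(0, \sigma^2)$. The seasonal pair is the linearization
of the single-component cosinor
$A\cos(\omega t + \varphi)$ with $\beta_c = A\cos\varphi$,
$\beta_s = -A\sin\varphi$; `amplitude_phase()` recovers $A$ and $\varphi$
(and `extremum_days()` the calendar peak/trough) from any draw, so the
amplitude and acrophase have full posterior distributions. Sex is coded
0 = male, 1 = female: $\beta_\text{sex}$ *is* the female-minus-male
contrast. SVL and latitude (UTM northing) are standardized on the pooled
modeled sample; the centers and scales are stored in the fit and reused at
prediction time.

### Priors and sampling

Coefficients get $N(0, \text{precision} = 0.001)$ priors (sd ≈ 31.6 —
effectively flat on log/ilr scales; the precision parameterization follows
the convention of the BUGS-family samplers this protocol is usually run
with, since a literal sd of 0.001 would be an absurd spike at zero).
The precisions $1/\sigma^2$ and $1/\sigma^2_{pop}$ get
$\text{Gamma}(0.001, 0.001)$ priors — the conventional conjugate
formulation on precisions (mean 1, variance 1000), chosen over priors on
the sd scale and recorded here because the two are not equivalent.

Under these priors every full conditional is conjugate, so `gibbs_lmm()`
runs an exact blocked Gibbs sampler: $(\beta, u)$ are drawn jointly from
their multivariate-normal full conditional — blocking matters, because
updating $\beta_0$ and the $u_j$ separately leaves a nearly flat direction
(add a constant to $\beta_0$, subtract it from every $u_j$) that mixes
very slowly — then the two precisions from their gamma conditionals. There
is no tuning, draws are reproducible bit-for-bit from the seed (chain $c$
uses `seed + c - 1`), and mixing is near-independent (effective sample
sizes typically ≥ 70% of the draw count). The default protocol is 3 chains
of 10,000 retained draws; convergence is declared when every split
$\hat R < 1.01$ and every effective sample size ≥ 400 (`check_convergence`;
failures warn and attach a worst-first report, never pass silently).

As an independent check, the test suite compares posterior means against
the REML optimum from `lme4::lmer` on the same design — a completely
separate likelihood-based route to the same estimand under flat priors.

## Reference intervals and derived quantities

The RI for a variable is the **mode and central 95% interval of the
posterior predictive distribution** for a new individual at a reference
profile (given sex, average size and latitude, seasonal terms at the
MESOR), back-transformed to the measurement scale: `exp` for log-WBC;
joint ilr inversion for the differential, pairing the four coordinate
models draw-by-(chain, iteration) — the coordinate models are fit
independently, so some pairing convention is unavoidable, and index
pairing is the one implemented and documented. By default the predictive
includes a freshly drawn population effect (`new_population = TRUE`),
because an RI is meant to apply to an individual from *any* population; a
within-population mode exists for local screening. The mode is estimated
by a Gaussian kernel density (Silverman's bandwidth, 512-point grid over
the sample range) — pinned by tests against analytic normal and log-normal
cases; bounds are empirical percentiles. Prediction intervals (new
individual: parameter + population + residual variance) are deliberately
distinct from credible intervals (parameters only); both appear in the
outputs.

Derived outputs mirror the quantities such a study reports: draw-wise
female-minus-male contrasts of MESOR/amplitude/phase with $P_{\beta>0}$
(`sex_contrasts`, `contrast`), phase contrasts in days wrapped to
$(-\tau/2, \tau/2]$, the probability that the seasonal displacement
exceeds the RI half-width (`amplitude_vs_ri`), observed fractions outside
the RI (`observed_exceedance_fraction` — leukocytosis screening), the
among-population share of unexplained variance
$\sigma^2_{pop}/(\sigma^2_{pop}+\sigma^2)$ computed draw-wise
(`variance_fraction`), and the heterophil:lymphocyte stress index
(`hl_ratio`).

## The synthetic cohort generator

No raw cohort is distributed, so validation is by parameter recovery on
synthetic cohorts that replicate the study design (`simulate_cohort`):
794 individuals (498 males, 296 females) in 54 populations — 30 northern,
14 central, 10 southern sites on a UTM-northing gradient spanning the
Italian range (populations' latitudes are drawn uniformly within regional
bands, an assumption made for simulation only since per-site coordinates
are not published). Capture days are uniform within the regional windows
(February 13–October 6 north, April 2–August 15 center, April 27–September
5 south). SVL is truncated normal per sex: males mean 63.6 mm on
47.1–79.4 mm, females 59.4 mm on 43.5–76.2 mm, with sds (≈ 4.5 / 5.2 mm)
chosen so the standard error at the design sample sizes matches the
printed ± 0.2 / 0.3 mm (the study prints SEs, not sds). Per-site sample
sizes use a right-skewed log-normal-weight allocation with a floor of two
individuals of each sex per site, matching the reported "on average 10 ± 2
males (range 2–77), 9 ± 1 females (range 2–38)".

Default generating parameters (`default_true_params`) sit at the order of
the reported effects: log-WBC MESOR $\log(5360) \approx 8.59$; male
seasonal trough on day 138 (May 18) with amplitude 0.25 on the log scale,
females wider (0.45) and a week later; female baseline +0.12; latitude
slope +0.10 per SD; total unexplained sd 0.52 (the width implied by the
reported WBC interval) split so the among-population share is 57%. The ilr
coordinates use the ilr image of the modal male differential
(83.4, 1.1, 2.7, 2.5, 2.0)% as MESOR, amplitude 0.10 peaking near
mid-June, moderate sex/size/latitude effects, and an even
population/residual variance split. All are plain list entries and can be
overridden.

`simulate_smears` closes the loop at the counting stage: fields accumulate
Poisson cell counts until the stopping rule is met, then tallies are
multinomial in the individual's true differential, so
`estimate_wbc`/`differential_from_counts` can be validated against known
truth.

What the generator does **not** emulate: real spatial autocorrelation
beyond the latitude trend, year effects (the source design pools a decade),
recaptures, disease states (beyond an optional contamination fraction that
inflates WBC three-fold), measurement error in SVL or dates, and
non-Gaussian residuals. Passing recovery tests therefore demonstrate the
estimator is correct *under its own assumptions*, not that those
assumptions hold in any particular field dataset.

## Numerical choices and problem sizes

* Day-rounding of extrema is half-up (a 182.5-day trough offset reports as
  183); peak/trough always differ by 182–183 days after wrapping.
* `ilr_inv` subtracts the row maximum before exponentiating, so extreme
  coordinates cannot overflow; closure absorbs the shift.
* Posterior modes use `stats::density` (`bw = "nrd0"`, n = 512) restricted
  to the sample range; constant samples short-circuit to that constant.
* Ties at exactly zero in sign-probability contrasts split 0.5/0.5.
* The test and validation suites run the sampler at 3 chains × 400–600
  retained draws after 150–300 burn-in (the blocked sampler's near-iid
  mixing makes this adequate for interval estimates; the shipped default
  remains 10,000/chain), recovery experiments use 20 replicates at the
  full design scale (54 populations, 794 rows), coverage experiments ~800
  fresh individuals, and analytic checks of the mode/percentile estimator
  use $10^6$ samples.
* `run_pipeline` derives every stage's seed from the single run seed, and
  reruns with the same config produce byte-identical tables; the manifest
  (config + seed + versions) makes a run reproducible from its outputs.

## Limitations

* The four ilr-coordinate models are independent by design; joint
  back-transformation relies on index pairing, and cross-coordinate
  residual correlation is not modeled.
* The model has no sex-specific size or latitude main-effect slopes — only
  the seasonal terms interact with sex/size/latitude — so sex differences
  in those slopes fold into the residual.
* RIs assume the fitted covariate ranges; profiles outside them warn and
  extrapolate.
* Variance-fraction summaries use draw-wise ratios; summaries of posterior
  means of the variances would differ slightly for skewed posteriors.
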