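---
title: "Model-based synthetic estimation of regional suicide risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based synthetic estimation of regional suicide risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the method

Suicide is rare (on the order of 5--30 deaths per 100,000 person-years) but
strongly patterned: risk differs by sex, by individual clinical history, and
— substantially — between health regions. Health administrative data
(physician claims, hospital discharges, drug plans, vital statistics) record
the individual-level antecedents; policy planners, however, need *regional*
risk forecasts to direct prevention resources.

`regionrisk` implements the model-based synthetic estimation approach to
this problem in three stages.

**1. Sex-specific case-control logistic models.** Because the outcome is
rare, models are developed on all suicide cases plus a fraction $f$ (by
default 1%) of living individuals sampled per calendar year, each control
used at most once. Candidate predictors are binary lookback-window
indicators ("any event of this type in the $w$ months before the index
date", $w \in \{3, 6, 12, 24, 36, 48, 60\}$), continuous covariates (age,
comorbidity score, regional mental-health budget) and ordered deprivation
quintiles. Development proceeds as: LASSO screening (penalty by
cross-validated deviance), a correlation filter that flags pairs with
$|r| \ge 0.60$ and keeps the higher-priority member, then backward
elimination on an information criterion (AIC by default, BIC reported).
Discrimination is summarized by the C statistic (concordance probability,
with a DeLong-type interval) and calibration by the Brier score and decile
calibration bins.

**2. Intercept correction.** Case-control sampling leaves slope estimates
consistent but inflates the intercept by $\ln(1/f)$. Before any
population-scale prediction the intercept is shifted:
$\beta_0^{\mathrm{pop}} = \beta_0^{\mathrm{cc}} + \ln f$. With $f = 0.01$
the shift is $-\ln 100 \approx -4.6052$. The pipeline uses the *realized*
sampling fraction (controls drawn over eligible person-years), which also
absorbs the slight eligible-pool depletion caused by the only-once control
rule (under 1% over nine years at $f = 0.01$).

**3. Synthetic estimation.** For each region, year and sex, every binary
predictor is aggregated to the within-region proportion and every
continuous predictor to the within-region mean, evaluated for the *whole*
population of the region-year (not the outcome-enriched sample) at a common
December 31 reference date. The regional logit is
$\eta_r = \beta_0^{\mathrm{pop}} + \beta^\top \bar{x}_r$, and
$\mathrm{expit}(\eta_r) \times 10^5$ is the regional rate per 100,000.
Forecast quality is scored against observed regional rates by MAE, RMSE
(reported per 1,000 population by default; the unit is switchable and
always recorded in the report) and the overlap of the top-5 predicted and
observed high-risk regions, with rate ties broken deterministically by
region identifier.

```{r, eval = FALSE}
library(regionrisk)
cfg <- population_config(n_persons = 500000, seed = 1)
res <- run_pipeline(cfg)          # simulate, sample, screen, fit, validate
res$models$male                   # coefficient table, C statistic, Brier
res$report                        # MAE / RMSE / top-5 overlap by year & sex
```

## The synthetic world

No suitable person-level data can be redistributed, so the package ships a
generator whose defaults encode the study conditions the methods target:

* **Scale and period.** A closed cohort aged 15+ across 18 health regions,
  observed 2002--2019, with development years 2002--2010 and validation
  years 2011--2019.
* **Outcome schedule.** Male suicide rates decline linearly from 27 to 20
  per 100,000 over the period; female rates hold at 6.5 per 100,000. The
  per-sex-year intercept is solved numerically so the simulated marginal
  rate matches this schedule given the covariates.
* **Latent severity.** Each person carries a latent severity
  $z \sim N(\mu_r, 1)$ whose regional mean $\mu_r$ is the covariate-mediated
  region effect. All event processes load on $z$, which (a) induces the
  positive correlations among clinical predictors that make the $\ge 0.60$
  correlation filter meaningful and (b) produces strong regional rate
  variation through the covariates alone — roughly 11 to 175 per 100,000
  in males and 3 to 95 in females across the default regions, a spread of
  the same order as published regional variation. Two regions are large
  and urban (34% of the population together), most are mid-sized, and the
  highest-severity regions are small (1--3% each).
* **Event histories.** Eight event types (hospitalized suicide attempt,
  mental-health and physical emergency visits, psychiatrist and GP
  contacts, mood/anxiety, substance-use and respiratory diagnoses) occur as
  dated yearly events with probability $\mathrm{expit}(a_e + \lambda_e z)$,
  starting five years before the first study year so 60-month windows are
  fully observable from year one. True coefficients mirror the magnitudes
  of published sex-specific models (e.g. 1.88 for a hospitalized suicide
  attempt within 60 months in males). Deprivation quintiles, extra window
  widths and extra event types are carried as true-null candidates so that
  variable screening has something real to do.
* **Missingness.** Per-variable missingness is injected at feature-building
  time at rates between 0.87% and 4.12% (the documented range for this kind
  of administrative data), and resolved by complete-case analysis by
  default; mean/mode imputation is available.

What the generator deliberately does **not** emulate: real geography or
demography, diagnosis coding and its derivation, secular drift in covariate
distributions (the male decline is intercept-driven), deaths from other
causes, and migration between regions. Passing tests therefore demonstrate
the statistical machinery — not that any particular real population behaves
this way.

## Numerical and design choices

* **Windows are half-open**: an event exactly at `index_date` counts, one
  exactly $w$ months earlier does not; month arithmetic rolls back
  impossible dates (Dec 31 − 3 months = Sep 30). Cases take their outcome
  year's December 31 reference date as index date (the same clock the
  generative model uses); controls receive a uniformly random index date
  within their sampling year.
* **Outcome assessment is annual** at December 31. Regional aggregation
  uses the same fixed reference date for everyone, per region-year (not
  pooled over the period), so sub-annual windows are well defined for a
  population.
* **Deprivation groups are quintiles** (five groups, configurable), mapped
  against reference-distribution cut points; group 1 is the most
  privileged, out-of-range scores clamp to the extreme groups.
* **Correlated pairs** are resolved by an explicit caller-supplied priority
  order — the reproducible stand-in for the judgment call about clinical
  and policy utility; constant columns (undefined correlation) are reported
  separately, never dropped silently.
* **Backward elimination** accepts the removal that most decreases the
  criterion and stops otherwise, so the accepted-step criterion sequence is
  non-increasing by construction; the full trace is stored on the model.
* **Calibration bins** rank by predicted risk with a stable sort (ties keep
  row order), so constant predictions degrade gracefully to a row-order
  partition.
* **Serialization**: coefficient tables are CSV with `# key: value`
  metadata headers, a terminal `Constant` row, display odds ratios rounded
  to 2 decimals, full-precision coefficients, typographic minus signs
  normalized on ingest, and atomic write-then-rename semantics.
* **Problem sizes.** The shipped tests exercise the full pipeline at
  500,000 persons over 18 years and parameter recovery with 50 replicates
  of 200,000 persons over 3 study years — sizes chosen to make binomial
  noise small relative to the effects under study while staying desk-scale.

## Known limitations

* **The Jensen gap.** Evaluating the inverse logit at mean covariates is
  not the mean of individual risks; with the generator's deliberately
  strong individual-level heterogeneity the synthetic estimator
  underpredicts absolute levels (by roughly $e^{\sigma^2_\eta/2}$ in the
  rare-outcome regime). Regional *ranking* — the decision-relevant output —
  is much less affected, and `jensen_gap_diagnostic()` quantifies the gap
  per region. Close absolute agreement on real data implies low
  within-region dispersion of the linear predictor; the package reports
  both absolute differences and ranking overlap so either regime is
  visible.
* **One intercept per model.** A single fitted intercept averages the
  training years; a secular trend not carried by the covariates (as in the
  default male world) shifts validation-year levels while leaving
  within-year regional comparisons intact.
* **Controls can pre-date cases.** The generator makes a control's later
  outcome impossible by construction; the sampler does not exclude
  future cases. This mirrors the ambiguity in the design it emulates and is
  flagged rather than resolved.
* Uncertainty intervals for regional estimates, spatial smoothing and
  shrinkage across regions are out of scope.
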