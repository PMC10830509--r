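# coralcomp

Analysis of larval settlement-competency time series in broadcast-spawning
corals.

Reef recovery, population connectivity and restoration planning all hinge on
two early-life-history parameters that are unknown for most coral species:
the **precompetency period** (the time between fertilization and the onset of
the ability to settle) and the **competency window** (how long that ability
lasts within the pelagic larval duration). Both are estimated from repeated
24-h settlement assays, in which replicate wells of ~10 larvae are offered a
settlement cue (filtered-seawater control, live crustose coralline algae
(CCA), CCA extract, GLW-amide peptide, biofilmed disc, or conditioned reef
rubble) at a series of larval ages, and the settled larvae are counted.

`coralcomp` provides the full analysis pipeline for such assays, plus a
synthetic-data generator with known ground truth so every estimator can be
validated by parameter recovery. It is aimed at larval ecologists and
restoration practitioners working with well-plate settlement assays.

## Models

**Time to competency (TC50).** Well-level settlement proportions are
binarized at a threshold τ (default 0.3): a well is *competent* when
`n_settled / n_larvae ≥ τ`. Competency is then modelled against larval age
`t` (days after fertilization) per settlement cue `c` by Bayesian logistic
regression

```
  competent ~ Bernoulli(p),   logit(p) = α_c + β_c t
```

with weakly-informative priors (Normal(0,5) intercepts after age-centring,
Normal(0,2.5) slopes, half-Normal(0,2) SDs for cohort-level varying
intercepts when ≥2 cohorts are present). The age at which the cohort is more
likely competent than not,

```
  TC50_c = −α_c / β_c        (per posterior draw; β_c ≤ 0 ⇒ beyond the assay)
```

is reported as the posterior median with a 95% credible interval, swept over
thresholds 0.1–0.9, and contrasted between cues by exceedance probabilities.
Sampling uses 3 chains × 6000 iterations (warm-up 2000, thin 10) with
split-R̂ / ESS diagnostics.

**Settlement through time.** Raw settlement counts are modelled by a
Bayesian binomial GAM: a cubic regression spline of age (≤5 knots at age
quantiles) conditional on cue, with a varying effect of well plate by age.
Each posterior draw's curve is integrated (trapezoid rule, 100-point grid)
to an area under the curve (AUC), and cues are ranked by pairwise AUC
exceedance probabilities into strings such as `Rubble > CCA = Disc >
Control`.

**Species-level summaries.** TC50s are classified into short (<3 d), mid
(3–5 d) and long (>5 d) precompetency classes; TC50 is regressed on average
oocyte diameter (Gaussian GLM/OLS); passive transport distance is
`speed × 86400 × days`; and a competency×survival dispersal-potential curve
uses exponential survival `exp(−0.05 t)`.

A 21-species TC50/oocyte-diameter summary table is packaged
(`table1_fixture()`).

## Worked example

```r
library(coralcomp)

summarize_species_table(table1_fixture())
#> Species-level competency summary (n = 21 )
#>   mean TC50 4.0 d; earliest Gret (2.1 d); latest Aaus (6.2 d)
#>   classes: short 3 (14%), mid 15 (71%), long 3 (14%)

egg_size_regression(table1_fixture())
#> TC50 ~ oocyte diameter (n = 21): slope 0.003675 d/um, adj R^2 = 0.26, p = 0.011
```

The mean time to competency across the packaged species table is 4.0 days;
the earliest species reaches competency at 2.1 days and the latest at 6.2.
Larger eggs take significantly longer to reach competency (p = 0.011).

Fitting the competency model to a synthetic cohort with known truth
(control-curve onset 4 d, slope 1.5 logit/d):

```r
pr  <- species_profile(species_id = "SynA")
obs <- simulate_assays(pr, assay_design(), seed = 1)
rec <- binarize_competency(obs, threshold = 0.3)
fit <- fit_competency_model(rec, sampler_config(seed = 1))
tc50_from_draws(fit, "Control")
#>   species_id     cue threshold tc50_median ci_lower ci_upper truncated
#> 1       SynA Control       0.3       3.033     2.42     3.59     FALSE
```

The well-level truth for the control (plate effects integrated out) is 3.39
days, inside the credible interval. Strong cues such as rubble induce
settlement before the first assay day, so their TC50 is unidentified from
below — visible as a wide lower credible bound, exactly as such estimates
behave on real assay series.

```r
transport_distance(10, 4)   # cm/s, days
#> 34.56   (~35 km of additional transport for a 4-day precompetency delay)
```

The end-to-end pipeline (`run_pipeline(run_config(...))`, or the
`inst/cli/coralcomp` script with subcommands `simulate`, `fit-tc50`,
`sweep`, `fit-gam`, `rank-cues`, `classify`, `summarize`, `regress-egg`,
`transport`, `dispersal`, `run-all`) writes TC50 tables, threshold sweeps,
settlement curves, AUC posteriors, cue rankings, dispersal curves,
diagnostics and a JSON manifest.

## Vignette

`vignettes/settlement-competency-methods.Rmd` documents the models and their
assumptions, all tunable parameters with defaults and units, what the
synthetic generator does and does not emulate, numerical choices, and known
limitations.
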