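---
title: "Methods: modelling coral larval settlement competency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling coral larval settlement competency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralcomp)
```

## The data and the scientific questions

A settlement assay series offers replicate wells of coral larvae (nominally
10 per well, 6 wells per treatment) a candidate settlement cue at a sequence
of larval ages, scoring each well 24–36 h later for the number of settled
larvae. From such series we want three things: the **precompetency period**
(when does the cohort acquire the ability to settle), the temporal shape of
settlement through the **competency window**, and a ranking of **cue
effectiveness** per species.

## Cohort competency and TC50

### Binarization

A well is scored *competent* when its settled proportion reaches the
settlement threshold τ: `n_settled / n_larvae ≥ τ`, default τ = 0.3. The
comparison is inclusive: with 10 larvae, exactly 3 settled counts as
competent. The threshold marks physiological capability, not realized
settlement — 30% settling is taken as evidence the cohort *can* settle even
if many larvae choose not to. Strict comparison is available
(`inclusive = FALSE`); with the nominal 10-larvae wells the two differ only
at exactly 3/10. Wells with zero larvae loaded are rejected with a warning.

### The logistic competency model

Per species, competency is modelled against larval age `t` (days after
fertilization, the age at assay set-up) and settlement cue `c`:

$$\text{competent}_i \sim \text{Bernoulli}(p_i), \qquad
  \operatorname{logit}(p_i) = \alpha_{c(i)} + \beta_{c(i)}\, t_i$$

With two or more larval cohorts, cohort-level varying intercepts
$u_k \sim N(0, \sigma_u^2)$ are added; with a single cohort (the common
case) the model reduces to fixed cue-specific intercepts and slopes. No
plate effect enters this model — plate dependency is handled in the
settlement-through-time GAM, where the raw proportions (not a cohort-level
binarization) make it identifiable.

**Priors.** The analysis tradition this package follows left priors
unstated (package defaults of the original software). We state ours:
Normal(0, 5) on intercepts after centring age, Normal(0, 2.5) on age slopes,
half-Normal(0, 2) on hierarchical SDs. They are weakly informative at the
logit scale of desk-sized assays: wide enough not to move well-identified
estimates, strong enough to regularize complete separation (which arises
routinely when a strong cue induces settlement at every assayed age). Age
centring keeps the intercept prior meaningful; draws are transformed back to
the natural scale before reporting, so `TC50 = −α/β` holds per draw.

**Sampling.** Default settings are 3 chains × 6000 iterations, warm-up
2000, thinned at rate 10 (400 retained draws per chain). The sampler is an
independence Metropolis–Hastings with a multivariate-t (df 5) proposal built
from the Laplace approximation at the posterior mode, re-moment-matched to
the warm-up draws and then frozen (so the retained chain is a valid,
non-adaptive MCMC with the exact likelihood as target). For single-cohort
fits the posterior factorizes exactly over cues and each cue's (α, β) block
is sampled separately, which keeps acceptance high (~0.7) and effective
sample sizes close to the retained draw count. This replaces the original
NUTS machinery, which is not available here; for these smooth 2-to-15
dimensional posteriors an exact-likelihood independence sampler is both
simpler and easy to diagnose. Split-R̂ and ESS (Geyer initial-monotone
autocovariance sums on split chains) are computed per parameter; the default
health criterion is R̂ < 1.01 and ESS > 400.

### TC50 extraction and truncation

Per draw, `TC50 = −α/β` when β > 0 — the age at which the fitted competency
probability crosses 0.5. Draws with β ≤ 0 never cross 0.5 from below and
are mapped to +∞ rather than given an invented value; the reported estimate
(posterior median and central 95% interval, computed by an
infinite-value-aware quantile) is flagged `truncated` when the median
exceeds the extent of the experiment. Negative TC50s are reported as-is:
they mean the cohort was already competent before the first assay, so the
crossing age is unidentified from below (the credible interval shows this
honestly).

### Threshold sweep and cue contrasts

The sweep re-binarizes the raw observations at each τ in 0.1–0.9 (step 0.1)
and refits; on monotone latent truth TC50 is non-decreasing in τ. A "Best"
pseudo-cue reports the non-control cue with the earliest median per
threshold (the control is a baseline, not an inducer; ties break
alphabetically for determinism). Cue contrasts are exceedance
probabilities: entry (A, B) is the fraction of paired draws with
`TC50_A < TC50_B`, ties counting ½ — which preserves
`M[A,B] + M[B,A] = 1` exactly, including when both draws are +∞.

One wording ambiguity is resolved here: "days to >0.5 settlement
probability" is interpreted as the posterior competency-probability curve
crossing 0.5 (the logistic inflection), not as raw settlement exceeding
50%.

## Settlement through time (binomial GAM)

Raw counts are modelled as
`n_settled ~ Binomial(n_larvae, p)`, `logit(p) = cue + f_cue(age) + plate
terms`, where `f_cue` is a cubic regression spline of age per cue with
knots at empirical age quantiles, capped at 5 (requests above the cap or
above the number of distinct ages are reduced/warned). The "varying effect
of well plate by age" is a plate-level random intercept plus random linear
age slope — the minimal structure consistent with six-well-plate
dependency.

**Estimation.** Smoothing and random-effect variances are estimated by REML
with `mgcv` (empirical Bayes), and coefficient uncertainty is drawn from
the Bayesian posterior of the penalized fit, N(β̂, V_p) — the standard
posterior-simulation route for penalized GLMs. A full MCMC over the ~150
coefficients (mostly plate effects) was tried and rejected: independence
samplers are hopeless at that dimension (acceptance ~10⁻³), and nothing in
the downstream quantities (population-level curves and their AUCs) is
sensitive to the difference, as the parameter-recovery tests show. Draws
are organized into chains per `sampler_config()` so the same diagnostics
apply.

**Curves and AUC.** Fitted curves are population-level: plate random
effects are marginalized at their zero mean (the hierarchical predictor
alternative is noted but not used). Extrapolation beyond the observed age
range is refused. Each draw's curve is integrated on the response
(probability) scale — areas have units of proportion-days and are bounded
by the age range — by the trapezoid rule on a uniform grid of `resolution`
points (default 100). Trapezoid is exact for affine integrands and within
10⁻³ relative of a 100× finer grid on the smooth curves arising here; both
properties are tested.

**Ranking.** Cues are ordered by median AUC; adjacent cues are joined with
"=" when the exceedance probability of the higher over the lower is below
the cutoff, and separated by ">" otherwise, chaining ties transitively. The
cutoff is not stated in the reporting tradition; the default is 0.95,
configurable, and recorded with every ranking.

## Species-level summaries

* **Classes:** short < 3 d, mid 3–5 d (inclusive on both ends), long > 5 d.
  The source texts disagree at the boundary (one variant uses "short ≤3");
  no species table value equals 3.0 exactly, so the classifications
  coincide; boundaries are configurable.
* **Egg-size regression:** Gaussian GLM with identity link = OLS, solved by
  the normal equations (exact, dependency-free), with adjusted R² =
  1 − (1 − R²)(n−1)/(n−2) and a two-sided slope t-test on n − 2 df.
* **Transport:** `km = speed[cm/s] × 86400 × days / 10⁵`, displayed to the
  nearest km.
* **Dispersal potential:** survival `exp(−r t)` with default decay r = 0.05
  per day, multiplied pointwise by any competency curve in [0, 1]. The
  conceptual figure this mirrors is explicitly an illustration, so the
  function takes an arbitrary competency curve rather than encoding one.

## The synthetic-assay generator

The generator states a ground truth and simulates the design the analysis
assumes: a logistic competency onset (baseline onset age, slope in logit
units/day), additive cue shifts on the logit scale, an asymptote (maximum
settlement proportion), an optional multiplicative temporal envelope
`1 + Σ Gaussian bumps` clipped to [0, 1] (negative amplitudes create the
mid-series troughs seen in long assay series), and plate-level random
intercepts and age-slopes applied on the logit scale of the well
probability. Defaults: onset 4 d, slope 1.5 logit/d, asymptote 0.9, cue
shifts Control 0 < Peptide 0.8 < Extract 1.2 < Disc 1.8 < CCA 2.5 < Rubble
3.0, plate SD 0.3, plate-slope SD 0.05, 6 wells × 10 larvae per
cue×timepoint, assays at days 2–14. These are the design values of the
assay tradition where stated (10 larvae, 6 wells, 6 cues, assays from day
2); where unstated (cue shift sizes, plate SDs, the control's spontaneous
settlement level) they are fixed once at values a larval ecologist would
call typical — e.g. the control's baseline gives ~4% settlement at day 2,
making spontaneous settlement present but rare, and rubble the strongest
cue. Larvae per well can be Poisson-jittered to emulate limited larval
availability.

The generator's true "onset age" is a property of individual larvae; what
the competency model estimates is the age at which a *well* of n larvae
reaches the threshold with probability 0.5. `true_competency_age()`
computes that quantity independently — root-finding on the binomial tail
probability with plate effects integrated out by equal-weight normal
quadrature (32 nodes per dimension) — and is the oracle for the
parameter-recovery tests.

**What a green test establishes, and what it does not.** The generator
emulates binomial sampling, plate dependency, cue effects, onset logistics
and multimodal envelopes. It does not emulate: larval mortality or
exhaustion of cultures (real series end when larvae run out), drift in cue
inductivity as substrates condition, between-cohort variation beyond a
shared intercept shift, or choice behaviour (wells offer a single cue).
Recovery on synthetic data therefore validates the estimators' arithmetic
and calibration under the stated model, not the model's adequacy for any
particular real dataset.

## Numerical choices

* Independence-MH proposal: multivariate t, df 5, covariance inflated ×1.3;
  adaptation uses the second half of warm-up and requires ≥25 warm-up
  acceptances, else the Laplace proposal is kept. Optimization starts at 0
  (log-SD at log 0.5) with BFGS, reltol 10⁻¹².
* Non-positive-definite Hessians are repaired by eigenvalue clamping at
  10⁻⁸ of the largest magnitude.
* Quantiles of draw vectors containing +∞ use a type-7 rule that returns
  +∞ whenever the interpolation touches an infinite order statistic
  (avoiding NaN from `0 × ∞`).
* Stage seeds derive from one global seed by a fixed affine map into
  [1, 2³¹ − 2], so adding a pipeline stage never perturbs earlier stages.
* Degenerate inputs: constant ages refuse a spline basis; < 3 distinct
  timepoints refuse a GAM; a single plate drops the varying effects with a
  warning; a single chain reports R̂ as undefined rather than guessing.
* CSV dialect is fixed (comma, ".", no quoting of plain labels) so
  simulated fixtures round-trip byte-identically.

## Known limitations

* TC50 below the first assay age is unidentified from below; the package
  reports the resulting wide or negative lower bounds rather than censoring
  them. Designs should start assays before expected onset when possible.
* The GAM's coefficient posterior is a Gaussian approximation conditioned
  on REML variance estimates; hyperparameter uncertainty is not propagated.
* Exceedance-based ranking strings depend on the chosen cutoff and on draw
  count; with few draws the "=" / ">" boundary is itself uncertain.
* The dispersal-potential model is deliberately schematic (exponential
  survival, no hydrodynamics); it is a lens for comparing species, not a
  dispersal simulation.
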