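---
title: "An integrated multi-state and age-at-death survival model for monitored carnivore populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated multi-state and age-at-death survival model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynxmark)
```

## Scope and data model

`lynxmark` estimates age- and sex-specific annual survival of individually
identifiable carnivores from four data streams collected by long-running
monitoring programmes: systematic camera-trap sessions, opportunistic
pictures and chance observations, live captures with VHF/GPS telemetry, and
dead recoveries — plus an independent sample of carcasses whose age at death
is known from the birth year. The motivating system is the reintroduced
Eurasian lynx, whose demographic year (the "lynx year") runs from 1 May to
30 April; all occasion grids, age-class transitions and random year effects
align to it.

Preprocessing applies a fixed set of rules before any model sees the data:

* Detections and recoveries are binned into half-open 1- or 2-month
  occasions within lynx years. Several detections of one animal in the same
  subarea and occasion collapse to one code; when detections span two
  subareas within an occasion, the chronologically last one wins and the
  conflict is logged (the underlying records do not say where the animal
  spent most of the interval, so some rule is needed; "last detection" is
  the package's declared choice).
* A dead recovery outranks a live detection in the same occasion: death is
  terminal, and the recovery fixes the latent state.
* Age classes: juvenile in the first year of life, subadult in the second,
  adult from the third. Animals without a known birth year are treated as
  adults from their first detection — a deliberate bias-variance trade-off,
  because most such animals first appear during winter surveys at an age
  that makes subadulthood unlikely.
* Identification from pictures requires matching left- and right-flank coat
  patterns. Unmatched single-side records form pseudo-individuals; among
  them the whole less-abundant side is deleted (ties delete the left side,
  a deterministic declared rule), both-flank individuals are never touched.
* Animals removed by translocation are censored at the capture date; if
  that capture is their first known record they are excluded outright.
  Animals seen outside the study population exactly once, with inside
  detections before and after, have the single outside record removed.
* Animals known only from their carcass enter the age-at-death sample, not
  the encounter histories (a history must start with a live detection).

## The multi-state process

Two layouts are supported. With two connected subareas the state space is
(1) alive subarea 1, (2) died-this-interval subarea 1, (3) alive subarea 2,
(4) died-this-interval subarea 2, (5) alive outside, (6) died-this-interval
outside, (7) dead before — with bidirectional movement between the subareas
and permanent one-way emigration to outside. The one-area layout collapses
to five states. Interval survival is annual survival powered by
`1/intervals_per_year`, so six 2-month (or twelve monthly) interval
survivals multiply back to the annual scale.

Mortality is assumed to happen **before** movement within an interval.
This is what makes the model identifiable with sparse recoveries: a carcass
is always found in the area where the animal started the interval, so the
died-this-interval columns of the transition matrix do not involve movement
parameters at all (a property the test-suite verifies by construction and
by comparing matrices under different movement values).

Linear predictors use the logit link:

* Survival: `b0[area, sex, age] + sigma_S * gamma[group, year]`, with the
  random-effect group being the subarea (two-subarea layout) or the age
  class (one-area layout, where among-year variance visibly decreases with
  age); outside survival is a single constant `b03`, because emigrants are
  rarely re-observed and their survival is a nuisance parameter.
* Detection: `a0[area, sex, age, telemetry] + a1*systmon + a2*(oppmon - 1)
  + sigma_p * eps[i]`. `systmon` is the monitored fraction of the occasion
  under a systematic survey (0–1); `oppmon` scores opportunistic effort on
  a 1–3 scale, entered centred at its baseline level 1 so intercepts are
  detection at baseline effort. Effort effects are shared between subareas.
  The individual effect absorbs heterogeneity from home ranges straddling
  borders, temporary migration, and — in the flank experiments — the halved
  encounter rate of single-flank pseudo-individuals. One telemetry
  intercept per area is shared across sex and age; in the one-area layout
  telemetry detection is fixed to probability 1 (collared animals are
  localised every occasion).
* Recovery: `d0[sex, age]` plus additive subarea offsets `d12`, `d13`
  (equal inside/outside in the one-area layout). The optional
  `recovery_age_structured = FALSE` collapses `d0` to one level per sex;
  see *Numerical behaviour* for why that matters in small samples.

Sex is latent for unsexed animals: the likelihood is a two-component
mixture with proportions `psi`, and observed sexes contribute their
categorical `log psi` term, so the sex ratio is informed by the data rather
than fixed. This marginal formulation is mathematically equivalent to
sampling a latent sex indicator but keeps the posterior smooth.

## Likelihood

The latent state sequence is marginalized by the forward algorithm,
conditioning on the state at first capture (no entry process is modelled;
occasions before first capture are skipped, trailing non-detections are
informative and retained to the end of the study, the recovery occasion, or
the censor cut). Per-occasion normalisation constants are accumulated in
log space; 200-occasion histories with probabilities at `1e-12` stay
finite. Covariates are indexed by the destination occasion: the transition
into occasion *t* uses age class, year and movement values at *t*, which
implements age-class changes taking effect at the first occasion of each
lynx year. The production path is a small C++ routine over per-individual
rate matrices; the generic R recursion (`forward_loglik`) is kept as the
reference implementation and the two are tested against each other and
against exhaustive path enumeration.

## Age-at-death model and integration

Ages at death of recovered carcasses (1–18 years; 18 is the cap, the oldest
recovery in the motivating system) follow a categorical distribution whose
cells derive from annual survival: the probability of dying in year *j*
given death within the cap is `prod(s[1:(j-1)]) * (1 - s[j])`, normalised.
Because carcass detection is not equal across ages, the integrated form
multiplies each cell by the age-specific recovery probability and
renormalises by `P`, the probability of dying *and being found* within the
cap — computed by a closed form whose adult part is a geometric series
(evaluated by its limit when adult survival is 1). When recovery is equal
across ages the correction cancels exactly; the tests assert this to
`1e-12`.

Integration means the two likelihood components share the age- and
sex-specific annual survival and the recovery parameters. The shared
survival is taken at the intercept (year-averaged) level. With two
subareas, survival and recovery are pooled across areas with weights
proportional to recovered-carcass counts (`pool_r = TRUE`), since the
carcass sample cannot be assigned to a subarea-specific schedule; this is a
package design choice and can be switched to unpooled.

## Fitting

*Maximum likelihood* maximises the data log-likelihood by BFGS on
unconstrained scales (log for standard deviations, stick-breaking logits
for each constrained movement pair, logit for the female proportion).
Random year effects are not estimable by plain maximisation and are
disabled; the individual detection effect is integrated out by 9-point
Gauss–Hermite quadrature with `sigma_p` estimated, the standard
mixed-model device.

*MCMC* samples the full posterior — marginalized likelihood, priors,
transform Jacobians — by componentwise adaptive random-walk Metropolis.
Proposal scales adapt in batches of 50 during warmup towards a 0.44
acceptance rate and are frozen afterwards, so the kept draws are from a
valid Markov chain. Priors: normal(0, 1.5²) on intercepts, normal(0, 0.5²)
on covariate coefficients, half-t(scale 1, df 2) on standard deviations
(the scale is configurable via `ms_priors()`; 1 is the package default),
uniform on each constrained movement simplex, flat Dirichlet on the sex
proportions, standard normal on the year and individual deviates
(non-centred parameterisation). Convergence is assessed by split-chain
R-hat and effective sample size computed from the pairwise-summed
autocorrelation sequence (initial monotone positive estimator); a fit whose
maximum R-hat exceeds the configured limit is flagged and warned about,
never silently returned. Posterior summaries are means with 2.5% and 97.5%
quantiles.

## The synthetic-data generator

`simulate_population()` generates complete datasets with the statistical
structure the analysis assumes: cohorts of juveniles entering at lynx-year
boundaries plus initial adults; latent states evolving by the transition
matrix (mortality before movement, permanent emigration); detections drawn
from the observation matrix with effort covariates (60-day winter
systematic sessions every 2–4 years per area, an opportunistic-effort
random walk on [1,3]), telemetry (collars fitted at a live capture, worn
for a configurable period), and normally distributed individual
heterogeneity on the detection logit; carcass recoveries; an independent
age-at-death
sample drawn from the recovery-corrected lifetime law; unknown sex and
unknown birth year at configurable fractions; translocation censoring; and
optional degradation to unmatched-flank pseudo-individuals. One seed drives
everything, and a fixed seed reproduces files byte for byte.

Default truth values mirror the magnitudes estimated for reintroduced
Alpine-type populations (adult survival ≈ 0.71–0.78, subadult ≈ 0.77–0.89,
juvenile ≈ 0.2–0.33, 2-monthly detection ≈ 0.1–0.4, monthly detection
≈ 0.4–0.7 in the small one-area population, recovery ≈ 0.02–0.33 varying
by area and age, about half of pictured animals unsexed). What the
generator does **not** emulate: spatial home ranges and edge effects,
litter structure and correlated sibling fates, individual heterogeneity in
survival, disease outbreaks or other shocks beyond the lognormal year
effect, and misidentification other than the flank-matching limit. Passing
recovery tests on these data therefore demonstrates correctness of the
estimator under the model's own assumptions — not robustness to the many
ways real monitoring data violate them.

The flank degradation deserves a note: each camera event photographs a
single flank with probability `mismatch_fraction`; an individual keeps its
identity only if some event captured both flanks or it was ever handled or
recovered. Matching is therefore *selective on observation length*, which
is the real mechanism behind the bias: animals dying young are
over-represented among split pseudo-individuals, so keeping all of them
biases juvenile survival downwards.

## Validation experiments

*Parameter recovery* uses a fixed, model-matched design: one-area monthly
layout, 3 lynx years (36 occasions), 60 initial adults + 30 juveniles per
year (150 individuals), truth S = 0.30/0.84/0.76 (juvenile/subadult/adult)
equal between sexes, monthly detection 0.5 inside and 0.05 outside,
recovery 0.2, annual emigration 0.10 (juveniles) and 0.02 (older), no year
or individual heterogeneity, no effort effects, a 100-carcass age sample,
half the individuals unsexed. A sex-pooled fixed-effect fit is correctly
specified here, so estimator bias is attributable to the estimator. Twenty
maximum-likelihood fits give the mean absolute error of adult survival;
three MCMC fits (3 chains, 400 warmup + 400 kept draws) check 95%-interval
coverage. These sizes keep a full validation run in minutes on one core;
they are stated here because they bound what the experiments can detect
(an S.E. of roughly 0.03–0.04 per replicate on adult survival).

*Flank sensitivity* degrades the same design (`mismatch_fraction = 0.8`, a
40-carcass age sample shared identically by both arms) and compares
juvenile survival between keeping all pseudo-individuals and applying the
deletion rule, paired by seed. The fit uses age-constant recovery —
matching the generating values — for the reason below. The expected
direction is a positive shift (deletion raises juvenile survival); its
magnitude at this scale is under one percentage point, much damped by the
shared age sample that anchors the juvenile schedule in both arms.

## Numerical behaviour and known limitations

* **A weakly identified corner.** With age-structured recovery and small
  samples, the corrected lifetime distribution admits a second mode:
  juvenile recovery near 1 with high juvenile survival reproduces a large
  age-1 carcass share almost as well as the truthful low-survival,
  moderate-recovery combination. The MCMC priors shrink this corner away;
  plain maximum likelihood can land in it. Where juvenile survival itself
  is the quantity of interest in a small maximum-likelihood fit, use
  `recovery_age_structured = FALSE` (if defensible) or MCMC.
* Movement pairs are estimated on a stick-breaking transform of the
  constrained simplex `m12 + m13 <= 1`; priors are uniform on the simplex
  (density 2), with the Jacobian applied on the sampling scale.
* The geometric term of the recovery probability `P` switches to its
  analytic limit within `1e-12` of adult survival 1.
* Emigration annualisation `1 - (1 - m)^intervals` ignores within-year
  mortality competition; documented as a simplification.
* The mean survival time of independent animals is the truncated discrete
  life expectancy from the start of the second year of life under the
  18-year cap — a package convention tested against cohort simulation, not
  against any externally printed value, because published "average survival
  time" figures rarely state their formula.
* Componentwise Metropolis is robust but not fast for models with many
  random effects; the full two-subarea model with year and individual
  effects mixes slowly at default test sizes, and the diagnostics will say
  so. A gradient-based sampler would be the natural upgrade.

## Session info

```{r}
sessionInfo()
```
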