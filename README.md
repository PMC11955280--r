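# lynxmark

Integrated multi-state mark–recapture and age-at-death survival estimation
for elusive, individually identifiable carnivores.

## The problem

Long-lived, secretive species such as the Eurasian lynx (*Lynx lynx*) are
monitored through a patchwork of data streams: systematic camera-trap
sessions in reference areas, opportunistic pictures, live captures,
VHF/GPS telemetry, and carcasses reported by the public and aged at
necropsy. None of these alone supports precise survival estimation over
decades, and naive estimators confound mortality with permanent emigration
and with detection failure. `lynxmark` implements an integrated model that
combines all of these streams in a single likelihood and returns **true**
(emigration-corrected) age- and sex-specific annual survival, written for
demographic analyses of reintroduced populations but applicable to any
species with individual identification and aged dead recoveries.

## The model

**Multi-state process.** Time is discretised into 1- or 2-month occasions
within demographic "lynx years" (1 May–30 April). The latent state of
individual *i* encodes location and fate: alive in subarea 1/2, alive
outside (after permanent emigration), died this interval in each area, and
an absorbing silent "dead before" state (7 states with two connected
subareas; 5 states for a single area). States evolve by a transition matrix
built from interval survival *s* = *S*^(1/6) (or *S*^(1/12)) and movement
probabilities *m₁₂, m₂₁, m₁₃, m₂₃*, with **mortality before movement**, so
carcasses are recovered where the interval started. Emissions are live
detections (probability *p*) for alive states and carcass recoveries
(probability *r*) for died-this-interval states.

**Linear predictors.** On the logit scale:
*S*: intercepts per area × sex × age class (juvenile / subadult / adult)
plus a random lynx-year effect σ_S·γ_v; *p*: intercepts per area × sex ×
age × telemetry status, effects of systematic (*systmon* ∈ [0,1]) and
opportunistic (*oppmon* ∈ [1,3]) monitoring effort, plus a random
individual effect σ_p·ε_i; *r*: sex × age intercepts with additive subarea
offsets. Sex is latent for unsexed animals via a two-component mixture with
proportions ψ.

**Age-at-death model.** Independently aged carcasses follow a categorical
lifetime distribution over ages 1–18,
θ_j ∝ ∏*s*₁..ⱼ₋₁(1−*s*ⱼ), corrected for age-dependent recovery:
θ_j = ∏*s*₁..ⱼ₋₁(1−*s*ⱼ)*r*ⱼ / P, where P is the probability of dying and
being found within 18 years. Survival and recovery parameters are **shared**
with the multi-state model, which is what identifies the correction.

**Inference.** The likelihood marginalizes latent states with the forward
algorithm (Rcpp fast path, log-space scaling) and latent sex analytically.
Fitting is by maximum likelihood (BFGS on unconstrained transforms;
individual effects marginalized by Gauss–Hermite quadrature) or by adaptive
componentwise Metropolis MCMC with the declared priors, with split-chain
R-hat and effective-sample-size diagnostics.

## Worked example

```r
library(lynxmark)

cfg <- sim_config("one_area", n_years = 6)        # small monthly-grid population
sim <- simulate_population(cfg, seed = 7)
bh  <- build_histories(sim$detections, sim$dead_recoveries,
                       sim$individuals, sim$grid)
spec <- ms_spec("one_area", n_years = 6, intervals_per_year = 12,
                year_effects = FALSE, individual_effects = FALSE)
ds  <- as_ms_dataset(bh$histories, sim$effort, sim$grid, spec)
fit <- fit_ms(ds, spec, fit_config("mle", seed = 1),
              ages_at_death = sim$ages_at_death)
print(fit)
```

```
ms_fit (mle): one_area layout, converged: TRUE
       parameter  mean q2.5 q97.5 rhat ess
 S[1,F,juvenile] 0.301   NA    NA   NA  NA
 S[1,F,subadult] 0.852   NA    NA   NA  NA
    S[1,F,adult] 0.652   NA    NA   NA  NA
 S[1,M,juvenile] 0.588   NA    NA   NA  NA
 S[1,M,subadult] 0.534   NA    NA   NA  NA
    S[1,M,adult] 0.799   NA    NA   NA  NA
```

The preprocessing report for the same run shows the cleanup bookkeeping
(112 simulated individuals, 81 usable histories, 20 never detected, 10 known
only from their carcass, 1 excluded because its first record was the
translocation capture), and `derived_report(fit)$survival_time` gives the
mean survival time of independent lynx, here 2.45 years (females) and
2.60 years (males) from a single moderately sized synthetic dataset — sex-
and age-specific estimates at this sample size carry wide uncertainty, which
is why the validation experiments below average over many replicates.

The `analysis/` directory holds the full workflow as numbered scripts:

1. `01_simulate.R` — generate the synthetic two-subarea and one-area datasets
2. `02_preprocess.R` — flank rule, record cleanup, occasion binning
3. `03_fit.R` — maximum-likelihood and MCMC fits with diagnostics
4. `04_derived.R` — annual survival per year, survival time, emigration
5. `05_experiments.R` — parameter-recovery and flank-sensitivity experiments

Each writes its tables under `results/`.

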