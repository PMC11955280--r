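#!/usr/bin/env Rscript
# Stage 3: fit the integrated model (multi-state encounter histories plus the
# recovery-corrected age-at-death sample sharing the same survival and
# recovery parameters).
#
# The one-area population is fitted both by maximum likelihood (fast point
# estimates; individual detection effects marginalized by quadrature) and by
# adaptive MCMC with year and individual random effects, priors as declared
# in the model spec, and split-chain R-hat / ESS diagnostics. The
# two-subarea population is fitted by maximum likelihood. Posterior-
# predictive detection and recovery counts are checked for the MCMC fit.

library(lynxmark)

run_one <- function(pop, mode, mcmc = list()) {
  cfg_dummy <- NULL
  res <- run_pipeline(data_dir = file.path("results", paste0("data_", pop)),
                      seed = 20260402L, mode = mode, mcmc = mcmc,
                      sex_structured = TRUE)
  res
}

cat("== one-area population, maximum likelihood ==\n")
res_mle <- run_one("one_area", "mle")
print(res_mle$fit)
write.csv(res_mle$fit$summary, "results/fit_one_area_mle.csv",
          row.names = FALSE)

cat("\n== one-area population, MCMC (reduced chains for illustration) ==\n")
res_mcmc <- run_one("one_area", "mcmc",
                    mcmc = list(chains = 3L, warmup = 200L, draws = 200L))
print(res_mcmc$fit)
bad <- subset(res_mcmc$fit$summary, !is.na(rhat) & rhat > 1.05)
cat(sprintf("parameters with r-hat > 1.05: %d of %d\n",
            nrow(bad), nrow(res_mcmc$fit$summary)))
write.csv(res_mcmc$fit$summary, "results/fit_one_area_mcmc.csv",
          row.names = FALSE)
ppc <- posterior_predictive_check(res_mcmc$fit, res_mcmc$dataset,
                                  n_rep = 30, seed = 20260403L)
cat(sprintf("posterior predictive: observed %d detections / %d recoveries; upper-tail p = %.2f / %.2f\n",
            attr(ppc, "observed")[1], attr(ppc, "observed")[2],
            attr(ppc, "p_upper")[1], attr(ppc, "p_upper")[2]))

cat("\n== two-subarea population, maximum likelihood ==\n")
res_two <- run_one("two_subarea", "mle")
print(res_two$fit)
write.csv(res_two$fit$summary, "results/fit_two_subarea_mle.csv",
          row.names = FALSE)
cat("fit summaries written under results/\n")
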