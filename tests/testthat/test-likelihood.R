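# Forward-algorithm likelihood: oracle equivalence, sex mixture, additivity,
# emission completeness, numerical stability, and agreement between the
# generic recursion and the structured fast path.

test_that("forward recursion conditions on first capture and handles a direct death", {
  rr <- random_rates("two_subarea")
  T_ <- build_transition_matrix(rr$s, rr$m, "two_subarea")
  O <- build_observation_matrix(rr$p, rr$r, "two_subarea")
  expect_equal(forward_loglik(1L, list(T_), list(O)), 0)
  # alive sub1 then recovered dead sub1: log[(1 - s1) r1]
  ll <- forward_loglik(c(1L, 2L), list(T_), list(O, O))
  expect_equal(ll, log((1 - rr$s[1]) * rr$r[1]), tolerance = 1e-12)
  # impossible: detection after dead recovery
  bad <- forward_loglik(c(1L, 2L, 1L), list(T_, T_), list(O, O, O))
  expect_identical(unclass(bad)[1], -Inf)
  expect_match(attr(bad, "diagnostic"), "impossible")
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(101)
  for (lay in c("two_subarea", "one_area")) {
    for (k in 1:60) {
      rr <- random_rates(lay)
      T_ <- build_transition_matrix(rr$s, rr$m, lay)
      O <- build_observation_matrix(rr$p, rr$r, lay)
      L <- sample(2:4, 1)
      y <- random_codes(lay, L)
      f <- forward_loglik(y, rep(list(T_), L - 1), rep(list(O), L))
      e <- enum_loglik(y, rep(list(T_), L - 1), rep(list(O), L))
      if (is.finite(f) || is.finite(e)) {
        expect_lt(abs(f - e), 1e-10)
      } else {
        expect_true(!is.finite(f) && !is.finite(e))
      }
    }
  }
})

test_that("structured fast path equals the generic recursion, including age steps", {
  set.seed(202)
  spec <- ms_spec("one_area", n_years = 2, sex_structured = FALSE,
                  year_effects = FALSE, individual_effects = FALSE,
                  effort_effects = FALSE)
  T_ <- 24L
  # juvenile entering at occasion 3: age class steps at the year boundary
  y <- rep(7L, T_)
  y[c(3, 5, 9, 16, 20)] <- 1L
  y[24] <- 5L
  ds <- tiny_dataset(spec, matrix(y, 1), age = NA)
  ds$age[1, ] <- c(rep(1L, 12), rep(2L, 12))
  p <- interior_params(spec, seed = 7)
  ll_fast <- sex_marginal_loglik(ds, p, spec)
  # generic route: per-occasion matrices with destination-indexed covariates
  ipy <- spec$intervals_per_year
  s_by_age <- plogis(p$b0[1, 1, ])^(1 / ipy)
  s3 <- plogis(p$b03)^(1 / ipy)
  p_by_age <- plogis(p$a0[1, 1, , 1])
  p3 <- plogis(p$a0[2, 1, , 1])
  r_by_age <- plogis(p$d0[1, ])
  codes5 <- c("1" = 1L, "2" = 3L, "5" = 2L, "6" = 4L, "7" = 5L)
  Tseq <- lapply(2:T_, function(t) {
    a <- ds$age[1, t]
    build_transition_matrix(c(s_by_age[a], s3), p$m[1, a, 1], "one_area")
  })
  Oseq <- lapply(1:T_, function(t) {
    a <- ds$age[1, t]
    build_observation_matrix(c(p_by_age[a], p3[a]),
                             c(r_by_age[a], r_by_age[a]), "one_area")
  })
  first <- ds$first[1]
  y5 <- codes5[as.character(y)]
  ll_ref <- forward_loglik(y5[first:T_], Tseq[(first):(T_ - 1)],
                           Oseq[first:T_])
  expect_equal(unname(ll_fast), unname(ll_ref), tolerance = 1e-10)
})

test_that("latent sex marginalization behaves as a two-component mixture", {
  spec <- ms_spec("one_area", n_years = 1, sex_structured = TRUE,
                  year_effects = FALSE, individual_effects = FALSE,
                  effort_effects = FALSE)
  yrow <- matrix(c(1L, 7L, 1L, 7L, 7L, 1L, 2L, rep(7L, 5)), 1)
  p <- interior_params(spec, seed = 9)
  p$b0[1, 2, ] <- p$b0[1, 1, ] - 0.8   # sexes differ
  ds_unk <- tiny_dataset(spec, yrow, sex = NA_integer_)
  ds_f <- tiny_dataset(spec, yrow, sex = 1L)
  ds_m <- tiny_dataset(spec, yrow, sex = 2L)
  # observed sexes carry a log(psi) categorical term; strip it to get the
  # pure per-sex likelihood components
  llF <- unname(sex_marginal_loglik(ds_f, p, spec) - log(p$psi[1]))
  llM <- unname(sex_marginal_loglik(ds_m, p, spec) - log(p$psi[2]))
  # degenerate mixture
  p1 <- p; p1$psi <- c(1, 0)
  expect_equal(sex_marginal_loglik(ds_unk, p1, spec), llF)
  # direct two-term mixture oracle
  p$psi <- c(0.37, 0.63)
  expect_equal(sex_marginal_loglik(ds_unk, p, spec),
               log(0.37 * exp(llF) + 0.63 * exp(llM)), tolerance = 1e-12)
  # equal component likelihoods make the mixture independent of psi
  p_eq <- p; p_eq$b0[1, 2, ] <- p_eq$b0[1, 1, ]
  p_eq$a0[, 2, , ] <- p_eq$a0[, 1, , ]
  p_eq$d0[2, ] <- p_eq$d0[1, ]
  p_eq$m[2, , ] <- p_eq$m[1, , ]
  llE1 <- sex_marginal_loglik(ds_unk, p_eq, spec)
  p_eq$psi <- c(0.9, 0.1)
  expect_equal(sex_marginal_loglik(ds_unk, p_eq, spec), llE1)
})

test_that("total log-likelihood is additive and reduces to the prior on empty data", {
  spec <- ms_spec("one_area", n_years = 1, sex_structured = FALSE,
                  year_effects = FALSE, individual_effects = FALSE,
                  effort_effects = FALSE)
  p <- interior_params(spec, seed = 31)
  grid <- occasion_grid(2010, 1, 1)
  empty <- as_ms_dataset(list(), NULL, grid, spec)
  expect_equal(total_loglik(empty, p, spec), log_prior(p, spec))
  yrows <- rbind(c(1L, 7L, 1L, 7L, 7L, 2L, rep(7L, 6)),
                 c(7L, 1L, 1L, 7L, 1L, 7L, rep(7L, 6)))
  ds <- tiny_dataset(spec, yrows)
  ll1 <- total_loglik(ds, p, spec, include_prior = FALSE)
  ds2 <- tiny_dataset(spec, rbind(yrows, yrows))
  expect_equal(total_loglik(ds2, p, spec, include_prior = FALSE), 2 * ll1,
               tolerance = 1e-10)
  expect_equal(ll1, sum(sex_marginal_loglik(ds, p, spec)), tolerance = 1e-12)
  # non-finite parameter
  p_bad <- p; p_bad$b03 <- NaN
  expect_identical(total_loglik(ds, p_bad, spec), -Inf)
})

test_that("summing over every observation sequence gives total probability one", {
  rr <- random_rates("one_area")
  T_ <- build_transition_matrix(rr$s, rr$m, "one_area")
  O <- build_observation_matrix(rr$p, rr$r, "one_area")
  seqs <- expand.grid(y2 = 1:5, y3 = 1:5)
  tot <- 0
  for (k in seq_len(nrow(seqs))) {
    y <- c(1L, seqs$y2[k], seqs$y3[k])
    ll <- forward_loglik(y, list(T_, T_), list(O, O, O))
    if (is.finite(ll)) tot <- tot + exp(ll)
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("log-likelihood stays finite over 200 occasions near the probability bounds", {
  spec <- ms_spec("one_area", n_years = 17, sex_structured = FALSE,
                  year_effects = FALSE, individual_effects = FALSE,
                  effort_effects = FALSE)
  T_ <- 200L
  y <- rep(7L, T_); y[1] <- 1L; y[200] <- 1L
  ds <- tiny_dataset(spec, matrix(y, 1))
  p <- ms_params(spec)
  p$b0[] <- qlogis(1 - 1e-12)    # survival ~ 1
  p$a0[] <- qlogis(1e-12)        # detection ~ 0
  p$d0[] <- qlogis(1e-12)
  p$m[] <- 1e-12
  ll <- sex_marginal_loglik(ds, p, spec)
  expect_true(is.finite(ll))
  # same parameters, same data: bitwise identical across calls
  expect_identical(ll, sex_marginal_loglik(ds, p, spec))
})
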