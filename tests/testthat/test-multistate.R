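# Transition/observation matrices, linear predictors, priors.

test_that("interval survival is the annual-survival root and inverts exactly", {
  expect_equal(interval_survival(1, 6), 1)
  expect_equal(interval_survival(0, 6), 0)
  expect_equal(interval_survival(0.78, 6), 0.78^(1 / 6))
  expect_equal(annualize(interval_survival(0.78, 6), 6), 0.78,
               tolerance = 1e-12)
  expect_equal(annualize(0.95, 12), 0.95^12)
  expect_error(interval_survival(1.2, 6), "outside")
})

test_that("transition matrix matches the printed structure", {
  # no death, no movement: identity on alive states
  T1 <- build_transition_matrix(c(1, 1, 1), c(0, 0, 0, 0), "two_subarea")
  alive <- c(1, 3, 5)
  expect_equal(T1[alive, alive], diag(3),
               ignore_attr = TRUE)
  # direct products
  T2 <- build_transition_matrix(c(0.9, 0.8, 0.7), c(0.1, 0, 0.05, 0.02),
                                "two_subarea")
  expect_equal(T2["alive_sub1", "alive_sub2"], 0.09)
  expect_equal(T2["alive_sub1", "died_sub1"], 0.1)
  expect_equal(T2["alive_sub2", "alive_sub1"], 0.8 * 0.05)
  expect_equal(T2["alive_outside", "died_outside"], 0.3)
  expect_equal(T2["died_sub1", "dead_before"], 1)
  expect_equal(T2["dead_before", "dead_before"], 1)
  # one-area layout
  T3 <- build_transition_matrix(c(0.9, 0.7), 0.2, "one_area")
  expect_equal(T3["alive_inside", "alive_outside"], 0.9 * 0.2)
  expect_equal(T3["alive_inside", "died_inside"], 0.1)
  expect_equal(T3["alive_outside", "alive_inside"], 0)  # no back-migration
  expect_error(build_transition_matrix(c(0.9, 0.8, 0.7),
                                       c(0.6, 0.5, 0, 0), "two_subarea"),
               "sum")
})

test_that("observation matrix emits per-state detection/recovery", {
  O <- build_observation_matrix(c(0.4, 0.2, 0.1), c(0.3, 0.2, 0.1),
                                "two_subarea")
  expect_equal(O["alive_sub1", "detected_alive_sub1"], 0.4)
  expect_equal(O["alive_sub1", "not_detected"], 0.6)
  expect_equal(O["died_sub2", "recovered_dead_sub2"], 0.2)
  expect_equal(O["dead_before", "not_detected"], 1)
  Od <- build_observation_matrix(c(1, 1, 1), c(1, 1, 1), "two_subarea")
  expect_true(all(Od[cbind(1:6, 1:6)] == 1))
})

test_that("matrices are row-stochastic and monotone in survival", {
  set.seed(42)
  for (lay in c("two_subarea", "one_area")) {
    for (k in 1:50) {
      rr <- random_rates(lay)
      T_ <- build_transition_matrix(rr$s, rr$m, lay)
      O <- build_observation_matrix(rr$p, rr$r, lay)
      expect_lt(max(abs(rowSums(T_) - 1)), 1e-12)
      expect_lt(max(abs(rowSums(O) - 1)), 1e-12)
    }
  }
  # increasing s raises every alive->alive entry, lowers alive->died
  rr <- random_rates("two_subarea")
  s_lo <- pmin(rr$s, 0.5); s_hi <- s_lo + 0.3
  Tl <- build_transition_matrix(s_lo, rr$m, "two_subarea")
  Th <- build_transition_matrix(s_hi, rr$m, "two_subarea")
  alive <- c(1, 3, 5); died <- c(2, 4, 6)
  pos <- Tl[alive, alive] > 0
  expect_true(all(Th[alive, alive][pos] > Tl[alive, alive][pos]))
  expect_true(all(Th[cbind(alive, died)] < Tl[cbind(alive, died)]))
})

test_that("carcasses appear where the interval started: recovery independent of movement", {
  # mortality precedes movement, so the probability of entering the
  # died-this-interval state of area k does not depend on any movement rate
  rr <- random_rates("two_subarea")
  m_a <- rr$m
  m_b <- c(0.3, 0.3, 0.1, 0.2)
  Ta <- build_transition_matrix(rr$s, m_a, "two_subarea")
  Tb <- build_transition_matrix(rr$s, m_b, "two_subarea")
  died <- c(2, 4, 6)
  expect_equal(Ta[, died], Tb[, died])
})

test_that("linear predictors follow their index structure", {
  spec <- ms_spec("two_subarea", n_years = 5)
  p <- ms_params(spec, n_ind = 3)
  p$b0[1, 1, 3] <- 1.2
  p$sigma_S <- c(0, 0)
  # degenerate random effect: every year equals the intercept
  expect_equal(survival_logit(p, spec, 1, 1, 3, 1), 1.2)
  expect_equal(survival_logit(p, spec, 1, 1, 3, 4), 1.2)
  # gamma shift is linear in sigma
  p$sigma_S <- c(0.3, 0.3); p$gamma[1, 2] <- 1
  expect_equal(survival_logit(p, spec, 1, 1, 3, 2), 1.5)
  expect_equal(survival_logit(p, spec, "outside", 1, 3, 2), p$b03)
  expect_true(plogis(survival_logit(p, spec, 1, 2, 2, 5)) > 0 &&
                plogis(survival_logit(p, spec, 1, 2, 2, 5)) < 1)

  # detection: systmon raises the log-odds by a1
  p$a1 <- 0.45
  l0 <- detection_logit(p, spec, 1, 1, 3, 0, systmon = 0, oppmon = 1)
  l1 <- detection_logit(p, spec, 1, 1, 3, 0, systmon = 1, oppmon = 1)
  expect_equal(l1 - l0, 0.45)
  # telemetry intercept shared across sex and age
  p$a0[1, 1, 1, 2] <- 2.2
  expect_equal(detection_logit(p, spec, 1, 2, 3, 1), 2.2)
  expect_equal(detection_logit(p, spec, 1, 1, 2, 1), 2.2)
  # one-area layout: active collar -> detection probability 1
  spec1 <- ms_spec("one_area", n_years = 5)
  p1 <- ms_params(spec1)
  expect_equal(plogis(detection_logit(p1, spec1, 1, 1, 3, 1)), 1)

  # recovery offsets are additive and shared across sex/age
  p$d0[1, 3] <- -1; p$d0[2, 1] <- -2; p$d12 <- 0.5; p$d13 <- -3
  expect_equal(recovery_logit(p, spec, 2, 1, 3) -
                 recovery_logit(p, spec, 1, 1, 3), 0.5)
  expect_equal(recovery_logit(p, spec, 2, 2, 1) -
                 recovery_logit(p, spec, 1, 2, 1), 0.5)
  expect_equal(recovery_logit(p, spec, "outside", 1, 3), -1 - 3)
  # d12 = 0 -> equal recovery in both subareas
  p$d12 <- 0
  expect_equal(recovery_logit(p, spec, 2, 1, 3),
               recovery_logit(p, spec, 1, 1, 3))
})

test_that("log prior: support, modes, and unit mass of its components", {
  spec <- ms_spec("two_subarea", n_years = 3, year_effects = FALSE,
                  individual_effects = FALSE)
  p <- ms_params(spec)
  base <- log_prior(p, spec)
  expect_true(is.finite(base))
  # movement constraint violation
  p_bad <- p; p_bad$m[1, 1, "m12"] <- 0.7; p_bad$m[1, 1, "m13"] <- 0.5
  expect_identical(log_prior(p_bad, spec), -Inf)
  # intercept at 0 is the normal mode
  p_off <- p; p_off$b03 <- 1
  expect_lt(log_prior(p_off, spec), base)
  # 1-D slices integrate to 1: intercept component ...
  f <- function(x) vapply(x, function(v) {
    q <- p; q$b03 <- v
    exp(log_prior(q, spec) - base) * dnorm(0, 0, 1.5)
  }, numeric(1))
  expect_equal(integrate(f, -30, 30)$value, 1, tolerance = 1e-6)
  # ... and the half-t prior on a standard deviation
  spec_i <- ms_spec("one_area", n_years = 3, year_effects = FALSE,
                    individual_effects = TRUE)
  pi_ <- ms_params(spec_i, n_ind = 0)
  b2 <- log_prior(pi_, spec_i)
  g <- function(x) vapply(x, function(v) {
    q <- pi_; q$sigma_p <- v
    exp(log_prior(q, spec_i) - b2) * dhalft(0)
  }, numeric(1))
  expect_equal(integrate(g, 0, 5000)$value, 1, tolerance = 1e-4)
  expect_equal(integrate(function(x) dhalft(x), 0, Inf)$value, 1,
               tolerance = 1e-6)
})
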