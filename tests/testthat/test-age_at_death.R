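# Age-at-death distribution, its recovery correction, and the lifetime
# likelihood.

test_that("uncorrected lifetime distribution is proper and matches a cohort simulation", {
  expect_equal(uncorrected_theta(c(0, 0, 0)),
               c(1, rep(0, 17)))
  set.seed(13)
  for (k in 1:25) {
    s <- runif(3, 0.05, 0.95)
    th <- uncorrected_theta(s)
    expect_equal(sum(th), 1, tolerance = 1e-12)
    expect_true(all(th >= 0))
  }
  expect_error(uncorrected_theta(c(1, 1, 1)), "undefined")
  # cohort simulation oracle
  s <- c(0.3, 0.8, 0.8)
  s18 <- c(s[1], s[2], rep(s[3], 16))
  n <- 2e5
  set.seed(99)
  alive <- rep(TRUE, n)
  death_year <- rep(NA_integer_, n)
  for (j in 1:18) {
    dies <- alive & runif(n) > s18[j]
    death_year[dies] <- j
    alive <- alive & !dies
  }
  emp <- tabulate(death_year, 18) / sum(!is.na(death_year))
  th <- uncorrected_theta(s)
  mc_se <- sqrt(th * (1 - th) / sum(!is.na(death_year)))
  expect_true(all(abs(emp - th) < 4 * mc_se + 1e-8))
})

test_that("recovery probability closed form equals the 18-term sum", {
  s <- c(0.3, 0.75, 0.8); r <- c(0.1, 0.3, 0.15)
  term_sum <- function(s, r, t_max = 18) {
    s18 <- c(s[1], s[2], rep(s[3], t_max - 2))
    r18 <- c(r[1], r[2], rep(r[3], t_max - 2))
    sum(cumprod(c(1, s18[-t_max])) * (1 - s18) * r18)
  }
  expect_equal(recovery_probability_P(s, r), term_sum(s, r),
               tolerance = 1e-12)
  expect_equal(recovery_probability_P(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(recovery_probability_P(s, c(0, 0, 0)), 0)
  set.seed(8)
  for (k in 1:200) {
    s <- runif(3); r <- runif(3)
    expect_lt(abs(recovery_probability_P(s, r) - term_sum(s, r)), 1e-10)
  }
  # adult survival at 1: geometric series limit (16 equal terms)
  s1 <- c(0.3, 0.75, 1)
  expect_equal(recovery_probability_P(s1, r), term_sum(s1, r),
               tolerance = 1e-12)
  s_near <- c(0.3, 0.75, 1 - 1e-13)
  expect_equal(recovery_probability_P(s_near, r),
               recovery_probability_P(s1, r), tolerance = 1e-8)
})

test_that("recovery-corrected distribution cancels constant recovery and responds to r", {
  set.seed(21)
  for (k in 1:25) {
    s <- runif(3, 0.05, 0.95)
    r_const <- rep(runif(1, 0.05, 0.95), 3)
    expect_equal(corrected_theta(s, r_const), uncorrected_theta(s),
                 tolerance = 1e-12)
    r <- runif(3, 0.05, 0.95)
    expect_equal(sum(corrected_theta(s, r)), 1, tolerance = 1e-12)
  }
  # raising subadult recovery raises the subadult cell
  s <- c(0.3, 0.8, 0.78); r <- c(0.2, 0.3, 0.2)
  r_hi <- r; r_hi[2] <- r[2] + 0.2
  expect_gt(corrected_theta(s, r_hi)[2], corrected_theta(s, r)[2])
})

test_that("lifetime likelihood: certainty, additivity, sex mixture, domain", {
  s <- rbind(c(0, 0.5, 0.5), c(0, 0.5, 0.5))
  r <- matrix(1, 2, 3)
  one <- data.frame(sex = "F", age_years = 1)
  # certain first-year death and recovery: only the categorical sex term is left
  expect_equal(age_at_death_loglik(one, s, r, psi = c(1, 0)), 0)
  expect_equal(age_at_death_loglik(one, s, r, psi = c(0.5, 0.5)), log(0.5))
  s2 <- rbind(c(0.3, 0.8, 0.7), c(0.35, 0.75, 0.72))
  r2 <- rbind(c(0.2, 0.3, 0.15), c(0.1, 0.2, 0.25))
  recs <- data.frame(sex = c("F", "M", "unknown"), age_years = c(1, 3, 7))
  ll <- age_at_death_loglik(recs, s2, r2, psi = c(0.4, 0.6))
  expect_equal(age_at_death_loglik(rbind(recs, recs), s2, r2,
                                   psi = c(0.4, 0.6)), 2 * ll)
  thF <- corrected_theta(s2[1, ], r2[1, ])
  thM <- corrected_theta(s2[2, ], r2[2, ])
  by_hand <- log(0.4) + log(thF[1]) + log(0.6) + log(thM[3]) +
    log(0.4 * thF[7] + 0.6 * thM[7])
  expect_equal(ll, by_hand, tolerance = 1e-12)
  expect_error(age_at_death_loglik(data.frame(sex = "F", age_years = 19),
                                   s2, r2), "outside")
})

test_that("maximum likelihood on simulated lifetimes recovers the survival schedule", {
  truth <- c(0.3, 0.84, 0.76)
  r_const <- rep(0.3, 3)
  th <- corrected_theta(truth, r_const)
  set.seed(555)
  ages <- sample.int(18, 1e4, replace = TRUE, prob = th)
  recs <- data.frame(sex = "F", age_years = ages)
  nll <- function(q) {
    s <- plogis(q)
    -age_at_death_loglik(recs, rbind(s, s), rbind(r_const, r_const))
  }
  opt <- optim(qlogis(c(0.5, 0.5, 0.5)), nll, method = "BFGS")
  expect_lt(max(abs(plogis(opt$par) - truth)), 0.02)
})
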