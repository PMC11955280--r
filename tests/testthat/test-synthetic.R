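# Synthetic-data generator: structural invariants, sampling-error checks,
# determinism, serialisation.

test_that("immortal populations produce no deaths and no recoveries", {
  cfg <- sim_config("one_area", n_years = 2, n_initial_adults = 40,
                    cohort_size = 10,
                    S_annual = array(1, dim = c(1, 2, 3)), S_outside = 1,
                    sigma_S = c(0, 0, 0), n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 2)
  expect_equal(nrow(sim$dead_recoveries), 0L)
  expect_true(all(is.na(sim$truth$death_occasion)))
})

test_that("with certain detection and recovery, counts match the latent truth", {
  cfg <- sim_config("one_area", n_years = 1, n_initial_adults = 3000,
                    cohort_size = 0,
                    S_annual = array(0.76, dim = c(1, 2, 3)),
                    sigma_S = c(0, 0, 0), sigma_p = 0,
                    p_base = array(1, dim = c(2, 2, 3)),
                    r = array(1, dim = c(2, 2, 3)),
                    m = array(0, dim = c(2, 3, 1),
                              dimnames = list(NULL, NULL, "m13")),
                    telemetry_fraction = 0, translocation_fraction = 0,
                    translocation_first_fraction = 0,
                    n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 4)
  z <- attr(sim$truth, "states")
  n_alive_occasions <- sum(z %in% c(1L, 3L, 5L))
  expect_equal(nrow(sim$detections), n_alive_occasions)
  n_deaths <- sum(!is.na(sim$truth$death_occasion))
  expect_equal(nrow(sim$dead_recoveries), n_deaths)
  # empirical annual death frequency within 3 binomial SEs of 1 - S
  n <- nrow(sim$truth)
  p_die <- 1 - 0.76
  se <- sqrt(p_die * (1 - p_die) / n)
  expect_lt(abs(n_deaths / n - p_die), 3 * se)
})

test_that("one-way emigration: the outside population never shrinks", {
  m <- array(0, dim = c(2, 3, 1), dimnames = list(NULL, NULL, "m13"))
  m[, , 1] <- 0.05
  cfg <- sim_config("one_area", n_years = 2, n_initial_adults = 300,
                    cohort_size = 0,
                    S_annual = array(1, dim = c(1, 2, 3)), S_outside = 1,
                    sigma_S = c(0, 0, 0), m = m, n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 6)
  z <- attr(sim$truth, "states")
  outside <- colSums(z == 5L)
  expect_true(all(diff(outside) >= 0))
  expect_gt(outside[ncol(z)], 0)
})

test_that("detection frequency matches the intercept when effort and heterogeneity are off", {
  p_true <- 0.35
  cfg <- sim_config("one_area", n_years = 2, n_initial_adults = 1500,
                    cohort_size = 0,
                    S_annual = array(0.9, dim = c(1, 2, 3)),
                    sigma_S = c(0, 0, 0), sigma_p = 0,
                    p_base = array(p_true, dim = c(2, 2, 3)),
                    a1 = 0, a2 = 0,
                    m = array(0, dim = c(2, 3, 1),
                              dimnames = list(NULL, NULL, "m13")),
                    telemetry_fraction = 0, translocation_fraction = 0,
                    translocation_first_fraction = 0, n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 8)
  z <- attr(sim$truth, "states")
  n_alive <- sum(z %in% c(1L, 5L))
  phat <- nrow(sim$detections) / n_alive
  se <- sqrt(p_true * (1 - p_true) / n_alive)
  expect_lt(abs(phat - p_true), 3 * se)
})

test_that("no detection after a recovery; recoveries only of dead animals", {
  cfg <- sim_config("two_subarea", n_years = 4, n_initial_adults = c(40, 20),
                    cohort_size = c(15, 8), n_extra_carcasses = 50)
  sim <- simulate_population(cfg, seed = 10)
  rec_occ <- occasion_of_date(sim$grid, sim$dead_recoveries$date)
  names(rec_occ) <- sim$dead_recoveries$id
  for (k in seq_along(rec_occ)) {
    idk <- names(rec_occ)[k]
    det_occ <- occasion_of_date(sim$grid,
                                sim$detections$date[sim$detections$id == idk])
    if (length(det_occ)) expect_true(max(det_occ) <= rec_occ[k])
  }
  truth <- sim$truth
  dead_ids <- truth$id[!is.na(truth$death_occasion)]
  expect_true(all(sim$dead_recoveries$id %in% dead_ids))
})

test_that("empirical movement frequencies match the configured rates", {
  m <- array(0, dim = c(2, 3, 1), dimnames = list(NULL, NULL, "m13"))
  m_true <- 0.04
  m[, , 1] <- m_true
  cfg <- sim_config("one_area", n_years = 1, n_initial_adults = 8000,
                    cohort_size = 0,
                    S_annual = array(1, dim = c(1, 2, 3)), S_outside = 1,
                    sigma_S = c(0, 0, 0), m = m,
                    telemetry_fraction = 0, translocation_fraction = 0,
                    translocation_first_fraction = 0, n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 12)
  z <- attr(sim$truth, "states")
  at_risk <- 0L; moved <- 0L
  for (t in 2:ncol(z)) {
    inside_prev <- z[, t - 1L] == 1L
    at_risk <- at_risk + sum(inside_prev)
    moved <- moved + sum(inside_prev & z[, t] == 5L)
  }
  se <- sqrt(m_true * (1 - m_true) / at_risk)
  expect_lt(abs(moved / at_risk - m_true), 3 * se)
})

test_that("datasets round-trip through CSV and are byte-identical under a fixed seed", {
  cfg <- sim_config("two_subarea", n_years = 3, n_initial_adults = c(15, 8),
                    cohort_size = c(6, 3), n_extra_carcasses = 30)
  sim <- simulate_population(cfg, seed = 14)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(sim, d1)
  sim_again <- simulate_population(cfg, seed = 14)
  write_dataset(sim_again, d2)
  for (f in c("detections.csv", "dead_recoveries.csv", "individuals.csv",
              "effort.csv", "ages_at_death.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- read_dataset(d1)
  expect_equal(nrow(back$detections), nrow(sim$detections))
  expect_equal(nrow(back$dead_recoveries), nrow(sim$dead_recoveries))
  expect_equal(nrow(back$individuals), nrow(sim$individuals))
  expect_equal(back$layout, "two_subarea")
  # binning the re-read records reproduces identical histories
  bh1 <- build_histories(sim$detections, sim$dead_recoveries,
                         sim$individuals, sim$grid)
  bh2 <- build_histories(back$detections, back$dead_recoveries,
                         back$individuals, back$grid)
  expect_equal(names(bh1$histories), names(bh2$histories))
  for (id in names(bh1$histories))
    expect_equal(bh1$histories[[id]]$y, bh2$histories[[id]]$y)
})

test_that("flank degradation is selective and reverts at fraction zero", {
  cfg <- sim_config("one_area", n_years = 3, n_initial_adults = 50,
                    cohort_size = 25, n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 16)
  expect_identical(degrade_to_flanks(sim, 0, seed = 1)$detections,
                   sim$detections)
  deg <- degrade_to_flanks(sim, 1, seed = 1)
  # fraction 1: every camera-only individual is split
  camera_only <- setdiff(
    unique(sim$detections$id[!(sim$detections$source %in%
                                 c("live_capture", "telemetry"))]),
    c(unique(sim$detections$id[sim$detections$source %in%
                                 c("live_capture", "telemetry")]),
      sim$dead_recoveries$id))
  map <- attr(deg, "flank_map")
  expect_setequal(map$orig, camera_only)
  expect_true(all(deg$individuals$flank %in% c("both", "left", "right")))
  # split animals observed longer are rarer than short-lived ones at
  # intermediate fractions (selection by number of events)
  deg2 <- degrade_to_flanks(sim, 0.5, seed = 2)
  map2 <- attr(deg2, "flank_map")
  n_events <- table(sim$detections$id)
  if (!is.null(map2) && nrow(map2) > 3) {
    split_events <- mean(n_events[map2$orig])
    all_events <- mean(n_events[camera_only])
    expect_lt(split_events, all_events + 1e-9)
  }
})
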