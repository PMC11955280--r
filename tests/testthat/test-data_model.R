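# Preprocessing: occasion binning, age classes, flank rule, record cleanup.

test_that("detections bin to the occasion containing their date", {
  g2 <- occasion_grid(2010, 2, 2)
  expect_equal(occasion_of_date(g2, as.Date("2010-05-15")), 1L)  # (2010, 0)
  expect_equal(occasion_of_date(g2, as.Date("2011-04-30")), 6L)  # (2010, 5)
  g1 <- occasion_grid(2010, 2, 1)
  expect_equal(occasion_of_date(g1, as.Date("2010-05-15")), 1L)
  expect_equal(occasion_of_date(g1, as.Date("2010-06-15")), 2L)
  expect_error(occasion_of_date(g2, as.Date("2009-04-30")), "outside")
})

test_that("binning partitions the window and respects the occasion count", {
  set.seed(71)
  for (im in c(1L, 2L)) {
    g <- occasion_grid(2000, 4, im)
    expect_equal(g$per_year, 12 / im)
    expect_equal(g$n_occasions, 4 * 12 / im)
    dates <- as.Date("2000-05-01") + sample.int(4 * 365 - 5, 300)
    occ <- occasion_of_date(g, dates)
    expect_true(all(occ >= 1 & occ <= g$n_occasions))
    # lynx-year consistency: occasion's lynx year equals the date's
    expect_equal(g$table$lynx_year[occ], lynx_year_of(dates))
  }
})

test_that("same-occasion records collapse with dead recovery precedence and last-detection subarea", {
  g <- occasion_grid(2010, 1, 2)
  recs <- data.frame(
    date = as.Date(c("2010-05-02", "2010-05-20", "2010-06-10", "2010-08-01")),
    subarea = c("sub1", "sub1", "sub2", "sub1"),
    dead = c(FALSE, FALSE, FALSE, TRUE))
  y <- bin_to_occasions(recs, g)
  # occasion 1: sub1 twice then sub2 last -> coded sub2, conflict logged
  expect_equal(unname(y[1]), 3L)
  expect_equal(attr(y, "conflicts"), 1L)
  # occasion 2: recovery code
  expect_equal(unname(y[2]), 2L)
  y2 <- bin_to_occasions(data.frame(
    date = as.Date(c("2010-05-02", "2010-05-20")),
    subarea = c("sub1", "sub1"), dead = c(FALSE, TRUE)), g)
  expect_equal(unname(y2[1]), 2L)   # recovery outranks detection
})

test_that("age classes follow the first/second/third-year rule", {
  expect_equal(assign_age_class(2005, 2005, 2005), 1L)
  expect_equal(assign_age_class(2005, 2006, 2005), 2L)
  expect_equal(assign_age_class(2005, 2007, 2005), 3L)
  expect_equal(assign_age_class(2005, 2020, 2005), 3L)
  # unknown birth year: adult from first detection
  expect_equal(assign_age_class(NA, 2010, 2010), 3L)
  expect_error(assign_age_class(2005, 2004, 2004), "precedes")
  # non-decreasing along any trajectory
  yrs <- 2005:2015
  cls <- assign_age_class(rep(2005, length(yrs)), yrs, 2005)
  expect_true(all(diff(cls) >= 0))
})

test_that("flank rule deletes the less abundant single-flank group", {
  mk <- function(nb, nl, nr) data.frame(
    id = sprintf("x%03d", seq_len(nb + nl + nr)),
    flank = rep(c("both", "left", "right"), c(nb, nl, nr)))
  res <- filter_single_flanks(mk(100, 70, 82))
  expect_equal(length(res$retained_ids), 182L)
  expect_equal(length(res$deleted_ids), 70L)
  expect_equal(res$deleted_side, "left")
  res0 <- filter_single_flanks(mk(10, 0, 0))
  expect_equal(length(res0$retained_ids), 10L)
  expect_equal(length(res0$deleted_ids), 0L)
  # tie broken by deleting the left-only group
  res_tie <- filter_single_flanks(mk(5, 3, 3))
  expect_equal(res_tie$deleted_side, "left")
  expect_equal(length(res_tie$deleted_ids), 3L)
  # both-flank individuals are never deleted; count equals the minority size
  set.seed(5)
  for (k in 1:20) {
    nb <- sample(0:30, 1); nl <- sample(0:30, 1); nr <- sample(0:30, 1)
    r <- filter_single_flanks(mk(nb, nl, nr))
    expect_true(all(grepl("both", rep("both", nb))))  # structural
    expect_equal(length(r$deleted_ids),
                 if (nl + nr == 0) 0L else min(nl, nr))
    expect_true(all(sprintf("x%03d", seq_len(nb)) %in% r$retained_ids))
  }
})

test_that("single outside records are removed, censoring truncates, translocation-first excludes", {
  T_ <- 12L
  h <- list(id = "a", first = 2L, last = T_,
            y = c(7L, 1L, 7L, 5L, 7L, 1L, rep(7L, 6)),
            censor_occasion = NA_integer_, translocation_first = FALSE)
  out <- apply_record_cleanup(h)
  expect_true(out$outside_removed)
  expect_equal(out$y[4], 7L)
  expect_false(out$excluded)
  # two outside records stay
  h2 <- h; h2$y[8] <- 5L
  expect_false(apply_record_cleanup(h2)$outside_removed)
  # outside record not followed by an inside detection stays (emigrant)
  h3 <- h; h3$y[6] <- 7L
  expect_false(apply_record_cleanup(h3)$outside_removed)
  # censoring: likelihood window ends the occasion before the translocation
  h4 <- h; h4$censor_occasion <- 10L
  out4 <- apply_record_cleanup(h4)
  expect_equal(out4$last, 9L)
  expect_true(all(out4$y[10:12] == 7L))
  # translocation capture as first record -> excluded
  h5 <- h; h5$translocation_first <- TRUE
  expect_true(apply_record_cleanup(h5)$excluded)
})

test_that("histories survive a JSON write/read round trip", {
  cfg <- sim_config("one_area", n_years = 2, n_initial_adults = 25,
                    cohort_size = 10, n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 11)
  bh <- build_histories(sim$detections, sim$dead_recoveries,
                        sim$individuals, sim$grid)
  path <- withr::local_tempfile(fileext = ".json")
  write_histories(bh$histories, path, layout = "one_area")
  back <- read_histories(path)
  expect_equal(length(back), length(bh$histories))
  for (id in names(bh$histories)) {
    expect_equal(back[[id]]$y, bh$histories[[id]]$y)
    expect_equal(back[[id]]$first, bh$histories[[id]]$first)
    expect_equal(back[[id]]$last, bh$histories[[id]]$last)
    expect_equal(back[[id]]$age_class,
                 as.integer(bh$histories[[id]]$age_class))
    expect_equal(back[[id]]$sex, bh$histories[[id]]$sex)
  }
})

test_that("age class is constant within lynx years and steps only at boundaries", {
  cfg <- sim_config("two_subarea", n_years = 3, n_initial_adults = c(10, 5),
                    cohort_size = c(8, 4), n_extra_carcasses = 0)
  sim <- simulate_population(cfg, seed = 3)
  bh <- build_histories(sim$detections, sim$dead_recoveries,
                        sim$individuals, sim$grid)
  yr <- sim$grid$table$lynx_year
  for (h in bh$histories) {
    cls <- h$age_class[h$first:h$last]
    expect_true(all(diff(cls) >= 0))
    chg <- which(diff(h$age_class) != 0)
    if (length(chg))
      expect_true(all(yr[chg + 1] != yr[chg]))
  }
})
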