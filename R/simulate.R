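# Synthetic monitoring data with the statistical structure the analysis
# assumes: cohorts entering at lynx-year boundaries, latent states evolving
# by the transition matrix (mortality before movement), detections from the
# observation matrix with effort covariates and telemetry, carcass
# recoveries, an independent age-at-death sample, censoring at translocation
# and optional unmatched-flank pseudo-individuals.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a long-running lynx monitoring
#' programme. The two-subarea layout mirrors an Alpine-type population on a
#' 2-month grid (subarea 1 a high-density core, subarea 2 a sparser subarea);
#' the one-area layout a small reintroduced population on a monthly grid.
#' Survival, detection and recovery magnitudes follow the estimates reported
#' for those populations (adult survival ~0.71-0.78, juvenile ~0.2-0.33,
#' 2-monthly detection ~0.1-0.4, monthly detection ~0.4-0.7 in the small
#' population); about half of all pictured individuals are of unknown sex
#' and half lack a known birth year.
#'
#' @param layout `"two_subarea"` or `"one_area"`.
#' @param n_years number of lynx years simulated.
#' @param start_lynx_year first lynx year.
#' @param interval_months 2 (two-subarea default) or 1 (one-area default).
#' @param n_initial_adults adults present at the first occasion, per inside
#'   area.
#' @param cohort_size juveniles entering at the start of each lynx year, per
#'   inside area.
#' @param S_annual `A x 2 x 3` array (area, sex F/M, age class) of true
#'   annual survival inside; `S_outside` scalar annual survival outside.
#' @param sigma_S year-effect SD on the survival logit (length A for the
#'   two-subarea layout, length 3 — per age class — for the one-area layout).
#' @param sigma_p individual-effect SD on the detection logit.
#' @param p_base `(A+1) x 2 x 3` array of detection probability per occasion
#'   at baseline effort without a collar (last area = outside).
#' @param p_tele detection probability per occasion with an active collar
#'   (fixed to 1 in the one-area layout).
#' @param a1,a2 effects (log-odds) of systematic monitoring and of one unit
#'   of opportunistic-effort score on detection.
#' @param r `(A+1) x 2 x 3` array of dead-recovery probability.
#' @param m `2 x 3 x k` array of per-interval movement probabilities
#'   (`m12, m13, m21, m23` for two subareas; `m13` for one area).
#' @param psi true sex proportions (F, M).
#' @param telemetry_fraction fraction of individuals fitted with a collar;
#'   `telemetry_years` collar lifetime in years.
#' @param unknown_sex_fraction fraction of individuals whose sex is not
#'   recorded; `unknown_birth_fraction` likewise for the birth year.
#' @param translocation_fraction fraction of detected individuals removed by
#'   translocation (censored at the capture date);
#'   `translocation_first_fraction` fraction whose translocation capture is
#'   their first known record (excluded by the cleanup rule).
#' @param systmon_period a systematic camera-trap session is run every this
#'   many years in each area (60 winter days).
#' @param n_extra_carcasses size of the independent age-at-death sample.
#' @param carcass_unknown_sex_fraction fraction of carcasses without sex.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(layout = c("two_subarea", "one_area"),
                       n_years = 10, start_lynx_year = 2005,
                       interval_months = NULL,
                       n_initial_adults = NULL, cohort_size = NULL,
                       S_annual = NULL, S_outside = 0.7,
                       sigma_S = NULL, sigma_p = 1,
                       p_base = NULL, p_tele = NULL,
                       a1 = 0.45, a2 = 0,
                       r = NULL, m = NULL, psi = c(0.5, 0.5),
                       telemetry_fraction = 0.15, telemetry_years = 2,
                       unknown_sex_fraction = 0.49,
                       unknown_birth_fraction = 0.5,
                       translocation_fraction = 0.02,
                       translocation_first_fraction = 0.01,
                       systmon_period = 3,
                       n_extra_carcasses = 150,
                       carcass_unknown_sex_fraction = 0.1) {
  layout <- match.arg(layout)
  A <- if (layout == "two_subarea") 2L else 1L
  if (is.null(interval_months))
    interval_months <- if (layout == "two_subarea") 2L else 1L
  ipy <- 12L %/% interval_months
  if (is.null(n_initial_adults))
    n_initial_adults <- if (A == 2L) c(30L, 15L) else 40L
  if (is.null(cohort_size))
    cohort_size <- if (A == 2L) c(12L, 6L) else 12L
  if (is.null(S_annual)) {
    S_annual <- if (A == 2L) {
      array(c(0.33, 0.29, 0.28, 0.20,    # juveniles F/M by area
              0.82, 0.84, 0.89, 0.77,    # subadults
              0.78, 0.78, 0.78, 0.71),   # adults
            dim = c(2, 2, 3))
    } else {
      array(c(0.29, 0.30, 0.75, 0.70, 0.76, 0.76), dim = c(1, 2, 3))
    }
  }
  if (is.null(sigma_S))
    sigma_S <- if (layout == "two_subarea") c(0.3, 0.5) else c(0.7, 0.4, 0.3)
  if (is.null(p_base)) {
    p_base <- if (A == 2L) {
      array(c(0.40, 0.20, 0.25, 0.32, 0.02, 0.02,
              0.11, 0.16, 0.09, 0.14, 0.02, 0.02,
              0.12, 0.19, 0.11, 0.14, 0.02, 0.02),
            dim = c(3, 2, 3))
    } else {
      array(c(0.43, 0.69, 0.05, 0.05,
              0.53, 0.57, 0.05, 0.05,
              0.55, 0.63, 0.05, 0.05), dim = c(2, 2, 3))
    }
  }
  if (is.null(p_tele)) p_tele <- if (layout == "one_area") 1 else 0.95
  if (is.null(r)) {
    r <- if (A == 2L) {
      array(c(0.11, 0.07, 0.02, 0.02, 0.01, 0.01,
              0.13, 0.33, 0.03, 0.09, 0.02, 0.02,
              0.13, 0.15, 0.03, 0.04, 0.02, 0.02),
            dim = c(3, 2, 3))
    } else {
      array(c(0.30, 0.07, 0.30, 0.07,
              0.52, 0.08, 0.52, 0.08,
              0.08, 0.21, 0.08, 0.21), dim = c(2, 2, 3))
    }
  }
  if (is.null(m)) {
    if (layout == "two_subarea") {
      m <- array(0, dim = c(2, 3, 4),
                 dimnames = list(NULL, NULL, c("m12", "m13", "m21", "m23")))
      # juvenile 2-monthly movement; older classes move less
      m[, 1, "m12"] <- c(0.01, 0.02)
      m[, 1, "m21"] <- c(0.08, 0.06)
      m[, 1, "m13"] <- 1 - (1 - 0.01)^(1 / ipy)
      m[, 1, "m23"] <- 1 - (1 - c(0.04, 0.07))^(1 / ipy)
      for (ag in 2:3) m[, ag, ] <- m[, 1, ] / 4
    } else {
      m <- array(0, dim = c(2, 3, 1), dimnames = list(NULL, NULL, "m13"))
      m[, 1, 1] <- 1 - (1 - c(0.006, 0.14))^(1 / ipy)
      m[, 2:3, 1] <- m[, 1, 1] / 4
    }
  }
  structure(list(layout = layout, n_years = as.integer(n_years),
                 start_lynx_year = as.integer(start_lynx_year),
                 interval_months = as.integer(interval_months),
                 n_area_in = A, n_initial_adults = n_initial_adults,
                 cohort_size = cohort_size, S_annual = S_annual,
                 S_outside = S_outside, sigma_S = sigma_S, sigma_p = sigma_p,
                 p_base = p_base, p_tele = p_tele, a1 = a1, a2 = a2, r = r,
                 m = m, psi = psi,
                 telemetry_fraction = telemetry_fraction,
                 telemetry_years = telemetry_years,
                 unknown_sex_fraction = unknown_sex_fraction,
                 unknown_birth_fraction = unknown_birth_fraction,
                 translocation_fraction = translocation_fraction,
                 translocation_first_fraction = translocation_first_fraction,
                 systmon_period = systmon_period,
                 n_extra_carcasses = n_extra_carcasses,
                 carcass_unknown_sex_fraction = carcass_unknown_sex_fraction),
            class = "sim_config")
}

# systematic sessions: 60 winter days (December-January here) every
# `systmon_period` years, staggered across areas; value = monitored fraction
# of the months in each occasion
sim_effort <- function(config, grid) {
  A <- config$n_area_in
  systmon <- matrix(0, A, grid$n_occasions)
  months0 <- 5L + grid$table$within * grid$interval_months  # first month (May=5)
  for (a in seq_len(A)) {
    session_years <- which((seq_len(grid$n_years) - 1L + a) %%
                             config$systmon_period == 0L)
    for (yr in session_years) {
      occ <- which(grid$table$lynx_year == grid$start_lynx_year + yr - 1L)
      for (t in occ) {
        mns <- ((months0[t] - 1L + seq_len(grid$interval_months) - 1L) %% 12L) + 1L
        systmon[a, t] <- mean(mns %in% c(12L, 1L))
      }
    }
  }
  oppmon <- matrix(0, A, grid$n_years)
  for (a in seq_len(A)) {
    x <- 1.5
    for (y in seq_len(grid$n_years)) {
      x <- min(3, max(1, x + sample(c(-0.25, 0, 0.25), 1)))
      oppmon[a, y] <- x
    }
  }
  list(systmon = systmon, oppmon = oppmon)
}

#' Simulate a complete monitoring dataset
#'
#' States evolve occasion by occasion via the layout's transition matrix
#' (mortality before movement, permanent emigration); detections and carcass
#' recoveries are drawn from the observation matrix with effort covariates,
#' telemetry status and individual heterogeneity; an independent age-at-death
#' sample is drawn from the recovery-corrected lifetime distribution.
#' Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `detections`, `dead_recoveries`, `individuals`,
#'   `effort`, `ages_at_death` (data frames), `truth` (per-individual truth
#'   records with the latent state matrix as attribute `"states"`), `grid`,
#'   and `config`.
#' @export
simulate_population <- function(config, seed = 1L) {
  set.seed(seed)
  grid <- occasion_grid(config$start_lynx_year, config$n_years,
                        config$interval_months)
  A <- config$n_area_in
  T_ <- grid$n_occasions
  ipy <- grid$per_year
  eff <- sim_effort(config, grid)
  yr_idx <- occasion_year_index(grid)

  # roster: initial adults + yearly juvenile cohorts per area
  entry <- integer(0); area0 <- integer(0); birth <- integer(0)
  for (a in seq_len(A)) {
    n0 <- config$n_initial_adults[a]
    entry <- c(entry, rep(1L, n0))
    area0 <- c(area0, rep(a, n0))
    birth <- c(birth, grid$start_lynx_year - sample(2:8, n0, replace = TRUE))
    for (y in seq_len(config$n_years)) {
      nc <- config$cohort_size[a]
      entry <- c(entry, rep((y - 1L) * ipy + 1L, nc))
      area0 <- c(area0, rep(a, nc))
      birth <- c(birth, rep(grid$start_lynx_year + y - 1L, nc))
    }
  }
  n <- length(entry)
  ids <- sprintf("L%03d", seq_len(n))
  sex <- 1L + (runif(n) > config$psi[1])          # 1 F, 2 M
  eps <- rnorm(n)
  G <- if (config$layout == "two_subarea") A else 3L
  gamma <- matrix(rnorm(G * config$n_years), G, config$n_years)

  # interval survival per (area, sex, age, year) with the year effect
  s_int <- array(0, c(A, 2, 3, config$n_years))
  for (a in seq_len(A)) for (sx in 1:2) for (ag in 1:3) {
    re <- if (config$layout == "two_subarea")
      config$sigma_S[a] * gamma[a, ] else config$sigma_S[ag] * gamma[ag, ]
    s_int[a, sx, ag, ] <-
      plogis(qlogis(config$S_annual[a, sx, ag]) + re)^(1 / ipy)
  }
  s_out <- config$S_outside^(1 / ipy)

  age_at <- function(t) {
    pmin(pmax(grid$table$lynx_year[t] - birth + 1L, 1L), 3L)
  }

  # latent states, vectorised over individuals per occasion
  z <- matrix(0L, n, T_)
  z[cbind(seq_len(n), entry)] <- 2L * area0 - 1L   # alive in entry area
  for (t in 2:T_) {
    prev <- z[, t - 1L]
    z[entry == t, t] <- 2L * area0[entry == t] - 1L
    act <- which(entry < t)
    if (length(act) == 0L) next
    ag <- age_at(t)[act]
    yv <- yr_idx[t]
    p_ <- prev[act]
    newz <- integer(length(act))
    newz[p_ %in% c(2L, 4L, 6L)] <- 7L
    newz[p_ == 7L] <- 7L
    for (a in seq_len(A)) {
      alive_a <- which(p_ == 2L * a - 1L)
      if (!length(alive_a)) next
      ii <- act[alive_a]
      sv <- s_int[cbind(a, sex[ii], ag[alive_a], yv)]
      dies <- runif(length(ii)) > sv
      out <- rep(2L * a - 1L, length(ii))       # stay by default
      out[dies] <- 2L * a
      mv <- runif(length(ii))
      if (config$layout == "two_subarea") {
        m12 <- config$m[cbind(sex[ii], ag[alive_a],
                              if (a == 1L) 1L else 3L)]
        m13 <- config$m[cbind(sex[ii], ag[alive_a],
                              if (a == 1L) 2L else 4L)]
        to_other <- !dies & mv < m12
        to_out <- !dies & mv >= m12 & mv < m12 + m13
        out[to_other] <- 2L * (3L - a) - 1L
        out[to_out] <- 5L
      } else {
        m13 <- config$m[cbind(sex[ii], ag[alive_a], 1L)]
        out[!dies & mv < m13] <- 5L
      }
      newz[alive_a] <- out
    }
    alive_o <- which(p_ == 5L)
    if (length(alive_o)) {
      dies <- runif(length(alive_o)) > s_out
      newz[alive_o] <- ifelse(dies, 6L, 5L)
    }
    z[act, t] <- newz
  }

  # telemetry: collar fitted at a capture occasion during life
  tele <- matrix(0L, n, T_)
  collar_start <- rep(NA_integer_, n)
  alive_mat <- z %in% c(1L, 3L, 5L)
  dim(alive_mat) <- dim(z)
  collared <- which(runif(n) < config$telemetry_fraction)
  for (i in collared) {
    alive_occ <- which(alive_mat[i, ])
    if (!length(alive_occ)) next
    st <- alive_occ[sample.int(length(alive_occ), 1L)]
    en <- min(st + config$telemetry_years * ipy - 1L, T_)
    span <- st:en
    span <- span[alive_mat[i, span]]
    tele[i, span] <- 1L
    collar_start[i] <- st
  }

  # detection probabilities
  base_logit <- array(qlogis(config$p_base), dim = dim(config$p_base))
  p_mat <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    ag <- age_at(t)
    st <- z[, t]
    for (a in seq_len(A)) {
      sel <- st == 2L * a - 1L
      if (!any(sel)) next
      p_mat[sel, t] <- plogis(
        base_logit[cbind(a, sex[sel], ag[sel])] +
          config$a1 * eff$systmon[a, t] +
          config$a2 * (eff$oppmon[a, yr_idx[t]] - 1) +
          config$sigma_p * eps[sel])
    }
    sel <- st == 5L
    if (any(sel))
      p_mat[sel, t] <- plogis(base_logit[cbind(A + 1L, sex[sel], ag[sel])] +
                                config$sigma_p * eps[sel])
  }
  p_tele_eff <- if (config$layout == "one_area") 1 else config$p_tele
  p_mat[tele == 1L] <- p_tele_eff
  det <- alive_mat & matrix(runif(n * T_), n, T_) < p_mat

  # carcass recoveries
  rec <- matrix(FALSE, n, T_)
  died_state <- z %in% c(2L, 4L, 6L)
  dim(died_state) <- dim(z)
  for (t in seq_len(T_)) {
    ii <- which(died_state[, t])
    if (!length(ii)) next
    a <- z[ii, t] / 2L
    rv <- config$r[cbind(pmin(a, A + 1L), sex[ii], age_at(t)[ii])]
    rec[ii, t] <- runif(length(ii)) < rv
  }

  # assemble detection rows
  day_pool <- config$interval_months * 28L
  det_idx <- which(det, arr.ind = TRUE)
  det_rows <- NULL
  if (nrow(det_idx)) {
    i <- det_idx[, 1]; t <- det_idx[, 2]
    a <- (z[det_idx] + 1L) %/% 2L
    dates <- occasion_start_date(grid, t) + sample.int(day_pool, length(t),
                                                       replace = TRUE) - 1L
    src <- ifelse(tele[det_idx] == 1L, "telemetry",
                  ifelse(a <= A & eff$systmon[cbind(pmin(a, A), t)] > 0 &
                           runif(length(t)) < 0.5,
                         "systematic_camera", "opportunistic_camera"))
    det_rows <- data.frame(id = ids[i], date = dates,
                           subarea = SUBAREA_LEVELS[ifelse(a > A, 3L, a)],
                           source = src, flank = "both",
                           stringsAsFactors = FALSE)
  }
  # collar-fitting captures
  cap <- which(!is.na(collar_start))
  if (length(cap)) {
    tcs <- collar_start[cap]
    a <- (z[cbind(cap, tcs)] + 1L) %/% 2L
    det_rows <- rbind(det_rows, data.frame(
      id = ids[cap], date = occasion_start_date(grid, tcs),
      subarea = SUBAREA_LEVELS[ifelse(a > A, 3L, a)],
      source = "live_capture", flank = "both", stringsAsFactors = FALSE))
  }

  # recovery rows
  rec_idx <- which(rec, arr.ind = TRUE)
  death_occ <- rep(NA_integer_, n)
  death_area <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    d <- which(died_state[i, ])
    if (length(d)) { death_occ[i] <- d[1L]; death_area[i] <- (z[i, d[1L]]) %/% 2L }
  }
  sex_obs <- ifelse(runif(n) < config$unknown_sex_fraction, "unknown",
                    c("F", "M")[sex])
  birth_obs <- ifelse(runif(n) < config$unknown_birth_fraction,
                      NA_integer_, birth)
  rec_rows <- NULL
  if (nrow(rec_idx)) {
    i <- rec_idx[, 1]; t <- rec_idx[, 2]
    a <- z[rec_idx] %/% 2L
    rec_rows <- data.frame(
      id = ids[i],
      date = occasion_start_date(grid, t) + sample.int(day_pool, length(t),
                                                       replace = TRUE) - 1L,
      subarea = SUBAREA_LEVELS[ifelse(a > A, 3L, a)],
      sex = sex_obs[i], birth_lynx_year = birth_obs[i],
      stringsAsFactors = FALSE)
  }

  # translocations: censor some detected individuals at a capture; a few have
  # the translocation capture as their first known record
  det_any <- ids %in% det_rows$id
  transloc <- which(det_any & runif(n) < config$translocation_fraction)
  censor_occ <- rep(NA_integer_, n)
  transloc_first <- rep(FALSE, n)
  for (i in transloc) {
    occ_i <- sort(unique(occasion_of_date(grid, det_rows$date[det_rows$id == ids[i]])))
    live_after <- which(alive_mat[i, ] & seq_len(T_) > occ_i[1L])
    if (!length(live_after)) next
    cocc <- live_after[sample.int(length(live_after), 1L)]
    censor_occ[i] <- cocc
    a <- (z[i, cocc] + 1L) %/% 2L
    det_rows <- rbind(det_rows, data.frame(
      id = ids[i], date = occasion_start_date(grid, cocc),
      subarea = SUBAREA_LEVELS[ifelse(a > A, 3L, a)],
      source = "live_capture", flank = "both", stringsAsFactors = FALSE))
    # the animal is removed: no records after the translocation capture
    drop <- det_rows$id == ids[i] &
      occasion_of_date(grid, det_rows$date) > cocc
    det_rows <- det_rows[!drop, , drop = FALSE]
    if (!is.null(rec_rows)) {
      rec_rows <- rec_rows[!(rec_rows$id == ids[i]), , drop = FALSE]
    }
  }
  never_seen <- which(!det_any & !(ids %in% rec_rows$id))
  tf <- never_seen[runif(length(never_seen)) <
                     config$translocation_first_fraction * 5]
  for (i in tf) {
    alive_occ <- which(alive_mat[i, ])
    if (!length(alive_occ)) next
    cocc <- alive_occ[sample.int(length(alive_occ), 1L)]
    censor_occ[i] <- cocc
    transloc_first[i] <- TRUE
    a <- (z[i, cocc] + 1L) %/% 2L
    det_rows <- rbind(det_rows, data.frame(
      id = ids[i], date = occasion_start_date(grid, cocc),
      subarea = SUBAREA_LEVELS[ifelse(a > A, 3L, a)],
      source = "live_capture", flank = "both", stringsAsFactors = FALSE))
  }

  # telemetry occasion ranges as strings
  tele_str <- vapply(seq_len(n), function(i) {
    occ <- which(tele[i, ] == 1L)
    if (!length(occ)) return("")
    brk <- c(0L, which(diff(occ) > 1L), length(occ))
    paste(vapply(seq_len(length(brk) - 1L), function(k) {
      sprintf("%d-%d", occ[brk[k] + 1L], occ[brk[k + 1L]])
    }, character(1)), collapse = ";")
  }, character(1))

  individuals <- data.frame(
    id = ids, sex = sex_obs, birth_lynx_year = birth_obs,
    censor_occasion = censor_occ, translocation_first = transloc_first,
    telemetry = tele_str, flank = "both", stringsAsFactors = FALSE)

  # independent age-at-death sample from the recovery-corrected lifetime law
  wts <- config$n_initial_adults + config$cohort_size * config$n_years
  wts <- wts / sum(wts)
  ages <- NULL
  if (config$n_extra_carcasses > 0L) {
    csex <- 1L + (runif(config$n_extra_carcasses) > config$psi[1])
    age_j <- integer(config$n_extra_carcasses)
    for (sx in 1:2) {
      sel <- csex == sx
      if (!any(sel)) next
      s3c <- colSums(wts * matrix(config$S_annual[, sx, ], A, 3))
      r3c <- colSums(wts * matrix(config$r[seq_len(A), sx, ], A, 3))
      th <- corrected_theta(s3c, r3c)
      age_j[sel] <- sample.int(T_MAX, sum(sel), replace = TRUE, prob = th)
    }
    ages <- data.frame(
      sex = ifelse(runif(config$n_extra_carcasses) <
                     config$carcass_unknown_sex_fraction, "unknown",
                   c("F", "M")[csex]),
      age_years = age_j, stringsAsFactors = FALSE)
  }

  effort <- data.frame(
    subarea = rep(SUBAREA_LEVELS[seq_len(A)], each = T_),
    lynx_year = rep(grid$table$lynx_year, A),
    within = rep(grid$table$within, A),
    systmon = as.vector(t(eff$systmon)),
    oppmon = as.vector(vapply(seq_len(A), function(a)
      eff$oppmon[a, yr_idx], numeric(T_))),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    id = ids, sex_true = c("F", "M")[sex], birth_year = birth,
    entry_occasion = entry, entry_area = area0,
    death_occasion = death_occ, death_area = death_area,
    recovered = ids %in% rec_rows$id,
    censor_occasion = censor_occ, stringsAsFactors = FALSE)
  attr(truth, "states") <- z
  attr(truth, "gamma") <- gamma
  attr(truth, "eps") <- eps

  list(detections = det_rows,
       dead_recoveries = if (is.null(rec_rows))
         data.frame(id = character(0), date = as.Date(character(0)),
                    subarea = character(0), sex = character(0),
                    birth_lynx_year = integer(0)) else rec_rows,
       individuals = individuals, effort = effort, ages_at_death = ages,
       truth = truth, grid = grid, config = config)
}

#' Degrade identities to unmatched left/right-flank pseudo-individuals
#'
#' Emulates the identification limit of single-flank camera pictures. Each
#' camera event photographs only one flank (left or right, equal chance)
#' with probability `mismatch_fraction`, and both flanks otherwise. An
#' individual is matched across sides — and keeps its identity — if it has at
#' least one double-sided event or was ever handled (live capture,
#' telemetry) or recovered dead (both flanks are photographed at handling or
#' necropsy). Remaining individuals split into a left-only and a right-only
#' pseudo-individual carrying their single-sided events. Because matching
#' becomes more likely the longer an animal is observed, animals dying young
#' are over-represented among the split pseudo-individuals, which is what
#' biases survival estimates when all pseudo-individuals are retained.
#'
#' @param sim output of [simulate_population()].
#' @param mismatch_fraction probability that a camera event is single-sided.
#' @param seed integer seed.
#' @return modified `sim` with pseudo-individuals in `detections` and
#'   `individuals`, and attribute `"flank_map"` (data frame `orig, left_id,
#'   right_id`).
#' @export
degrade_to_flanks <- function(sim, mismatch_fraction, seed = 1L) {
  set.seed(seed)
  if (mismatch_fraction <= 0) return(sim)
  det <- sim$detections
  camera <- det$source %in% c("systematic_camera", "opportunistic_camera",
                              "chance_picture")
  single <- camera & runif(nrow(det)) < mismatch_fraction
  det$flank <- ifelse(single, ifelse(runif(nrow(det)) < 0.5, "left", "right"),
                      "both")
  handled <- unique(c(det$id[!camera], sim$dead_recoveries$id,
                      det$id[det$flank == "both"]))
  split_ids <- setdiff(unique(det$id), handled)
  if (!length(split_ids)) { sim$detections <- det; return(sim) }
  map <- data.frame(orig = split_ids,
                    left_id = paste0(split_ids, "_L"),
                    right_id = paste0(split_ids, "_R"),
                    stringsAsFactors = FALSE)
  ind <- sim$individuals
  new_ind <- list()
  for (k in seq_along(split_ids)) {
    idk <- split_ids[k]
    sel <- det$id == idk
    side <- det$flank[sel]
    det$id[sel] <- ifelse(side == "left", map$left_id[k], map$right_id[k])
    row <- ind[ind$id == idk, ]
    for (side_nm in c("left", "right")) {
      if (!any(side == side_nm)) next
      r2 <- row
      r2$id <- if (side_nm == "left") map$left_id[k] else map$right_id[k]
      r2$flank <- side_nm
      r2$sex <- "unknown"            # single-flank animals cannot be sexed
      new_ind[[length(new_ind) + 1L]] <- r2
    }
    ind <- ind[ind$id != idk, ]
  }
  sim$detections <- det
  sim$individuals <- rbind(ind, do.call(rbind, new_ind))
  attr(sim, "flank_map") <- map
  sim
}

#' Write a simulated dataset as delimited text files
#'
#' Emits the CSV dialects the preprocessing functions read
#' (`detections.csv`, `dead_recoveries.csv`, `individuals.csv`, `effort.csv`,
#' `ages_at_death.csv`), the grid description `dataset.yaml`, and
#' `truth.json`.
#'
#' @param sim output of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(sim$detections, "detections.csv")
  wr(sim$dead_recoveries, "dead_recoveries.csv")
  wr(sim$individuals, "individuals.csv")
  wr(sim$effort, "effort.csv")
  if (!is.null(sim$ages_at_death)) wr(sim$ages_at_death, "ages_at_death.csv")
  yaml::write_yaml(list(layout = sim$config$layout,
                        start_lynx_year = sim$grid$start_lynx_year,
                        n_years = sim$grid$n_years,
                        interval_months = sim$grid$interval_months),
                   file.path(dir, "dataset.yaml"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir directory containing the CSV files.
#' @return list with the data frames, the [occasion_grid()] and the layout.
#' @export
read_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  grid <- occasion_grid(meta$start_lynx_year, meta$n_years,
                        meta$interval_months)
  rd <- function(f, ...) read.csv(file.path(dir, f), stringsAsFactors = FALSE, ...)
  det <- rd("detections.csv")
  det$date <- as.Date(det$date)
  rec <- rd("dead_recoveries.csv")
  if (nrow(rec)) rec$date <- as.Date(rec$date)
  ind <- rd("individuals.csv")
  ind$telemetry[is.na(ind$telemetry)] <- ""
  ages <- if (file.exists(file.path(dir, "ages_at_death.csv")))
    rd("ages_at_death.csv") else NULL
  list(detections = det, dead_recoveries = rec, individuals = ind,
       effort = rd("effort.csv"), ages_at_death = ages,
       grid = grid, layout = meta$layout)
}
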