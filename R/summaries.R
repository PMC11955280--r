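# Derived quantities and the end-to-end pipeline: annual survival per lynx
# year, mean survival time of independent animals, annualised emigration,
# and the simulate -> preprocess -> fit -> report orchestration.

#' Posterior distribution of annual survival in a given lynx year
#'
#' Per draw, annual survival for the year is the product of that year's
#' interval survivals, i.e. the inverse-logit of
#' `b0[area, sex, age] + sigma_S * gamma[group, year]` (the six or twelve
#' equal interval survivals multiply back to the annual scale).
#'
#' @param fit an `ms_fit`.
#' @param area inside-area index.
#' @param sex 1 female, 2 male.
#' @param age age class 1..3.
#' @param year 1-based lynx-year index within the fitted window.
#' @return list with `mean`, `q2.5`, `q97.5` and (MCMC) the vector of draws.
#' @export
annual_survival_by_year <- function(fit, area, sex, age, year) {
  spec <- fit$spec
  if (year < 1L || year > spec$n_years)
    stop("year outside the fitted range 1..", spec$n_years)
  if (fit$mode == "mle" || is.null(fit$draws)) {
    s <- plogis(survival_logit(fit$params, spec, area, sex, age, year))
    return(list(mean = s, q2.5 = NA_real_, q97.5 = NA_real_, draws = s))
  }
  params0 <- ms_params(spec, n_ind = length(fit$params$eps))
  nd <- dim(fit$draws)
  vals <- numeric(nd[1] * nd[2])
  k <- 0L
  for (ch in seq_len(nd[2])) for (i in seq_len(nd[1])) {
    p <- ms_unflatten(fit$draws[i, ch, ], spec, params0)
    k <- k + 1L
    vals[k] <- plogis(survival_logit(p, spec, area, sex, age, year))
  }
  list(mean = mean(vals), q2.5 = unname(quantile(vals, 0.025)),
       q97.5 = unname(quantile(vals, 0.975)), draws = vals)
}

#' Mean survival time after independence
#'
#' Truncated discrete life expectancy from the start of the second year of
#' life (independence): the expected number of additional whole years lived,
#' `sum over k = 2..t_max of prod(s[2:k])`, capped at `t_max` years of age.
#' With survival 1 throughout this equals `t_max - 1` years.
#'
#' @param s annual survival schedule: length-3 class vector
#'   `c(juvenile, subadult, adult)` (juvenile unused) or per-age-year vector.
#' @param t_max maximum age (default 18).
#' @return expected years lived after independence.
#' @export
mean_survival_time <- function(s, t_max = T_MAX) {
  s <- expand_schedule(s, t_max)
  s[1] <- 1   # juvenile survival does not enter: expectation from independence
  if (any(is.na(s)) || any(s < 0 | s > 1)) stop("survival outside [0, 1]")
  sum(cumprod(s[2:t_max]))
}

#' Annual movement probability from a per-interval probability
#'
#' `1 - (1 - m)^intervals_per_year`: the probability of at least one move
#' within a year of independent interval opportunities (within-year mortality
#' competition ignored).
#'
#' @param m_interval per-interval movement probability.
#' @param intervals_per_year 6 or 12.
#' @export
annualize_movement <- function(m_interval, intervals_per_year) {
  1 - (1 - m_interval)^intervals_per_year
}

#' @rdname annualize_movement
#' @param m_annual annual movement probability.
#' @export
deannualize_movement <- function(m_annual, intervals_per_year) {
  1 - (1 - m_annual)^(1 / intervals_per_year)
}

#' Derived-quantity report from a fitted model
#'
#' Annual survival (intercept level) with uncertainty intervals, mean
#' survival time of independent animals, and annualised emigration per sex
#' and age class.
#'
#' @param fit an `ms_fit`.
#' @return list of data frames `survival`, `survival_time`, `emigration`.
#' @export
derived_report <- function(fit) {
  spec <- fit$spec
  summ <- fit$summary
  sexes <- if (spec$n_sex == 2L) c("F", "M") else "all"
  ipy <- spec$intervals_per_year
  get <- function(nm) {
    row <- summ[summ$parameter == nm, ]
    if (nrow(row) == 0L) c(NA_real_, NA_real_, NA_real_)
    else c(row$mean, row$q2.5, row$q97.5)
  }
  surv <- do.call(rbind, lapply(seq_len(spec$n_area_in), function(a) {
    do.call(rbind, lapply(seq_along(sexes), function(sx) {
      do.call(rbind, lapply(1:3, function(ag) {
        v <- get(sprintf("S[%d,%s,%s]", a, sexes[sx], AGE_CLASSES[ag]))
        data.frame(area = a, sex = sexes[sx], age_class = AGE_CLASSES[ag],
                   S = v[1], q2.5 = v[2], q97.5 = v[3])
      }))
    }))
  }))
  mst <- do.call(rbind, lapply(seq_len(spec$n_area_in), function(a) {
    do.call(rbind, lapply(seq_along(sexes), function(sx) {
      s_sub <- get(sprintf("S[%d,%s,subadult]", a, sexes[sx]))[1]
      s_ad <- get(sprintf("S[%d,%s,adult]", a, sexes[sx]))[1]
      data.frame(area = a, sex = sexes[sx],
                 mean_survival_time_years =
                   mean_survival_time(c(NA, s_sub, s_ad)))
    }))
  }))
  emig_name <- if (spec$layout == "two_subarea") c("m13", "m23") else "m13"
  emig <- do.call(rbind, lapply(emig_name, function(nm) {
    do.call(rbind, lapply(seq_along(sexes), function(sx) {
      do.call(rbind, lapply(1:3, function(ag) {
        v <- get(sprintf("%s[%s,%s]", nm, sexes[sx], AGE_CLASSES[ag]))[1]
        data.frame(movement = nm, sex = sexes[sx],
                   age_class = AGE_CLASSES[ag], interval_prob = v,
                   annual_prob = annualize_movement(v, ipy))
      }))
    }))
  }))
  list(survival = surv, survival_time = mst, emigration = emig)
}

#' Write / read encounter histories as JSON
#'
#' @param histories named list from [build_histories()].
#' @param path JSON file path.
#' @param layout layout name (controls code labels).
#' @export
write_histories <- function(histories, path, layout = "two_subarea") {
  codes <- obs_codes(layout)
  lab <- names(codes)[match(seq_len(7L), codes)]
  out <- lapply(histories, function(h) {
    list(id = h$id,
         sex = if (is.na(h$sex)) "unknown" else c("F", "M")[h$sex],
         birth_lynx_year = h$birth_lynx_year,
         first = h$first, last = h$last,
         codes = lab[h$y], age_class = h$age_class, tele = h$tele)
  })
  jsonlite::write_json(list(layout = layout,
                            n_occasions = length(histories[[1]]$y),
                            histories = unname(out)),
                       path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  codes <- obs_codes(x$layout)
  hs <- x$histories
  out <- lapply(seq_len(nrow(hs)), function(i) {
    h <- hs[i, ]
    sex <- match(h$sex, c("F", "M"))
    list(id = h$id, sex = sex,
         birth_lynx_year = if (is.null(h$birth_lynx_year[[1]]))
           NA_integer_ else as.integer(h$birth_lynx_year),
         first = as.integer(h$first), last = as.integer(h$last),
         y = as.integer(codes[unlist(h$codes)]),
         age_class = as.integer(unlist(h$age_class)),
         tele = as.integer(unlist(h$tele)))
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Run the full pipeline: simulate (or load) -> preprocess -> fit -> report
#'
#' Orchestrates all stages end to end, logging every preprocessing deletion
#' with counts, and writes the derived-quantity tables when `out_dir` is
#' given. Deterministic given `seed`.
#'
#' @param config a [sim_config()]; ignored when `data_dir` is given.
#' @param seed integer seed for simulation and fitting.
#' @param out_dir optional output directory for data and result files.
#' @param data_dir optional directory of an existing dataset written by
#'   [write_dataset()] (skips simulation).
#' @param mode `"mle"` or `"mcmc"`.
#' @param mcmc list of overrides for [fit_config()] in MCMC mode.
#' @param flank_fraction fraction of eligible individuals degraded to
#'   single-flank pseudo-individuals before preprocessing.
#' @param apply_flank_rule apply [filter_single_flanks()]? Disabling keeps
#'   every single-flank pseudo-individual (used by the deletion-rule
#'   sensitivity experiment).
#' @param sex_structured,effort_effects model-structure toggles passed to
#'   [ms_spec()] (random effects are used in MCMC mode only).
#' @return list with `sim`, `preprocess_report`, `flank_report`, `dataset`,
#'   `fit`, `derived`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir = NULL,
                         data_dir = NULL, mode = "mle", mcmc = list(),
                         flank_fraction = 0, apply_flank_rule = TRUE,
                         sex_structured = TRUE,
                         effort_effects = TRUE) {
  if (is.null(data_dir)) {
    sim <- simulate_population(config, seed)
    if (flank_fraction > 0)
      sim <- degrade_to_flanks(sim, flank_fraction, seed + 1L)
    if (!is.null(out_dir)) write_dataset(sim, file.path(out_dir, "data"))
    data <- sim
    layout <- config$layout
    grid <- sim$grid
    ages <- sim$ages_at_death
  } else {
    sim <- NULL
    data <- read_dataset(data_dir)
    layout <- data$layout
    grid <- data$grid
    ages <- data$ages_at_death
  }
  # flank rule
  flanks <- data.frame(id = data$individuals$id,
                       flank = if (is.null(data$individuals$flank)) "both"
                               else data$individuals$flank)
  fl <- if (apply_flank_rule) filter_single_flanks(flanks)
        else list(retained_ids = flanks$id,
                  report = data.frame(n_both = sum(flanks$flank == "both"),
                                      n_left_only = sum(flanks$flank == "left"),
                                      n_right_only = sum(flanks$flank == "right"),
                                      n_deleted = 0L, deleted_side = "none"))
  individuals <- data$individuals[data$individuals$id %in% fl$retained_ids, ]
  detections <- data$detections[data$detections$id %in% fl$retained_ids, ]
  recoveries <- data$dead_recoveries[data$dead_recoveries$id %in%
                                       c(fl$retained_ids, ""), ]
  bh <- build_histories(detections, recoveries, individuals, grid)
  n_years <- grid$n_years
  spec <- ms_spec(layout = layout, n_years = n_years,
                  intervals_per_year = grid$per_year,
                  sex_structured = sex_structured,
                  year_effects = (mode == "mcmc"),
                  individual_effects = (mode == "mcmc"),
                  effort_effects = effort_effects)
  dataset <- as_ms_dataset(bh$histories, data$effort, grid, spec)
  cfg_args <- c(list(mode = mode, seed = seed), mcmc)
  cfg <- do.call(fit_config, cfg_args)
  fit <- fit_ms(dataset, spec, cfg, ages_at_death = ages)
  derived <- derived_report(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_histories(bh$histories,
                    file.path(out_dir, "histories.json"), layout)
    write.csv(fit$summary, file.path(out_dir, "posterior_summary.csv"),
              row.names = FALSE)
    for (nm in names(derived))
      write.csv(derived[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    report <- c(as.list(bh$report), as.list(fl$report))
    jsonlite::write_json(report, file.path(out_dir, "cleanup_report.json"),
                         auto_unbox = TRUE)
  }
  list(sim = sim, preprocess_report = bh$report, flank_report = fl$report,
       dataset = dataset, fit = fit, derived = derived)
}
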