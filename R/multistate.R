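# Multi-state live-encounter / dead-recovery model: state spaces, transition
# and observation matrices, linear predictors, parameter containers, priors.
#
# Two layouts:
#  * "two_subarea" (7 states): alive sub1, died-this-interval sub1, alive sub2,
#    died-this-interval sub2, alive outside, died-this-interval outside,
#    dead before. Bidirectional movement between the subareas, permanent
#    emigration to outside.
#  * "one_area" (5 states): alive inside, alive outside, died-this-interval
#    inside, died-this-interval outside, dead before. Emigration only.
#
# Mortality happens before movement within an interval, so carcasses are
# recovered where the animal started the interval.

#' State space for a layout
#'
#' @param layout `"two_subarea"` (7 states) or `"one_area"` (5 states).
#' @return object of class `state_space` with ordered state labels and the
#'   observation-column labels of the observation matrix.
#' @export
state_space <- function(layout = c("two_subarea", "one_area")) {
  layout <- match.arg(layout)
  if (layout == "two_subarea") {
    states <- c("alive_sub1", "died_sub1", "alive_sub2", "died_sub2",
                "alive_outside", "died_outside", "dead_before")
    obs <- c("detected_alive_sub1", "recovered_dead_sub1",
             "detected_alive_sub2", "recovered_dead_sub2",
             "detected_alive_outside", "recovered_dead_outside",
             "not_detected")
  } else {
    states <- c("alive_inside", "alive_outside", "died_inside",
                "died_outside", "dead_before")
    obs <- c("detected_alive_inside", "detected_alive_outside",
             "recovered_dead_inside", "recovered_dead_outside",
             "not_detected")
  }
  structure(list(layout = layout, states = states, obs = obs,
                 n_states = length(states)), class = "state_space")
}

#' Interval survival from annual survival
#'
#' The model works on 1- or 2-month occasions; interval survival is annual
#' survival raised to the power `1/intervals_per_year`.
#'
#' @param S_annual annual survival probability in \[0, 1\].
#' @param intervals_per_year 6 (2-month occasions) or 12 (monthly).
#' @return interval survival probability.
#' @export
interval_survival <- function(S_annual, intervals_per_year) {
  if (any(S_annual < 0 | S_annual > 1)) stop("annual survival outside [0, 1]")
  S_annual^(1 / intervals_per_year)
}

#' Annual survival from interval survival (inverse of [interval_survival()])
#' @param s interval survival probability.
#' @param intervals_per_year 6 or 12.
#' @export
annualize <- function(s, intervals_per_year) s^intervals_per_year

#' Transition matrix for one interval
#'
#' Row-stochastic matrix over the layout's states. Mortality precedes
#' movement: from an alive state the animal first dies with probability
#' `1 - s` (entering the died-this-interval state of its current area), and
#' only survivors move. Died-this-interval states pass to the absorbing
#' "dead before" state; emigration (to outside) is permanent.
#'
#' @param s interval survival per area: named or positional vector
#'   `c(sub1, sub2, outside)` for the two-subarea layout, `c(inside, outside)`
#'   for the one-area layout.
#' @param m movement probabilities per interval: `c(m12, m13, m21, m23)` for
#'   two subareas (1<->2 moves and emigration from each), `c(m13)` for one
#'   area (emigration only).
#' @param layout layout name or a [state_space()].
#' @return row-stochastic matrix with state dimnames.
#' @export
build_transition_matrix <- function(s, m, layout = "two_subarea") {
  ss <- if (inherits(layout, "state_space")) layout else state_space(layout)
  if (any(s < 0 | s > 1)) stop("interval survival outside [0, 1]")
  if (any(m < 0 | m > 1)) stop("movement probability outside [0, 1]")
  if (ss$layout == "two_subarea") {
    stopifnot(length(s) >= 3, length(m) >= 4)
    m12 <- m[[1]]; m13 <- m[[2]]; m21 <- m[[3]]; m23 <- m[[4]]
    if (m12 + m13 > 1 || m21 + m23 > 1) stop("movement probabilities sum > 1")
    s1 <- s[[1]]; s2 <- s[[2]]; s3 <- s[[3]]
    T_ <- matrix(0, 7, 7, dimnames = list(ss$states, ss$states))
    T_[1, ] <- c(s1 * (1 - m12 - m13), 1 - s1, s1 * m12, 0, s1 * m13, 0, 0)
    T_[2, 7] <- 1
    T_[3, ] <- c(s2 * m21, 0, s2 * (1 - m21 - m23), 1 - s2, s2 * m23, 0, 0)
    T_[4, 7] <- 1
    T_[5, ] <- c(0, 0, 0, 0, s3, 1 - s3, 0)
    T_[6, 7] <- 1
    T_[7, 7] <- 1
  } else {
    stopifnot(length(s) >= 2, length(m) >= 1)
    m13 <- m[[1]]
    s1 <- s[[1]]; s3 <- s[[2]]
    T_ <- matrix(0, 5, 5, dimnames = list(ss$states, ss$states))
    T_[1, ] <- c(s1 * (1 - m13), s1 * m13, 1 - s1, 0, 0)
    T_[2, ] <- c(0, s3, 0, 1 - s3, 0)
    T_[3, 5] <- 1
    T_[4, 5] <- 1
    T_[5, 5] <- 1
  }
  T_
}

#' Observation (emission) matrix for one occasion
#'
#' Each alive state emits its "detected alive" code with the area's detection
#' probability, each died-this-interval state its "recovered dead" code with
#' the recovery probability, otherwise "not detected". The absorbing dead
#' state is silent.
#'
#' @param p detection probability per alive area: `c(sub1, sub2, outside)` or
#'   `c(inside, outside)`.
#' @param r recovery probability per area, same shape as `p`.
#' @param layout layout name or [state_space()].
#' @return row-stochastic matrix, rows = states, columns = observation codes.
#' @export
build_observation_matrix <- function(p, r, layout = "two_subarea") {
  ss <- if (inherits(layout, "state_space")) layout else state_space(layout)
  if (any(p < 0 | p > 1) || any(r < 0 | r > 1))
    stop("detection/recovery probability outside [0, 1]")
  if (ss$layout == "two_subarea") {
    stopifnot(length(p) >= 3, length(r) >= 3)
    O <- matrix(0, 7, 7, dimnames = list(ss$states, ss$obs))
    for (a in 1:3) {
      O[2 * a - 1, 2 * a - 1] <- p[[a]]; O[2 * a - 1, 7] <- 1 - p[[a]]
      O[2 * a, 2 * a] <- r[[a]];         O[2 * a, 7] <- 1 - r[[a]]
    }
    O[7, 7] <- 1
  } else {
    stopifnot(length(p) >= 2, length(r) >= 2)
    O <- matrix(0, 5, 5, dimnames = list(ss$states, ss$obs))
    O[1, 1] <- p[[1]]; O[1, 5] <- 1 - p[[1]]
    O[2, 2] <- p[[2]]; O[2, 5] <- 1 - p[[2]]
    O[3, 3] <- r[[1]]; O[3, 5] <- 1 - r[[1]]
    O[4, 4] <- r[[2]]; O[4, 5] <- 1 - r[[2]]
    O[5, 5] <- 1
  }
  O
}

#' Prior hyperparameters
#'
#' Defaults: normal(0, 1.5^2) on intercepts, normal(0, 0.5^2) on covariate
#' coefficients, half-t(scale 1, df 2) on standard deviations, uniform on each
#' constrained movement simplex, flat Dirichlet on the sex proportions.
#'
#' @param intercept_sd,coef_sd,sigma_scale,sigma_df hyperparameters.
#' @export
ms_priors <- function(intercept_sd = 1.5, coef_sd = 0.5,
                      sigma_scale = 1, sigma_df = 2) {
  list(intercept_sd = intercept_sd, coef_sd = coef_sd,
       sigma_scale = sigma_scale, sigma_df = sigma_df)
}

#' Model specification
#'
#' Declares the layout, occasion resolution and which effects are active.
#' With `sex_structured = FALSE` all sex dimensions collapse to one class and
#' the sex mixture is not used. In the one-area layout telemetry detection is
#' fixed to 1 (collared animals are localised every occasion); in the
#' two-subarea layout a single telemetry detection intercept is shared across
#' sex and age classes.
#'
#' @param layout `"two_subarea"` or `"one_area"`.
#' @param n_years number of lynx years.
#' @param intervals_per_year occasions per lynx year; defaults to 6 for the
#'   two-subarea layout and 12 for the one-area layout.
#' @param sex_structured separate parameters per sex plus latent sex mixture?
#' @param year_effects random lynx-year effects on survival?
#' @param individual_effects random individual effects on detection?
#' @param effort_effects systematic/opportunistic monitoring covariates on
#'   detection?
#' @param pool_r pool recovery probabilities across subareas (weighted by
#'   recovered-carcass counts) for the age-at-death correction?
#' @param recovery_age_structured estimate a separate recovery intercept per
#'   age class? With `FALSE` a single per-sex recovery level is shared across
#'   ages (removes the weakly identified survival/recovery trade-off of the
#'   corrected age-at-death distribution in small datasets).
#' @param priors from [ms_priors()].
#' @return object of class `ms_spec`.
#' @export
ms_spec <- function(layout = c("two_subarea", "one_area"), n_years,
                    intervals_per_year = NULL, sex_structured = TRUE,
                    year_effects = TRUE, individual_effects = TRUE,
                    effort_effects = TRUE, pool_r = TRUE,
                    recovery_age_structured = TRUE, priors = ms_priors()) {
  layout <- match.arg(layout)
  if (is.null(intervals_per_year))
    intervals_per_year <- if (layout == "two_subarea") 6L else 12L
  structure(list(
    layout = layout, n_years = as.integer(n_years),
    intervals_per_year = as.integer(intervals_per_year),
    n_area_in = if (layout == "two_subarea") 2L else 1L,
    n_sex = if (sex_structured) 2L else 1L,
    sex_structured = sex_structured,
    year_effects = year_effects,
    individual_effects = individual_effects,
    effort_effects = effort_effects,
    pool_r = pool_r,
    recovery_age_structured = recovery_age_structured,
    priors = priors,
    state_space = state_space(layout)
  ), class = "ms_spec")
}

#' Serialise / restore a model specification as YAML
#' @param spec an [ms_spec()].
#' @param path file path.
#' @export
write_ms_spec <- function(spec, path) {
  x <- unclass(spec)
  x$state_space <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_ms_spec
#' @export
read_ms_spec <- function(path) {
  x <- yaml::read_yaml(path)
  ms_spec(layout = x$layout, n_years = x$n_years,
          intervals_per_year = x$intervals_per_year,
          sex_structured = x$sex_structured, year_effects = x$year_effects,
          individual_effects = x$individual_effects,
          effort_effects = x$effort_effects, pool_r = x$pool_r,
          recovery_age_structured =
            if (is.null(x$recovery_age_structured)) TRUE
            else x$recovery_age_structured,
          priors = do.call(ms_priors, x$priors))
}

#' Parameter container
#'
#' All model parameters on their natural scales, dimensioned by the spec.
#' Intercept arrays are indexed `[area, sex, age]` (age: 1 juvenile,
#' 2 subadult, 3 adult); detection intercepts carry a fourth telemetry
#' dimension (1 = no collar, 2 = active collar). `gamma` (year deviates) and
#' `eps` (individual deviates) are standard-normal under the prior.
#'
#' @param spec an [ms_spec()].
#' @param n_ind number of individuals (length of `eps`).
#' @return a named list of class `ms_params` with zero-initialised logit-scale
#'   intercepts (probabilities 0.5) and zero effects.
#' @export
ms_params <- function(spec, n_ind = 0L) {
  A <- spec$n_area_in
  S <- spec$n_sex
  p <- list(
    b0 = array(0, dim = c(A, S, 3)),
    b03 = 0,
    sigma_S = if (spec$layout == "two_subarea") rep(0, A) else rep(0, 3),
    gamma = matrix(0, nrow = if (spec$layout == "two_subarea") A else 3,
                   ncol = spec$n_years),
    a0 = array(0, dim = c(A + 1L, S, 3, 2)),
    a1 = 0, a2 = 0,
    sigma_p = 0, eps = rep(0, n_ind),
    d0 = array(0, dim = c(S, 3)),
    d12 = 0, d13 = 0,
    m = array(0, dim = c(S, 3, if (spec$layout == "two_subarea") 4L else 1L),
              dimnames = list(NULL, NULL,
                              if (spec$layout == "two_subarea")
                                c("m12", "m13", "m21", "m23") else "m13")),
    psi = c(F = 0.5, M = 0.5)
  )
  structure(p, class = "ms_params")
}

# sex index clamped to the spec's sex dimension (1 when sex-pooled)
sex_eff <- function(spec, sex) if (spec$n_sex == 1L) rep(1L, length(sex)) else sex

#' Annual-survival linear predictor (logit scale)
#'
#' `b0[area, sex, age] + sigma_S * gamma[group, year]` where the random-effect
#' group is the subarea (two-subarea layout) or the age class (one-area
#' layout). `area = "outside"` returns the constant outside mean `b03`.
#'
#' @param params an [ms_params()].
#' @param spec an [ms_spec()].
#' @param area inside-area index (1-based) or `"outside"`.
#' @param sex 1 female, 2 male.
#' @param age age class 1..3.
#' @param year 1-based lynx-year index.
#' @export
survival_logit <- function(params, spec, area, sex, age, year) {
  if (identical(area, "outside")) return(params$b03)
  sx <- sex_eff(spec, sex)
  if (spec$layout == "two_subarea") {
    params$b0[cbind(area, sx, age)] +
      params$sigma_S[area] * params$gamma[cbind(area, year)]
  } else {
    params$b0[cbind(1L, sx, age)] +
      params$sigma_S[age] * params$gamma[cbind(age, year)]
  }
}

#' Detection linear predictor (logit scale)
#'
#' Inside areas: `a0[area, sex, age, tele] + a1*systmon + a2*(oppmon - 1) +
#' sigma_p * eps[i]`; outside: the telemetry/age/sex intercept only. The
#' opportunistic-effort score is centred at its baseline level 1 so the
#' intercept is detection at baseline effort. With an active collar the shared
#' telemetry intercept applies (and in the one-area layout detection is fixed
#' to probability 1, returning `Inf`).
#'
#' @inheritParams survival_logit
#' @param tele 0/1 active telemetry collar.
#' @param systmon systematic-monitoring covariate in \[0, 1\].
#' @param oppmon opportunistic-effort score in \[1, 3\].
#' @param eps individual standard-normal deviate (scalar or vector).
#' @export
detection_logit <- function(params, spec, area, sex, age, tele,
                            systmon = 0, oppmon = 1, eps = 0) {
  if (spec$layout == "one_area" && any(tele == 1L)) {
    out <- detection_logit(params, spec, area, sex, age, rep(0L, length(tele)),
                           systmon, oppmon, eps)
    out[tele == 1L] <- Inf
    return(out)
  }
  sx <- sex_eff(spec, sex)
  a_idx <- if (identical(area, "outside")) spec$n_area_in + 1L else area
  # shared telemetry intercept across sex and age classes
  sx <- ifelse(tele == 1L, 1L, sx)
  age <- ifelse(tele == 1L, 1L, age)
  base <- params$a0[cbind(a_idx, sx, age, tele + 1L)]
  if (!identical(area, "outside") && spec$effort_effects) {
    base <- base + params$a1 * systmon + params$a2 * (oppmon - 1)
  }
  base + params$sigma_p * eps
}

#' Dead-recovery linear predictor (logit scale)
#'
#' `d0[sex, age]` plus the additive subarea offset (`d12` for subarea 2,
#' `d13` for outside) in the two-subarea layout; equal inside and outside in
#' the one-area layout.
#'
#' @inheritParams survival_logit
#' @export
recovery_logit <- function(params, spec, area, sex, age) {
  sx <- sex_eff(spec, sex)
  base <- params$d0[cbind(sx, age)]
  if (spec$layout == "two_subarea") {
    ai <- if (identical(area, "outside")) 3L else as.integer(area)
    base <- base + c(0, params$d12, params$d13)[ai]
  }
  base
}

#' Joint log prior density of a parameter set
#'
#' Sum of the log prior densities of all free parameters: normal on
#' intercepts, normal on covariate coefficients, half-t on standard
#' deviations, standard normal on year/individual deviates, uniform on each
#' constrained movement simplex (density 2 on `m12 + m13 <= 1` pairs, 1 on a
#' single emigration probability), flat Dirichlet on the sex proportions.
#' Parameters outside their support give `-Inf`.
#'
#' @param params an [ms_params()].
#' @param spec an [ms_spec()].
#' @return scalar log density.
#' @export
log_prior <- function(params, spec) {
  pr <- spec$priors
  lp <- 0
  # movement support
  m <- params$m
  if (any(m < 0 | m > 1)) return(-Inf)
  if (spec$layout == "two_subarea") {
    if (any(m[, , "m12"] + m[, , "m13"] > 1) ||
        any(m[, , "m21"] + m[, , "m23"] > 1)) return(-Inf)
    lp <- lp + 2 * length(m[, , 1]) * log(2)  # two uniform simplexes per class
  }
  if (any(params$psi < 0) || abs(sum(params$psi) - 1) > 1e-8) return(-Inf)
  if (any(params$sigma_S < 0) || params$sigma_p < 0) return(-Inf)
  d0_free <- if (isFALSE(spec$recovery_age_structured)) params$d0[, 1]
             else params$d0
  ints <- c(params$b0, params$b03, free_a0(params, spec), d0_free)
  lp <- lp + sum(dnorm(ints, 0, pr$intercept_sd, log = TRUE))
  coefs <- c(if (spec$effort_effects) c(params$a1, params$a2),
             if (spec$layout == "two_subarea") c(params$d12, params$d13))
  if (length(coefs))
    lp <- lp + sum(dnorm(coefs, 0, pr$coef_sd, log = TRUE))
  if (spec$year_effects) {
    lp <- lp + sum(dhalft(params$sigma_S, pr$sigma_scale, pr$sigma_df,
                          log = TRUE))
    lp <- lp + sum(dnorm(params$gamma, 0, 1, log = TRUE))
  }
  if (spec$individual_effects) {
    lp <- lp + dhalft(params$sigma_p, pr$sigma_scale, pr$sigma_df, log = TRUE)
    lp <- lp + sum(dnorm(params$eps, 0, 1, log = TRUE))
  }
  lp
}

# free detection intercepts: all no-collar entries, plus (two-subarea layout)
# one shared telemetry intercept per area; one-area telemetry is fixed to 1.
free_a0 <- function(params, spec) {
  vals <- as.vector(params$a0[, , , 1])
  if (spec$layout == "two_subarea")
    vals <- c(vals, params$a0[, 1, 1, 2])
  vals
}
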