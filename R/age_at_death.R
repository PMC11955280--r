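# Age-at-death (dead-recovery) model: the lifetime of a recovered carcass is
# a categorical variable over ages 1..T_max (T_max = 18, the oldest animal
# recovered), whose cell probabilities derive from age-specific annual
# survival — and, in the recovery-corrected form, from age-specific recovery
# probabilities estimated in the multi-state model. Age-to-class mapping:
# year 1 = juvenile survival, year 2 = subadult, years 3..T_max = adult.

T_MAX <- 18L

# expand 3-class schedule to per-age-year vector of length T_max
expand_schedule <- function(x, t_max = T_MAX) {
  if (length(x) == t_max) return(x)
  stopifnot(length(x) == 3L)
  c(x[1], x[2], rep(x[3], t_max - 2L))
}

#' Age-at-death distribution without recovery correction
#'
#' Probability of dying in year `j` of life, conditional on dying within
#' `t_max` years: `theta_j = prod(s[1:(j-1)]) * (1 - s[j]) /
#' (1 - prod(s[1:t_max]))`.
#'
#' @param s annual survival: either a length-3 class vector
#'   `c(juvenile, subadult, adult)` or a full per-age-year vector.
#' @param t_max maximum age (default 18).
#' @return probability vector of length `t_max` summing to 1.
#' @export
uncorrected_theta <- function(s, t_max = T_MAX) {
  s <- expand_schedule(s, t_max)
  if (any(s < 0 | s > 1)) stop("survival outside [0, 1]")
  cum <- cumprod(c(1, s[-t_max]))
  denom <- 1 - prod(s)
  if (denom <= 0) stop("all annual survivals are 1: age at death undefined")
  cum * (1 - s) / denom
}

#' Probability of dying and being recovered within the maximum lifespan
#'
#' Closed form `P = (1-s1) r1 + s1 (1-s2) r2 + s1 s2 (1-s3) r3 *
#' (s3^(t_max-2) - 1) / (s3 - 1)`, the adult term being a geometric series
#' over years 3..t_max (evaluated by its limit, `t_max - 2` equal terms, when
#' adult survival is 1).
#'
#' @param s length-3 class vector of annual survival.
#' @param r length-3 class vector of recovery probabilities.
#' @param t_max maximum age (default 18).
#' @return scalar probability.
#' @export
recovery_probability_P <- function(s, r, t_max = T_MAX) {
  stopifnot(length(s) == 3L, length(r) == 3L)
  if (any(s < 0 | s > 1) || any(r < 0 | r > 1))
    stop("probabilities outside [0, 1]")
  geom <- if (abs(s[3] - 1) < 1e-12) t_max - 2L
          else (s[3]^(t_max - 2L) - 1) / (s[3] - 1)
  (1 - s[1]) * r[1] + s[1] * (1 - s[2]) * r[2] +
    s[1] * s[2] * (1 - s[3]) * r[3] * geom
}

#' Recovery-corrected age-at-death distribution
#'
#' Probability of dying *and being found* at age `j`, conditional on dying
#' and being found within `t_max` years:
#' `theta_j = prod(s[1:(j-1)]) * (1 - s[j]) * r[j] / P`. When recovery is
#' equal across ages the correction cancels and the uncorrected distribution
#' is returned exactly.
#'
#' @param s,r length-3 class vectors (or full per-age-year vectors) of annual
#'   survival and recovery probability.
#' @param t_max maximum age (default 18).
#' @return probability vector of length `t_max` summing to 1.
#' @export
corrected_theta <- function(s, r, t_max = T_MAX) {
  s <- expand_schedule(s, t_max)
  r <- expand_schedule(r, t_max)
  if (any(s < 0 | s > 1) || any(r < 0 | r > 1))
    stop("probabilities outside [0, 1]")
  cum <- cumprod(c(1, s[-t_max]))
  num <- cum * (1 - s) * r
  P <- sum(num)
  if (P <= 0) stop("recovery probability P is zero: corrected theta undefined")
  num / P
}

#' Log-likelihood of age-at-death records
#'
#' Each record contributes `log theta[sex, age]` under the recovery-corrected
#' age-at-death distribution; unknown sex is marginalized over the sex
#' proportions `psi`.
#'
#' @param records data frame with columns `sex` (`"F"|"M"|"unknown"`) and
#'   `age_years` (integers in `1..t_max`).
#' @param s,r 2 x 3 matrices (sex x age class) of annual survival and
#'   recovery probability.
#' @param psi length-2 sex proportions `(F, M)`.
#' @param t_max maximum age (default 18).
#' @return scalar log-likelihood.
#' @export
age_at_death_loglik <- function(records, s, r, psi = c(0.5, 0.5),
                                t_max = T_MAX) {
  age <- as.integer(records$age_years)
  if (any(age < 1L | age > t_max))
    stop("age at death outside 1..", t_max)
  thF <- corrected_theta(s[1, ], r[1, ], t_max)
  thM <- corrected_theta(s[2, ], r[2, ], t_max)
  sex <- records$sex
  lF <- log(thF[age])
  lM <- log(thM[age])
  # observed sexes carry their categorical sex term, as in the encounter model
  contrib <- ifelse(sex == "F", log(psi[1]) + lF,
                    ifelse(sex == "M", log(psi[2]) + lM,
                           mix_logsumexp(lF, lM, psi[1], psi[2])))
  sum(contrib)
}
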