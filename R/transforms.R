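# Bijections between the constrained parameter list and an unconstrained
# vector for optimisation/MCMC: identity on intercepts, coefficients and
# standard-normal deviates, log on standard deviations, stick-breaking logits
# on each constrained movement pair, logit on a single emigration probability
# and on the female proportion.

clip01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

# names and sizes of the estimated blocks, in flattening order
ms_par_blocks <- function(spec, n_ind = 0L) {
  A <- spec$n_area_in; S <- spec$n_sex
  blocks <- list(b0 = A * S * 3L, b03 = 1L,
                 a0_free = (A + 1L) * S * 3L +
                   if (spec$layout == "two_subarea") A + 1L else 0L)
  if (spec$effort_effects) blocks$effort <- 2L
  blocks$d0 <- S * (if (isFALSE(spec$recovery_age_structured)) 1L else 3L)
  if (spec$layout == "two_subarea") blocks$d_off <- 2L
  if (spec$year_effects) {
    G <- if (spec$layout == "two_subarea") A else 3L
    blocks$log_sigma_S <- G
    blocks$gamma <- G * spec$n_years
  }
  if (spec$individual_effects) {
    blocks$log_sigma_p <- 1L
    blocks$eps <- n_ind
  }
  blocks$m <- S * 3L * (if (spec$layout == "two_subarea") 4L else 1L)
  if (spec$sex_structured) blocks$psi <- 1L
  blocks
}

#' Flatten a parameter set to an unconstrained vector
#'
#' Only the parameters active under `spec` are included; standard deviations
#' are log-transformed, movement pairs stick-breaking-logit-transformed, the
#' female proportion logit-transformed.
#'
#' @param params an [ms_params()].
#' @param spec an [ms_spec()].
#' @return named numeric vector.
#' @export
ms_flatten <- function(params, spec) {
  out <- c(b0 = as.vector(params$b0), b03 = params$b03,
           a0 = free_a0(params, spec))
  if (spec$effort_effects) out <- c(out, a1 = params$a1, a2 = params$a2)
  out <- c(out, d0 = if (isFALSE(spec$recovery_age_structured))
    as.vector(params$d0[, 1]) else as.vector(params$d0))
  if (spec$layout == "two_subarea")
    out <- c(out, d12 = params$d12, d13 = params$d13)
  if (spec$year_effects)
    out <- c(out, log_sigma_S = log(pmax(params$sigma_S, 1e-12)),
             gamma = as.vector(params$gamma))
  if (spec$individual_effects)
    out <- c(out, log_sigma_p = log(max(params$sigma_p, 1e-12)),
             eps = params$eps)
  if (spec$layout == "two_subarea") {
    S <- spec$n_sex
    q <- numeric(0)
    for (pair in list(c(1L, 2L), c(3L, 4L))) {
      u1 <- clip01(params$m[, , pair[1]] + params$m[, , pair[2]])
      u2 <- clip01(ifelse(u1 > 0, params$m[, , pair[1]] / u1, 0.5))
      q <- c(q, qlogis(as.vector(u1)), qlogis(as.vector(u2)))
    }
    out <- c(out, m = q)
  } else {
    out <- c(out, m = qlogis(clip01(as.vector(params$m))))
  }
  if (spec$sex_structured)
    out <- c(out, psi = qlogis(clip01(params$psi[1])))
  out
}

#' Rebuild a parameter set from an unconstrained vector
#'
#' Inverse of [ms_flatten()]. Parameters not active under `spec` keep the
#' values in `params0`.
#'
#' @param theta numeric vector as produced by [ms_flatten()].
#' @param spec an [ms_spec()].
#' @param params0 template [ms_params()] supplying fixed entries and sizes.
#' @return an [ms_params()] list.
#' @export
ms_unflatten <- function(theta, spec, params0) {
  p <- params0
  A <- spec$n_area_in; S <- spec$n_sex
  pos <- 0L
  take <- function(k) {
    if (k == 0L) return(numeric(0))
    v <- theta[(pos + 1L):(pos + k)]
    pos <<- pos + k
    v
  }
  p$b0 <- array(take(A * S * 3L), dim = c(A, S, 3))
  p$b03 <- take(1L)
  a0 <- array(0, dim = c(A + 1L, S, 3, 2))
  a0[, , , 1] <- take((A + 1L) * S * 3L)
  if (spec$layout == "two_subarea") {
    tele <- take(A + 1L)
    for (a in seq_len(A + 1L)) a0[a, , , 2] <- tele[a]
  }
  p$a0 <- a0
  if (spec$effort_effects) { p$a1 <- take(1L); p$a2 <- take(1L) }
  p$d0 <- if (isFALSE(spec$recovery_age_structured))
    array(rep(take(S), 3L), dim = c(S, 3))
  else array(take(S * 3L), dim = c(S, 3))
  if (spec$layout == "two_subarea") { p$d12 <- take(1L); p$d13 <- take(1L) }
  if (spec$year_effects) {
    G <- if (spec$layout == "two_subarea") A else 3L
    p$sigma_S <- exp(take(G))
    p$gamma <- matrix(take(G * spec$n_years), G, spec$n_years)
  }
  if (spec$individual_effects) {
    p$sigma_p <- exp(take(1L))
    p$eps <- take(length(params0$eps))
  }
  if (spec$layout == "two_subarea") {
    m <- array(0, dim = c(S, 3, 4),
               dimnames = list(NULL, NULL, c("m12", "m13", "m21", "m23")))
    for (k in 0:1) {
      u1 <- plogis(matrix(take(S * 3L), S, 3))
      u2 <- plogis(matrix(take(S * 3L), S, 3))
      m[, , 2 * k + 1] <- u1 * u2
      m[, , 2 * k + 2] <- u1 * (1 - u2)
    }
    p$m <- m
  } else {
    p$m <- array(plogis(take(S * 3L)), dim = c(S, 3, 1),
                 dimnames = list(NULL, NULL, "m13"))
  }
  if (spec$sex_structured) {
    f <- plogis(take(1L))
    p$psi <- c(F = f, M = 1 - f)
  }
  if (pos != length(theta)) stop("parameter vector length mismatch")
  p
}

# log |d(constrained)/d(unconstrained)| for the MCMC target
ms_log_jacobian <- function(theta, spec) {
  lj <- 0
  nm <- names(theta)
  sig <- grepl("^log_sigma", nm)
  lj <- lj + sum(theta[sig])
  mq <- theta[startsWith(nm, "m")]
  S3 <- length(mq)
  if (spec$layout == "two_subarea") {
    k <- S3 / 4L
    for (pair in 0:1) {
      q1 <- mq[(2 * pair * k + 1):(2 * pair * k + k)]
      q2 <- mq[(2 * pair * k + k + 1):(2 * pair * k + 2 * k)]
      u1 <- plogis(q1); u2 <- plogis(q2)
      lj <- lj + sum(log(u1) + log(u1 * (1 - u1)) + log(u2 * (1 - u2)))
    }
  } else {
    u <- plogis(mq)
    lj <- lj + sum(log(u * (1 - u)))
  }
  if (spec$sex_structured) {
    f <- plogis(theta[startsWith(nm, "psi")])
    lj <- lj + sum(log(f * (1 - f)))
  }
  lj
}
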