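# Marginalized likelihood of encounter histories: latent states are summed
# out by the forward algorithm, latent sex by a two-component mixture.
# Conditioning is on the state at first capture (no entry process); occasions
# before first capture are skipped entirely.

#' Forward-algorithm log-likelihood of one encounter history
#'
#' Computes `log P(y[2..L] | z[1])` for a sequence of observation codes under
#' per-interval transition matrices and per-occasion observation matrices,
#' with per-occasion normalisation in log space. The initial state is the
#' state observed at first capture. An impossible history (e.g. a detection
#' after a dead recovery) returns `-Inf` with a `"diagnostic"` attribute.
#'
#' @param y integer observation codes (1-based columns of the observation
#'   matrices); `y[1]` is the first capture.
#' @param Tseq list of transition matrices; `Tseq[[t]]` governs the interval
#'   from occasion `t` to `t + 1` (at least `length(y) - 1` entries).
#' @param Oseq list of observation matrices per occasion (at least
#'   `length(y)` entries; `Oseq[[1]]` is unused because the likelihood
#'   conditions on the first capture).
#' @param init_state state index at first capture; defaults to the state
#'   whose observation column is `y[1]` (valid for both layouts' conventions,
#'   where detectable state k emits column k).
#' @return scalar log-likelihood; 0 for a history of length 1.
#' @export
forward_loglik <- function(y, Tseq, Oseq, init_state = y[1]) {
  L <- length(y)
  if (L <= 1L) return(0)
  K <- nrow(Tseq[[1L]])
  alpha <- numeric(K)
  alpha[init_state] <- 1
  ll <- 0
  for (t in 2:L) {
    alpha <- as.vector(alpha %*% Tseq[[t - 1L]])
    alpha <- alpha * Oseq[[t]][, y[t]]
    tot <- sum(alpha)
    if (!(tot > 0)) {
      out <- -Inf
      attr(out, "diagnostic") <-
        sprintf("impossible observation code %d at position %d", y[t], t)
      return(out)
    }
    ll <- ll + log(tot)
    alpha <- alpha / tot
  }
  ll
}

#' Filtered latent-state probabilities (utility)
#'
#' Same recursion as [forward_loglik()] but returning the per-occasion
#' filtered distribution over states.
#'
#' @inheritParams forward_loglik
#' @return matrix `length(y) x K` of filtered probabilities (rows sum to 1).
#' @export
forward_filter <- function(y, Tseq, Oseq, init_state = y[1]) {
  L <- length(y)
  K <- nrow(Tseq[[1L]])
  out <- matrix(0, L, K)
  alpha <- numeric(K)
  alpha[init_state] <- 1
  out[1L, ] <- alpha
  if (L == 1L) return(out)
  for (t in 2:L) {
    alpha <- as.vector(alpha %*% Tseq[[t - 1L]]) * Oseq[[t]][, y[t]]
    tot <- sum(alpha)
    if (!(tot > 0)) stop("impossible history at position ", t)
    alpha <- alpha / tot
    out[t, ] <- alpha
  }
  out
}

# ---- dataset container ------------------------------------------------------

#' Assemble a model-ready dataset from encounter histories
#'
#' @param histories named list from [build_histories()].
#' @param effort data frame `subarea, lynx_year, within, systmon, oppmon`
#'   covering the inside areas and all occasions, or `NULL` for zero effort.
#' @param grid the [occasion_grid()].
#' @param spec an [ms_spec()] (layout and effect toggles).
#' @return object of class `ms_dataset`: observation-code matrix `y`
#'   (individuals x occasions, internal coding), `first`, `last`, `sex`
#'   (0 unknown, 1 F, 2 M), per-occasion `age` and `tele` matrices, the
#'   effort matrices and bookkeeping fields.
#' @export
as_ms_dataset <- function(histories, effort, grid, spec) {
  n <- length(histories)
  T_ <- grid$n_occasions
  A <- spec$n_area_in
  y <- matrix(OBS_ND, n, T_)
  age <- matrix(3L, n, T_)
  tele <- matrix(0L, n, T_)
  first <- integer(n); last <- integer(n); sex <- integer(n)
  for (i in seq_len(n)) {
    h <- histories[[i]]
    y[i, ] <- h$y
    age[i, ] <- h$age_class
    tele[i, ] <- h$tele
    first[i] <- h$first
    last[i] <- h$last
    sex[i] <- if (is.na(h$sex)) 0L else h$sex
  }
  systmon <- matrix(0, A, T_)
  oppmon <- matrix(1, A, grid$n_years)
  if (!is.null(effort)) {
    a <- area_index(effort$subarea)
    keep <- a <= A
    occ <- (effort$lynx_year[keep] - grid$start_lynx_year) * grid$per_year +
      effort$within[keep] + 1L
    systmon[cbind(a[keep], occ)] <- effort$systmon[keep]
    yr <- effort$lynx_year[keep] - grid$start_lynx_year + 1L
    oppmon[cbind(a[keep], yr)] <- effort$oppmon[keep]
  }
  structure(list(
    y = y, first = first, last = last, sex = sex, age = age, tele = tele,
    year = occasion_year_index(grid), systmon = systmon, oppmon = oppmon,
    ids = names(histories), n = n, n_occasions = T_, grid = grid
  ), class = "ms_dataset")
}

#' @export
print.ms_dataset <- function(x, ...) {
  cat(sprintf("ms_dataset: %d individuals x %d occasions (%d recoveries, %d unknown sex)\n",
              x$n, x$n_occasions, sum(x$y %in% c(2L, 4L, 6L)),
              sum(x$sex == 0L)))
  invisible(x)
}

# ---- rate tables ------------------------------------------------------------

# interval survival per (area, sex, age, year) inside the study population
build_s_tab <- function(params, spec) {
  A <- spec$n_area_in; S <- spec$n_sex; Y <- spec$n_years
  arr <- array(0, c(A, S, 3, Y))
  for (a in seq_len(A)) for (ag in 1:3) {
    re <- if (spec$layout == "two_subarea")
      params$sigma_S[a] * params$gamma[a, ]
    else params$sigma_S[ag] * params$gamma[ag, ]
    for (sx in seq_len(S))
      arr[a, sx, ag, ] <- plogis(params$b0[a, sx, ag] + re)
  }
  arr^(1 / spec$intervals_per_year)
}

# detection logit per (area incl. outside, sex, age, tele, occasion),
# before the individual random effect
build_p_logit_tab <- function(params, spec, dataset) {
  A <- spec$n_area_in
  T_ <- dataset$n_occasions
  eff <- matrix(0, A, T_)
  if (spec$effort_effects) {
    eff <- params$a1 * dataset$systmon +
      params$a2 * (dataset$oppmon[, dataset$year, drop = FALSE] - 1)
  }
  arr <- array(0, c(A + 1L, spec$n_sex, 3, 2, T_))
  for (a in seq_len(A + 1L)) for (sx in seq_len(spec$n_sex))
    for (ag in 1:3) for (te in 1:2) {
      sxe <- if (te == 2L) 1L else sx     # shared telemetry intercept
      age_ <- if (te == 2L) 1L else ag
      v <- rep(params$a0[a, sxe, age_, te], T_)
      if (a <= A) v <- v + eff[a, ]
      arr[a, sx, ag, te, ] <- v
    }
  arr
}

build_r_tab <- function(params, spec) {
  A <- spec$n_area_in
  arr <- array(0, c(A + 1L, spec$n_sex, 3))
  off <- if (spec$layout == "two_subarea") c(0, params$d12, params$d13) else c(0, 0)
  for (a in seq_len(A + 1L)) for (sx in seq_len(spec$n_sex))
    arr[a, sx, ] <- params$d0[sx, ] + off[a]
  plogis(arr)
}

# n x T rate matrices for one (assumed) sex
ms_rate_mats <- function(dataset, params, spec, sx) {
  n <- dataset$n; T_ <- dataset$n_occasions
  sxe <- min(sx, spec$n_sex)
  agev <- as.vector(dataset$age)
  yrv <- rep(dataset$year, each = n)
  tv <- rep(seq_len(T_), each = n)
  stab <- build_s_tab(params, spec)
  ptab <- build_p_logit_tab(params, spec, dataset)
  rtab <- build_r_tab(params, spec)
  A <- spec$n_area_in
  zeros <- matrix(0, n, T_)
  sm <- function(a) matrix(stab[cbind(a, sxe, agev, yrv)], n, T_)
  s1m <- sm(1L)
  s2m <- if (A == 2L) sm(2L) else zeros
  s3m <- matrix(plogis(params$b03)^(1 / spec$intervals_per_year), n, T_)
  telev <- as.vector(dataset$tele) + 1L
  peff <- params$sigma_p * params$eps
  if (length(peff) == 0L) peff <- 0
  pm <- function(a) {
    pl <- matrix(ptab[cbind(a, sxe, agev, telev, tv)], n, T_)
    plogis(pl + peff)
  }
  p1m <- pm(1L)
  p2m <- if (A == 2L) pm(2L) else zeros
  p3m <- pm(A + 1L)
  if (spec$layout == "one_area") {        # collared animals always localised
    p1m[dataset$tele == 1L] <- 1
    p3m[dataset$tele == 1L] <- 1
  }
  rm_ <- function(a) matrix(rtab[cbind(a, sxe, agev)], n, T_)
  r1m <- rm_(1L)
  r2m <- if (A == 2L) rm_(2L) else zeros
  r3m <- rm_(A + 1L)
  mm <- function(k) matrix(params$m[cbind(sxe, agev, k)], n, T_)
  if (spec$layout == "two_subarea") {
    m12m <- mm(1L); m13m <- mm(2L); m21m <- mm(3L); m23m <- mm(4L)
  } else {
    m13m <- mm(1L); m12m <- zeros; m21m <- zeros; m23m <- zeros
  }
  list(s1 = s1m, s2 = s2m, s3 = s3m, p1 = p1m, p2 = p2m, p3 = p3m,
       r1 = r1m, r2 = r2m, r3 = r3m,
       m12 = m12m, m13 = m13m, m21 = m21m, m23 = m23m)
}

# the C++ forward pass for one assumed sex
msdr_loglik_sex <- function(dataset, params, spec, sx) {
  if (dataset$n == 0L) return(numeric(0))
  rm <- ms_rate_mats(dataset, params, spec, sx)
  msdr_forward_cpp(dataset$y, dataset$first, dataset$last,
                   rm$s1, rm$s2, rm$s3, rm$p1, rm$p2, rm$p3,
                   rm$r1, rm$r2, rm$r3, rm$m12, rm$m13, rm$m21, rm$m23)
}

# pairwise log(wa*exp(a) + wb*exp(b)) with -Inf safety
mix_logsumexp <- function(a, b, wa, wb) {
  la <- log(wa) + a
  lb <- log(wb) + b
  m <- pmax(la, lb)
  out <- ifelse(is.finite(m), m + log(exp(la - m) + exp(lb - m)), m)
  out
}

# Gauss-Hermite nodes and weights for a standard-normal integral
# (Golub-Welsch eigen decomposition of the Jacobi matrix)
gauss_hermite <- function(n = 9L) {
  i <- seq_len(n - 1L)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- a
  J[cbind(i + 1L, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = sqrt(2) * e$values[ord],
       weights = (e$vectors[1, ]^2)[ord])
}

# log-likelihood at one assumed sex, marginalizing the individual detection
# effect over its standard-normal distribution when `gh` quadrature is given
msdr_loglik_sex_gh <- function(dataset, params, spec, sx, gh = NULL) {
  if (is.null(gh) || !spec$individual_effects || params$sigma_p == 0)
    return(msdr_loglik_sex(dataset, params, spec, sx))
  terms <- vapply(seq_along(gh$nodes), function(k) {
    pk <- params
    pk$eps <- gh$nodes[k]
    log(gh$weights[k]) + msdr_loglik_sex(dataset, pk, spec, sx)
  }, numeric(dataset$n))
  if (dataset$n == 1L) terms <- matrix(terms, nrow = 1L)
  apply(terms, 1, logsumexp)
}

#' Per-individual log-likelihood, marginalized over latent sex
#'
#' Known-sex individuals contribute the forward log-likelihood at their sex;
#' unknown-sex individuals the mixture `log(psi_F L_F + psi_M L_M)`. With a
#' `gh` quadrature rule the individual detection effect is marginalized over
#' its standard-normal distribution (used in maximum-likelihood mode);
#' otherwise the per-individual deviates in `params$eps` are used as given.
#'
#' @param dataset an [as_ms_dataset()].
#' @param params an [ms_params()].
#' @param spec an [ms_spec()].
#' @param gh optional Gauss-Hermite rule (list `nodes`, `weights`).
#' @return numeric vector of per-individual log-likelihood contributions.
#' @export
sex_marginal_loglik <- function(dataset, params, spec, gh = NULL) {
  if (spec$n_sex == 1L)
    return(msdr_loglik_sex_gh(dataset, params, spec, 1L, gh))
  llF <- msdr_loglik_sex_gh(dataset, params, spec, 1L, gh)
  llM <- msdr_loglik_sex_gh(dataset, params, spec, 2L, gh)
  # sex itself is a draw from the sex proportions: observed sexes contribute
  # log psi, unknown sexes the full mixture
  ifelse(dataset$sex == 1L, log(params$psi[1]) + llF,
         ifelse(dataset$sex == 2L, log(params$psi[2]) + llM,
                mix_logsumexp(llF, llM, params$psi[1], params$psi[2])))
}

#' Log posterior kernel of the integrated model
#'
#' Sum of the multi-state data log-likelihood, the (optional) recovery-
#' corrected age-at-death log-likelihood sharing the same survival and
#' recovery parameters, and the log prior.
#'
#' @inheritParams sex_marginal_loglik
#' @param ages_at_death optional data frame `sex ("F"|"M"|"unknown"),
#'   age_years (1..18)`.
#' @param include_prior add [log_prior()]? (`FALSE` gives the data
#'   log-likelihood used in maximum-likelihood mode.)
#' @param gh optional Gauss-Hermite rule passed to [sex_marginal_loglik()].
#' @return scalar log density; `-Inf` for non-finite parameters.
#' @export
total_loglik <- function(dataset, params, spec, ages_at_death = NULL,
                         include_prior = TRUE, gh = NULL) {
  if (!all(is.finite(unlist(params[c("b0", "b03", "a0", "a1", "a2", "d0",
                                     "d12", "d13", "sigma_S", "sigma_p",
                                     "m", "psi")]))))
    return(-Inf)
  ll <- sum(sex_marginal_loglik(dataset, params, spec, gh))
  if (!is.null(ages_at_death) && nrow(ages_at_death) > 0L) {
    sched <- integrated_schedules(params, spec, dataset)
    ll <- ll + age_at_death_loglik(ages_at_death, sched$s, sched$r,
                                   params$psi)
  }
  if (include_prior) ll <- ll + log_prior(params, spec)
  ll
}

#' Annual survival and recovery schedules shared with the age-at-death model
#'
#' The integrated model assumes age- and sex-specific annual survival is
#' common to both data sources. Annual survival is taken at the intercept
#' (year-averaged) level; with two subareas and `pool_r = TRUE`, survival and
#' recovery are pooled across areas weighted by recovered-carcass counts
#' (recovery weights include the outside area; equal weights when the dataset
#' has no recoveries).
#'
#' @inheritParams sex_marginal_loglik
#' @return list with `s` and `r`: 2 x 3 matrices (sex x age class).
#' @export
integrated_schedules <- function(params, spec, dataset = NULL) {
  A <- spec$n_area_in
  s <- matrix(0, 2, 3)
  r <- matrix(0, 2, 3)
  rtab <- build_r_tab(params, spec)
  if (A == 1L) {
    for (sx in 1:2) {
      sxe <- min(sx, spec$n_sex)
      s[sx, ] <- plogis(params$b0[1, sxe, ])
      r[sx, ] <- rtab[1, sxe, ]
    }
    return(list(s = s, r = r))
  }
  w_in <- rep(1, A)
  w_all <- rep(1, A + 1L)
  if (spec$pool_r && !is.null(dataset)) {
    counts <- c(sum(dataset$y == 2L), sum(dataset$y == 4L),
                sum(dataset$y == 6L))
    if (sum(counts[1:2]) > 0) w_in <- counts[1:2]
    if (sum(counts) > 0) w_all <- counts
  }
  w_in <- w_in / sum(w_in)
  w_all <- w_all / sum(w_all)
  for (sx in 1:2) {
    sxe <- min(sx, spec$n_sex)
    s[sx, ] <- colSums(w_in * plogis(matrix(params$b0[, sxe, ], A, 3)))
    r[sx, ] <- colSums(w_all * matrix(rtab[, sxe, ], A + 1L, 3))
  }
  list(s = s, r = r)
}
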