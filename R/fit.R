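# Fitting the integrated model: fast maximum likelihood (fixed effects) for
# testing and simulation experiments, and componentwise adaptive
# random-walk Metropolis for the full Bayesian model, with split-chain R-hat
# and effective-sample-size diagnostics.

#' Fitting configuration
#'
#' @param mode `"mle"` (maximise the data log-likelihood; random effects
#'   disabled) or `"mcmc"` (sample the posterior).
#' @param chains number of MCMC chains (>= 2 for R-hat).
#' @param warmup,draws iterations discarded/kept per chain.
#' @param seed integer seed; every stochastic step derives from it.
#' @param rhat_limit convergence flag threshold on split-chain R-hat.
#' @param min_ess effective-sample-size threshold for the flag.
#' @param optim_maxit BFGS iteration cap in MLE mode.
#' @export
fit_config <- function(mode = c("mle", "mcmc"), chains = 4L, warmup = 1000L,
                       draws = 1000L, seed = 1L, rhat_limit = 1.05,
                       min_ess = 100, optim_maxit = 500L) {
  mode <- match.arg(mode)
  if (mode == "mcmc" && chains < 2L) stop("r-hat needs at least 2 chains")
  if (draws <= 0L) stop("draws must be positive")
  list(mode = mode, chains = as.integer(chains), warmup = as.integer(warmup),
       draws = as.integer(draws), seed = as.integer(seed),
       rhat_limit = rhat_limit, min_ess = min_ess,
       optim_maxit = as.integer(optim_maxit))
}

# natural-scale quantities derived from a parameter set, as a named vector
natural_params <- function(params, spec) {
  A <- spec$n_area_in
  sexes <- if (spec$n_sex == 2L) c("F", "M") else "all"
  out <- c()
  for (a in seq_len(A)) for (sx in seq_along(sexes)) for (ag in 1:3)
    out[sprintf("S[%d,%s,%s]", a, sexes[sx], AGE_CLASSES[ag])] <-
      plogis(params$b0[a, sx, ag])
  out["S_outside"] <- plogis(params$b03)
  for (a in seq_len(A + 1L)) for (sx in seq_along(sexes)) for (ag in 1:3)
    out[sprintf("p[%d,%s,%s]", a, sexes[sx], AGE_CLASSES[ag])] <-
      plogis(params$a0[a, sx, ag, 1])
  rtab <- build_r_tab(params, spec)
  for (a in seq_len(A + 1L)) for (sx in seq_along(sexes)) for (ag in 1:3)
    out[sprintf("r[%d,%s,%s]", a, sexes[sx], AGE_CLASSES[ag])] <-
      rtab[a, sx, ag]
  for (k in seq_len(dim(params$m)[3]))
    for (sx in seq_along(sexes)) for (ag in 1:3)
      out[sprintf("%s[%s,%s]", dimnames(params$m)[[3]][k], sexes[sx],
                  AGE_CLASSES[ag])] <- params$m[sx, ag, k]
  if (spec$effort_effects) { out["a1"] <- params$a1; out["a2"] <- params$a2 }
  if (spec$layout == "two_subarea") {
    out["d12"] <- params$d12; out["d13"] <- params$d13
  }
  if (spec$year_effects)
    out[paste0("sigma_S", seq_along(params$sigma_S))] <- params$sigma_S
  if (spec$individual_effects) out["sigma_p"] <- params$sigma_p
  if (spec$sex_structured) out["psi_F"] <- params$psi[1]
  out
}

#' Fit the integrated model
#'
#' In MLE mode the data log-likelihood (encounter histories plus optional
#' age-at-death records) is maximised over the fixed-effect parameters on
#' unconstrained scales by BFGS; random year and individual effects are not
#' estimable by plain maximisation and are switched off (with a message if
#' the spec requested them). In MCMC mode the full posterior kernel —
#' marginalized likelihood, priors, transform Jacobian — is sampled by
#' componentwise adaptive random-walk Metropolis (adaptation frozen after
#' warmup), and split-chain R-hat and effective sample sizes are attached.
#' Non-convergence flags the result; it is never silent.
#'
#' @param dataset an [as_ms_dataset()].
#' @param spec an [ms_spec()].
#' @param config a [fit_config()].
#' @param ages_at_death optional age-at-death data frame (`sex, age_years`).
#' @return an object of class `ms_fit`: `params` (point estimate or posterior
#'   mean on natural scales), `summary` (per-parameter mean, 2.5 and 97.5
#'   percent quantiles, R-hat, ESS for MCMC), `draws`, `loglik`, `converged`,
#'   `unidentifiable`.
#' @export
fit_ms <- function(dataset, spec, config = fit_config(),
                   ages_at_death = NULL) {
  n_rec_obs <- sum(dataset$y %in% c(2L, 4L, 6L))
  unident <- character(0)
  if (n_rec_obs == 0L &&
      (is.null(ages_at_death) || nrow(ages_at_death) == 0L))
    unident <- c("d0", if (spec$layout == "two_subarea") c("d12", "d13"))
  if (config$mode == "mle") {
    spec_f <- spec
    if (spec$year_effects) {
      message("MLE mode: random year effects disabled")
      spec_f$year_effects <- FALSE
    }
    # individual detection effects are marginalized by Gauss-Hermite
    # quadrature in MLE mode (sigma_p is still estimated)
    gh <- if (spec_f$individual_effects) gauss_hermite(9L) else NULL
    params0 <- ms_params(spec_f, n_ind = 0L)
    if (spec_f$individual_effects) params0$sigma_p <- 0.5
    theta0 <- ms_flatten(params0, spec_f)
    nll <- function(theta) {
      p <- ms_unflatten(theta, spec_f, params0)
      -total_loglik(dataset, p, spec_f, ages_at_death,
                    include_prior = FALSE, gh = gh)
    }
    opt <- optim(theta0, nll, method = "BFGS",
                 control = list(maxit = config$optim_maxit,
                                reltol = 1e-10))
    params_hat <- ms_unflatten(opt$par, spec_f, params0)
    nat <- natural_params(params_hat, spec_f)
    summ <- data.frame(parameter = names(nat), mean = unname(nat),
                       q2.5 = NA_real_, q97.5 = NA_real_,
                       rhat = NA_real_, ess = NA_real_)
    return(structure(list(mode = "mle", spec = spec_f, params = params_hat,
                          loglik = -opt$value,
                          converged = opt$convergence == 0L,
                          unidentifiable = unident, summary = summ,
                          draws = NULL, config = config),
                     class = "ms_fit"))
  }
  # --- MCMC ---
  params0 <- ms_params(spec, n_ind = dataset$n)
  theta0 <- ms_flatten(params0, spec)
  d <- length(theta0)
  target <- function(theta) {
    p <- ms_unflatten(theta, spec, params0)
    total_loglik(dataset, p, spec, ages_at_death, include_prior = TRUE) +
      ms_log_jacobian(theta, spec)
  }
  n_iter <- config$warmup + config$draws
  draws <- array(NA_real_, c(config$draws, config$chains, d),
                 dimnames = list(NULL, NULL, names(theta0)))
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch * 10007L)   # distinct stream per chain
    th <- theta0
    for (try in 1:25) {
      cand <- theta0 + rnorm(d, sd = 0.1)
      if (is.finite(target(cand))) { th <- cand; break }
    }
    lp <- target(th)
    if (!is.finite(lp)) stop("could not initialise chain ", ch)
    ls <- rep(log(0.25), d)
    acc <- numeric(d)
    for (it in seq_len(n_iter)) {
      for (j in seq_len(d)) {
        prop <- th
        prop[j] <- th[j] + exp(ls[j]) * rnorm(1)
        lpp <- target(prop)
        if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
          th <- prop; lp <- lpp; acc[j] <- acc[j] + 1
        }
      }
      if (it <= config$warmup && it %% 50L == 0L) {
        rate <- acc / 50
        acc[] <- 0
        ls <- ls + ifelse(rate > 0.44, 1, -1) * min(0.3, 5 / sqrt(it))
      }
      if (it > config$warmup) draws[it - config$warmup, ch, ] <- th
    }
  }
  # natural-scale draws
  nat0 <- natural_params(params0, spec)
  nat_draws <- array(NA_real_, c(config$draws, config$chains, length(nat0)),
                     dimnames = list(NULL, NULL, names(nat0)))
  for (ch in seq_len(config$chains)) for (k in seq_len(config$draws)) {
    p <- ms_unflatten(draws[k, ch, ], spec, params0)
    nat_draws[k, ch, ] <- natural_params(p, spec)
  }
  diag_df <- diagnostics(nat_draws)
  flat <- matrix(nat_draws, nrow = config$draws * config$chains,
                 dimnames = list(NULL, names(nat0)))
  summ <- data.frame(
    parameter = names(nat0),
    mean = colMeans(flat),
    q2.5 = apply(flat, 2, quantile, 0.025),
    q97.5 = apply(flat, 2, quantile, 0.975),
    rhat = diag_df$rhat, ess = diag_df$ess, row.names = NULL)
  post_mean_theta <- apply(matrix(draws, ncol = d,
                                  dimnames = list(NULL, names(theta0))),
                           2, mean)
  params_hat <- ms_unflatten(post_mean_theta, spec, params0)
  conv <- all(summ$rhat < config$rhat_limit, na.rm = TRUE)
  if (!conv) warning("MCMC non-convergence: max r-hat = ",
                     round(max(summ$rhat, na.rm = TRUE), 3))
  structure(list(mode = "mcmc", spec = spec, params = params_hat,
                 loglik = NA_real_, converged = conv,
                 unidentifiable = unident, summary = summ,
                 draws = draws, natural_draws = nat_draws, config = config),
            class = "ms_fit")
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("ms_fit (%s): %s layout, converged: %s\n", x$mode,
              x$spec$layout, x$converged))
  surv <- x$summary[grepl("^S\\[", x$summary$parameter), ]
  print(surv, row.names = FALSE, digits = 3)
  if (length(x$unidentifiable))
    cat("unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

# ---- convergence diagnostics ------------------------------------------------

split_chain_matrix <- function(x) {
  # iterations x chains -> half-length iterations x 2*chains
  n <- nrow(x) %/% 2L
  cbind(x[seq_len(n), , drop = FALSE],
        x[(nrow(x) - n + 1L):nrow(x), , drop = FALSE])
}

rhat_split <- function(x) {
  x <- split_chain_matrix(x)
  n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_split <- function(x) {
  x <- split_chain_matrix(x)
  n <- nrow(x); m <- ncol(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  max_lag <- min(n - 2L, 500L)
  acov <- sapply(seq_len(m), function(j)
    acf(x[, j], lag.max = max_lag, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)[-1L]) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  npair <- length(rho) %/% 2L
  psum <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  tau <- 1
  prev <- Inf
  for (k in seq_len(npair)) {
    if (psum[k] < 0) break
    pk <- min(psum[k], prev)
    tau <- tau + 2 * pk
    prev <- pk
  }
  n * m / tau
}

#' Split-chain R-hat and effective sample size
#'
#' Potential scale reduction computed on split chains and effective sample
#' size from the pairwise-summed autocorrelation sequence (initial monotone
#' positive estimator).
#'
#' @param draws array `iterations x chains x parameters` (at least 2 chains)
#'   with parameter dimnames.
#' @return data frame `parameter, rhat, ess`, with attribute `"flagged"`
#'   listing parameters whose R-hat exceeds `rhat_limit`.
#' @param rhat_limit threshold for the flag attribute.
#' @export
diagnostics <- function(draws, rhat_limit = 1.05) {
  if (length(dim(draws)) != 3L) stop("draws must be iterations x chains x parameters")
  if (dim(draws)[2] < 2L) stop("r-hat undefined for a single chain")
  pn <- dimnames(draws)[[3]]
  if (is.null(pn)) pn <- paste0("par", seq_len(dim(draws)[3]))
  out <- data.frame(
    parameter = pn,
    rhat = vapply(seq_len(dim(draws)[3]),
                  function(k) rhat_split(draws[, , k]), numeric(1)),
    ess = vapply(seq_len(dim(draws)[3]),
                 function(k) ess_split(draws[, , k]), numeric(1)))
  attr(out, "flagged") <- out$parameter[!is.na(out$rhat) &
                                          out$rhat > rhat_limit]
  out
}

# ---- posterior predictive check --------------------------------------------

# replay the state+observation process over the dataset skeleton for one
# parameter set; returns replicate detection and recovery counts
replicate_counts <- function(dataset, params, spec) {
  n <- dataset$n; T_ <- dataset$n_occasions
  if (n == 0L) return(c(n_detections = 0, n_recoveries = 0))
  sex_use <- dataset$sex
  unk <- sex_use == 0L
  if (any(unk))
    sex_use[unk] <- 1L + (runif(sum(unk)) > params$psi[1])
  ratesF <- ms_rate_mats(dataset, params, spec, 1L)
  ratesM <- if (spec$n_sex == 2L) ms_rate_mats(dataset, params, spec, 2L)
            else ratesF
  z <- matrix(0L, n, T_)
  state0 <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L)[dataset$y[cbind(seq_len(n), dataset$first)]]
  z[cbind(seq_len(n), dataset$first)] <- state0
  n_det <- 0L; n_rec <- 0L
  pick <- function(mat, i, t) mat[cbind(i, rep(t, length(i)))]
  for (t in 2:T_) {
    act <- which(dataset$first < t & dataset$last >= t)
    if (!length(act)) next
    prev <- z[act, t - 1L]
    newz <- rep(7L, length(act))
    for (st in c(1L, 3L, 5L)) {
      ii <- which(prev == st)
      if (!length(ii)) next
      gi <- act[ii]
      R <- ifelse(sex_use[gi] == 1L, 1L, 2L)
      getr <- function(nm) {
        a <- pick(ratesF[[nm]], gi, t)
        b <- pick(ratesM[[nm]], gi, t)
        ifelse(R == 1L, a, b)
      }
      s <- switch(as.character(st), "1" = getr("s1"), "3" = getr("s2"),
                  "5" = getr("s3"))
      dies <- runif(length(gi)) > s
      out <- rep(st, length(gi))
      out[dies] <- st + 1L
      if (st != 5L) {
        mv <- runif(length(gi))
        mA <- if (st == 1L) getr("m12") else getr("m21")
        mO <- if (st == 1L) getr("m13") else getr("m23")
        out[!dies & mv < mA] <- if (st == 1L) 3L else 1L
        out[!dies & mv >= mA & mv < mA + mO] <- 5L
      }
      newz[ii] <- out
    }
    z[act, t] <- newz
    # observations
    for (st in c(1L, 3L, 5L)) {
      ii <- act[newz == st]
      if (!length(ii)) next
      R <- ifelse(sex_use[ii] == 1L, 1L, 2L)
      pnm <- c("1" = "p1", "3" = "p2", "5" = "p3")[as.character(st)]
      p <- ifelse(R == 1L, pick(ratesF[[pnm]], ii, t),
                  pick(ratesM[[pnm]], ii, t))
      n_det <- n_det + sum(runif(length(ii)) < p)
    }
    for (st in c(2L, 4L, 6L)) {
      ii <- act[newz == st]
      if (!length(ii)) next
      R <- ifelse(sex_use[ii] == 1L, 1L, 2L)
      rnm <- c("2" = "r1", "4" = "r2", "6" = "r3")[as.character(st)]
      r <- ifelse(R == 1L, pick(ratesF[[rnm]], ii, t),
                  pick(ratesM[[rnm]], ii, t))
      n_rec <- n_rec + sum(runif(length(ii)) < r)
    }
  }
  c(n_detections = n_det, n_recoveries = n_rec)
}

#' Posterior predictive check
#'
#' Draws replicate datasets over the observed dataset's skeleton (same
#' individuals, first captures and censoring) from posterior draws (MCMC) or
#' the point estimate (MLE) and compares detection and recovery counts with
#' the observed ones.
#'
#' @param fit an `ms_fit`.
#' @param dataset the fitted [as_ms_dataset()].
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return data frame of replicate statistics with the observed values and
#'   tail probabilities as attributes.
#' @export
posterior_predictive_check <- function(fit, dataset, n_rep = 50L, seed = 1L) {
  set.seed(seed)
  spec <- fit$spec
  params0 <- ms_params(spec, n_ind = dataset$n)
  stats <- matrix(0, n_rep, 2,
                  dimnames = list(NULL, c("n_detections", "n_recoveries")))
  for (k in seq_len(n_rep)) {
    params <- if (fit$mode == "mcmc") {
      i <- sample.int(dim(fit$draws)[1], 1L)
      ch <- sample.int(dim(fit$draws)[2], 1L)
      ms_unflatten(fit$draws[i, ch, ], spec, params0)
    } else fit$params
    stats[k, ] <- replicate_counts(dataset, params, spec)
  }
  obs <- c(n_detections = sum(dataset$y %in% c(1L, 3L, 5L)) -
             dataset$n,                      # first captures conditioned on
           n_recoveries = sum(dataset$y %in% c(2L, 4L, 6L)))
  out <- as.data.frame(stats)
  attr(out, "observed") <- obs
  attr(out, "p_upper") <- colMeans(sweep(stats, 2, obs, ">="))
  out
}
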