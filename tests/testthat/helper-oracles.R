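# Independent oracles and small generators shared across tests.

# brute-force likelihood: sum over every latent state path (used against the
# forward recursion; deliberately naive)
enum_loglik <- function(y, Tseq, Oseq, init_state = y[1]) {
  K <- nrow(Tseq[[1]])
  L <- length(y)
  if (L <= 1L) return(0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L - 1L)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    z <- c(init_state, paths[r, ])
    pr <- 1
    for (t in 2:L) {
      pr <- pr * Tseq[[t - 1L]][z[t - 1L], z[t]] * Oseq[[t]][z[t], y[t]]
      if (pr == 0) break
    }
    tot <- tot + pr
  }
  log(tot)
}

# random valid rates for a layout (interior probabilities)
random_rates <- function(layout) {
  n_area <- if (layout == "two_subarea") 3L else 2L
  s <- runif(n_area, 0.05, 0.95)
  p <- runif(n_area, 0.05, 0.95)
  r <- runif(n_area, 0.05, 0.95)
  m <- if (layout == "two_subarea") {
    u <- runif(2, 0, 0.9); v <- runif(2)
    c(u[1] * v[1], u[1] * (1 - v[1]), u[2] * v[2], u[2] * (1 - v[2]))
  } else runif(1, 0, 0.5)
  list(s = s, p = p, r = r, m = m)
}

# observation-code sequence simulated from the HMM itself (always has
# positive probability), starting from a live-detection state
simulate_codes <- function(T_, O, L, layout) {
  z <- if (layout == "two_subarea") sample(c(1L, 3L, 5L), 1L)
       else sample(1:2, 1L)
  y <- integer(L)
  y[1] <- z                                  # detectable state k emits code k
  for (t in 2:L) {
    z <- sample.int(ncol(T_), 1L, prob = T_[z, ])
    y[t] <- sample.int(ncol(O), 1L, prob = O[z, ])
  }
  y
}

# arbitrary (possibly impossible) code sequence
random_codes <- function(layout, L) {
  nc <- if (layout == "two_subarea") 7L else 5L
  first <- if (layout == "two_subarea") sample(c(1L, 3L, 5L), 1L)
           else sample(c(1L, 2L), 1L)
  c(first, sample.int(nc, L - 1L, replace = TRUE))
}

# tiny one-area dataset (hand-built histories) for likelihood-level tests
tiny_dataset <- function(spec, y_rows, sex = NULL, age = 3L) {
  T_ <- ncol(y_rows)
  grid <- occasion_grid(2010, ceiling(T_ / spec$intervals_per_year),
                        12 / spec$intervals_per_year)
  n <- nrow(y_rows)
  hs <- lapply(seq_len(n), function(i) {
    y <- rep(7L, grid$n_occasions)
    y[seq_len(T_)] <- y_rows[i, ]
    obs <- which(y != 7L)
    list(id = paste0("i", i), sex = if (is.null(sex)) NA_integer_ else sex[i],
         birth_lynx_year = NA_integer_, first = obs[1L],
         last = grid$n_occasions, y = y,
         age_class = rep(age, grid$n_occasions),
         tele = rep(0L, grid$n_occasions))
  })
  names(hs) <- vapply(hs, `[[`, character(1), "id")
  as_ms_dataset(hs, NULL, grid, spec)
}

# parameter set with every probability interior (avoids -Inf paths)
interior_params <- function(spec, n_ind = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ms_params(spec, n_ind)
  p$b0[] <- rnorm(length(p$b0), 0.5, 0.5)
  p$b03 <- rnorm(1, 0.5, 0.5)
  p$a0[] <- rnorm(length(p$a0), -0.5, 0.5)
  p$d0[] <- rnorm(length(p$d0), -1, 0.5)
  p$m[] <- runif(length(p$m), 0.01, 0.2)
  if (spec$layout == "two_subarea") {
    p$d12 <- rnorm(1, 0, 0.3); p$d13 <- rnorm(1, 0, 0.3)
  }
  p
}
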