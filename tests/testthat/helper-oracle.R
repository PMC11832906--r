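# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain loops, direct products,
# expand.grid state enumeration, logs taken only at the end.

# Brute-force event count: scan inter-image gaps within each stream.
oracle_event_count <- function(times_min, gap) {
  if (length(times_min) == 0L) return(0L)
  n <- 1L
  for (i in seq_along(times_min)[-1L])
    if (times_min[i] - times_min[i - 1L] >= gap) n <- n + 1L
  n
}

# State distribution by direct enumeration (expand.grid order, normalised
# with plain exponentials).
oracle_state_probs <- function(f, g = NULL) {
  S <- length(f)
  states <- as.matrix(expand.grid(rep(list(0:1), S)))
  wts <- numeric(nrow(states))
  for (r in seq_len(nrow(states))) {
    e <- sum(f * states[r, ])
    if (!is.null(g))
      for (nm in names(g)) {
        ij <- match(strsplit(nm, ":")[[1]], names(f))
        e <- e + g[[nm]] * states[r, ij[1]] * states[r, ij[2]]
      }
    wts[r] <- exp(e)
  }
  list(states = states, probs = wts / sum(wts))
}

# Marginalized likelihood of one site by direct summation over all states.
# p_mat: occasions x species detection probabilities; hist in {0,1,NA}.
oracle_site_lik <- function(hist, f, g, p_mat) {
  en <- oracle_state_probs(f, g)
  tot <- 0
  for (r in seq_len(nrow(en$states))) {
    z <- en$states[r, ]
    det <- 1
    for (s in seq_along(f)) {
      ys <- hist[, s]
      ok <- which(!is.na(ys))
      if (z[s] == 1) {
        for (k in ok)
          det <- det * ifelse(ys[k] == 1, p_mat[k, s], 1 - p_mat[k, s])
      } else if (any(ys[ok] == 1)) det <- 0
    }
    tot <- tot + en$probs[r] * det
  }
  tot
}

# Full-dataset log-likelihood: loops over sites, builds p from the design
# matrices with its own logistic.
oracle_loglik <- function(y, f_mat, g_mat, pair_names, p_arr) {
  J <- dim(y)[1]; S <- dim(y)[3]
  ll <- 0
  for (j in seq_len(J)) {
    f <- f_mat[j, ]
    names(f) <- dimnames(y)[[3]]
    g <- if (length(pair_names)) as.list(stats::setNames(g_mat[j, ], pair_names))
         else NULL
    ll <- ll + log(oracle_site_lik(y[j, , , drop = TRUE], f, g,
                                   p_arr[j, , , drop = TRUE]))
  }
  ll
}

# A small standard dataset + design shared by likelihood tests.
make_toy_msom_data <- function(J = 20, K = 5, S = 3, seed = 101,
                               miss_rate = 0.1) {
  set.seed(seed)
  species <- c("roe", "red", "wolf")[seq_len(S)]
  y <- array(rbinom(J * K * S, 1, 0.3), c(J, K, S),
             dimnames = list(NULL, NULL, species))
  y[array(runif(J * K * S) < miss_rate, dim(y))] <- NA
  site_covs <- data.frame(x1 = rnorm(J), x2 = rnorm(J))
  obs <- matrix(rbinom(J * K, 1, 0.4), J, K)
  occ <- stats::setNames(rep(list(~ x1), S), species)
  if (S >= 2) occ[[paste(species[1:2], collapse = ":")]] <- ~ x2
  if (S >= 3) {
    occ[[paste(species[c(1, 3)], collapse = ":")]] <- ~ 1
    occ[[paste(species[c(2, 3)], collapse = ":")]] <- ~ x1 + x2
  }
  det <- stats::setNames(rep(list(~ x2 + u), S), species)
  list(y = y, site_covs = site_covs, obs_covs = list(u = obs),
       occ_formulas = occ, det_formulas = det, species = species)
}
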