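test_that("state probabilities reproduce uniform, independent and coupled cases", {
  # all natural parameters zero: uniform over the four states
  expect_equal(unname(state_probabilities(c(0, 0))), rep(0.25, 4))

  # no pairwise term: distribution factorises into independent Bernoullis
  set.seed(5)
  for (i in 1:10) {
    f <- rnorm(2, 0, 2)
    pr <- state_probabilities(f)
    expect_equal(unname(pr["11"]), plogis(f[1]) * plogis(f[2]),
                 tolerance = 1e-12)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }

  # coupled two-species case, checked against direct enumeration
  pr <- state_probabilities(c(a = 0.5, b = -0.5), c("a:b" = 1))
  expect_equal(unname(pr["11"]),
               exp(1) / (1 + exp(0.5) + exp(-0.5) + exp(1)),
               tolerance = 1e-12)
  expect_lt(abs(unname(pr["11"]) - 0.4551), 1e-4)
  expect_lt(abs(unname(pr["10"] + pr["11"]) - 0.7311), 1e-4)
})

test_that("state probabilities sum to one over random draws and match the oracle", {
  set.seed(17)
  for (i in 1:25) {
    S <- sample(1:3, 1)
    f <- rnorm(S, 0, 3)
    names(f) <- letters[seq_len(S)]
    g <- NULL
    if (S >= 2) {
      prs <- combn(names(f), 2)
      g <- stats::setNames(rnorm(ncol(prs), 0, 2),
                           apply(prs, 2, paste, collapse = ":"))
    }
    pr <- state_probabilities(f, g)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    en <- oracle_state_probs(f, g)
    key <- apply(en$states, 1, function(z) paste(z, collapse = ""))
    expect_equal(unname(pr[key]), en$probs, tolerance = 1e-12)
  }
})

test_that("detection probability is the logistic of the linear predictor", {
  expect_equal(detection_probability(c(0, 0, 0), c(1, 2, 3)), 0.5)
  expect_lt(abs(detection_probability(-1.568, 1) - 0.173), 1e-3)
  set.seed(8)
  a <- rnorm(4); V <- matrix(rnorm(12), 3)
  expect_equal(detection_probability(a, V),
               1 / (1 + exp(-drop(V %*% a))), tolerance = 1e-12)
  expect_error(detection_probability(c(0, 1), c(1, 2, 3)), "columns")
})

test_that("single-species site likelihoods match the textbook closed form", {
  # psi = p = 0.5, two occasions
  expect_equal(exp(site_log_likelihood(c(0, 0), f = 0, p = 0.5)), 0.625)
  expect_equal(exp(site_log_likelihood(c(1, 0), f = 0, p = 0.5)), 0.125)
  # psi * p^2 when both occasions detect
  expect_equal(exp(site_log_likelihood(c(1, 1), f = 0, p = 0.3)),
               0.5 * 0.09)
  # missing occasions contribute nothing
  expect_equal(site_log_likelihood(c(1, NA, 0), f = 0.7, p = 0.4),
               site_log_likelihood(c(1, 0), f = 0.7, p = 0.4))
  expect_error(site_log_likelihood(c(NA, NA), f = 0, p = 0.5), "missing")
})

test_that("the marginalized log-likelihood equals brute-force enumeration", {
  toy <- make_toy_msom_data(J = 20, K = 5, S = 3)
  d <- camsom:::msom_designs(toy$y, toy$occ_formulas, toy$det_formulas,
                             toy$site_covs, toy$obs_covs)
  set.seed(99)
  for (i in 1:10) {
    par <- rnorm(d$npar, 0, 0.8)
    # oracle rebuilds f, g, p itself from the design matrices
    f_mat <- sapply(d$species, function(s)
      drop(d$Xocc[[s]] %*% camsom:::par_block(d, par, paste0("psi[", s, "]"))))
    g_mat <- sapply(d$pairs, function(nm)
      drop(d$Xpair[[nm]] %*% camsom:::par_block(d, par, paste0("psi[", nm, "]"))))
    p_arr <- array(dim = c(d$J, d$K, d$S))
    for (s in seq_len(d$S)) {
      q <- drop(d$Wdet[[s]] %*%
                  camsom:::par_block(d, par, paste0("p[", d$species[s], "]")))
      p_arr[, , s] <- matrix(1 / (1 + exp(-q)), d$J, d$K)
    }
    expect_equal(camsom:::msom_loglik(d, par),
                 oracle_loglik(toy$y, f_mat, g_mat, d$pairs, p_arr),
                 tolerance = 1e-10)
  }
})

test_that("the analytic gradient matches central finite differences", {
  toy <- make_toy_msom_data(J = 15, K = 4, S = 3, seed = 55)
  d <- camsom:::msom_designs(toy$y, toy$occ_formulas, toy$det_formulas,
                             toy$site_covs, toy$obs_covs)
  set.seed(56)
  par <- rnorm(d$npar, 0, 0.5)
  ga <- camsom:::msom_grad(d, par)
  gn <- vapply(seq_len(d$npar), function(i) {
    h <- 1e-6 * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    (camsom:::msom_loglik(d, up) - camsom:::msom_loglik(d, dn)) / (2 * h)
  }, numeric(1))
  expect_equal(ga, gn, tolerance = 1e-5)
})

test_that("the grouped detection path agrees with elementwise evaluation", {
  toy <- make_toy_msom_data(J = 12, K = 6, S = 2, seed = 77)
  d <- camsom:::msom_designs(toy$y, toy$occ_formulas, toy$det_formulas,
                             toy$site_covs, toy$obs_covs)
  d_plain <- d
  d_plain$grp <- vector("list", d$S)  # force the elementwise fallback
  set.seed(78)
  for (i in 1:5) {
    par <- rnorm(d$npar)
    expect_equal(camsom:::msom_loglik(d, par),
                 camsom:::msom_loglik(d_plain, par), tolerance = 1e-12)
    expect_equal(camsom:::msom_grad(d, par),
                 camsom:::msom_grad(d_plain, par), tolerance = 1e-9)
  }
})

test_that("the likelihood is invariant to species relabeling", {
  toy <- make_toy_msom_data(J = 18, K = 5, S = 3, seed = 31)
  d <- camsom:::msom_designs(toy$y, toy$occ_formulas, toy$det_formulas,
                             toy$site_covs, toy$obs_covs)
  set.seed(32)
  par <- rnorm(d$npar, 0, 0.6)
  ll <- camsom:::msom_loglik(d, par)

  # permute species order (and rename pairs to match the new order)
  perm <- c(3, 1, 2)
  y2 <- toy$y[, , perm]
  occ2 <- toy$occ_formulas
  det2 <- toy$det_formulas[dimnames(y2)[[3]]]
  d2 <- camsom:::msom_designs(y2, occ2, det2, toy$site_covs, toy$obs_covs)
  # map the packed parameters by name
  par2 <- numeric(d2$npar)
  names(par) <- d$par_names
  canon <- function(nms) {
    # pair names may appear with members swapped; canonicalise
    vapply(nms, function(x) {
      m <- regmatches(x, regexec("^(psi|p)\\[([^]]+)\\] (.*)$", x))[[1]]
      sp <- paste(sort(strsplit(m[3], ":")[[1]]), collapse = ":")
      paste0(m[2], "[", sp, "] ", m[4])
    }, character(1))
  }
  par2 <- par[match(canon(d2$par_names), canon(d$par_names))]
  expect_equal(camsom:::msom_loglik(d2, unname(par2)), ll, tolerance = 1e-10)
})

test_that("daily Bernoulli and binomial detection-frequency forms agree", {
  # with constant p, the site likelihood depends on the history only through
  # the detection count: the Bernoulli product equals the binomial form up
  # to the (parameter-free) binomial coefficient
  f <- 0.3; p <- 0.35; K <- 6
  hist1 <- c(1, 1, 0, 0, 0, 0)
  hist2 <- c(0, 0, 1, 0, 1, 0)
  expect_equal(site_log_likelihood(hist1, f = f, p = p),
               site_log_likelihood(hist2, f = f, p = p), tolerance = 1e-12)
  # and equals psi * dbinom / choose + (1 - psi) * [y = 0]
  lik <- plogis(f) * dbinom(2, K, p) / choose(K, 2)
  expect_equal(exp(site_log_likelihood(hist1, f = f, p = p)), lik,
               tolerance = 1e-12)
})
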