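# A fitted shell whose coefficients we set by hand: derived quantities are
# deterministic functions of the coefficients, so closed-form cases can be
# checked exactly.
shell_fit <- function(f1 = 0.5, f2 = -0.5, f12 = 1.0, J = 7) {
  set.seed(1)
  y <- array(rbinom(J * 3 * 2, 1, 0.4), c(J, 3, 2),
             dimnames = list(NULL, NULL, c("a", "b")))
  fit <- msom(y, occ_formulas = list(a = ~1, b = ~1, "a:b" = ~1),
              det_formulas = list(a = ~1, b = ~1),
              control = msom_control(nstart = 1, maxit = 5, se = FALSE))
  cf <- fit$coefficients
  cf["psi[a] (Intercept)"] <- f1
  cf["psi[b] (Intercept)"] <- f2
  cf["psi[a:b] (Intercept)"] <- f12
  fit$coefficients <- cf
  fit$vcov <- diag(0.01, fit$npar)
  dimnames(fit$vcov) <- list(names(cf), names(cf))
  fit
}

test_that("marginal occupancy matches state enumeration and logistic reduction", {
  fit <- shell_fit(0.5, -0.5, 1.0)
  psi <- marginal_occupancy(fit, average = FALSE)
  expect_equal(unname(psi[1, "a"]), 0.7311, tolerance = 1e-4)
  expect_equal(unname(psi[1, "b"]), 0.5566, tolerance = 1e-4)
  en <- oracle_state_probs(c(a = 0.5, b = -0.5), c("a:b" = 1))
  expect_equal(unname(psi[1, "a"]), sum(en$probs[en$states[, 1] == 1]),
               tolerance = 1e-12)

  avg <- marginal_occupancy(fit)
  expect_equal(avg$estimate, unname(psi[1, ]), ignore_attr = TRUE)
  expect_true(all(avg$se > 0))

  # with the pairwise term at zero the marginal is exactly logistic
  fit0 <- shell_fit(0.8, -1.3, 0)
  psi0 <- marginal_occupancy(fit0, average = FALSE)
  expect_equal(unname(psi0[1, ]), plogis(c(0.8, -1.3)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("conditional occupancy follows from the state distribution", {
  fit <- shell_fit(0.5, -0.5, 1.0)
  c1 <- conditional_occupancy(fit, "a", given = "b", present = TRUE)
  expect_equal(c1$estimate, 0.4551 / 0.5566, tolerance = 1e-3)

  # independence: conditional equals marginal either way
  fit0 <- shell_fit(0.5, -0.5, 0)
  for (pres in c(TRUE, FALSE))
    expect_equal(
      conditional_occupancy(fit0, "a", "b", present = pres)$estimate,
      plogis(0.5), tolerance = 1e-12)

  # strong positive dependence forces the conditional towards one
  fit_inf <- shell_fit(0.5, -0.5, 30)
  expect_gt(conditional_occupancy(fit_inf, "a", "b")$estimate, 0.999)

  expect_error(conditional_occupancy(fit, "a", "zz"), "not in the model")
})

test_that("the law of total probability ties marginals and conditionals", {
  fit <- shell_fit(-0.3, 0.9, -0.7)
  psi_a <- marginal_occupancy(fit, average = FALSE)[1, "a"]
  psi_b <- marginal_occupancy(fit, average = FALSE)[1, "b"]
  a_if_b <- conditional_occupancy(fit, "a", "b", TRUE, average = FALSE)[1]
  a_not_b <- conditional_occupancy(fit, "a", "b", FALSE, average = FALSE)[1]
  expect_equal(unname(psi_a),
               unname(a_if_b * psi_b + a_not_b * (1 - psi_b)),
               tolerance = 1e-12)
})

test_that("co-occurrence probability never exceeds either marginal", {
  fit <- shell_fit(0.4, 0.2, 0.8)
  co <- cooccurrence_probability(fit, c("a", "b"), average = FALSE)
  psi <- marginal_occupancy(fit, average = FALSE)
  expect_true(all(co <= psi[, "a"] + 1e-12))
  expect_true(all(co <= psi[, "b"] + 1e-12))
  en <- oracle_state_probs(c(a = 0.4, b = 0.2), c("a:b" = 0.8))
  both <- en$states[, 1] == 1 & en$states[, 2] == 1
  expect_equal(unname(co[1]), sum(en$probs[both]), tolerance = 1e-12)
  expect_error(cooccurrence_probability(fit, c("a", "zz")), "two modelled")
})

test_that("detection predictions equal direct logistic evaluation with CIs", {
  sim <- simulate_survey(sim_config(J = 40), seed = 29)
  fit <- msom(sim$y, sim$config$occ_formulas, sim$config$det_formulas,
              sim$truth$site_covs_std, sim$obs_covs,
              control = msom_control(nstart = 1))
  grid <- expand.grid(visual = c(-1, 0, 1), tri = 0, trail = c(0, 1),
                      hunting = c(0, 1))
  pred <- predict_detection(fit, grid)
  expect_equal(nrow(pred), nrow(grid) * 3L)
  a <- coef(fit)[sprintf("p[roe] %s",
                         c("(Intercept)", "visual", "tri", "trail", "hunting"))]
  roe <- pred[pred$species == "roe", ]
  q <- a[1] + a[2] * grid$visual + a[3] * grid$tri + a[4] * grid$trail +
    a[5] * grid$hunting
  expect_equal(roe$p, unname(plogis(q)), tolerance = 1e-12)
  expect_true(all(roe$lower <= roe$p & roe$p <= roe$upper))

  # mean covariates reduce to the logistic of the intercept
  p0 <- predict_detection(fit, data.frame(visual = 0, tri = 0, trail = 0,
                                          hunting = 0), species = "roe")
  expect_equal(p0$p, unname(plogis(a[1])), tolerance = 1e-12)

  # a negative hunting coefficient lowers detection on hunting days
  if (a[5] < 0) {
    ph <- predict_detection(fit, data.frame(visual = 0, tri = 0, trail = 0,
                                            hunting = c(0, 1)), species = "roe")
    expect_lt(ph$p[2], ph$p[1])
  }
  expect_error(predict_detection(fit, data.frame(visual = 0)), "lacks")
})

test_that("the occupancy summary reports coherent naive, psi and p values", {
  sim <- simulate_survey(sim_config(J = 45), seed = 37)
  # at survey-scale J some pair slopes are weakly identified; the fit warns
  # about the non-PD Hessian, which is expected here
  fit <- suppressWarnings(
    msom(sim$y, sim$config$occ_formulas, sim$config$det_formulas,
         sim$truth$site_covs_std, sim$obs_covs,
         control = msom_control(nstart = 1)))
  tab <- occupancy_summary(fit)
  expect_equal(tab$species, sim$config$species)
  expect_true(all(tab$psi >= 0 & tab$psi <= 1))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$se_psi > 0 & tab$se_p > 0))
  arr_naive <- naive_occupancy(sim$y)
  expect_equal(tab$naive_psi, unname(arr_naive))
  # psi-hat should not fall below naive occupancy by more than noise
  expect_true(all(tab$psi > tab$naive_psi - 0.15))
  # evaluation at covariate means is a different but nearby aggregation
  tab_m <- occupancy_summary(fit, at_means = TRUE)
  expect_true(all(abs(tab_m$psi - tab$psi) < 0.25))
  expect_true(all(tab_m$p >= 0 & tab_m$p <= 1))
  # predict() dispatch reaches the same workers
  expect_equal(predict(fit, "occupancy"), marginal_occupancy(fit))
})
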