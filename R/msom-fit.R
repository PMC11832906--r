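#' Fit a multi-species occupancy model by maximum likelihood
#'
#' Fits the Rota-type co-occurrence occupancy model: the latent community
#' state of the S species at each site follows a multivariate Bernoulli
#' distribution whose per-species (`f_i`) and pairwise (`f_ij`) natural
#' parameters are linear in site covariates; daily detection of each species,
#' conditional on presence, is Bernoulli with a logit-linear model in site-
#' and occasion-level covariates. Higher than pairwise interaction terms are
#' fixed at zero. The marginalized likelihood is maximized by quasi-Newton
#' (BFGS) with analytic gradients and multiple starting points, since these
#' likelihoods can be multimodal in small samples.
#'
#' @param y detection histories: a `detection_array` from
#'   [build_detection_array()], any sites x occasions x species array in
#'   \{0, 1, NA\}, or a named list of site x occasion matrices.
#' @param occ_formulas named list of one-sided formulas over the site
#'   covariates: one per species for the marginal natural parameters, and
#'   optionally one per pair under names like `"roe:red"` (`~1` for a
#'   constant dependence; omit the pair, or give `"absent"`, to force
#'   independence).
#' @param det_formulas named list, one formula per species, over site
#'   covariates and/or occasion covariates supplied in `obs_covs`.
#' @param site_covs data frame of site covariates (one row per site),
#'   typically standardized with [standardize_covariates()].
#' @param obs_covs named list of site x occasion matrices for covariates
#'   that vary by day (e.g. hunting calendar, daily human presence).
#' @param start optional full starting vector; by default occupancy
#'   intercepts start at the logit of naive occupancy, detection intercepts
#'   at `logit(0.1)`, slopes at 0.
#' @param control a list from [msom_control()].
#' @return an object of class `"msom"` with methods [print()], [summary()],
#'   [coef()], [vcov()], [logLik()] (hence [AIC()]), [predict()],
#'   [simulate()] and [plot()].
#' @references Rota, C.T. et al. (2016) A multispecies occupancy model for
#'   two or more interacting species. Methods in Ecology and Evolution 7,
#'   1164-1173.
#' @export
msom <- function(y, occ_formulas, det_formulas, site_covs = NULL,
                 obs_covs = NULL, start = NULL, control = msom_control()) {
  cl <- match.call()
  d <- msom_designs(y, occ_formulas, det_formulas, site_covs, obs_covs)
  if (!all(colSums(d$detected) >= 1))
    warning("species with zero detections: ",
            paste(d$species[colSums(d$detected) == 0], collapse = ", "),
            "; their parameters are weakly identified")

  base <- start %||% msom_start(d)
  if (length(base) != d$npar)
    stop("`start` must have length ", d$npar)
  starts <- list(base)
  if (control$nstart > 1L) {
    if (!is.null(control$seed)) set.seed(control$seed)
    for (i in seq_len(control$nstart - 1L))
      starts[[i + 1L]] <- base + stats::rnorm(d$npar, 0, control$jitter_sd)
  }

  negll <- function(par) -msom_loglik(d, par)
  neggr <- function(par) -msom_grad(d, par)

  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, negll, neggr, method = "BFGS",
                            control = list(maxit = control$maxit,
                                           reltol = control$reltol)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    # BFGS can stall with a stale curvature approximation; restarting from
    # the incumbent resets it cheaply
    tries <- 0L
    while (max(abs(neggr(opt$par))) > control$gtol && tries < control$restarts) {
      opt2 <- stats::optim(opt$par, negll, neggr, method = "BFGS",
                           control = list(maxit = control$maxit,
                                          reltol = control$reltol))
      improved <- opt2$value < opt$value - 1e-10
      opt <- opt2
      tries <- tries + 1L
      if (!improved) break
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")

  # Newton polish: BFGS tends to stop on relative-change long before the
  # gradient tolerance; a few damped Newton steps with the observed Hessian
  # drive the gradient norm down cheaply near the optimum.
  par <- best$par
  par0 <- par
  g <- msom_grad(d, par)
  H <- msom_hessian(d, par)
  it <- 0L
  while (max(abs(g)) > control$gtol && it < 30L) {
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    ll0 <- msom_loglik(d, par)
    tt <- 1
    repeat {
      cand <- par - tt * step
      if (msom_loglik(d, cand) >= ll0 - 1e-9 || tt < 1e-4) break
      tt <- tt / 2
    }
    if (tt < 1e-4) break
    par <- cand
    g <- msom_grad(d, par)
    it <- it + 1L
    if (it %% 10L == 0L) H <- msom_hessian(d, par)
  }
  # refresh the Hessian for the variance matrix only if the polish moved
  # the parameters appreciably (it changes at second order in the step)
  if (it > 0L && control$se && max(abs(par - par0)) > 1e-4)
    H <- msom_hessian(d, par)

  names(par) <- d$par_names
  gradnorm <- max(abs(g))
  converged <- is.finite(gradnorm) && gradnorm < control$gtol
  vc <- if (control$se) try(solve(-H), silent = TRUE)
        else matrix(NA_real_, d$npar, d$npar)
  se <- rep(NA_real_, d$npar)
  if (control$se && !inherits(vc, "try-error") && all(is.finite(vc))) {
    dg <- diag(vc)
    if (any(dg <= 0)) {
      warning("Hessian not positive-definite at the optimum; ",
              "some standard errors are undefined")
      se[dg > 0] <- sqrt(dg[dg > 0])
    } else se <- sqrt(dg)
    dimnames(vc) <- list(d$par_names, d$par_names)
  } else {
    if (control$se) warning("singular Hessian; standard errors undefined")
    vc <- matrix(NA_real_, d$npar, d$npar,
                 dimnames = list(d$par_names, d$par_names))
  }
  names(se) <- d$par_names

  ll <- msom_loglik(d, par)
  structure(list(
    call = cl, coefficients = par, se = se, vcov = vc,
    logLik = ll, npar = d$npar, nobs = d$J,
    AIC = -2 * ll + 2 * d$npar,
    converged = converged, gradnorm = gradnorm,
    optim = list(value = best$value, counts = best$counts,
                 convergence = best$convergence, nstart = length(starts)),
    species = d$species, pairs = d$pairs,
    occ_formulas = occ_formulas, det_formulas = det_formulas,
    designs = d), class = "msom")
}

#' Optimizer settings for [msom()]
#'
#' @param nstart number of starting points (first is the deterministic
#'   default start, the rest are jittered `N(0, jitter_sd^2)` around it).
#' @param jitter_sd standard deviation of the start jitter.
#' @param seed optional seed for the jitter draws.
#' @param maxit,reltol passed to [stats::optim()] (BFGS).
#' @param gtol convergence declared when the gradient infinity-norm falls
#'   below this.
#' @param restarts extra BFGS restarts allowed when the gradient norm is
#'   still above `gtol`.
#' @param se compute the observed-information variance matrix (disable for
#'   large model-comparison simulations where only the likelihood and AIC
#'   are needed).
#' @return list of settings.
#' @export
msom_control <- function(nstart = 5L, jitter_sd = 0.5, seed = NULL,
                         maxit = 500L, reltol = 1e-12, gtol = 1e-6,
                         restarts = 3L, se = TRUE) {
  list(nstart = as.integer(nstart), jitter_sd = jitter_sd, seed = seed,
       maxit = maxit, reltol = reltol, gtol = gtol, restarts = restarts,
       se = se)
}

# Default start: occupancy intercepts at logit(naive psi) (clamped),
# detection intercepts at logit(0.1), all slopes 0.
msom_start <- function(d) {
  par <- numeric(d$npar)
  surveyed <- rowSums(matrix(d$surveyed_any, d$J, d$K)) > 0
  for (s in seq_along(d$species)) {
    nm <- paste0("psi[", d$species[s], "]")
    nv <- sum(d$detected[, s]) / max(1, sum(surveyed))
    par[d$offsets[[nm]] + 1L] <- logit(min(max(nv, 0.05), 0.95))
  }
  for (s in d$species) {
    nm <- paste0("p[", s, "]")
    par[d$offsets[[nm]] + 1L] <- logit(0.1)
  }
  par
}
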