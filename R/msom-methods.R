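#' @export
print.msom <- function(x, ...) {
  cat("Multi-species occupancy model (multivariate Bernoulli,",
      "pairwise interactions)\n")
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  cat("Modelled pairs:",
      if (length(x$pairs)) paste(x$pairs, collapse = ", ") else "none",
      "\n")
  cat(sprintf("Sites: %d   Parameters: %d\n", x$nobs, x$npar))
  cat(sprintf("logLik: %.3f   AIC: %.3f   converged: %s (|grad| = %.2e)\n",
              x$logLik, x$AIC, x$converged, x$gradnorm))
  invisible(x)
}

#' @export
summary.msom <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(call = object$call, coefficients = tab,
              logLik = object$logLik, AIC = object$AIC,
              npar = object$npar, nobs = object$nobs,
              converged = object$converged, gradnorm = object$gradnorm)
  class(out) <- "summary.msom"
  out
}

#' @export
print.summary.msom <- function(x, digits = 4, ...) {
  cat("Call:\n"); print(x$call); cat("\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nlogLik: %.3f   AIC: %.3f   (%d parameters, %d sites)\n",
              x$logLik, x$AIC, x$npar, x$nobs))
  if (!x$converged)
    cat(sprintf("Warning: optimizer did not meet the gradient tolerance (|grad| = %.2e)\n",
                x$gradnorm))
  invisible(x)
}

#' @export
coef.msom <- function(object, ...) object$coefficients

#' @export
vcov.msom <- function(object, ...) object$vcov

#' @export
logLik.msom <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' Model predictions
#'
#' @param object an [msom()] fit.
#' @param type `"occupancy"` (marginal psi), `"state"` (full community-state
#'   distribution), `"conditional"`, `"cooccurrence"`, or `"detection"`.
#' @param newdata new covariate rows (sites for the occupancy types, a
#'   detection-covariate grid for `"detection"`).
#' @param ... passed to the corresponding worker:
#'   [marginal_occupancy()], [conditional_occupancy()],
#'   [cooccurrence_probability()], [predict_detection()].
#' @return see the workers.
#' @export
predict.msom <- function(object, type = c("occupancy", "state", "conditional",
                                          "cooccurrence", "detection"),
                         newdata = NULL, ...) {
  type <- match.arg(type)
  switch(type,
    occupancy = marginal_occupancy(object, site_covs = newdata, ...),
    state = state_dist(object, site_covs = newdata),
    conditional = conditional_occupancy(object, site_covs = newdata, ...),
    cooccurrence = cooccurrence_probability(object, site_covs = newdata, ...),
    detection = {
      if (is.null(newdata)) stop("`newdata` grid required for detection")
      predict_detection(object, newdata, ...)
    })
}

#' Simulate detection histories from a fitted model
#'
#' Draws latent community states from the fitted state distribution at each
#' site, then daily detections on the surveyed occasions (parametric
#' bootstrap of the observation process).
#'
#' @param object an [msom()] fit.
#' @param nsim number of replicate arrays.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` detection arrays shaped like the fitted data.
#' @export
simulate.msom <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$designs
  pr <- state_dist(object)
  p <- vapply(seq_len(d$S), function(s)
    stats::plogis(drop(d$Wdet[[d$species[s]]] %*%
      par_block(d, object$coefficients, paste0("p[", d$species[s], "]")))),
    numeric(d$J * d$K))
  lapply(seq_len(nsim), function(r) {
    st <- apply(pr, 1L, function(w) sample.int(nrow(d$Zmat), 1L, prob = w))
    z <- d$Zmat[st, , drop = FALSE]
    out <- d$y
    for (s in seq_len(d$S)) {
      ym <- matrix(stats::rbinom(d$J * d$K, 1L,
                                 p[, s] * rep(z[, s], times = d$K)),
                   d$J, d$K)
      ym[is.na(d$y[, , s])] <- NA_integer_
      out[, , s] <- ym
    }
    out
  })
}

#' Plot detection prediction curves
#'
#' Convenience display of [predict_detection()] over one covariate, one
#' panel line per species, optionally split by a second (0/1) covariate such
#' as a hunting-day indicator.
#'
#' @param x an [msom()] fit.
#' @param covariate name of the detection covariate on the x-axis.
#' @param by optional name of a binary covariate drawn as two line styles.
#' @param at fixed values for the remaining detection covariates (default 0,
#'   i.e. covariate means on the standardized scale).
#' @param n grid resolution.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the prediction data frame.
#' @export
plot.msom <- function(x, covariate, by = NULL, at = list(), n = 50, ...) {
  d <- x$designs
  vars <- unique(unlist(lapply(x$det_formulas[d$species], all.vars)))
  if (!covariate %in% vars) stop("'", covariate, "' is not a detection covariate")
  rng <- range(d$long[[covariate]], na.rm = TRUE)
  grid <- data.frame(v = seq(rng[1L], rng[2L], length.out = n))
  names(grid) <- covariate
  for (v in setdiff(vars, c(covariate, by)))
    grid[[v]] <- at[[v]] %||% 0
  lev <- if (is.null(by)) NA else c(0, 1)
  preds <- lapply(lev, function(l) {
    if (!is.null(by)) grid[[by]] <- l
    predict_detection(x, grid)
  })
  pm <- do.call(cbind, lapply(preds, function(pr)
    matrix(pr$p, nrow = n, dimnames = list(NULL, unique(pr$species)))))
  graphics::matplot(grid[[covariate]], pm, type = "l",
                    lty = rep(seq_along(lev), each = d$S),
                    col = rep(seq_len(d$S), times = length(lev)),
                    xlab = covariate, ylab = "detection probability", ...)
  graphics::legend("topleft", legend = d$species, col = seq_len(d$S),
                   lty = 1, bty = "n")
  invisible(do.call(rbind, preds))
}
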