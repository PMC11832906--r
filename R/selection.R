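#' The nine-model candidate set for a three-species co-occurrence analysis
#'
#' Builds the standard 3 x 3 hypothesis grid used for a hunted ungulate, a
#' second ungulate and a predator: three detection structures (baseline
#' `visual + tri + trail`; adding daily human presence; adding the hunting
#' calendar) crossed with three dependence structures (species independent;
#' constant pairwise dependence `~ 1`; pairwise dependence modelled with
#' site covariates). Marginal occupancy formulas are species-role specific
#' and identical across the nine models:
#' \describe{
#'   \item{first species (hunted ungulate)}{`~ forest + tri + roads`}
#'   \item{second species (ungulate)}{`~ tri + buildings`}
#'   \item{third species (predator)}{`~ tri + hum_passage`}
#' }
#' and the covariate-linked dependence models are `~ open + roads` (the two
#' ungulates), `~ forest + buildings` (first ungulate and predator) and
#' `~ buildings` (second ungulate and predator).
#'
#' With fewer than two species the dependence structures collapse and the
#' set degenerates to the three detection hypotheses.
#'
#' @param species up to three species labels, in the role order above.
#' @param available optional character vector of available covariate names;
#'   when supplied, the set is validated against it and missing covariates
#'   are reported by name.
#' @return named list of model specifications (`M1` ... `M9`), each a list
#'   with elements `label`, `occ_formulas`, `det_formulas` ready for
#'   [msom()] / [fit_candidates()].
#' @export
candidate_models <- function(species = c("roe", "red", "wolf"),
                             available = NULL) {
  if (length(species) < 1L || length(species) > 3L)
    stop("`species` must have length 1 to 3")
  needed <- c("visual", "tri", "trail", "human", "hunting",
              "forest", "open", "roads", "buildings", "hum_passage")
  if (!is.null(available)) {
    miss <- setdiff(needed, available)
    if (length(miss))
      stop("covariates required by the candidate set are missing: ",
           paste(miss, collapse = ", "))
  }
  S <- length(species)
  occ_marginal <- stats::setNames(
    list(~ forest + tri + roads, ~ tri + buildings, ~ tri + hum_passage)[seq_len(S)],
    species)
  pair_const <- pair_cov <- list()
  if (S >= 2L) {
    pn <- function(i, j) paste(species[c(i, j)], collapse = ":")
    pair_const[[pn(1, 2)]] <- ~ 1
    pair_cov[[pn(1, 2)]] <- ~ open + roads
    if (S == 3L) {
      pair_const[[pn(1, 3)]] <- ~ 1
      pair_const[[pn(2, 3)]] <- ~ 1
      pair_cov[[pn(1, 3)]] <- ~ forest + buildings
      pair_cov[[pn(2, 3)]] <- ~ buildings
    }
  }
  det_base <- ~ visual + tri + trail
  det_human <- ~ visual + tri + trail + human
  det_hunting <- ~ visual + tri + trail + hunting
  det_of <- function(f) stats::setNames(rep(list(f), S), species)

  spec <- function(label, det, pairs)
    list(label = label, occ_formulas = c(occ_marginal, pairs),
         det_formulas = det_of(det))

  if (S == 1L)
    return(list(M1 = spec("co-occurrence", det_base, list()),
                M4 = spec("human presence", det_human, list()),
                M7 = spec("hunting", det_hunting, list())))
  list(
    M1 = spec("co-occurrence: independent", det_base, list()),
    M2 = spec("co-occurrence: constant dependence", det_base, pair_const),
    M3 = spec("co-occurrence: covariate dependence", det_base, pair_cov),
    M4 = spec("human presence: independent", det_human, list()),
    M5 = spec("human presence: constant dependence", det_human, pair_const),
    M6 = spec("human presence: covariate dependence", det_human, pair_cov),
    M7 = spec("hunting: independent", det_hunting, list()),
    M8 = spec("hunting: constant dependence", det_hunting, pair_const),
    M9 = spec("hunting: covariate dependence", det_hunting, pair_cov)
  )
}

#' Fit every model of a candidate set
#'
#' @param candidates list from [candidate_models()] (or any named list of
#'   `occ_formulas`/`det_formulas` specifications).
#' @param y,site_covs,obs_covs,control passed to [msom()].
#' @return named list of `"msom"` fits.
#' @export
fit_candidates <- function(candidates, y, site_covs = NULL, obs_covs = NULL,
                           control = msom_control()) {
  stats::setNames(lapply(candidates, function(sp)
    msom(y, sp$occ_formulas, sp$det_formulas, site_covs, obs_covs,
         control = control)), names(candidates))
}

#' AIC ranking of candidate models
#'
#' Orders fitted candidates by AIC and reports the difference to the best
#' model. Non-converged fits are listed last and flagged rather than
#' dropped; exact AIC ties (difference below 1e-6) are broken in favour of
#' the model with fewer parameters.
#'
#' @param fits named list of [msom()] fits, or a named numeric vector of AIC
#'   values (for re-ranking published AICs).
#' @return data frame `model`, `npar`, `logLik`, `AIC`, `dAIC`, `converged`,
#'   sorted ascending by AIC.
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0L) stop("no models to rank")
  if (is.numeric(fits)) {
    tab <- data.frame(model = names(fits) %||% paste0("M", seq_along(fits)),
                      npar = NA_integer_, logLik = NA_real_,
                      AIC = as.numeric(fits), converged = TRUE)
  } else {
    tab <- data.frame(
      model = names(fits) %||% paste0("M", seq_along(fits)),
      npar = vapply(fits, function(f) f$npar, integer(1)),
      logLik = vapply(fits, function(f) f$logLik, numeric(1)),
      AIC = vapply(fits, function(f) f$AIC, numeric(1)),
      converged = vapply(fits, function(f) f$converged, logical(1)))
  }
  ref <- if (any(tab$converged)) min(tab$AIC[tab$converged]) else min(tab$AIC)
  tab$dAIC <- tab$AIC - ref
  aic_key <- round(tab$AIC / 1e-6) * 1e-6  # tie tolerance
  ord <- order(!tab$converged, aic_key, tab$npar)
  tab <- tab[ord, c("model", "npar", "logLik", "AIC", "dAIC", "converged")]
  rownames(tab) <- NULL
  tab
}
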