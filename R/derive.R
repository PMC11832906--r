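# Post-fit quantities: marginal / conditional / co-occurrence probabilities,
# averaged occupancy and detection summaries, detection prediction curves.

# Per-site distribution over the 2^S community states at a parameter vector.
state_dist <- function(fit, par = fit$coefficients, site_covs = NULL) {
  d <- fit$designs
  if (is.null(site_covs)) {
    Xocc <- d$Xocc; Xpair <- d$Xpair
  } else {
    site_covs <- as.data.frame(site_covs)
    Xocc <- lapply(d$species, function(s)
      stats::model.matrix(norm_formula(fit$occ_formulas[[s]] %||% ~1, s),
                          site_covs))
    names(Xocc) <- d$species
    Xpair <- lapply(d$pairs, function(nm) {
      f <- fit$occ_formulas[[nm]] %||%
        fit$occ_formulas[[paste(rev(strsplit(nm, ":")[[1]]), collapse = ":")]]
      stats::model.matrix(norm_formula(f, nm), site_covs)
    })
    names(Xpair) <- d$pairs
  }
  J <- nrow(Xocc[[1L]])
  f <- vapply(d$species, function(s)
    drop(Xocc[[s]] %*% par_block(d, par, paste0("psi[", s, "]"))), numeric(J))
  if (is.null(dim(f))) f <- matrix(f, nrow = J)
  g <- if (length(d$pairs))
    vapply(d$pairs, function(nm)
      drop(Xpair[[nm]] %*% par_block(d, par, paste0("psi[", nm, "]"))),
      numeric(J))
  else matrix(0, J, 0)
  if (is.null(dim(g))) g <- matrix(g, nrow = J)
  eta <- f %*% t(d$Zmat) + g %*% t(d$PairZ)
  pr <- exp(eta - row_logsumexp(eta))
  colnames(pr) <- apply(d$Zmat, 1L, paste, collapse = "")
  pr
}

# Delta-method SE of scalar fun(par) at the MLE.
delta_se <- function(fit, fun, h = 1e-6) {
  if (anyNA(fit$vcov)) return(NA_real_)
  par <- fit$coefficients
  g <- vapply(seq_along(par), function(i) {
    hi <- h * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + hi
    dn <- par; dn[i] <- dn[i] - hi
    (fun(up) - fun(dn)) / (2 * hi)
  }, numeric(1))
  sqrt(max(0, drop(t(g) %*% fit$vcov %*% g)))
}

#' Marginal occupancy probabilities
#'
#' `psi_i(site) = sum over states with z_i = 1 of P(z | site)`. With all
#' pairwise natural parameters zero this reduces to `plogis(f_i)`.
#'
#' @param fit an [msom()] fit.
#' @param site_covs optional data frame of new sites; defaults to the sites
#'   the model was fitted to.
#' @param average if `TRUE` (default), the mean over sites per species with
#'   a delta-method standard error; otherwise the per-site matrix.
#' @return data frame (`species`, `estimate`, `se`) or a sites x species
#'   matrix.
#' @export
marginal_occupancy <- function(fit, site_covs = NULL, average = TRUE) {
  d <- fit$designs
  psi_of <- function(par) state_dist(fit, par, site_covs) %*% d$Zmat
  psi <- psi_of(fit$coefficients)
  colnames(psi) <- d$species
  if (!average) return(psi)
  data.frame(
    species = d$species,
    estimate = colMeans(psi),
    se = vapply(seq_len(d$S), function(s)
      delta_se(fit, function(p) mean(psi_of(p)[, s])), numeric(1)),
    row.names = NULL)
}

#' Conditional occupancy given another species' presence or absence
#'
#' `P(z_i = 1 | z_j = c)` from the fitted community-state distribution.
#' When the pairwise natural parameter linking i and j is zero (and no third
#' species couples them), the conditional equals the marginal.
#'
#' @param fit an [msom()] fit.
#' @param species focal species i.
#' @param given conditioning species j.
#' @param present condition on presence (`TRUE`) or absence of `given`.
#' @param site_covs optional new sites.
#' @param average mean over sites (default) or per-site vector.
#' @return data frame (`species`, `given`, `present`, `estimate`, `se`) or a
#'   per-site vector.
#' @export
conditional_occupancy <- function(fit, species, given, present = TRUE,
                                  site_covs = NULL, average = TRUE) {
  d <- fit$designs
  i <- match(species, d$species); j <- match(given, d$species)
  if (is.na(i) || is.na(j)) stop("species not in the model")
  cond_of <- function(par) {
    pr <- state_dist(fit, par, site_covs)
    zi <- d$Zmat[, i] == 1
    zj <- if (present) d$Zmat[, j] == 1 else d$Zmat[, j] == 0
    rowSums(pr[, zi & zj, drop = FALSE]) / rowSums(pr[, zj, drop = FALSE])
  }
  val <- cond_of(fit$coefficients)
  if (!average) return(val)
  data.frame(species = species, given = given, present = present,
             estimate = mean(val),
             se = delta_se(fit, function(p) mean(cond_of(p))))
}

#' Pairwise co-occurrence probability
#'
#' `P(z_i = 1, z_j = 1)` per site (never exceeding either marginal).
#'
#' @inheritParams conditional_occupancy
#' @param pair character vector of the two species.
#' @return data frame (`pair`, `estimate`, `se`) or a per-site vector.
#' @export
cooccurrence_probability <- function(fit, pair, site_covs = NULL,
                                     average = TRUE) {
  d <- fit$designs
  ij <- match(pair, d$species)
  if (anyNA(ij) || length(ij) != 2L) stop("`pair` must name two modelled species")
  co_of <- function(par) {
    pr <- state_dist(fit, par, site_covs)
    keep <- d$Zmat[, ij[1L]] == 1 & d$Zmat[, ij[2L]] == 1
    rowSums(pr[, keep, drop = FALSE])
  }
  val <- co_of(fit$coefficients)
  if (!average) return(val)
  data.frame(pair = paste(pair, collapse = ":"), estimate = mean(val),
             se = delta_se(fit, function(p) mean(co_of(p))))
}

#' Predict detection probabilities on a covariate grid
#'
#' Evaluates each species' logistic detection model on new covariate rows,
#' with delta-method confidence intervals computed on the logit scale and
#' back-transformed — the construction behind detection-by-trail-category
#' figures with hunting on/off.
#'
#' @param fit an [msom()] fit.
#' @param newdata data frame containing every covariate named in the
#'   detection formulas (site- and occasion-level alike).
#' @param species species to predict for (default all).
#' @param level confidence level for the intervals.
#' @return long data frame: `species`, the grid columns, `p`, `se`, `lower`,
#'   `upper`.
#' @export
predict_detection <- function(fit, newdata, species = NULL, level = 0.95) {
  d <- fit$designs
  species <- species %||% d$species
  bad <- setdiff(species, d$species)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  newdata <- as.data.frame(newdata)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(species, function(s) {
    f <- norm_formula(fit$det_formulas[[s]], s)
    miss <- setdiff(all.vars(f), names(newdata))
    if (length(miss))
      stop("`newdata` lacks covariates: ", paste(miss, collapse = ", "))
    W <- stats::model.matrix(f, newdata)
    a <- par_block(d, fit$coefficients, paste0("p[", s, "]"))
    q <- drop(W %*% a)
    nm <- paste0("p[", s, "]")
    idx <- d$offsets[[nm]] + seq_len(d$blocks[[nm]])
    se_logit <- if (anyNA(fit$vcov)) rep(NA_real_, length(q))
                else sqrt(pmax(0, rowSums((W %*% fit$vcov[idx, idx]) * W)))
    p <- stats::plogis(q)
    cbind(data.frame(species = s), newdata,
          data.frame(p = p, se = p * (1 - p) * se_logit,
                     lower = stats::plogis(q - zq * se_logit),
                     upper = stats::plogis(q + zq * se_logit)))
  })
  do.call(rbind, out)
}

#' Occupancy and detection summary of a fitted model
#'
#' One row per species: naive occupancy, mean marginal occupancy over the
#' analysed sites with delta-method SE, and mean detection probability over
#' the surveyed site-occasions with delta-method SE. Averages are taken over
#' the observed covariates (prediction at covariate means is available via
#' `at_means = TRUE`).
#'
#' @param fit an [msom()] fit.
#' @param at_means evaluate at covariate means instead of averaging
#'   per-site/per-occasion predictions.
#' @return data frame: `species`, `naive_psi`, `psi`, `se_psi`, `p`, `se_p`.
#' @export
occupancy_summary <- function(fit, at_means = FALSE) {
  d <- fit$designs
  surveyed <- apply(!is.na(d$y), 1L, any)
  naive <- colSums(d$detected) / sum(surveyed)

  psi_fun <- function(s) {
    if (at_means) {
      # evaluate at the design means: one pseudo-site
      Xm <- lapply(d$Xocc, function(X) matrix(colMeans(X), 1L))
      function(par) {
        f <- vapply(d$species, function(sp)
          drop(Xm[[sp]] %*% par_block(d, par, paste0("psi[", sp, "]"))),
          numeric(1))
        g <- if (length(d$pairs)) vapply(d$pairs, function(nm)
          drop(matrix(colMeans(d$Xpair[[nm]]), 1L) %*%
                 par_block(d, par, paste0("psi[", nm, "]"))), numeric(1))
        else numeric(0)
        pr <- state_probabilities(f, if (length(g)) stats::setNames(g, d$pairs))
        sum(pr[state_matrix(d$S)[, s] == 1])
      }
    } else {
      function(par) mean((state_dist(fit, par) %*% d$Zmat)[, s])
    }
  }
  p_fun <- function(s) {
    ok <- !is.na(as.vector(d$y[, , s]))
    function(par) {
      q <- drop(d$Wdet[[d$species[s]]] %*%
                  par_block(d, par, paste0("p[", d$species[s], "]")))
      if (at_means) stats::plogis(mean(q[ok])) else mean(stats::plogis(q[ok]))
    }
  }

  psi <- se_psi <- p <- se_p <- numeric(d$S)
  for (s in seq_len(d$S)) {
    fp <- psi_fun(s); fd <- p_fun(s)
    psi[s] <- fp(fit$coefficients); se_psi[s] <- delta_se(fit, fp)
    p[s] <- fd(fit$coefficients); se_p[s] <- delta_se(fit, fd)
  }
  data.frame(species = d$species, naive_psi = naive,
             psi = psi, se_psi = se_psi, p = p, se_p = se_p,
             row.names = NULL)
}
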