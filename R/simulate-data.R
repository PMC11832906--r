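# Synthetic camera-trap survey generator.
#
# Emulates the statistical structure of a winter alpine survey: a regular
# grid of camera sites with staggered deployment starts (all cameras run
# until the end of the study window), three focal species whose community
# states follow the multivariate Bernoulli model with covariate-linked
# pairwise dependence, daily Bernoulli detection driven by site covariates
# (visual clarity, terrain ruggedness, on/off trail) and day covariates
# (hunting calendar, daily human presence), plus image-level fabrication so
# the whole pipeline — image records -> events -> detection histories — can
# be exercised end to end against known truth.

#' Configuration of the synthetic survey
#'
#' Defaults reproduce the study conditions the generator emulates: 56 active
#' sites surveyed November through April, staggered deployments with mean
#' 112 (sd 38) trap days, three interacting species, a two-day-per-week
#' hunting calendar inside the hunting season, and camera bursts of three
#' images 0.1 s apart grouped by the 5-minute event rule.
#'
#' True coefficients are expressed on the standardized covariate scale and
#' named exactly like [msom()] coefficients, so recovery can be scored by
#' name. Pairs omitted from `occ_formulas` are structurally independent.
#'
#' @param J number of camera sites.
#' @param species species labels (first = hunted ungulate, last = predator;
#'   a `"human"` stream is always generated in addition).
#' @param study_start,study_end study window (dates).
#' @param mean_trap_days,sd_trap_days,min_trap_days deployment lengths are
#'   drawn `N(mean, sd)`, rounded and clamped to `[min, window]`; every
#'   camera records until `study_end`, so starts are staggered.
#' @param trail_probs named probabilities of the four trail categories
#'   (`"off trail"` is the off-trail state; everything else is on-trail).
#' @param occ_formulas,det_formulas model structure generating the data.
#' @param beta named vector of true coefficients ([msom()] naming).
#' @param hunting_season,hunting_weekdays hunting days are the given
#'   weekdays (0 = Sunday) inside the season window.
#' @param human_intercept,human_slope_passage,human_slope_trail logit model
#'   for daily human presence at a site.
#' @param events_per_day,human_events_per_day mean of the zero-truncated
#'   Poisson number of independent events on a detection day.
#' @param seed default RNG seed used by [simulate_survey()].
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(J = 56,
                       species = c("roe", "red", "wolf"),
                       study_start = "2021-11-01",
                       study_end = "2022-04-30",
                       mean_trap_days = 112,
                       sd_trap_days = 38,
                       min_trap_days = 14,
                       trail_probs = c("off trail" = 0.82, "animal path" = 0.05,
                                       "hiking trail" = 0.07, "forest road" = 0.06),
                       occ_formulas = NULL,
                       det_formulas = NULL,
                       beta = NULL,
                       hunting_season = c("2021-11-01", "2022-01-31"),
                       hunting_weekdays = c(0, 3),
                       human_intercept = -2.2,
                       human_slope_passage = 0.9,
                       human_slope_trail = 1.2,
                       events_per_day = 1.6,
                       human_events_per_day = 1.3,
                       seed = 1L) {
  S <- length(species)
  if (is.null(occ_formulas)) {
    occ_formulas <- stats::setNames(
      list(~ forest + tri + roads, ~ tri + buildings,
           ~ tri + hum_passage)[seq_len(S)], species)
    if (S == 3L) {
      occ_formulas[[paste(species[c(1, 2)], collapse = ":")]] <- ~ open + roads
      occ_formulas[[paste(species[c(1, 3)], collapse = ":")]] <- ~ forest + buildings
      occ_formulas[[paste(species[c(2, 3)], collapse = ":")]] <- ~ buildings
    }
  }
  if (is.null(det_formulas))
    det_formulas <- stats::setNames(
      rep(list(~ visual + tri + trail + hunting), S), species)
  if (is.null(beta)) beta <- default_true_beta(species)
  structure(list(
    J = J, species = species,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    mean_trap_days = mean_trap_days, sd_trap_days = sd_trap_days,
    min_trap_days = min_trap_days, trail_probs = trail_probs,
    occ_formulas = occ_formulas, det_formulas = det_formulas, beta = beta,
    hunting_season = as.Date(hunting_season),
    hunting_weekdays = hunting_weekdays,
    human_intercept = human_intercept,
    human_slope_passage = human_slope_passage,
    human_slope_trail = human_slope_trail,
    events_per_day = events_per_day,
    human_events_per_day = human_events_per_day,
    seed = seed), class = "sim_config")
}

# True coefficients for the default three-species structure: directions
# follow the ecology the generator emulates (ungulates avoid rugged terrain
# and trails, the predator uses trails and rugged ground, hunting depresses
# detection of the hunted ungulate only), magnitudes kept moderate.
default_true_beta <- function(species) {
  if (length(species) != 3L)
    stop("default true coefficients are defined for three species; ",
         "supply `beta` explicitly")
  s1 <- species[1L]; s2 <- species[2L]; s3 <- species[3L]
  nm <- function(block, terms) paste0(block, " ", terms)
  v <- c(
    stats::setNames(c(2.4, 0.5, -1.2, 0.5),
      nm(paste0("psi[", s1, "]"), c("(Intercept)", "forest", "tri", "roads"))),
    stats::setNames(c(-0.7, -0.8, -1.0),
      nm(paste0("psi[", s2, "]"), c("(Intercept)", "tri", "buildings"))),
    stats::setNames(c(-0.6, 0.7, 0.8),
      nm(paste0("psi[", s3, "]"), c("(Intercept)", "tri", "hum_passage"))),
    stats::setNames(c(0.4, -1.0, 0.5),
      nm(paste0("psi[", s1, ":", s2, "]"), c("(Intercept)", "open", "roads"))),
    stats::setNames(c(0.4, -0.4, 0.5),
      nm(paste0("psi[", s1, ":", s3, "]"), c("(Intercept)", "forest", "buildings"))),
    stats::setNames(c(0.5, -0.3),
      nm(paste0("psi[", s2, ":", s3, "]"), c("(Intercept)", "buildings"))),
    stats::setNames(c(-1.55, 0.4, -0.6, -0.35, -0.15),
      nm(paste0("p[", s1, "]"),
         c("(Intercept)", "visual", "tri", "trail", "hunting"))),
    stats::setNames(c(-3.2, 0.1, 0.15, -1.0, 0.0),
      nm(paste0("p[", s2, "]"),
         c("(Intercept)", "visual", "tri", "trail", "hunting"))),
    stats::setNames(c(-3.7, 0.25, 0.1, 0.5, 0.1),
      nm(paste0("p[", s3, "]"),
         c("(Intercept)", "visual", "tri", "trail", "hunting")))
  )
  v
}

# Zero-truncated Poisson (n >= 1) via inverse cdf.
rtpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

#' Simulate a complete camera-trap survey
#'
#' Draws deployments, site covariates, day-level covariates (hunting
#' calendar, daily human presence), latent community states from the
#' multivariate Bernoulli model, daily detections conditional on the states,
#' and fabricates the image records behind each detection day: a
#' zero-truncated Poisson number of events at times at least six minutes
#' apart, each a burst of three images 0.1 s apart, so the 5-minute grouping
#' rule reconstructs them exactly. Human image records are generated from
#' the same daily human-presence covariate.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`); identical seeds give
#'   identical output.
#' @param records fabricate image records (`TRUE` by default); estimator
#'   simulation studies that work from the detection array directly can
#'   skip this step.
#' @return list of class `"camsom_sim"`: `records` (image table),
#'   `deployments`, `site_covs` (raw scale, plus `trail_cat`),
#'   `obs_covs` (list of site x day matrices: `hunting`, `human`), `y`
#'   (the directly simulated detection array), and `truth` (`beta`, latent
#'   states `z`, per-site state probabilities, standardized site covariates
#'   used internally).
#' @export
simulate_survey <- function(config = sim_config(), seed = config$seed,
                            records = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  J <- config$J; species <- config$species; S <- length(species)
  days <- seq(config$study_start, config$study_end, by = "day")
  K <- length(days)
  if (config$min_trap_days > K)
    stop("deployment lengths exceed the study window")

  site_id <- sprintf("CT%03d", seq_len(J))
  td <- pmin(pmax(round(stats::rnorm(J, config$mean_trap_days,
                                     config$sd_trap_days)),
                  config$min_trap_days), K)
  deployments <- data.frame(
    camera_id = site_id, site_id = site_id,
    start_date = config$study_end - td + 1L,
    end_date = config$study_end)

  trail_cat <- sample(names(config$trail_probs), J, replace = TRUE,
                      prob = config$trail_probs)
  on_trail <- as.integer(trail_cat != "off trail")
  forest <- 100 * stats::rbeta(J, 5, 1.8)
  open <- pmax(0, 100 - forest - stats::runif(J, 0, 15))
  site_covs <- data.frame(
    site_id = site_id,
    forest = forest,
    open = open,
    tri = stats::rgamma(J, shape = 4, scale = 3),
    roads = stats::rexp(J, 1 / 800),
    buildings = stats::rexp(J, 1 / 1000),
    hum_passage = stats::rgamma(J, shape = 1.2, scale = 5),
    visual = stats::runif(J, 20, 100),
    trail_cat = trail_cat,
    trail = on_trail)

  std <- standardize_covariates(site_covs[setdiff(names(site_covs), "site_id")])

  # day-level covariates
  wd <- as.POSIXlt(days)$wday
  hunting_day <- as.integer(days >= config$hunting_season[1L] &
                              days <= config$hunting_season[2L] &
                              wd %in% config$hunting_weekdays)
  hunting <- matrix(hunting_day, J, K, byrow = TRUE)
  p_hum <- stats::plogis(config$human_intercept +
                           config$human_slope_passage * std$hum_passage +
                           config$human_slope_trail * on_trail)
  human <- matrix(stats::rbinom(J * K, 1L, rep(p_hum, times = K)), J, K)

  deployed <- outer(seq_len(J), seq_len(K),
                    function(j, k) days[k] >= deployments$start_date[j])
  human[!deployed] <- NA_integer_

  # designs shared with the estimator: a placeholder history fixes shapes
  y0 <- array(NA_integer_, c(J, K, S),
              dimnames = list(site = site_id, occasion = format(days),
                              species = species))
  for (j in seq_len(J)) y0[j, deployed[j, ], ] <- 0L
  d <- msom_designs(y0, config$occ_formulas, config$det_formulas,
                    site_covs = std,
                    obs_covs = list(hunting = hunting, human = human))
  beta <- config$beta[d$par_names]
  if (anyNA(beta))
    stop("`beta` lacks coefficients: ",
         paste(d$par_names[is.na(beta)], collapse = ", "))
  names(beta) <- d$par_names

  # latent states and daily detections
  parts <- msom_eval(d, beta)
  pr <- exp(parts$logpi)
  st <- apply(pr, 1L, function(w) sample.int(2^S, 1L, prob = w))
  z <- d$Zmat[st, , drop = FALSE]
  colnames(z) <- species

  y <- y0
  pdet <- matrix(NA_real_, J * K, S)
  for (s in seq_len(S)) {
    p <- stats::plogis(drop(d$Wdet[[s]] %*%
      par_block(d, beta, paste0("p[", species[s], "]"))))
    pdet[, s] <- p
    ym <- matrix(stats::rbinom(J * K, 1L, p * rep(z[, s], times = K)), J, K)
    ym[!deployed] <- NA_integer_
    y[, , s] <- ym
  }

  # fabricate image records: species streams plus the human stream
  rec_tab <- NULL
  if (records) {
    rec <- list()
    for (s in seq_len(S))
      rec[[species[s]]] <- fabricate_records(
        y[, , s] == 1L, site_id, days, species[s], config$events_per_day)
    rec[["human"]] <- fabricate_records(
      !is.na(human) & human == 1L, site_id, days, "human",
      config$human_events_per_day)
    rec_tab <- do.call(rbind, rec)
    rec_tab <- rec_tab[order(rec_tab$camera_id, rec_tab$species,
                             rec_tab$timestamp, method = "radix"), ]
    rownames(rec_tab) <- NULL
  }

  structure(list(
    records = rec_tab, deployments = deployments, site_covs = site_covs,
    obs_covs = list(hunting = hunting, human = human),
    occasion_dates = days, y = y,
    truth = list(beta = beta, z = z, state_probs = pr,
                 detection_prob = pdet, site_covs_std = std,
                 occ_formulas = config$occ_formulas,
                 det_formulas = config$det_formulas),
    config = config, seed = seed), class = "camsom_sim")
}

# Turn a site x day detection indicator into burst image records. Event
# start minutes are drawn on a 6-minute lattice so events stay >= the
# 5-minute grouping gap apart; each event is three images 0.1 s apart.
fabricate_records <- function(hit, site_id, days, label, lambda) {
  hit <- matrix(hit, nrow = length(site_id))  # guard 1-day windows
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(camera_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      species = character(), n_individuals = integer()))
  slots <- seq(0, 1434, by = 6)  # minutes within the day
  n_ev <- pmin(rtpois(nrow(idx), lambda), length(slots))
  mins <- unlist(lapply(seq_len(nrow(idx)), function(r)
    sort(sample(slots, n_ev[r]))))
  day0 <- as.POSIXct(paste(format(days[rep(idx[, 2L], n_ev)]), "00:00:00"),
                     tz = "UTC")
  start <- day0 + mins * 60
  ts <- rep(start, each = 3L) + rep(c(0, 0.1, 0.2), length(start))
  data.frame(
    camera_id = rep(site_id[rep(idx[, 1L], n_ev)], each = 3L),
    timestamp = ts,
    species = label,
    n_individuals = 1L)
}

#' Score parameter recovery across simulation replicates
#'
#' Compares replicate maximum-likelihood fits against the generating
#' coefficients: mean estimate, bias, RMSE and the coverage of the
#' (1 - alpha) Wald confidence interval, per coefficient.
#'
#' @param fits list of [msom()] fits to replicate datasets from the same
#'   generating configuration.
#' @param truth named vector of generating coefficients (e.g.
#'   `sim$truth$beta`).
#' @param level nominal confidence level.
#' @return data frame: `parameter`, `truth`, `mean_est`, `bias`, `rmse`,
#'   `coverage`, `n_rep`; empty when no fits are supplied.
#' @export
roundtrip_score <- function(fits, truth, level = 0.95) {
  empty <- data.frame(parameter = character(), truth = numeric(),
                      mean_est = numeric(), bias = numeric(),
                      rmse = numeric(), coverage = numeric(),
                      n_rep = integer())
  if (length(fits) == 0L) return(empty)
  nms <- names(truth)
  for (f in fits)
    if (!setequal(names(f$coefficients), nms))
      stop("fit coefficients do not match `truth` (species/formula mismatch)")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- t(vapply(fits, function(f) f$coefficients[nms], numeric(length(nms))))
  ses <- t(vapply(fits, function(f) f$se[nms], numeric(length(nms))))
  cover <- abs(sweep(est, 2L, truth)) <= zq * ses
  data.frame(
    parameter = nms,
    truth = as.numeric(truth),
    mean_est = colMeans(est),
    bias = colMeans(est) - as.numeric(truth),
    rmse = sqrt(colMeans(sweep(est, 2L, truth)^2)),
    coverage = colMeans(cover),
    n_rep = length(fits),
    row.names = NULL)
}
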