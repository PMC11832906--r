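# Design-matrix construction for the multi-species occupancy model.
#
# The community state at a site is a binary vector z over S species with a
# multivariate Bernoulli distribution parameterized by natural parameters:
# one f_i per species and one f_ij per modelled pair; three-way and higher
# terms are fixed at zero. Each f is a linear function of site covariates.
# Detection for species i on occasion k is Bernoulli(p_ik) conditional on
# z_i = 1, with logit(p_ik) linear in site- and occasion-level covariates.

# Normalise y to a J x K x S array with species names.
as_y_array <- function(y) {
  if (is.list(y) && !is.array(y)) {
    if (is.null(names(y))) stop("`y` list must be named by species")
    dims <- unique(lapply(y, dim))
    if (length(dims) != 1L) stop("all detection matrices must share J x K")
    arr <- array(NA_integer_, c(dims[[1]], length(y)),
                 dimnames = list(rownames(y[[1]]), colnames(y[[1]]), names(y)))
    for (s in seq_along(y)) arr[, , s] <- as.matrix(y[[s]])
    return(arr)
  }
  if (length(dim(y)) != 3L) stop("`y` must be a sites x occasions x species array")
  if (is.null(dimnames(y)[[3L]]))
    dimnames(y)[[3L]] <- paste0("sp", seq_len(dim(y)[3L]))
  y
}

norm_formula <- function(f, what) {
  if (is.null(f)) return(NULL)
  if (is.character(f)) {
    if (tolower(f) %in% c("absent", "0", "none")) return(NULL)
    f <- stats::as.formula(paste("~", sub("^~", "", f)))
  }
  if (!inherits(f, "formula")) stop("invalid formula for ", what)
  if (length(f) == 3L) stop("formulas must be one-sided (", what, ")")
  f
}

# Build every fixed ingredient of the likelihood once.
msom_designs <- function(y, occ_formulas, det_formulas,
                         site_covs = NULL, obs_covs = NULL) {
  y <- as_y_array(y)
  J <- dim(y)[1L]; K <- dim(y)[2L]; S <- dim(y)[3L]
  species <- dimnames(y)[[3L]]
  if (is.null(site_covs)) site_covs <- data.frame(row.names = seq_len(J))
  site_covs <- as.data.frame(site_covs)
  if (nrow(site_covs) != J) stop("`site_covs` must have one row per site")

  missing_f <- setdiff(species, names(det_formulas))
  if (length(missing_f))
    stop("no detection formula for: ", paste(missing_f, collapse = ", "))
  missing_f <- setdiff(species, names(occ_formulas))
  if (length(missing_f))
    stop("no occupancy formula for: ", paste(missing_f, collapse = ", "))

  # pairs in lexicographic species order; a pair is in the model only if a
  # formula (possibly ~1) is supplied for "a:b" (either name order accepted)
  all_pairs <- if (S >= 2L) t(utils::combn(seq_len(S), 2L))
               else matrix(integer(), 0L, 2L)
  pair_names <- if (nrow(all_pairs)) apply(all_pairs, 1L, function(ij)
    paste(species[ij], collapse = ":")) else character()
  rev_names <- if (nrow(all_pairs)) apply(all_pairs, 1L, function(ij)
    paste(rev(species[ij]), collapse = ":")) else character()
  unknown <- setdiff(names(occ_formulas), c(species, pair_names, rev_names))
  if (length(unknown))
    stop("occupancy formula for unknown species/pair: ",
         paste(unknown, collapse = ", "))

  Xocc <- lapply(species, function(s) {
    f <- norm_formula(occ_formulas[[s]], paste0("psi[", s, "]"))
    if (is.null(f)) f <- ~1
    stats::model.matrix(f, site_covs)
  })
  names(Xocc) <- species

  Xpair <- list()
  for (r in seq_len(nrow(all_pairs))) {
    nm <- pair_names[r]
    f <- occ_formulas[[nm]] %||% occ_formulas[[rev_names[r]]]
    f <- norm_formula(f, paste0("psi[", nm, "]"))
    if (!is.null(f)) Xpair[[nm]] <- stats::model.matrix(f, site_covs)
  }
  inc_pairs <- match(names(Xpair), pair_names)

  # long detection data: row (j, k) sits at index (k-1)*J + j (column-major)
  long <- site_covs[rep(seq_len(J), times = K), , drop = FALSE]
  rownames(long) <- NULL
  if (!is.null(obs_covs)) {
    if (is.null(names(obs_covs))) stop("`obs_covs` must be a named list")
    for (nm in names(obs_covs)) {
      m <- as.matrix(obs_covs[[nm]])
      if (!all(dim(m) == c(J, K)))
        stop("obs covariate '", nm, "' must be a ", J, " x ", K, " matrix")
      long[[nm]] <- as.vector(m)
    }
  }
  surveyed_any <- as.vector(apply(!is.na(y), c(1L, 2L), any))

  Wdet <- lapply(species, function(s) {
    f <- norm_formula(det_formulas[[s]], paste0("p[", s, "]"))
    vars <- all.vars(f)
    miss <- setdiff(vars, names(long))
    if (length(miss))
      stop("detection covariates not found: ", paste(miss, collapse = ", "))
    d <- long[, vars, drop = FALSE]
    if (length(vars)) {
      bad <- !stats::complete.cases(d) & surveyed_any
      if (any(bad))
        stop("NA detection covariates on surveyed occasions (species ", s, ")")
      d[!stats::complete.cases(d), ] <- 0  # unsurveyed filler rows
    }
    stats::model.matrix(f, d)
  })
  names(Wdet) <- species

  # parameter layout: occupancy per species, then pairs, then detection
  blocks <- list(); par_names <- character()
  for (s in species) {
    blocks[[paste0("psi[", s, "]")]] <- ncol(Xocc[[s]])
    par_names <- c(par_names, paste0("psi[", s, "] ", colnames(Xocc[[s]])))
  }
  for (nm in names(Xpair)) {
    blocks[[paste0("psi[", nm, "]")]] <- ncol(Xpair[[nm]])
    par_names <- c(par_names, paste0("psi[", nm, "] ", colnames(Xpair[[nm]])))
  }
  for (s in species) {
    blocks[[paste0("p[", s, "]")]] <- ncol(Wdet[[s]])
    par_names <- c(par_names, paste0("p[", s, "] ", colnames(Wdet[[s]])))
  }
  sizes <- unlist(blocks)
  offsets <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(offsets) <- names(blocks)

  Zmat <- state_matrix(S)
  PairZ <- if (length(inc_pairs))
    vapply(inc_pairs, function(r)
      Zmat[, all_pairs[r, 1L]] * Zmat[, all_pairs[r, 2L]], numeric(2^S))
  else matrix(0, 2^S, 0)
  if (is.null(dim(PairZ))) PairZ <- matrix(PairZ, ncol = length(inc_pairs))

  detected <- vapply(seq_len(S), function(s)
    rowSums(y[, , s, drop = FALSE] == 1L, na.rm = TRUE) > 0, logical(J))

  # flattened histories with missingness weights (hot-path precomputation)
  ydet <- lapply(seq_len(S), function(s) {
    yv <- as.vector(y[, , s])
    wt <- as.numeric(!is.na(yv))
    yv[is.na(yv)] <- 0
    list(wy = wt * as.numeric(yv), wt = wt)
  })
  grp <- lapply(seq_len(S), function(s)
    det_grouping(Wdet[[s]], ydet[[s]], J, K))
  conflict <- (detected %*% t(1 - state_matrix(S))) > 0

  list(y = y, J = J, K = K, S = S, species = species,
       ydet = ydet, grp = grp, conflict = conflict,
       pairs = names(Xpair), pair_idx = all_pairs[inc_pairs, , drop = FALSE],
       Xocc = Xocc, Xpair = Xpair, Wdet = Wdet,
       Zmat = Zmat, PairZ = PairZ, detected = detected,
       blocks = sizes, offsets = offsets, npar = sum(sizes),
       par_names = par_names, site_covs = site_covs, long = long,
       surveyed_any = surveyed_any)
}

# Extract one named block from the packed parameter vector.
par_block <- function(d, par, name) {
  par[d$offsets[[name]] + seq_len(d$blocks[[name]])]
}

# Group the detection design by unique occasion pattern. Most detection
# covariates are site-level; the day-varying ones (hunting calendar, daily
# human presence) are binary, so within a site the linear predictor takes
# only a handful of distinct values. Summing Bernoulli log-likelihood terms
# over (site x pattern) cells instead of (site x occasion) makes the
# likelihood cost independent of the number of occasions. Falls back to
# elementwise evaluation (grp = NULL) when the day-varying part of the
# design is effectively continuous.
det_grouping <- function(W, yd, J, K, max_patterns = 64L) {
  q <- ncol(W)
  is_site <- vapply(seq_len(q), function(c) {
    m <- matrix(W[, c], J, K)
    all(m == m[, 1L])
  }, logical(1))
  obs_cols <- which(!is_site)
  if (length(obs_cols)) {
    key <- do.call(paste, c(asplit(W[, obs_cols, drop = FALSE], 2L),
                            sep = "\r"))
    upat <- unique(key)
    if (length(upat) > max_patterns) return(NULL)
    pat <- match(key, upat)
    Vobs <- W[match(upat, key), obs_cols, drop = FALSE]
  } else {
    pat <- rep(1L, J * K)
    Vobs <- matrix(numeric(), 1L, 0L)
  }
  m <- nrow(Vobs)
  jidx <- rep(seq_len(J), times = K)
  surv <- yd$wt == 1
  N <- matrix(tabulate(jidx[surv] + J * (pat[surv] - 1L), nbins = J * m),
              J, m)
  SWY <- rowsum(yd$wy * W, jidx)          # J x q: sum_k wy * design row
  list(is_site = is_site, obs_cols = obs_cols,
       Wsite = W[seq_len(J), is_site, drop = FALSE],
       Vobs = Vobs, N = N, SWY = SWY)
}
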