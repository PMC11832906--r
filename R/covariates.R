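#' Standardize a covariate to mean 0 and standard deviation 1
#'
#' Centring/scaling statistics use the sample (n - 1) standard deviation and
#' are attached to the result so the transformation can be inverted with
#' [unstandardize()]. Binary indicators and categorical codes should not be
#' standardized; pass only continuous covariates.
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized numeric vector with attributes `center` and `scale`.
#' @examples
#' standardize(c(1, 2, 3))  # -1, 0, 1
#' @export
standardize <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("cannot standardize a constant covariate (sd = 0)")
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  structure((x - m) / s, center = m, scale = s)
}

#' Invert [standardize()]
#' @param z vector carrying `center` and `scale` attributes.
#' @return the original-scale values.
#' @export
unstandardize <- function(z) {
  m <- attr(z, "center"); s <- attr(z, "scale")
  if (is.null(m) || is.null(s))
    stop("`z` has no center/scale attributes; was it standardized?")
  as.numeric(z * s + m)
}

#' Standardize the continuous columns of a covariate table
#'
#' Applies [standardize()] to every numeric column that is not a 0/1
#' indicator, leaving indicators, characters and factors untouched. The
#' per-column centring statistics are stored in a `scaling` attribute.
#'
#' @param covs data frame of site or occasion covariates.
#' @param exclude column names to leave unscaled.
#' @return data frame of the same shape; attribute `scaling` holds a
#'   two-row matrix (center, scale) per standardized column.
#' @export
standardize_covariates <- function(covs, exclude = character()) {
  covs <- as.data.frame(covs)
  scl <- list()
  for (nm in names(covs)) {
    x <- covs[[nm]]
    if (nm %in% exclude || !is.numeric(x)) next
    if (all(x %in% c(0, 1, NA))) next  # binary indicator
    z <- standardize(x)
    scl[[nm]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
    covs[[nm]] <- as.numeric(z)
  }
  attr(covs, "scaling") <- if (length(scl)) do.call(cbind, scl) else NULL
  covs
}

#' Pairwise-correlation screening with VIF diagnostics
#'
#' When two covariates correlate beyond `r_threshold` (|Pearson r|), only one
#' can enter the occupancy/detection models. The drop rule is explicit:
#' `priority` orders covariates from most to least preferred, and in each
#' offending pair the lower-priority member is removed, repeating until no
#' retained pair exceeds the threshold. Variance inflation factors of the
#' retained set are reported as a diagnostic; the decision rule itself is the
#' pairwise threshold.
#'
#' @param covs data frame of numeric covariates (sites x covariates).
#' @param r_threshold pairs with |r| >= this are collinear (default 0.6).
#' @param priority character vector ordering covariates from highest to
#'   lowest retention priority; defaults to column order, but an explicit
#'   choice is strongly recommended since the result depends on it.
#' @return list with `retained`, `dropped` (data frame: covariate, because_of,
#'   r), `correlation` (full matrix), `vif` (retained set).
#' @examples
#' x <- data.frame(a = rnorm(50)); x$b <- 2 * x$a; x$c <- rnorm(50)
#' screen_collinearity(x, priority = c("a", "c", "b"))$retained
#' @export
screen_collinearity <- function(covs, r_threshold = 0.6,
                                priority = names(covs)) {
  covs <- as.data.frame(covs)
  if (!all(vapply(covs, is.numeric, logical(1))))
    stop("all covariates must be numeric; code categories before screening")
  if (!setequal(priority, names(covs)))
    stop("`priority` must be a permutation of the covariate names")
  if (ncol(covs) == 0L)
    return(list(retained = character(), dropped = empty_drop_table(),
                correlation = matrix(numeric(), 0, 0), vif = numeric()))

  cm <- if (ncol(covs) > 1L) stats::cor(covs, use = "pairwise.complete.obs")
        else matrix(1, 1, 1, dimnames = list(names(covs), names(covs)))
  keep <- priority
  dropped <- empty_drop_table()
  repeat {
    if (length(keep) < 2L) break
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) < r_threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    winner <- keep[min(worst)]  # keep is priority-ordered
    loser <- keep[max(worst)]
    dropped <- rbind(dropped, data.frame(
      covariate = loser, because_of = winner, r = cm[winner, loser]))
    keep <- setdiff(keep, loser)
  }
  keep <- keep[order(match(keep, names(covs)))]  # restore column order
  list(retained = keep, dropped = dropped, correlation = cm,
       vif = vif(covs[, keep, drop = FALSE]))
}

empty_drop_table <- function() {
  data.frame(covariate = character(), because_of = character(), r = numeric())
}

#' Variance inflation factors
#'
#' VIF of covariate i is 1 / (1 - R^2) from regressing it on all the others.
#'
#' @param covs data frame of numeric covariates.
#' @return named numeric vector (all 1 when fewer than two covariates).
#' @export
vif <- function(covs) {
  covs <- as.data.frame(covs)
  p <- ncol(covs)
  if (p == 0L) return(numeric())
  if (p == 1L) return(stats::setNames(1, names(covs)))
  vapply(names(covs), function(nm) {
    fit <- stats::lm(stats::reformulate(setdiff(names(covs), nm), nm),
                     data = covs)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}
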