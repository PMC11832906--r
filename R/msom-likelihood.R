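# Marginalized likelihood of the multi-species occupancy model.
#
# Per site j the contribution is
#   L_j = sum_z P(z | f_j) * prod_i D_ij(z_i)
# where P(z) = exp(sum_i f_i z_i + sum_{i<i'} f_ii' z_i z_i') / normaliser,
# D_ij(1) is the Bernoulli detection likelihood of species i's history over
# the non-missing occasions, and D_ij(0) is 1 when the history is all-zero
# and 0 otherwise. Everything is accumulated in log space with log-sum-exp;
# the gradient uses the posterior over community states, so one gradient
# evaluation costs about as much as two likelihood evaluations.

# Shared evaluation of the marginalized likelihood (and optionally its
# analytic gradient). Detection terms use the grouped (site x day-pattern)
# representation when available, so the per-evaluation cost is independent
# of the number of occasions; otherwise they fall back to elementwise sums.
msom_eval <- function(d, par, want_grad = FALSE) {
  J <- d$J; S <- d$S; K <- d$K
  f <- vapply(d$species, function(s)
    drop(d$Xocc[[s]] %*% par_block(d, par, paste0("psi[", s, "]"))),
    numeric(J))
  if (is.null(dim(f))) f <- matrix(f, nrow = J)
  g <- if (length(d$pairs))
    vapply(d$pairs, function(nm)
      drop(d$Xpair[[nm]] %*% par_block(d, par, paste0("psi[", nm, "]"))),
      numeric(J))
  else matrix(0, J, 0)
  if (is.null(dim(g))) g <- matrix(g, nrow = J)

  eta <- tcrossprod(f, d$Zmat) + tcrossprod(g, d$PairZ)  # J x 2^S
  logZ <- row_logsumexp(eta)
  logpi <- eta - logZ

  ll1 <- matrix(0, J, S)
  dp <- vector("list", S)  # per-species intermediates for the gradient
  for (s in seq_len(S)) {
    a <- par_block(d, par, paste0("p[", d$species[s], "]"))
    gp <- d$grp[[s]]
    if (!is.null(gp)) {
      qsite <- if (any(gp$is_site)) drop(gp$Wsite %*% a[gp$is_site])
               else numeric(J)
      qv <- if (length(gp$obs_cols)) drop(gp$Vobs %*% a[gp$obs_cols]) else 0
      Qg <- outer(qsite, qv, "+")                        # J x patterns
      ll1[, s] <- drop(gp$SWY %*% a) - rowSums(gp$N * softplus(Qg))
      dp[[s]] <- Qg
    } else {
      q <- drop(d$Wdet[[s]] %*% a)
      ll1[, s] <- rowSums(matrix(
        d$ydet[[s]]$wy * q - d$ydet[[s]]$wt * softplus(q), J, K))
      dp[[s]] <- q
    }
  }

  A <- logpi + tcrossprod(ll1, d$Zmat)
  A[d$conflict] <- -Inf
  L <- row_logsumexp(A)
  out <- list(loglik = sum(L), L = L, logpi = logpi, ll1 = ll1)
  if (!want_grad) return(out)

  w <- exp(A - L)
  w[!is.finite(w)] <- 0
  pri <- exp(logpi)
  Epost <- w %*% d$Zmat
  Eprior <- pri %*% d$Zmat

  gr <- numeric(d$npar)
  for (s in seq_len(S)) {
    nm <- paste0("psi[", d$species[s], "]")
    gr[d$offsets[[nm]] + seq_len(d$blocks[[nm]])] <-
      crossprod(d$Xocc[[d$species[s]]], Epost[, s] - Eprior[, s])
  }
  if (length(d$pairs)) {
    EpostP <- w %*% d$PairZ
    EpriorP <- pri %*% d$PairZ
    for (r in seq_along(d$pairs)) {
      nm <- paste0("psi[", d$pairs[r], "]")
      gr[d$offsets[[nm]] + seq_len(d$blocks[[nm]])] <-
        crossprod(d$Xpair[[d$pairs[r]]], EpostP[, r] - EpriorP[, r])
    }
  }
  for (s in seq_len(S)) {
    nm <- paste0("p[", d$species[s], "]")
    gp <- d$grp[[s]]
    if (!is.null(gp)) {
      Gm <- gp$N * sigmoid(dp[[s]])
      ga <- drop(crossprod(gp$SWY, Epost[, s]))
      if (any(gp$is_site))
        ga[gp$is_site] <- ga[gp$is_site] -
          drop(crossprod(gp$Wsite, Epost[, s] * rowSums(Gm)))
      if (length(gp$obs_cols))
        ga[gp$obs_cols] <- ga[gp$obs_cols] -
          drop(crossprod(gp$Vobs, drop(crossprod(Gm, Epost[, s]))))
    } else {
      resid <- (d$ydet[[s]]$wy - d$ydet[[s]]$wt * sigmoid(dp[[s]])) *
        rep(Epost[, s], times = K)
      ga <- drop(crossprod(d$Wdet[[s]], resid))
    }
    gr[d$offsets[[nm]] + seq_len(d$blocks[[nm]])] <- ga
  }
  out$grad <- gr
  out
}

msom_loglik <- function(d, par, by_site = FALSE) {
  e <- msom_eval(d, par)
  if (by_site) e$L else e$loglik
}

msom_grad <- function(d, par) msom_eval(d, par, want_grad = TRUE)$grad

# Observed information by central finite differences of the analytic
# gradient (step scaled to parameter magnitude).
msom_hessian <- function(d, par, h = 1e-5) {
  n <- length(par)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + hi
    dn <- par; dn[i] <- dn[i] - hi
    H[, i] <- (msom_grad(d, up) - msom_grad(d, dn)) / (2 * hi)
  }
  (H + t(H)) / 2
}

#' Community state probabilities from natural parameters
#'
#' Evaluates the multivariate Bernoulli distribution over all `2^S` community
#' states at one site, given the per-species natural parameters `f` and the
#' pairwise natural parameters `g`. A pairwise parameter of zero means the
#' two species occur independently; setting all of `g` to zero factorises the
#' distribution into independent Bernoullis with `plogis(f)` marginals.
#'
#' @param f numeric vector of per-species natural parameters, optionally
#'   named by species.
#' @param g named numeric vector of pairwise natural parameters with names
#'   like `"sp1:sp2"`; omitted pairs are 0.
#' @return named numeric vector of probabilities over the `2^S` states, in
#'   lexicographic order (names like `"010"` follow the species order in
#'   `f`), summing to 1.
#' @examples
#' state_probabilities(c(roe = 0.5, red = -0.5), c("roe:red" = 1))
#' @export
state_probabilities <- function(f, g = NULL) {
  S <- length(f)
  if (!is.numeric(f) || !all(is.finite(f)))
    stop("`f` must be finite numeric")
  sp <- names(f) %||% paste0("sp", seq_len(S))
  Z <- state_matrix(S)
  eta <- drop(Z %*% f)
  if (!is.null(g)) {
    if (is.null(names(g))) stop("`g` must be named like 'sp1:sp2'")
    for (nm in names(g)) {
      ij <- match(strsplit(nm, ":", fixed = TRUE)[[1L]], sp)
      if (anyNA(ij) || length(ij) != 2L)
        stop("pair name '", nm, "' does not match species in `f`")
      eta <- eta + g[[nm]] * Z[, ij[1L]] * Z[, ij[2L]]
    }
  }
  eta <- eta - max(eta)
  pr <- exp(eta) / sum(exp(eta))
  names(pr) <- apply(Z, 1L, paste, collapse = "")
  pr
}

#' Detection probability from coefficients and a design row
#'
#' The logistic detection model: `p = plogis(sum(alpha * v))`.
#'
#' @param alpha detection coefficient vector (intercept first).
#' @param v design row matching `alpha`, or a design matrix (rows evaluated
#'   independently).
#' @return detection probability/ies in (0, 1).
#' @export
detection_probability <- function(alpha, v) {
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(v) != length(alpha))
    stop("design has ", ncol(v), " columns but `alpha` has length ",
         length(alpha))
  drop(stats::plogis(v %*% alpha))
}

#' Log-likelihood contribution of one site
#'
#' Marginalizes one site's detection history over the latent community
#' states. Mainly useful for didactic checks against closed forms; [msom()]
#' evaluates all sites at once.
#'
#' @param history occasions x species matrix in \{0, 1, NA\} (a vector is a
#'   single-species history).
#' @param f,g natural parameters as in [state_probabilities()].
#' @param p detection probabilities: occasions x species matrix (recycled
#'   from a length-S vector for constant p).
#' @return log-likelihood of the site's history.
#' @examples
#' # single species, psi = p = 0.5, two occasions, no detections:
#' exp(site_log_likelihood(c(0, 0), f = 0, p = 0.5))  # 0.625
#' @export
site_log_likelihood <- function(history, f, g = NULL, p) {
  history <- as.matrix(history)
  S <- length(f)
  if (ncol(history) != S)
    stop("`history` must have one column per species")
  if (all(is.na(history))) stop("history is all-missing")
  K <- nrow(history)
  p <- if (is.matrix(p)) p else matrix(p, K, S, byrow = TRUE)
  pr <- state_probabilities(f, g)
  Z <- state_matrix(S)
  ll_state <- vapply(seq_len(nrow(Z)), function(r) {
    tot <- 0
    for (s in seq_len(S)) {
      ys <- history[, s]; ok <- !is.na(ys)
      if (Z[r, s] == 1) {
        tot <- tot + sum(ys[ok] * log(p[ok, s]) +
                           (1 - ys[ok]) * log1p(-p[ok, s]))
      } else if (any(ys[ok] == 1)) tot <- -Inf
      if (!is.finite(tot)) break
    }
    tot
  }, numeric(1))
  drop(row_logsumexp(matrix(log(pr) + ll_state, nrow = 1L)))
}
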