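---
title: "Co-occurrence occupancy modelling for camera-trap surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence occupancy modelling for camera-trap surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camsom)
```

## The problem

Camera traps record interacting species — here the motivating system is two
alpine ungulates (roe deer, red deer) and their predator (the wolf) sharing
a landscape with hunters and hikers — but raw photo streams are a biased
measure of where species actually occur: a species can be present and never
walk past the lens. `camsom` implements the full path from classified images
to inference that corrects for imperfect detection while allowing the
species' occupancy states to depend on one another.

The pipeline has four stages:

1. **events** — consecutive photos of one species at one camera are grouped
   into independent detection events; descriptive statistics (capture rate
   per 100 trap days, naive occupancy) summarise the survey.
2. **histories** — events are collapsed to daily detection/non-detection
   per site and species, aligned on the calendar so day-level covariates
   (hunting days, human presence) attach cleanly.
3. **model** — a multi-species occupancy model is fitted by maximum
   likelihood.
4. **derived quantities** — marginal, conditional and co-occurrence
   probabilities, averaged occupancy/detection summaries, and detection
   prediction curves.

## The model

Let $z_j \in \{0,1\}^S$ be the latent community state at site $j$ (which of
the $S$ species are present). Following Rota et al. (2016), $z_j$ follows a
multivariate Bernoulli distribution in natural-parameter form:

$$
P(z_j) \propto \exp\Big(\sum_i f_{ij}\, z_{ij} \;+\; \sum_{i<i'} f_{ii'j}\,
z_{ij} z_{i'j}\Big),
$$

with per-species natural parameters $f_{ij} = x_j^\top \beta_i$ and pairwise
parameters $f_{ii'j} = x_j^\top \beta_{ii'}$, both linear in site
covariates. $f_{ii'} \equiv 0$ is exactly conditional independence of
species $i$ and $i'$; a constant $f_{ii'}$ is a fixed association; a
covariate-linked $f_{ii'}$ lets the association itself vary across the
landscape. Three-way and higher natural parameters are fixed at zero — a
deliberate model restriction that matches the candidate structures the
package encodes and keeps the parameter count manageable at survey-scale
sample sizes.

Conditional on presence ($z_{ij} = 1$), daily detection is Bernoulli with
$\mathrm{logit}(p_{ijk}) = v_{jk}^\top \alpha_i$, where $v_{jk}$ may mix
site-level covariates (visual clarity, terrain ruggedness, on/off trail)
and day-level ones (hunting calendar, human presence that day). The
marginal likelihood of site $j$'s history sums over all $2^S$ states:

$$
L_j = \sum_{z} P(z)\, \prod_i D_{ij}(z_i), \qquad
D_{ij}(1) = \prod_{k \text{ surveyed}} p_{ijk}^{y_{ijk}}
(1-p_{ijk})^{1-y_{ijk}},
$$

with $D_{ij}(0) = 1$ if species $i$ was never detected at $j$ and $0$
otherwise; missing occasions (camera not deployed) contribute nothing.
With a constant $p$ this daily-Bernoulli form is equivalent to the binomial
detection-frequency form up to a parameter-free combinatorial constant, so
the two parameterizations share their maximum-likelihood estimates.

## Estimation

`msom()` maximizes $\sum_j \log L_j$ by BFGS with **analytic gradients**.
The gradient has a clean missing-information structure: for occupancy
parameters it is the design-weighted difference between the posterior and
prior expectations of the state vector; for detection parameters it is the
Bernoulli score weighted by the posterior probability that the species was
present. All state sums are accumulated with log-sum-exp.

Numerical choices, and why:

* **Multi-start.** These likelihoods can be multimodal at small $J$. The
  default is 5 starts: a deterministic start (occupancy intercepts at
  `logit(naive psi)`, detection intercepts at `logit(0.1)`, slopes 0) plus
  jittered copies (`N(0, 0.5^2)`). Large-$J$ simulation studies in the test
  suite use `nstart = 1`; at those sample sizes the likelihood surface is
  effectively unimodal and the deterministic start is reliable.
* **Convergence** is declared when the gradient infinity-norm falls below
  `1e-6`. BFGS alone often stalls at its relative-change criterion before
  reaching that, so the fit finishes with damped Newton steps using the
  observed Hessian ("polish"). The convergence flag is honest: it reports
  the final gradient norm, and non-converged fits are flagged, never
  silently dropped.
* **Standard errors** come from the inverse observed Hessian, computed by
  central finite differences of the analytic gradient. A non-positive
  -definite Hessian (common for weakly identified pair slopes at
  survey-scale $J \approx 56$) yields `NA` standard errors and a warning
  rather than fabricated uncertainty.
* **Speed.** The detection log-likelihood is evaluated on the grouped
  (site × day-pattern) representation: day-varying detection covariates
  are typically binary calendars, so each site has only a few distinct
  daily detection probabilities, making the cost per likelihood evaluation
  independent of the number of occasions. Models with effectively
  continuous day-level covariates fall back to elementwise evaluation
  automatically.

Inference on coefficients is by Wald $z$ tests ($p = 2(1-\Phi(|\hat\beta /
\mathrm{SE}|))$), matching the single-p-per-coefficient reporting style of
the motivating analysis; profile-likelihood intervals are not implemented.

## Covariate preparation

Continuous covariates are standardized to mean 0, sd 1 (sample, $n-1$
denominator — the convention of the statistical software this workflow
descends from); binary indicators and categorical codes are left alone.
Collinearity screening applies a pairwise $|r| \ge 0.6$ drop rule; VIFs are
reported as diagnostics but do not drive the decision. Which member of a
correlated pair is dropped is **not** guessed: the user supplies an explicit
priority order, because the retained member is an analysis decision, not a
statistical one.

## The candidate set

`candidate_models()` encodes the standard 3 × 3 hypothesis grid for a
hunted ungulate, a second ungulate and a predator: detection structures
{baseline, + daily human presence, + hunting calendar} crossed with
dependence structures {independent, constant pairwise, covariate-linked
pairwise}. Marginal occupancy formulas are role-specific and fixed across
the grid. One wrinkle in the published table this set descends from: the
first ungulate's marginal formula appears once with `buildings` in place of
`roads` in the covariate-dependence co-occurrence model, while the
surrounding text, the AIC table and the other two dependence models all use
`roads`; the package uses `roads` throughout, treating the lone
`buildings` entry as a typographical slip. `rank_models()` sorts by AIC,
reports $\Delta$AIC against the best model, flags non-converged candidates
(listed last), and breaks exact ties in favour of fewer parameters.

## Derived quantities

All post-fit probabilities are functions of the fitted state distribution
at each site: marginal $\psi_i = \sum_{z: z_i = 1} P(z)$, conditional
$\psi_{i|j=c}$, and co-occurrence $P(z_i = 1, z_j = 1)$. The single
$\psi$/$p$ per species reported by `occupancy_summary()` is the **mean of
per-site (per-site-occasion) predictions at the observed covariates**;
evaluation at covariate means is available via `at_means = TRUE` because
the aggregation convention genuinely matters and the reporting convention
in the field is not uniform. Standard errors for these summaries use the
delta method on the aggregated scale; detection prediction intervals are
delta-method on the logit scale, back-transformed, which keeps them inside
$(0,1)$.

## The synthetic survey generator

`sim_config()` / `simulate_survey()` emulate the survey design the package
is built around, so that every stage — including the image-level event rule
— can be validated against known truth:

* **Design:** 56 camera sites, studied November–April; staggered
  deployment starts with trap days drawn $N(112, 38^2)$ (clamped to the
  window), every camera recording until the study end. Total effort then
  concentrates near the reference value of 6244 trap days.
* **Covariates:** forest cover ~ Beta (predominantly wooded landscape),
  open cover as its noisy complement (deliberately collinear with forest so
  the screening step has something real to do), gamma-distributed terrain
  ruggedness and human-passage rates, exponential distances to roads and
  buildings, uniform visual clarity, and a four-level trail category with
  ~18% of cameras on trails.
* **Calendars:** hunting is active two fixed weekdays (Sunday, Wednesday)
  inside a November–January season; daily human presence is Bernoulli with
  a logit model in human passage and trail placement.
* **Truth:** occupancy and detection coefficients are set once, on the
  standardized scale, to magnitudes consistent with the reported estimates
  of the motivating analysis but moderated (|slopes| ≤ 1.2) so that the
  generating model is comfortably identifiable; directions follow the
  ecology (ungulates avoid rugged terrain and trails, wolves use both;
  hunting depresses detection of the hunted species only).
* **Image records:** each detected site-day receives a zero-truncated
  Poisson number of events at times ≥ 6 minutes apart, each a burst of
  three images 0.1 s apart — so the 5-minute grouping rule must
  reconstruct the simulated detection array *exactly*, and the test suite
  requires it to.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring sites, animal movement and home ranges, camera failures within
a deployment, observer misidentification, and seasonal drift in detection.
Passing simulation tests therefore demonstrates the estimator and pipeline
are correct under the stated generating model, not that real data meet its
assumptions.

## Validation studies and problem sizes

The test suite validates the likelihood against brute-force state
enumeration ($S = 3$, $J = 20$, $K = 5$, 50 random parameter draws, agreement
to 1e-10), the fitted MLE against a grid-search oracle on a two-site toy,
and calibration by simulation: 200 replicates at $J = 600$ sites ×
$K = 60$ occasions for Wald coverage and bias, and 100 replicates at
$J = 300$ per generating truth for AIC selection behaviour. These sizes were
chosen to make Monte-Carlo error small relative to the tolerances being
checked while keeping the full suite quick to run.

## Known limitations

* Pairwise dependence only; no three-way natural parameter.
* Single-season (static) occupancy; no dynamics, no spatial random effects.
* Wald inference only; bootstrap / profile intervals are out of scope.
* The event rule cannot re-identify individuals; the 5-minute gap is
  applied uniformly (configurable), which is the standard compromise.
* Exact reproduction of the motivating study's fitted coefficients
  requires its archived dataset; the package reproduces the workflow and
  its descriptive statistics, and validates the estimator on synthetic
  data instead.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_survey(sim_config(J = 56), seed = 1)

ev  <- group_events(sim$records, gap_minutes = 5)
arr <- build_detection_array(ev, sim$deployments, sim$config$species,
                             sim$config$study_start, sim$config$study_end)
event_summary(ev, arr)

covs <- standardize_covariates(sim$site_covs, exclude = "site_id")
screen_collinearity(covs[c("forest", "open", "tri", "roads", "buildings")],
                    priority = c("forest", "tri", "roads", "buildings", "open"))

fit <- msom(arr,
            occ_formulas = sim$config$occ_formulas,
            det_formulas = sim$config$det_formulas,
            site_covs = covs, obs_covs = sim$obs_covs)
summary(fit)
occupancy_summary(fit)
conditional_occupancy(fit, "roe", given = "wolf", present = TRUE)
```
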