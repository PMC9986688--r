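#' Retrospective log-likelihood of the observed PRS given phenotype
#'
#' The likelihood of the standardized PRS values conditional on each
#' individual's phenotype (case/control status and age), which is immune
#' to case-control ascertainment of the phenotype and explicitly
#' integrates over the unmeasured residual polygenic component:
#' \deqn{\ell(\alpha)=\sum_i \log\frac{P(\mathrm{pheno}_i \mid x_K=z_i;
#'   \alpha)\,\phi(z_i)}{\int P(\mathrm{pheno}_i \mid u; \alpha)\,
#'   \phi(u)\,du}.}
#' Phenotype probabilities come from the polygenic hazard model (see
#' [phenotype_prob_given_prs()]); all latent-variable integrals use
#' Gauss-Hermite quadrature.  At \eqn{\alpha = 0} the PRS carries no
#' phenotype information and the log-likelihood reduces exactly to
#' \eqn{\sum_i \log\phi(z_i)}.
#'
#' @param alpha Calibration parameter, in \[0, 1).
#' @param cohort A [cohort_table()].
#' @param baseline A `baseline_hazard` covering all cohort ages.
#' @param params A [variance_params()] object.
#' @param quadrature_order Number of Gauss-Hermite nodes.
#' @param prs_col PRS column used as \eqn{z} (default `"prs_std"`).
#' @return The log-likelihood (scalar).
#' @export
retrospective_loglik <- function(alpha, cohort, baseline,
                                 params = variance_params(),
                                 quadrature_order = 48L,
                                 prs_col = "prs_std") {
  stopifnot(inherits(cohort, "cohort_table"))
  if (alpha < 0 || alpha >= 1)
    stop("`alpha` must lie in [0, 1)", call. = FALSE)
  bl <- baseline_covers(baseline, params)
  gh <- gh_rule(quadrature_order)
  rl_loglik_cpp(bl$lambda0, polygenic_sd(bl$age, params),
                params$age_min, cohort$status, cohort$age,
                cohort[[prs_col]], alpha, gh$x, gh$w)
}

#' Estimate alpha by retrospective likelihood
#'
#' Maximizes [retrospective_loglik()] over \eqn{\alpha} by bounded
#' one-dimensional optimization, after constraining the baseline hazard
#' to the supplied population incidence.  The 95% confidence interval is
#' the set of grid values whose log-likelihood lies within
#' \eqn{\chi^2_1(0.95)/2 = 1.92} of the maximum; the reported endpoints
#' are the outermost grid points satisfying the condition.
#'
#' @param cohort A [cohort_table()].
#' @param incidence An [incidence_table()] covering the model age range.
#' @param params A [variance_params()] object.
#' @param bounds Search interval for \eqn{\alpha}, within \[0, 0.99\].
#' @param grid_step Resolution of the confidence-interval grid.
#' @param quadrature_order Number of Gauss-Hermite nodes.
#' @param prs_col PRS column used as \eqn{z}.
#' @param ci Compute the profile-likelihood interval (set `FALSE` to
#'   skip the extra likelihood evaluations).
#' @return An [alpha_estimate()] with method `"rl"`; `boundary` is set
#'   when the maximum lies at a search bound.
#' @export
estimate_alpha_rl <- function(cohort, incidence, params = variance_params(),
                              bounds = c(0, 0.99), grid_step = 0.001,
                              quadrature_order = 48L, prs_col = "prs_std",
                              ci = TRUE) {
  if (bounds[1] < 0 || bounds[2] > 0.99 || bounds[1] >= bounds[2])
    stop("`bounds` must be an increasing interval within [0, 0.99]",
         call. = FALSE)
  baseline <- constrain_baseline(incidence, params, quadrature_order)
  ll <- function(a) retrospective_loglik(a, cohort, baseline, params,
                                         quadrature_order, prs_col)
  opt <- stats::optimize(ll, interval = bounds, maximum = TRUE,
                         tol = 1e-5)
  a_hat <- opt$maximum
  ll_max <- opt$objective
  # optimize() never returns an exact endpoint; re-check the bounds.
  for (bnd in bounds) {
    ll_b <- ll(bnd)
    if (ll_b > ll_max) { a_hat <- bnd; ll_max <- ll_b }
  }
  boundary <- min(a_hat - bounds[1], bounds[2] - a_hat) < 2 * grid_step
  ci_lo <- ci_hi <- NA_real_
  if (ci) {
    thr <- ll_max - stats::qchisq(0.95, df = 1) / 2
    ci_lo <- min(profile_ci_endpoint(ll, a_hat, bounds[1], thr, grid_step),
                 a_hat)
    ci_hi <- max(profile_ci_endpoint(ll, a_hat, bounds[2], thr, grid_step),
                 a_hat)
  }
  alpha_estimate(a_hat, method = "rl", ci_low = ci_lo, ci_high = ci_hi,
                 loglik = ll_max, boundary = boundary)
}

# Outermost grid point (step `by`) between a_hat and `bound` whose
# log-likelihood stays at or above `thr`.  The profile is unimodal, so
# the crossing is located by root finding and then snapped to the grid.
profile_ci_endpoint <- function(ll, a_hat, bound, thr, by) {
  direction <- sign(bound - a_hat)
  if (direction == 0) return(a_hat)
  grid_snap <- function(a) round(a / by) * by
  if (ll(bound) >= thr) return(grid_snap(bound))
  root <- stats::uniroot(function(a) ll(a) - thr,
                         lower = min(a_hat, bound),
                         upper = max(a_hat, bound),
                         tol = by / 4)$root
  # outermost grid point on the a_hat side of the crossing
  cand <- if (direction > 0) floor(root / by) * by else ceiling(root / by) * by
  # guard against root-solver tolerance putting cand just past thr
  while (ll(cand) < thr && abs(cand - a_hat) > by / 2)
    cand <- cand - direction * by
  cand
}
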