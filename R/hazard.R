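#' Cumulative polygenic hazard for an individual
#'
#' The hazard at age \eqn{t} for an individual with measured polygenic
#' score \eqn{x_K} and residual polygenotype \eqn{x_R} is
#' \eqn{\lambda_0(t)\exp\{\sigma_P(t)(\alpha x_K +
#' \sqrt{1-\alpha^2}\,x_R)\}}.  Hazards are piecewise-constant per year of
#' age, so the cumulative hazard to age \eqn{t} is the sum over whole
#' years below \eqn{t}:
#' \deqn{\Lambda(t) = \sum_{u = a_{\min}}^{t-1} \lambda_0(u)
#'   e^{\sigma_P(u)(\alpha x_K + \sqrt{1-\alpha^2} x_R)}.}
#'
#' @param t Age in years (scalar), within the model range.
#' @param x_k Measured polygenic score (population z-score scale).
#' @param x_r Residual polygenic component.
#' @param alpha Proportion-of-variance parameter, in \[0, 1\].
#' @param baseline A `baseline_hazard` covering the model age range.
#' @param params A [variance_params()] object.
#' @return The cumulative hazard, a non-negative scalar (0 at
#'   `t = age_min`).
#' @export
cumulative_hazard <- function(t, x_k, x_r, alpha, baseline,
                              params = variance_params()) {
  check_ages(t, params)
  if (alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  bl <- baseline_covers(baseline, params)
  if (t == params$age_min) return(0)
  u <- seq.int(params$age_min, t - 1L)
  c_eff <- alpha * x_k + sqrt(1 - alpha^2) * x_r
  sum(bl$lambda0[seq_along(u)] * exp(polygenic_sd(u, params) * c_eff))
}

#' Phenotype probability given the measured PRS
#'
#' The probability of the observed phenotype (case at age \eqn{t}, or
#' unaffected control at censoring age \eqn{t}) given the PRS value
#' \eqn{x_K}, integrating the unmeasured residual component \eqn{x_R}
#' out against its standard-normal prior by Gauss-Hermite quadrature:
#' controls contribute \eqn{\int e^{-\Lambda(t)} \phi(x_R) dx_R}, cases
#' \eqn{\int e^{-\Lambda(t)} \lambda(t) \phi(x_R) dx_R}.
#'
#' @param status `"case"` or `"control"`.
#' @inheritParams cumulative_hazard
#' @param quadrature_order Number of Gauss-Hermite nodes.
#' @return A probability: in \[0, 1\] for controls; a non-negative yearly
#'   density for cases.
#' @export
phenotype_prob_given_prs <- function(status, t, x_k, alpha, baseline,
                                     params = variance_params(),
                                     quadrature_order = 48L) {
  status <- match.arg(status, c("case", "control"))
  check_ages(t, params)
  if (alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  bl <- baseline_covers(baseline, params)
  gh <- gh_rule(quadrature_order)
  c_eff <- alpha * x_k + sqrt(1 - alpha^2) * gh$x
  ages <- seq.int(params$age_min, t)
  sig <- polygenic_sd(ages, params)
  i_t <- length(ages)
  # Lambda(t | c) over nodes: sum over years strictly below t
  if (i_t > 1L) {
    haz_before <- exp(outer(sig[-i_t], c_eff)) * bl$lambda0[seq_len(i_t - 1L)]
    cumhaz <- colSums(haz_before)
  } else {
    cumhaz <- numeric(length(c_eff))
  }
  p_nodes <- exp(-cumhaz)
  if (status == "case")
    p_nodes <- p_nodes * bl$lambda0[i_t] * exp(sig[i_t] * c_eff)
  out <- sum(gh$w * p_nodes)
  if (!is.finite(out))
    stop(sprintf(
      "quadrature produced a non-finite value (status=%s, t=%d, x_k=%g, alpha=%g)",
      status, t, x_k, alpha), call. = FALSE)
  out
}
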