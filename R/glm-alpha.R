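#' Transformed PRS covariate for regression estimation of alpha
#'
#' Scales the standardized PRS by the age-specific polygenic standard
#' deviation, \eqn{S' = x_K / \sqrt{\gamma + \theta t}}.  When \eqn{S'}
#' is used as a covariate in a logistic (or Cox) regression of disease
#' status, its coefficient estimates \eqn{\alpha} directly, because the
#' marginal log-odds ratio per unit PRS at age \eqn{t} is approximately
#' \eqn{\alpha\sigma_P(t)}.
#'
#' @param x_k Standardized PRS value(s).
#' @param t Age(s) in years, recycled against `x_k`.
#' @param params A [variance_params()] object.
#' @return The transformed covariate \eqn{S'}.
#' @export
transform_prs_for_glm <- function(x_k, t, params = variance_params()) {
  v <- polygenic_variance(t, params)
  if (any(v <= 0))
    stop("non-positive polygenic variance at supplied ages", call. = FALSE)
  x_k / sqrt(v)
}

#' Estimate alpha by transformed-covariate logistic regression
#'
#' Fits a logistic regression of case/control status on the transformed
#' covariate \eqn{S' = x_K/\sqrt{\gamma+\theta t}} plus any adjustment
#' covariates (country as categorical, principal components as
#' continuous).  The coefficient of \eqn{S'} is the estimate
#' \eqn{\alpha_{GLM}}, with a Wald 95% interval.  This estimator ignores
#' the unmeasured residual polygenic component and therefore
#' underestimates \eqn{\alpha} when that component is active (index
#' event bias): disease onset selects against high residual
#' polygenotypes, inducing a negative PRS-residual correlation at later
#' ages.
#'
#' @param cohort A [cohort_table()] with both statuses.
#' @param params A [variance_params()] object.
#' @param covariates Character vector of adjustment covariate columns.
#' @param prs_col PRS column used for \eqn{x_K} (default `"prs_std"`).
#' @return An [alpha_estimate()] with method `"glm"`.
#' @export
estimate_alpha_glm <- function(cohort, params = variance_params(),
                               covariates = character(),
                               prs_col = "prs_std") {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(unique(cohort$status)) < 2L)
    stop("cohort must contain both cases and controls", call. = FALSE)
  sprime <- transform_prs_for_glm(cohort[[prs_col]], cohort$age, params)
  X <- covariate_matrix(cohort, covariates)
  dat <- data.frame(y = cohort$status, sprime = sprime)
  fit <- if (ncol(X)) stats::glm(y ~ sprime + X, family = stats::binomial(),
                                 data = dat)
         else stats::glm(y ~ sprime, family = stats::binomial(), data = dat)
  if (!fit$converged)
    stop("alpha GLM did not converge; check for separation or collinearity",
         call. = FALSE)
  est <- unname(stats::coef(fit)["sprime"])
  se <- sqrt(stats::vcov(fit)["sprime", "sprime"])
  if (!is.finite(est) || !is.finite(se))
    stop("alpha GLM produced non-finite estimates (possible separation)",
         call. = FALSE)
  alpha_estimate(est, method = "glm",
                 ci_low = est - stats::qnorm(0.975) * se,
                 ci_high = est + stats::qnorm(0.975) * se,
                 se = se)
}

#' Residualize the PRS on country and principal components
#'
#' Regresses the standardized PRS on country indicators and principal
#' components, adjusting for case/control status, and replaces
#' `prs_std` with the PRS minus the fitted country/PC contribution,
#' centered to overall mean zero.  The fitted status effect is retained
#' in the residual: only the nuisance structure (between-country mean
#' shifts, ancestry gradients) is removed, since removing the status
#' contrast would erase the signal alpha estimation relies on.
#'
#' @param cohort A [cohort_table()].
#' @param covariates Covariate columns to remove (default: `country`
#'   plus any `pc*` columns present).
#' @return The cohort with `prs_std` replaced by the residualized PRS.
#' @export
residualize_prs <- function(cohort,
                            covariates = c("country", pc_columns(cohort))) {
  stopifnot(inherits(cohort, "cohort_table"))
  covariates <- intersect(covariates, names(cohort))
  X <- covariate_matrix(cohort, covariates)
  if (ncol(X) == 0L) {
    cohort$prs_std <- cohort$prs_std - mean(cohort$prs_std)
    return(cohort)
  }
  dat <- data.frame(prs = cohort$prs_std, status = cohort$status)
  fit <- stats::lm(prs ~ status + X, data = dat)
  qrf <- fit$qr
  if (qrf$rank < ncol(qrf$qr))
    stop("rank-deficient design in PRS residualization", call. = FALSE)
  beta <- stats::coef(fit)
  nuisance <- drop(X %*% beta[grep("^X", names(beta))])
  adj <- cohort$prs_std - nuisance
  cohort$prs_std <- adj - mean(adj)
  cohort
}
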