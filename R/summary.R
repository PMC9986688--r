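#' Descriptive summary and effect size for a PRS in a cohort
#'
#' Computes the per-group mean and standard deviation of the raw PRS and
#' the log odds ratio per 1 standard deviation: the coefficient of the
#' PRS standardized by the control SD in a logistic regression of status
#' on the PRS plus any covariates, with a Wald 95% confidence interval.
#'
#' @param cohort A [cohort_table()] containing both cases and controls.
#' @param covariates Character vector of covariate column names
#'   (character columns are treated as categorical).
#' @param prs_col Which PRS column to summarize (default `"prs_raw"`).
#' @return An object of class `prs_summary` with fields `mean_controls`,
#'   `mean_cases`, `sd_controls`, `sd_cases`, `log_or_per_sd`, `ci_low`,
#'   `ci_high`, `se`, `n_cases`, `n_controls`.
#' @export
summarize_prs <- function(cohort, covariates = character(),
                          prs_col = "prs_raw") {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!(prs_col %in% names(cohort)))
    stop(sprintf("column `%s` absent from cohort", prs_col), call. = FALSE)
  y <- cohort$status
  if (length(unique(y)) < 2L)
    stop("cohort must contain both cases and controls", call. = FALSE)
  prs <- cohort[[prs_col]]
  m0 <- mean(prs[y == 0]); s0 <- stats::sd(prs[y == 0])
  m1 <- mean(prs[y == 1]); s1 <- stats::sd(prs[y == 1])
  if (!is.finite(s0) || s0 <= 0 || !is.finite(s1) || s1 <= 0)
    stop("degenerate PRS standard deviation within a status group",
         call. = FALSE)
  z <- prs / s0                       # per 1 control-SD convention
  X <- covariate_matrix(cohort, covariates)
  dat <- data.frame(y = y, z = z)
  fit <- if (ncol(X)) stats::glm(y ~ z + X, family = stats::binomial(),
                                 data = dat)
         else stats::glm(y ~ z, family = stats::binomial(), data = dat)
  if (!fit$converged)
    stop("logistic regression for log-OR per SD did not converge",
         call. = FALSE)
  eta <- unname(stats::coef(fit)["z"])
  se <- sqrt(stats::vcov(fit)["z", "z"])
  structure(
    list(mean_controls = m0, mean_cases = m1,
         sd_controls = s0, sd_cases = s1,
         log_or_per_sd = eta, se = se,
         ci_low = eta - stats::qnorm(0.975) * se,
         ci_high = eta + stats::qnorm(0.975) * se,
         n_cases = sum(y == 1), n_controls = sum(y == 0)),
    class = "prs_summary")
}

#' @export
print.prs_summary <- function(x, ...) {
  cat(sprintf(
    paste0("PRS summary (%d cases / %d controls)\n",
           "  mean (SD): controls %.3f (%.3f), cases %.3f (%.3f)\n",
           "  log-OR per 1 SD: %.3f (95%% CI %.3f - %.3f)\n"),
    x$n_cases, x$n_controls, x$mean_controls, x$sd_controls,
    x$mean_cases, x$sd_cases, x$log_or_per_sd, x$ci_low, x$ci_high))
  invisible(x)
}
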