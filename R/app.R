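#' Proportionality calibration of alpha against a reference PRS
#'
#' Under the rare-disease assumption, and ignoring differential age
#' effects, \eqn{\alpha} is approximately proportional to the log odds
#' ratio per 1 SD (\eqn{\eta}).  Using a reference PRS with known
#' \eqn{\eta_0} and \eqn{\alpha_0},
#' \deqn{\alpha_{APP} = (\eta / \eta_0)\,\alpha_0.}
#' This gives a quick estimate for a PRS developed and validated on a
#' different dataset, needing only its published effect size.
#'
#' @param eta Log odds ratio per 1 SD of the target PRS.
#' @param eta0 Log odds ratio per 1 SD of the reference PRS (positive).
#' @param alpha0 Reference alpha, in (0, 1).
#' @param round_constant Optional number of decimals at which to round
#'   the proportionality constant \eqn{\alpha_0/\eta_0} before applying
#'   it (matching how the constant is usually quoted, e.g. 0.887).
#' @return An [alpha_estimate()] with method `"app"` and no interval.
#' @examples
#' calibrate_alpha_app(eta = 0.394, eta0 = 0.497, alpha0 = 0.441)
#' @export
calibrate_alpha_app <- function(eta, eta0, alpha0, round_constant = NULL) {
  if (!is.finite(eta0) || eta0 <= 0)
    stop("`eta0` must be positive", call. = FALSE)
  if (!is.finite(alpha0) || alpha0 <= 0 || alpha0 >= 1)
    stop("`alpha0` must lie in (0, 1)", call. = FALSE)
  const <- alpha0 / eta0
  if (!is.null(round_constant)) const <- round(const, round_constant)
  alpha_estimate(const * eta, method = "app")
}

#' Published PRS calibration parameters
#'
#' Loads the packaged table of published calibration parameters
#' (means, SDs, log-OR per 1 SD, and alpha estimates by GLM and
#' retrospective likelihood) for eleven breast-cancer PRSs and their
#' CHEK2-variant-excluded versions, estimated on a large European
#' case-control consortium dataset.
#'
#' @return A data frame, one PRS per row.
#' @export
published_prs_parameters <- function() {
  path <- system.file("extdata", "prs_published_parameters.csv",
                      package = "prscalib", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Predicted alpha column by proportionality calibration
#'
#' Applies [calibrate_alpha_app()] to each row of a parameter table,
#' using one named PRS as the proportionality standard, and returns the
#' predicted retrospective-likelihood alpha values.
#'
#' @param table A data frame with columns `prs`, `log_or_per_sd` and
#'   `alpha_rl` (defaults to [published_prs_parameters()]).
#' @param standard Name of the reference PRS row.
#' @param round_constant Decimals at which the proportionality constant
#'   is rounded before use (default 3, the convention in which the
#'   constant is quoted as 0.887).
#' @param digits Decimals for the returned predictions (default 3).
#' @return The table with an added `alpha_app` column.
#' @export
predict_alpha_app <- function(table = published_prs_parameters(),
                              standard = "BCAC PRS313",
                              round_constant = 3, digits = 3) {
  stopifnot(all(c("prs", "log_or_per_sd", "alpha_rl") %in% names(table)))
  i <- match(standard, table$prs)
  if (is.na(i))
    stop(sprintf("standard PRS '%s' not found in table", standard),
         call. = FALSE)
  eta0 <- table$log_or_per_sd[i]
  alpha0 <- table$alpha_rl[i]
  table$alpha_app <- vapply(
    table$log_or_per_sd,
    function(eta) round(calibrate_alpha_app(eta, eta0, alpha0,
                                            round_constant)$alpha, digits),
    numeric(1))
  table
}
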