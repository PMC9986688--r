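#' Alpha estimates
#'
#' Container for an estimate of the calibration parameter
#' \eqn{\alpha} (square root of the proportion of polygenic variance
#' explained by the PRS), tagged by estimation method.
#'
#' @param alpha Point estimate.  Values outside \[0, 1) can arise from
#'   sampling noise in the regression estimator and are kept as-is with
#'   a warning.
#' @param method One of `"glm"`, `"rl"`, `"app"`.
#' @param ci_low,ci_high Optional 95% confidence limits.
#' @param loglik Optional maximized log-likelihood.
#' @param se Optional standard error.
#' @param boundary Logical; `TRUE` when a likelihood maximum sits at an
#'   optimization bound.
#' @return An object of class `alpha_estimate`.
#' @export
alpha_estimate <- function(alpha, method = c("glm", "rl", "app"),
                           ci_low = NA_real_, ci_high = NA_real_,
                           loglik = NA_real_, se = NA_real_,
                           boundary = FALSE) {
  method <- match.arg(method)
  if (is.finite(alpha) && (alpha < 0 || alpha >= 1))
    warning(sprintf("alpha estimate %.4f outside [0, 1)", alpha),
            call. = FALSE)
  if (is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= alpha && alpha <= ci_high))
    stop("confidence interval does not contain the estimate", call. = FALSE)
  structure(list(alpha = alpha, method = method,
                 ci_low = ci_low, ci_high = ci_high,
                 loglik = loglik, se = se, boundary = boundary),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  lab <- c(glm = "transformed-covariate GLM",
           rl = "retrospective likelihood",
           app = "proportionality calibration")[x$method]
  cat(sprintf("alpha = %.4f  [%s]\n", x$alpha, lab))
  if (is.finite(x$ci_low) || is.finite(x$ci_high))
    cat(sprintf("  95%% CI: %.4f - %.4f\n", x$ci_low, x$ci_high))
  if (is.finite(x$loglik))
    cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (isTRUE(x$boundary))
    cat("  note: maximum at an optimization bound\n")
  invisible(x)
}

#' Serialize an alpha estimate to JSON
#'
#' @param x An [alpha_estimate()].
#' @param n_cases,n_controls Optional cohort sizes recorded alongside.
#' @param settings Optional named list of estimation settings.
#' @param path Optional file to write; otherwise the JSON string is
#'   returned.
#' @return A JSON string (invisibly, if `path` is given).
#' @export
alpha_to_json <- function(x, n_cases = NA, n_controls = NA,
                          settings = list(), path = NULL) {
  stopifnot(inherits(x, "alpha_estimate"))
  obj <- list(method = x$method, alpha = x$alpha,
              ci = c(x$ci_low, x$ci_high), loglik = x$loglik,
              n_cases = n_cases, n_controls = n_controls,
              settings = settings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
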