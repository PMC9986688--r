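#' Age-dependent polygenic variance parameters
#'
#' The log-hazard polygenic variance is modelled as a linear function of
#' age, \eqn{\sigma_P^2(t) = \gamma + \theta t}.  The defaults
#' (\eqn{\gamma = 4.86}, \eqn{\theta = -0.06}) are the segregation-analysis
#' estimates used for breast cancer, under which the variance stays
#' positive only below age 81; the supported age range therefore defaults
#' to \[20, 79\].
#'
#' @param gamma Polygenic variance at age 0 (squared log-hazard-ratio
#'   units).  Must be positive, except for the degenerate no-polygene
#'   model `gamma = 0, theta = 0`.
#' @param theta Change in polygenic variance per year of age.
#' @param age_min,age_max Integer years bounding the supported range.
#'   `gamma + theta * t` must exceed `1e-10` at every age in the range
#'   (degenerate model excepted).
#'
#' @return An object of class `variance_params`.
#' @examples
#' vp <- variance_params()
#' polygenic_variance(50, vp) # 4.86 - 0.06 * 50
#' @export
variance_params <- function(gamma = 4.86, theta = -0.06,
                            age_min = 20L, age_max = 79L) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(theta), length(theta) == 1L, is.finite(theta))
  age_min <- as.integer(age_min)
  age_max <- as.integer(age_max)
  if (age_min >= age_max)
    stop("`age_min` must be strictly below `age_max`", call. = FALSE)
  degenerate <- gamma == 0 && theta == 0
  if (!degenerate) {
    if (gamma <= 0)
      stop("`gamma` must be positive", call. = FALSE)
    v <- gamma + theta * c(age_min, age_max)
    if (min(v) <= 1e-10)
      stop(sprintf(
        "polygenic variance gamma + theta*t must exceed 1e-10 over [%d, %d]; ",
        age_min, age_max),
        sprintf("got %.3g at the boundary", min(v)), call. = FALSE)
  }
  structure(
    list(gamma = gamma, theta = theta,
         age_min = age_min, age_max = age_max),
    class = "variance_params")
}

#' @export
print.variance_params <- function(x, ...) {
  cat(sprintf(
    "Polygenic variance model: sigma_P^2(t) = %.4g + (%.4g) t on ages [%d, %d]\n",
    x$gamma, x$theta, x$age_min, x$age_max))
  invisible(x)
}

check_ages <- function(t, params) {
  if (any(t < params$age_min | t > params$age_max))
    stop(sprintf("age outside the supported range [%d, %d]",
                 params$age_min, params$age_max), call. = FALSE)
  invisible(t)
}

#' Total polygenic variance at a given age
#'
#' @param t Age(s) in years, within the supported range of `params`.
#' @param params A [variance_params()] object.
#' @return \eqn{\gamma + \theta t}, vectorised over `t`.
#' @export
polygenic_variance <- function(t, params = variance_params()) {
  check_ages(t, params)
  params$gamma + params$theta * t
}

#' Variance of the measured (PRS) polygenic component at a given age
#'
#' The PRS explains a proportion \eqn{\alpha^2} of the polygenic
#' variance, so its age-specific variance is
#' \eqn{\sigma_K^2(t) = \alpha^2 (\gamma + \theta t)}.
#'
#' @inheritParams polygenic_variance
#' @param alpha Square root of the proportion of polygenic variance
#'   attributable to the PRS, in \[0, 1\].
#' @return \eqn{\alpha^2 (\gamma + \theta t)}.
#' @export
known_variance <- function(t, alpha, params = variance_params()) {
  if (any(alpha < 0 | alpha > 1))
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  alpha^2 * polygenic_variance(t, params)
}

polygenic_sd <- function(t, params) sqrt(polygenic_variance(t, params))
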