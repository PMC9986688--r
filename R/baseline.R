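#' Constrain the baseline hazard to population incidence
#'
#' Under the polygenic hazard model
#' \eqn{\lambda(t \mid x) = \lambda_0(t) \exp\{\sigma_P(t) x\}} with
#' \eqn{x \sim N(0,1)}, the population (marginal) incidence at age
#' \eqn{t} among survivors is
#' \deqn{\mu(t) = \frac{\int \lambda_0(t) e^{\sigma_P(t)x} S(t\mid x)
#'   \phi(x)\,dx}{\int S(t\mid x)\phi(x)\,dx},}
#' where \eqn{S(t \mid x)} is the survivor function accumulated over ages
#' below \eqn{t}.  Because \eqn{\lambda_0(t)} factors out of the
#' numerator, the baseline solves in closed form age by age, ascending.
#' Integrals use Gauss-Hermite quadrature.
#'
#' @param incidence An [incidence_table()] covering the model age range.
#' @param params A [variance_params()] object.
#' @param quadrature_order Number of Gauss-Hermite nodes (at least 8).
#' @return An object of class `baseline_hazard`: a data frame with
#'   columns `age` and `lambda0`.
#' @examples
#' bh <- constrain_baseline(ew_breast_incidence(), variance_params())
#' head(bh)
#' @export
constrain_baseline <- function(incidence, params = variance_params(),
                               quadrature_order = 48L) {
  if (quadrature_order < 8L)
    stop("`quadrature_order` must be at least 8", call. = FALSE)
  inc <- check_incidence_covers(incidence, params)
  ages <- inc$age
  mu <- inc$rate
  degenerate <- params$gamma == 0 && params$theta == 0
  sig <- if (degenerate) rep(0, length(ages)) else polygenic_sd(ages, params)
  gh <- gh_rule(quadrature_order)
  lambda0 <- numeric(length(ages))
  cumhaz <- numeric(length(gh$x))          # Lambda(t | x) at quadrature nodes
  for (i in seq_along(ages)) {
    surv <- exp(-cumhaz)
    rr <- exp(sig[i] * gh$x)               # relative risk at each node
    denom <- sum(gh$w * rr * surv)
    num <- sum(gh$w * surv)
    l0 <- if (mu[i] == 0) 0 else mu[i] * num / denom
    if (!is.finite(l0) || l0 < 0)
      stop(sprintf("baseline solve failed at age %d (lambda0 = %g)",
                   ages[i], l0), call. = FALSE)
    lambda0[i] <- l0
    cumhaz <- cumhaz + l0 * rr
  }
  structure(data.frame(age = ages, lambda0 = lambda0),
            class = c("baseline_hazard", "data.frame"))
}

#' Marginal incidence implied by a baseline hazard
#'
#' Recomputes the population incidence from a baseline hazard by
#' marginalising over the polygenic component; the self-consistency
#' counterpart of [constrain_baseline()].
#'
#' @param baseline A `baseline_hazard`.
#' @inheritParams constrain_baseline
#' @return Numeric vector of marginal rates, one per baseline age.
#' @export
marginal_incidence <- function(baseline, params = variance_params(),
                               quadrature_order = 48L) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  ages <- baseline$age
  degenerate <- params$gamma == 0 && params$theta == 0
  sig <- if (degenerate) rep(0, length(ages)) else polygenic_sd(ages, params)
  gh <- gh_rule(quadrature_order)
  mu <- numeric(length(ages))
  cumhaz <- numeric(length(gh$x))
  for (i in seq_along(ages)) {
    surv <- exp(-cumhaz)
    rr <- exp(sig[i] * gh$x)
    mu[i] <- baseline$lambda0[i] * sum(gh$w * rr * surv) / sum(gh$w * surv)
    cumhaz <- cumhaz + baseline$lambda0[i] * rr
  }
  mu
}

#' Write or read a baseline hazard as CSV
#'
#' @param baseline A `baseline_hazard`.
#' @param path Output (or input) CSV path with columns `age, lambda0`.
#' @return `write_baseline` returns `path` invisibly; `read_baseline`
#'   returns a `baseline_hazard`.
#' @export
write_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_hazard"))
  utils::write.csv(as.data.frame(baseline), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "lambda0") %in% names(df)))
  if (any(df$lambda0 < 0)) stop("negative baseline hazard", call. = FALSE)
  structure(data.frame(age = as.integer(df$age), lambda0 = df$lambda0),
            class = c("baseline_hazard", "data.frame"))
}

baseline_covers <- function(baseline, params) {
  need <- seq.int(params$age_min, params$age_max)
  if (!all(need %in% baseline$age))
    stop("baseline hazard does not cover the model age range", call. = FALSE)
  baseline[match(need, baseline$age), , drop = FALSE]
}
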