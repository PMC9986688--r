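# Independent oracles used across the suite.  These deliberately avoid
# the package's own numerical paths.

# Brute-force PRS score: explicit double loop over samples and variants.
oracle_score <- function(dosage, weights_df) {
  n <- nrow(dosage)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(nrow(weights_df))) {
      s <- s + weights_df$weight[j] * dosage[i, weights_df$variant[j]]
    }
    out[i] <- s
  }
  out
}

# Hand-rolled Newton-Raphson logistic regression (intercept + one
# covariate), independent of stats::glm.
oracle_logistic <- function(y, x, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- crossprod(X, y - p)
    info <- crossprod(X, X * W)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = unname(beta), se = unname(sqrt(diag(solve(info)))))
}

# Dense-trapezoid retrospective log-likelihood.  Phenotype probabilities
# are integrated over the residual polygenotype on a uniform grid; the
# denominator uses the rotation identity: alpha*U + sqrt(1-alpha^2)*X_R
# is standard normal when U, X_R are, so the double integral over
# (u, x_R) collapses to a single integral over the effective
# polygenotype c.
oracle_rl_loglik <- function(alpha, cohort, baseline, params,
                             npts = 4000, lim = 8) {
  ages <- seq.int(params$age_min, params$age_max)
  bl <- baseline[match(ages, baseline$age), ]
  sig <- sqrt(params$gamma + params$theta * ages)
  grid <- seq(-lim, lim, length.out = npts)
  h <- grid[2] - grid[1]
  trapz <- function(f) h * (sum(f) - (f[1] + f[npts]) / 2)
  b <- sqrt(1 - alpha^2)

  # P(status, age t | c) for a vector of effective polygenotypes c
  p_pheno <- function(status, t, cvec) {
    it <- t - params$age_min + 1L
    lam <- rep(0, length(cvec))
    if (it > 1L)
      for (u in seq_len(it - 1L))
        lam <- lam + bl$lambda0[u] * exp(sig[u] * cvec)
    p <- exp(-lam)
    if (status == 1L) p <- p * bl$lambda0[it] * exp(sig[it] * cvec)
    p
  }

  keys <- paste(cohort$status, cohort$age)
  denom <- vapply(unique(keys), function(k) {
    st <- as.integer(strsplit(k, " ")[[1]])
    trapz(p_pheno(st[1], st[2], grid) * dnorm(grid))
  }, numeric(1))
  names(denom) <- unique(keys)

  ll <- 0
  for (i in seq_len(nrow(cohort))) {
    num <- trapz(p_pheno(cohort$status[i], cohort$age[i],
                         alpha * cohort$prs_std[i] + b * grid) * dnorm(grid))
    ll <- ll + log(num) + dnorm(cohort$prs_std[i], log = TRUE) -
      log(denom[[keys[i]]])
  }
  ll
}
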