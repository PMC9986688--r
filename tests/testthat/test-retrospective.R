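test_that("at alpha = 0 the likelihood is exactly the normal density sum", {
  bl <- default_baseline()
  vp <- variance_params()
  co <- make_cohort(300, 500, 0.44, seed = 4)
  ll0 <- retrospective_loglik(0, co, bl, vp)
  expect_equal(ll0, sum(dnorm(co$prs_std, log = TRUE)), tolerance = 1e-12)
  # and is then independent of the incidence the baseline encodes
  inc2 <- ew_breast_incidence()
  inc2$rate <- inc2$rate * 2
  bl2 <- constrain_baseline(incidence_table(inc2$age, inc2$rate), vp)
  expect_equal(retrospective_loglik(0, co, bl2, vp), ll0, tolerance = 1e-12)
})

test_that("quadrature likelihood matches the dense-trapezoid oracle", {
  bl <- default_baseline()
  vp <- variance_params()
  co <- make_cohort(20, 30, 0.44, seed = 77)
  for (a in c(0.2, 0.44, 0.7)) {
    expect_lt(abs(retrospective_loglik(a, co, bl, vp) -
                    oracle_rl_loglik(a, co, bl, vp, npts = 4000, lim = 8)),
              1e-6)
  }
})

test_that("likelihood agrees with the R-level phenotype probabilities", {
  # reconstruct the likelihood record by record from the exported
  # phenotype-probability path and the same quadrature rule
  bl <- default_baseline()
  vp <- variance_params()
  co <- make_cohort(4, 6, 0.5, seed = 3)
  gh <- prscalib:::gh_rule(30)
  alpha <- 0.37
  ll_manual <- 0
  for (i in seq_len(nrow(co))) {
    st <- if (co$status[i] == 1) "case" else "control"
    num <- phenotype_prob_given_prs(st, co$age[i], co$prs_std[i], alpha,
                                    bl, vp)
    den <- sum(gh$w * vapply(gh$x, function(u)
      phenotype_prob_given_prs(st, co$age[i], u, alpha, bl, vp),
      numeric(1)))
    ll_manual <- ll_manual + log(num) - log(den) +
      dnorm(co$prs_std[i], log = TRUE)
  }
  expect_equal(retrospective_loglik(alpha, co, bl, vp), ll_manual,
               tolerance = 1e-10)
})

test_that("the profile is continuous and unimodal on a recovery cohort", {
  bl <- default_baseline()
  vp <- variance_params()
  co <- make_cohort(1500, 2500, 0.44, seed = 19)
  grid <- seq(0, 0.9, by = 0.05)
  ll <- vapply(grid, retrospective_loglik, numeric(1),
               cohort = co, baseline = bl, params = vp)
  expect_true(all(is.finite(ll)))
  # single sign change in the first differences: rises then falls
  expect_equal(sum(diff(sign(diff(ll))) != 0), 1)
  expect_gt(grid[which.max(ll)], 0.2)
  expect_lt(grid[which.max(ll)], 0.7)
})

test_that("RL estimation recovers alpha and flags boundary nulls", {
  vp <- variance_params()
  inc <- ew_breast_incidence()
  co <- make_cohort(2000, 3000, 0.44, seed = 42)
  est <- estimate_alpha_rl(co, inc, vp)
  expect_s3_class(est, "alpha_estimate")
  expect_lt(abs(est$alpha - 0.44), 0.06)   # ~3 MC SE at this cohort size
  expect_true(est$ci_low <= est$alpha & est$alpha <= est$ci_high)
  expect_false(est$boundary)
  # null cohort: estimate near zero, lower CI at the grid floor
  co0 <- make_cohort(600, 900, 0, seed = 23)
  est0 <- estimate_alpha_rl(co0, inc, vp)
  expect_lt(est0$alpha, 0.1)
  expect_equal(est0$ci_low, 0)
})

test_that("recovery holds across the plausible alpha range", {
  vp <- variance_params()
  inc <- ew_breast_incidence()
  for (true_alpha in c(0.2, 0.6)) {
    hats <- vapply(1:3, function(s) {
      co <- simulate_cohort(sim_config(3200, 4800, true_alpha,
                                       seed = 300 + s))
      estimate_alpha_rl(co, inc, vp, ci = FALSE)$alpha
    }, numeric(1))
    # bound: ~3x the Monte-Carlo SE of a 3-replicate mean at this n
    expect_lt(abs(mean(hats) - true_alpha), 0.035)
  }
})

test_that("alpha domain errors surface before any computation", {
  bl <- default_baseline()
  co <- make_cohort(30, 50, 0.3, seed = 2)
  expect_error(retrospective_loglik(1, co, bl), "\\[0, 1\\)")
  expect_error(retrospective_loglik(-0.1, co, bl), "\\[0, 1\\)")
  expect_error(estimate_alpha_rl(co, ew_breast_incidence(),
                                 bounds = c(0.5, 0.2)), "increasing")
})
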