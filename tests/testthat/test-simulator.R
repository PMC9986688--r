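test_that("cohorts are byte-identical under a fixed seed", {
  a <- make_cohort(300, 500, 0.44, seed = 101)
  b <- make_cohort(300, 500, 0.44, seed = 101)
  expect_identical(a, b)
  c2 <- make_cohort(300, 500, 0.44, seed = 102)
  expect_false(identical(a, c2))
  expect_equal(sum(a$status == 1), 300)
  expect_equal(sum(a$status == 0), 500)
})

test_that("a null incidence yields no cases and a generation error", {
  vp <- variance_params()
  null_inc <- incidence_table(20:79, rep(0, 60))
  bl <- constrain_baseline(null_inc, vp)
  set.seed(1)
  onsets <- replicate(25, simulate_individual(1.5, 1.5, 0.9, bl, vp,
                                              censor_age = 79))
  expect_true(all(is.na(onsets)))
  cfg <- sim_config(10, 10, 0.44, incidence = null_inc)
  expect_error(simulate_cohort(cfg), "incidence may be too low")
})

test_that("an extreme polygenotype with inflated hazard fails immediately", {
  vp <- variance_params()
  big <- incidence_table(20:79, rep(0.5, 60))
  bl <- constrain_baseline(big, vp)
  set.seed(2)
  onsets <- replicate(30, simulate_individual(8, 0, 0.99, bl, vp,
                                              censor_age = 79))
  expect_true(all(onsets == 20L))
})

test_that("case PRS means exceed control means exactly when alpha > 0", {
  co <- make_cohort(2500, 2500, 0.44, seed = 55)
  expect_gt(mean(co$prs_std[co$status == 1]),
            mean(co$prs_std[co$status == 0]))
  co0 <- make_cohort(2500, 2500, 0, seed = 56)
  d <- mean(co0$prs_std[co0$status == 1]) -
    mean(co0$prs_std[co0$status == 0])
  pooled_se <- sqrt(var(co0$prs_std[co0$status == 1]) / 2500 +
                      var(co0$prs_std[co0$status == 0]) / 2500)
  expect_lt(abs(d), 3 * pooled_se)
})

test_that("control PRS distribution stays near standard normal", {
  co <- make_cohort(1000, 6000, 0.44, seed = 77)
  s <- sd(co$prs_std[co$status == 0])
  # SE of an SD estimate is about sigma/sqrt(2n)
  expect_lt(abs(s - 1), 3 / sqrt(2 * 6000) + 0.02)
})

test_that("survivorship induces the negative PRS-residual correlation", {
  vp <- variance_params()
  bl <- default_baseline()
  alpha <- 0.6
  set.seed(91)
  n <- 40000
  x_k <- rnorm(n); x_r <- rnorm(n)
  censor <- rep(79L, n)
  u <- matrix(runif(n * 60), nrow = n)
  onset <- prscalib:::sim_onset_cpp(bl$lambda0,
                                    sqrt(polygenic_variance(20:79, vp)),
                                    20L, alpha * x_k + sqrt(1 - alpha^2) * x_r,
                                    censor, u)
  old_controls <- is.na(onset)
  expect_lt(cor(x_k[old_controls], x_r[old_controls]), 0)
  # a priori the components are uncorrelated
  expect_lt(abs(cor(x_k, x_r)), 3 / sqrt(n))
})

test_that("simulated onsets reproduce the input incidence", {
  vp <- variance_params()
  inc <- ew_breast_incidence()
  bl <- constrain_baseline(inc, vp)
  set.seed(424)
  n <- 200000
  x_k <- rnorm(n); x_r <- rnorm(n)
  u <- matrix(runif(n * 60), nrow = n)
  onset <- prscalib:::sim_onset_cpp(bl$lambda0,
                                    sqrt(polygenic_variance(20:79, vp)),
                                    20L, 0.44 * x_k + sqrt(1 - 0.44^2) * x_r,
                                    rep(79L, n), u)
  for (decade_start in c(20, 30, 40, 50, 60, 70)) {
    ages <- decade_start:min(decade_start + 9, 78)
    at_risk <- vapply(ages, function(t)
      sum(is.na(onset) | onset >= t), numeric(1))
    events <- vapply(ages, function(t) sum(onset == t, na.rm = TRUE),
                     numeric(1))
    p_obs <- sum(events) / sum(at_risk)
    p_exp <- sum(inc$rate[match(ages, inc$age)] * at_risk) / sum(at_risk)
    se <- sqrt(p_exp * (1 - p_exp) / sum(at_risk))
    expect_lt(abs(p_obs - p_exp), 3 * se + 0.02 * p_exp)
  }
})

test_that("country shifts move recorded PRS means but not disease risk", {
  shifts <- c(A = -0.4, B = 0.4)
  co <- simulate_cohort(sim_config(1500, 2500, 0.44, seed = 61,
                                   country_shifts = shifts))
  ctrl <- co[co$status == 0, ]
  expect_gt(mean(ctrl$prs_raw[ctrl$country == "B"]),
            mean(ctrl$prs_raw[ctrl$country == "A"]) + 0.5)
  # case fraction is country-independent by construction
  tab <- table(co$country, co$status)
  p <- prop.table(tab, 1)[, "1"]
  expect_lt(abs(p[["A"]] - p[["B"]]), 0.1)
})

test_that("the consortium-like preset hits the target case age structure", {
  cfg <- sim_config_bcac_like(2000, 2000, 0.44, seed = 71)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$age[co$status == 1]) - 59.9), 1.5)
})
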