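test_that("the shared-regressor bivariate fit equals per-equation OLS", {
  for (s in 1:10) {
    dat <- generate_complete(trial_config(n_patients = 150, seed = 600 + s))
    agg <- assemble_aggregate(dat, 1)
    e0 <- baseline_eq5d0 <- ceamiss:::baseline_eq5d0(dat)
    f <- bivariate_fit(agg, dat$baseline, e0)
    X <- ceamiss:::aggregate_design(dat$baseline, e0)
    for (col in c("cost", "qaly")) {
      y <- if (col == "cost") agg$total_cost else agg$total_qaly
      ols <- stats::lm.fit(X, y)
      expect_equal(unname(f$coef[, col]), unname(ols$coefficients),
                   tolerance = 1e-10)
    }
  }
})

test_that("identical outcome columns give identical coefficient vectors", {
  dat <- generate_complete(trial_config(n_patients = 100, seed = 61))
  agg <- assemble_aggregate(dat, 1)
  agg$total_qaly <- agg$total_cost
  f <- bivariate_fit(agg, dat$baseline, ceamiss:::baseline_eq5d0(dat))
  expect_equal(f$coef[, "cost"], f$coef[, "qaly"])
  expect_equal(f$sigma[1, 1], f$sigma[2, 2])
})

test_that("treatment-coefficient covariance is null when residuals are independent", {
  # independent residuals in truth: the off-diagonal of the delta
  # covariance should hover near zero across simulations
  z <- vapply(1:30, function(s) {
    dat <- generate_complete(trial_config(n_patients = 200,
                                          subject_sd_cost = 0,
                                          subject_sd_eq5d = 0,
                                          seed = 700 + s))
    f <- bivariate_fit(assemble_aggregate(dat, 1), dat$baseline,
                       ceamiss:::baseline_eq5d0(dat))
    f$delta_vcov[1, 2] / sqrt(f$delta_vcov[1, 1] * f$delta_vcov[2, 2])
  }, numeric(1))
  expect_lt(abs(mean(z)) / (stats::sd(z) / sqrt(length(z))), 3)
})

test_that("complete-case analysis matches the full fit on complete data", {
  dat <- generate_complete(trial_config(n_patients = 200, seed = 62))
  agg <- assemble_aggregate(dat, 1)
  full <- bivariate_fit(agg, dat$baseline, ceamiss:::baseline_eq5d0(dat))
  cc <- cca_fit(dat, 1)
  expect_equal(cc$delta, full$delta)
  expect_equal(cc$n_used, 200)
  # with missingness, n_used equals the complete cell of the pattern table
  masked <- simulate_trial(trial_config(seed = 63))
  cc1 <- cca_fit(masked, 1)
  p <- pattern_table(assemble_aggregate(masked, 1))
  expect_equal(cc1$n_used, p$n[1])
  expect_lt(cc1$n_used, 450)
  # incomplete totals are an error unless dropped
  expect_error(bivariate_fit(assemble_aggregate(masked, 1), masked$baseline,
                             ceamiss:::baseline_eq5d0(masked)),
               "drop_incomplete")
})

test_that("conditional-normal moments follow the closed form", {
  mu <- c(2, -1)
  sigma <- matrix(c(4, 1.2, 1.2, 0.25), 2)
  m <- conditional_outcome_moments(mu, sigma, partner_value = 0.5)
  expect_equal(m$mean, 2 + 1.2 / 0.25 * (0.5 - (-1)))
  expect_equal(m$var, 4 - 1.2^2 / 0.25)
  # independence: partner carries no information
  s0 <- diag(c(4, 0.25))
  m0 <- conditional_outcome_moments(mu, s0, 3)
  expect_equal(m0$mean, mu[1])
  expect_equal(m0$var, 4)
})

test_that("the selection model concurs with least squares on complete data", {
  dat <- generate_complete(trial_config(seed = 64))
  ls <- bivariate_fit(assemble_aggregate(dat, 1), dat$baseline,
                      ceamiss:::baseline_eq5d0(dat))
  b <- bpa_fit(dat, 1, bpa_config(iterations = 3000, burnin = 1000,
                                  seed = 64))
  # with vague priors and complete data the posterior mean should sit well
  # inside a fraction of the sampling SD of the least-squares estimate
  for (k in c("cost", "qaly")) {
    expect_lt(abs(b$delta[k] - ls$delta[k]),
              0.5 * sqrt(ls$delta_vcov[k, k]))
  }
  expect_true(all(b$rhat < 1.05))
})

test_that("posterior spread grows when totals are missing", {
  cfg <- trial_config(seed = 65)
  comp <- generate_complete(cfg)
  full <- bpa_fit(comp, 1, bpa_config(iterations = 2000, burnin = 500,
                                      seed = 65))
  masked <- impose_missingness(comp, cfg)
  miss <- bpa_fit(masked, 1, bpa_config(iterations = 2000, burnin = 500,
                                        seed = 65))
  expect_gt(sqrt(miss$delta_vcov["qaly", "qaly"]),
            sqrt(full$delta_vcov["qaly", "qaly"]))
})

test_that("under MAR the missingness submodels leave the posterior alone", {
  masked <- simulate_trial(trial_config(seed = 66))
  with_aux <- bpa_fit(masked, 1, bpa_config(iterations = 2000, burnin = 500,
                                            seed = 66))
  no_aux <- bpa_fit(masked, 1,
                    bpa_config(iterations = 2000, burnin = 500, seed = 66,
                               include_missingness_model = FALSE))
  for (k in c("cost", "qaly")) {
    sdk <- sqrt(with_aux$delta_vcov[k, k])
    expect_lt(abs(with_aux$delta[k] - no_aux$delta[k]), sdk / 2)
  }
})

test_that("prior-precision sensitivity barely moves the posterior", {
  masked <- simulate_trial(trial_config(seed = 67))
  lo <- bpa_fit(masked, 1, bpa_config(prior_precision = 0.001,
                                      iterations = 2000, burnin = 500,
                                      seed = 67))
  hi <- bpa_fit(masked, 1, bpa_config(prior_precision = 0.01,
                                      iterations = 2000, burnin = 500,
                                      seed = 67))
  for (k in c("cost", "qaly")) {
    expect_lt(abs(lo$delta[k] - hi$delta[k]),
              sqrt(lo$delta_vcov[k, k]))
  }
})
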