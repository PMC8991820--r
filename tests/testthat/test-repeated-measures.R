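# LSDV oracle: least squares with explicit subject dummies on the same
# treatment-by-week design columns (baseline week as reference)
lsdv_delta <- function(data, outcome) {
  df <- long_panel(data, outcome)
  df$week <- droplevels(df$week)
  X <- stats::model.matrix(~ treat * week, df)[, -1, drop = FALSE]
  fit <- stats::lm(df$y ~ factor(df$patient_id) + X)
  cf <- stats::coef(fit)
  names(cf) <- sub("^X", "", names(cf))
  cf[grep("^treat:week", names(cf))]
}

test_that("the within estimator equals LSDV on random small panels", {
  for (s in 1:10) {
    cfg <- trial_config(n_patients = 30, seed = 1000 + s)
    dat <- simulate_trial(cfg)
    fe <- fit_rmfe(dat, "cost")
    or <- lsdv_delta(dat, "cost")
    d <- intersect(grep("^treat:week", names(fe$beta), value = TRUE),
                   names(or)[!is.na(or)])
    expect_gt(length(d), 10)
    expect_equal(fe$beta[d], or[d], tolerance = 1e-8)
  }
})

test_that("within estimation ignores shifts in absorbed covariates", {
  dat <- simulate_trial(trial_config(n_patients = 60, seed = 21))
  f1 <- fit_rmfe(dat, "eq5d")
  dat2 <- dat
  dat2$baseline$age[3] <- dat2$baseline$age[3] + 40
  f2 <- fit_rmfe(dat2, "eq5d")
  d <- grep("^treat:week", names(f1$beta), value = TRUE)
  expect_equal(f1$beta[d], f2$beta[d], tolerance = 1e-10)
  expect_true(any(grepl("^age$", f1$absorbed)))
})

test_that("with no subject heterogeneity the RMM matches pooled OLS", {
  cfg <- trial_config(n_patients = 120, subject_sd_cost = 0,
                      subject_sd_eq5d = 0, seed = 22)
  dat <- generate_complete(cfg)
  rmm <- fit_rmm(dat, "eq5d")
  df <- long_panel(dat, "eq5d")
  ols <- stats::lm(y ~ treat + duration + age + size + site + week +
                     treat:week, data = df)
  cf <- stats::coef(ols)
  names(cf) <- sub("^week([0-9]+):treat$", "treat:week\\1", names(cf))
  d <- grep("^treat:week", names(rmm$beta), value = TRUE)
  expect_equal(rmm$beta[d], cf[d], tolerance = 1e-3)
})

test_that("both panel estimators recover known interaction effects", {
  cost_eff <- c(rep(120, 12), rep(250, 4))
  cfg <- trial_config(n_patients = 450, cost_effects = cost_eff, seed = 23)
  dat <- simulate_trial(cfg)
  for (fitter in list(fit_rmm, fit_rmfe)) {
    f <- fitter(dat, "cost")
    # pick a monthly and a yearly period
    for (wk in c("13", "104")) {
      nm <- paste0("treat:week", wk)
      truth <- cost_eff[match(as.numeric(wk),
                              dat$schedule$period_bounds[-1])]
      se <- sqrt(f$vcov[nm, nm])
      expect_lt(abs(f$beta[nm] - truth) / se, 3)
    }
    tot <- incremental_cost_total(f, 1, rate = 0)
    expect_lt(abs(tot$est - 12 * 120) / tot$se, 3)
  }
})

test_that("incremental totals are linear combinations of the coefficients", {
  dat <- generate_complete(trial_config(n_patients = 150, seed = 24))
  f <- fit_rmm(dat, "cost")
  # sum rule: three periods of 10/20/30 add to 60
  f0 <- f
  d <- grep("^treat:week", names(f0$beta))
  f0$beta[d] <- 0
  f0$beta[c("treat:week4", "treat:week8", "treat:week13")] <- c(10, 20, 30)
  expect_equal(incremental_cost_total(f0, 13 / 52 * 0 + 1, rate = 0)$est -
                 incremental_cost_total(f0, 1, rate = 0)$est, 0)
  expect_equal(sum(f0$beta[c("treat:week4", "treat:week8",
                             "treat:week13")]), 60)
  # with zero deltas the variance is the full quadratic form
  f0$beta[d] <- 0
  ict <- incremental_cost_total(f0, 1, rate = 0)
  expect_equal(ict$est, 0)
  w <- paste0("treat:week", default_schedule()$period_bounds[2:13])
  expect_equal(ict$var, drop(rep(1, 12) %*% f0$vcov[w, w] %*% rep(1, 12)))
  # horizon additivity: 3y total = 1y total + year-2,3 terms
  full <- incremental_cost_total(f, 3, rate = 0)$est
  y1 <- incremental_cost_total(f, 1, rate = 0)$est
  y23 <- sum(f$beta[c("treat:week104", "treat:week156")])
  expect_equal(full, y1 + y23, tolerance = 1e-10)
  # horizon beyond the fitted weeks errors
  f5 <- f
  f5$beta <- f5$beta[!grepl("treat:week260", names(f5$beta))]
  expect_error(incremental_cost_total(f5, 5), "beyond")
})

test_that("the QALY combination evaluates the printed trapezium formula", {
  dat <- generate_complete(trial_config(n_patients = 150, seed = 25))
  f <- fit_rmm(dat, "eq5d")
  # zero out everything, set the week-6 and week-26 arm differences
  f$beta[] <- 0
  f$beta["treat:week6"] <- 0.05
  f$beta["treat:week26"] <- 0.05
  r <- incremental_qaly_total(f, 0.5, rate = 0)
  expect_equal(r$est, 0.5 * (0.05 * 6 / 52 + 0.10 * 20 / 52))
  # doubling the coefficients doubles the total
  f2 <- f
  f2$beta <- 2 * f$beta
  expect_equal(incremental_qaly_total(f2, 0.5, rate = 0)$est, 2 * r$est)
  # a baseline arm difference enters every grid point
  f$beta["treat"] <- 0.1
  r2 <- incremental_qaly_total(f, 1, rate = 0)
  diffs <- c(0.1, 0.15, 0.15, 0.1)   # arm difference at weeks 0/6/26/52
  wk <- c(0, 6, 26, 52)
  manual <- sum(0.5 * (diffs[-4] + diffs[-1]) * diff(wk) / 52)
  expect_equal(r2$est, manual)
})

test_that("the cluster bootstrap is deterministic and consistent", {
  dat <- simulate_trial(trial_config(n_patients = 80, seed = 26))
  b1 <- bootstrap_cea(dat, 1, B = 20, seed = 9, method = "rmfe")
  b2 <- bootstrap_cea(dat, 1, B = 20, seed = 9, method = "rmfe")
  expect_identical(b1, b2)
  # degenerate data: identical patients, no noise -> identical draws
  cfg0 <- silent_config(n_patients = 40, recruit_window_months = 0,
                        missing_logit = list(intercept = -Inf), seed = 27)
  d0 <- generate_complete(cfg0)
  # zero residuals make lm grumble about perfect fits; that is the point
  b0 <- suppressWarnings(bootstrap_cea(d0, 1, B = 5, seed = 1,
                                       method = "rmfe"))
  expect_equal(max(apply(b0, 2, stats::sd)), 0, tolerance = 1e-10)
  # bootstrap mean near the point estimate
  dat2 <- simulate_trial(trial_config(n_patients = 200, seed = 28))
  fb <- bootstrap_cea(dat2, 1, B = 500, seed = 2, method = "rmfe",
                      rate = 0, qaly_rate = 0)
  fc <- fit_rmfe(dat2, "cost")
  fq <- fit_rmfe(dat2, "eq5d")
  pt <- c(incremental_cost_total(fc, 1, 0)$est,
          incremental_qaly_total(fq, 1, 0)$est)
  mcse <- apply(fb, 2, stats::sd) / sqrt(nrow(fb))
  expect_lt(abs(mean(fb[, 1]) - pt[1]) / mcse[1], 3)
  expect_lt(abs(mean(fb[, 2]) - pt[2]) / mcse[2], 3)
})

test_that("REML log-likelihood at convergence beats the zero-variance fit", {
  dat <- generate_complete(trial_config(n_patients = 100, seed = 29))
  rmm <- fit_rmm(dat, "eq5d", reml = FALSE)
  df <- long_panel(dat, "eq5d")
  ols <- stats::lm(y ~ treat + duration + age + size + site + week +
                     treat:week, data = df)
  expect_gte(as.numeric(stats::logLik(rmm$model)),
             as.numeric(stats::logLik(ols)) - 1e-6)
})
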