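test_that("degenerate noise yields the period and week intercepts exactly", {
  cfg <- silent_config(n_patients = 25, seed = 1)
  dat <- generate_complete(cfg)
  expect_equal(dat$costs$cost,
               unname(cfg$cost_intercepts[dat$costs$period]))
  expect_equal(dat$eq5d$utility,
               unname(cfg$eq5d_intercepts[as.character(dat$eq5d$week)]))
})

test_that("staggered recruitment gives the implied follow-up distribution", {
  cfg <- trial_config(n_patients = 10000, seed = 99)
  dat <- generate_complete(cfg)
  fu <- dat$baseline$censor_month
  expect_true(all(fu >= 29 & fu <= 65))
  # uniform recruitment over 36 months, end at 65: median follow-up 47
  expect_equal(median(fu), 47, tolerance = 0.02)
})

test_that("generation and masking are deterministic given the seed", {
  d1 <- simulate_trial(trial_config(n_patients = 80, seed = 5))
  d2 <- simulate_trial(trial_config(n_patients = 80, seed = 5))
  expect_identical(d1, d2)
  d3 <- simulate_trial(trial_config(n_patients = 80, seed = 6))
  expect_false(identical(d3$costs$cost, d1$costs$cost))
})

test_that("no missingness and no pruning leaves the dataset intact", {
  cfg <- trial_config(n_patients = 30, recruit_window_months = 0,
                      study_end_month = 261 * 12 / 52,
                      missing_logit = list(intercept = -Inf), seed = 2)
  dat <- generate_complete(cfg)
  masked <- impose_missingness(dat, cfg, telephone_rule = FALSE)
  expect_equal(masked$costs, dat$costs)
  expect_equal(masked$eq5d, dat$eq5d)
})

test_that("intercept-only logit at 0 marks about half the eligible items", {
  cfg <- trial_config(n_patients = 450, recruit_window_months = 0,
                      study_end_month = 261 * 12 / 52,
                      missing_logit = list(intercept = 0), seed = 31)
  dat <- generate_complete(cfg)
  masked <- impose_missingness(dat, cfg, telephone_rule = FALSE)
  # eligible items: all 16 periods and the 7 post-baseline weeks
  n_items <- nrow(masked$costs) + sum(masked$eq5d$week > 0)
  n_miss <- sum(!masked$costs$observed) +
    sum(!masked$eq5d$observed & masked$eq5d$week > 0)
  band <- 3 * sqrt(n_items * 0.25)
  expect_lt(abs(n_miss - n_items / 2), band)
  expect_true(all(masked$eq5d$observed[masked$eq5d$week == 0]))
})

test_that("telephone rule keeps the latest grid week within follow-up", {
  # recruited month 35, study end 65: 30 months follow-up (130 weeks)
  cfg <- silent_config(n_patients = 1,
                       missing_logit = list(intercept = -Inf), seed = 4)
  dat <- generate_complete(cfg)
  dat$baseline$recruit_month <- 35
  dat$baseline$censor_month <- 30
  masked <- impose_missingness(dat, cfg)
  ee <- masked$eq5d
  expect_true(ee$observed[ee$week == 104])
  expect_true(all(!ee$observed[ee$week %in% c(156, 208, 260)]))
  expect_true(all(ee$miss_design[ee$week %in% c(156, 208, 260)]))
  expect_true(all(ee$observed[ee$week %in% c(0, 6, 26, 52)]))
  # costs: periods closing after week 130 are missing by design
  cc <- masked$costs
  expect_true(all(!cc$observed[cc$week_end > 130]))
  expect_true(all(cc$observed[cc$week_end <= 130]))
})

test_that("the structural layer is idempotent", {
  cfg <- trial_config(n_patients = 60, seed = 8)
  dat <- generate_complete(cfg)
  m1 <- impose_missingness(dat, cfg, layers = "structural")
  m2 <- impose_missingness(m1, cfg, layers = "structural")
  m1$shadow <- m2$shadow <- NULL
  expect_equal(m1, m2)
})

test_that("item missingness frequency matches the configured logit", {
  # covariate-free mechanism at a known rate, full follow-up for everyone
  p_true <- stats::plogis(-1.2)
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    cfg <- trial_config(n_patients = 450, recruit_window_months = 0,
                        study_end_month = 261 * 12 / 52,
                        missing_logit = list(intercept = -1.2),
                        seed = 300 + s)
    masked <- simulate_trial(cfg, telephone_rule = FALSE)
    hits <- hits + sum(!masked$costs$observed) +
      sum(!masked$eq5d$observed & masked$eq5d$week > 0)
    total <- total + nrow(masked$costs) + sum(masked$eq5d$week > 0)
  }
  bt <- stats::binom.test(hits, total, p_true)
  expect_gt(bt$p.value, 0.001)
})

test_that("with the death hazard off no zero-assigned post-death records exist", {
  dat <- simulate_trial(trial_config(n_patients = 100, seed = 12))
  expect_true(all(is.na(dat$baseline$death_month)))
  # all-zero trajectories would be the footprint of a death assignment
  zero_runs <- tapply(dat$eq5d$utility[dat$eq5d$observed],
                      dat$eq5d$patient_id[dat$eq5d$observed],
                      function(u) all(u == 0))
  expect_false(any(zero_runs))
})

test_that("the shadow truth preserves the complete data for masked cells", {
  cfg <- trial_config(n_patients = 60, seed = 13)
  comp <- generate_complete(cfg)
  masked <- impose_missingness(comp, cfg)
  tr <- shadow_truth(masked)
  expect_equal(tr$costs$cost, comp$costs$cost)
  expect_equal(tr$eq5d$utility, comp$eq5d$utility)
  # masked cells are NA in the visible table
  expect_true(all(is.na(masked$costs$cost[!masked$costs$observed])))
})

test_that("trial tables round-trip through CSV", {
  dat <- simulate_trial(trial_config(n_patients = 20, seed = 14))
  dir <- tempfile("trial")
  write_trial(dat, dir)
  back <- read_trial(dir)
  expect_equal(back$baseline$censor_month, dat$baseline$censor_month)
  expect_equal(back$costs$cost, dat$costs$cost)
  expect_equal(back$eq5d$utility, dat$eq5d$utility)
  expect_equal(back$eq5d$miss_design, dat$eq5d$miss_design)
  unlink(dir, recursive = TRUE)
})

test_that("config validation rejects malformed effect vectors", {
  expect_error(trial_config(cost_effects = rep(0, 5)), "16")
  expect_error(trial_config(subject_sd_cost = -1), ">= 0")
  expect_error(trial_config(arm_allocation = 1.4), "probability")
})
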