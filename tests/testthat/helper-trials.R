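# Builders for small fixtures used across test files.

# a trial_data assembled by hand from explicit tables
hand_trial <- function(baseline, costs, eq5d) {
  sch <- default_schedule()
  if (is.null(costs$week_start)) {
    b <- sch$period_bounds
    costs$week_start <- b[costs$period]
    costs$week_end <- b[costs$period + 1L]
  }
  if (is.null(costs$miss_design)) costs$miss_design <- FALSE
  if (is.null(eq5d$miss_design)) eq5d$miss_design <- FALSE
  out <- list(baseline = baseline, costs = costs, eq5d = eq5d,
              schedule = sch, config = NULL, shadow = NULL)
  class(out) <- "trial_data"
  out
}

# baseline rows with neutral covariates
flat_baseline <- function(n, treat = rep(0L, n), censor_month = 65) {
  data.frame(patient_id = seq_len(n), treat = treat, age = 67, size = 5,
             duration = 1.5, site = 1L, ethnicity = 1L, diabetes = 0L,
             dvt_history = 0L, trial_leg = 0L, recruit_month = 0,
             censor_month = censor_month, death_month = NA_real_)
}

# full cost/eq5d grids with constant values, all observed
flat_costs <- function(n, value = 100) {
  g <- expand.grid(patient_id = seq_len(n), period = 1:16)
  g <- g[order(g$patient_id, g$period), ]
  g$cost <- value
  g$observed <- TRUE
  rownames(g) <- NULL
  g
}

flat_eq5d <- function(n, value = 0.6) {
  wk <- default_schedule()$eq5d_weeks
  g <- expand.grid(patient_id = seq_len(n), week = wk)
  g <- g[order(g$patient_id, g$week), ]
  g$utility <- value
  g$observed <- TRUE
  rownames(g) <- NULL
  g
}

flat_trial <- function(n, cost = 100, utility = 0.6, treat = rep(0L, n)) {
  hand_trial(flat_baseline(n, treat), flat_costs(n, cost),
             flat_eq5d(n, utility))
}

# a noiseless config: all effects zero, no heterogeneity
silent_config <- function(resid_sd_cost = 0, resid_sd_eq5d = 0, ...) {
  trial_config(cost_effects = rep(0, 16),
               eq5d_effects = list(
                 baseline_diff = 0,
                 delta = stats::setNames(rep(0, 7),
                                         c("6", "26", "52", "104", "156",
                                           "208", "260"))),
               covariate_effects = list(
                 cost = c(age = 0, size = 0, duration = 0),
                 eq5d = c(age = 0, size = 0, duration = 0)),
               site_effects = list(cost = rep(0, 5), eq5d = rep(0, 5)),
               subject_sd_cost = 0, subject_sd_eq5d = 0,
               resid_sd_cost = resid_sd_cost,
               resid_sd_eq5d = resid_sd_eq5d,
               ...)
}
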