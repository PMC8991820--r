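#' Configuration for a synthetic leg-ulcer trial
#'
#' Defines the generating model for a two-arm trial with staggered
#' recruitment over a fixed calendar window and a common administrative study
#' end, monthly cost periods in year 1 then yearly, and EQ-5D utilities at
#' weeks 0/6/26/52 plus at most one late telephone follow-up. Outcomes follow
#' a linear model: baseline covariates + a period/week effect + a
#' treatment-by-time interaction + a shared patient intercept + independent
#' residual noise.
#'
#' The default treatment effects encode the reference scenario used
#' throughout the package's validation: zero incremental cost in every
#' period, and a constant incremental utility at every post-baseline week
#' chosen so that the true undiscounted incremental QALY at the 3-year
#' horizon is exactly \code{true_dqaly_3y} (default 0.07).
#'
#' @param n_patients number of patients (default 450).
#' @param recruit_window_months recruitment window length (default 36).
#' @param study_end_month study end, months after first possible recruitment
#'   (default 65); follow-up is \code{study_end_month - recruit_month}.
#' @param arm_allocation probability of allocation to the early arm.
#' @param cost_effects true incremental period costs (GBP), length 16.
#' @param eq5d_effects list with \code{baseline_diff} (arm difference at
#'   week 0) and \code{delta}, a vector of incremental utilities named by
#'   post-baseline week ("6","26",...,"260").
#' @param true_dqaly_3y if \code{eq5d_effects} is NULL, the constant weekly
#'   incremental utility is solved so the undiscounted 3-year incremental
#'   QALY equals this value.
#' @param covariate_effects list with numeric vectors \code{cost} and
#'   \code{eq5d}, each with elements \code{age}, \code{size},
#'   \code{duration} (effects per centred unit).
#' @param site_effects list with vectors \code{cost} and \code{eq5d} of
#'   fixed site intercept shifts, length \code{n_sites}.
#' @param n_sites number of recruiting sites (fixed factor).
#' @param cost_intercepts mean period costs (GBP) under control, length 16.
#' @param eq5d_intercepts mean utilities under control, named by week.
#' @param subject_sd_cost,subject_sd_eq5d SD of the shared patient intercept
#'   on each outcome scale.
#' @param resid_sd_cost,resid_sd_eq5d within-patient residual SDs.
#' @param missing_logit coefficients of the item-level missingness logit
#'   (see [impose_missingness()]): \code{intercept} (or separate
#'   \code{intercept_cost}/\code{intercept_eq5d}), \code{treat},
#'   \code{duration}, \code{age}, \code{size}, \code{site} (vector),
#'   \code{time_years} (slope on weeks/52), and the outcome-history terms
#'   \code{prev_utility} and \code{prev_utility_treat} used to construct
#'   missingness that depends on observed outcomes.
#' @param death_rate annual death hazard (default 0, deaths off).
#' @param discount_rate annual discount rate carried into reporting.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return object of class \code{trial_config}.
#' @export
trial_config <- function(n_patients = 450,
                         recruit_window_months = 36,
                         study_end_month = 65,
                         arm_allocation = 0.5,
                         cost_effects = rep(0, 16),
                         eq5d_effects = NULL,
                         true_dqaly_3y = 0.07,
                         covariate_effects = list(
                           cost = c(age = 2, size = 8, duration = 10),
                           eq5d = c(age = -0.003, size = -0.004,
                                    duration = -0.005)),
                         site_effects = list(
                           cost = c(0, 40, -30, 20, -40),
                           eq5d = c(0, 0.02, -0.02, 0.01, -0.01)),
                         n_sites = 5,
                         cost_intercepts = c(700, 450, 350, 300, 260, 230,
                                             210, 190, 180, 170, 160, 150,
                                             400, 350, 300, 300),
                         eq5d_intercepts = c("0" = 0.45, "6" = 0.55,
                                             "26" = 0.60, "52" = 0.62,
                                             "104" = 0.63, "156" = 0.63,
                                             "208" = 0.62, "260" = 0.61),
                         subject_sd_cost = 120,
                         subject_sd_eq5d = 0.12,
                         resid_sd_cost = 250,
                         resid_sd_eq5d = 0.08,
                         missing_logit = list(intercept_cost = -4.8,
                                              intercept_eq5d = -3.2,
                                              treat = 0.1, duration = 0.05,
                                              age = 0.02, size = 0.01,
                                              site = c(0, 0.2, -0.2, 0.1, -0.1),
                                              time_years = 0.3),
                         death_rate = 0,
                         discount_rate = 0.035,
                         seed = NULL) {
  schedule <- default_schedule()
  if (is.null(eq5d_effects)) {
    # trapezium weight of a constant post-baseline utility shift over 3y:
    # 0.5*6/52 + 20/52 + 26/52 + 1 + 1 = 153/52
    d <- true_dqaly_3y * 52 / 153
    wk <- schedule$eq5d_weeks[-1]
    eq5d_effects <- list(baseline_diff = 0,
                         delta = stats::setNames(rep(d, length(wk)),
                                                 as.character(wk)))
  }
  cfg <- list(n_patients = n_patients,
              recruit_window_months = recruit_window_months,
              study_end_month = study_end_month,
              arm_allocation = arm_allocation,
              cost_effects = cost_effects,
              eq5d_effects = eq5d_effects,
              covariate_effects = covariate_effects,
              site_effects = site_effects,
              n_sites = n_sites,
              cost_intercepts = cost_intercepts,
              eq5d_intercepts = eq5d_intercepts,
              subject_sd_cost = subject_sd_cost,
              subject_sd_eq5d = subject_sd_eq5d,
              resid_sd_cost = resid_sd_cost,
              resid_sd_eq5d = resid_sd_eq5d,
              missing_logit = missing_logit,
              death_rate = death_rate,
              discount_rate = discount_rate,
              seed = seed,
              # population centres used for covariate effects and the
              # missingness linear predictor
              centres = c(age = 67, size = 5, duration = 1.5),
              schedule = schedule)
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  np <- length(cfg$schedule$period_bounds) - 1L
  if (length(cfg$cost_effects) != np) {
    stop("cost_effects must have exactly ", np, " entries")
  }
  if (length(cfg$cost_intercepts) != np) {
    stop("cost_intercepts must have exactly ", np, " entries")
  }
  wk <- as.character(cfg$schedule$eq5d_weeks)
  if (!all(wk %in% names(cfg$eq5d_intercepts))) {
    stop("eq5d_intercepts must be named by the EQ-5D week grid")
  }
  if (!all(wk[-1] %in% names(cfg$eq5d_effects$delta))) {
    stop("eq5d_effects$delta must be indexed by the post-baseline weeks")
  }
  sds <- c(cfg$subject_sd_cost, cfg$subject_sd_eq5d,
           cfg$resid_sd_cost, cfg$resid_sd_eq5d)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$arm_allocation < 0 || cfg$arm_allocation > 1) {
    stop("arm_allocation must be a probability")
  }
  if (length(cfg$site_effects$cost) != cfg$n_sites ||
      length(cfg$site_effects$eq5d) != cfg$n_sites) {
    stop("site_effects must have one entry per site")
  }
  if (cfg$death_rate < 0 || cfg$discount_rate < 0) {
    stop("rates must be >= 0")
  }
  invisible(cfg)
}

ml_coef <- function(ml, name, default = 0) {
  v <- ml[[name]]
  if (is.null(v)) default else v
}

#' Generate a fully observed synthetic trial
#'
#' Draws baseline covariates, staggered recruitment (uniform over the
#' window), optional exponential death times, and complete cost and EQ-5D
#' trajectories from the configured linear model. Patients who die are
#' assigned zero costs and zero utility from the death week onwards.
#'
#' @param config a [trial_config()].
#' @return Object of class \code{trial_data}: a list with data.frames
#'   \code{baseline}, \code{costs} (one row per patient-period) and
#'   \code{eq5d} (one row per patient-week), the \code{schedule}, and the
#'   generating \code{config}. All \code{observed} flags are TRUE.
#'   Attributes \code{floor_rate} / \code{clamp_rate} record the fraction of
#'   costs floored at 0 and utilities clamped into [-0.594, 1].
#' @export
generate_complete <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  sch <- config$schedule
  ctr <- config$centres

  baseline <- data.frame(
    patient_id = seq_len(n),
    treat = stats::rbinom(n, 1, config$arm_allocation),
    age = pmin(pmax(round(stats::rnorm(n, ctr["age"], 13)), 18), 95),
    size = round(stats::rlnorm(n, log(ctr["size"]), 0.8), 1),
    duration = round(stats::rlnorm(n, log(ctr["duration"]), 0.9), 2),
    site = sample.int(config$n_sites, n, replace = TRUE),
    ethnicity = stats::rbinom(n, 1, 0.85),
    diabetes = stats::rbinom(n, 1, 0.12),
    dvt_history = stats::rbinom(n, 1, 0.15),
    trial_leg = stats::rbinom(n, 1, 0.5),
    recruit_month = stats::runif(n, 0, config$recruit_window_months)
  )
  baseline$censor_month <- config$study_end_month - baseline$recruit_month
  baseline$death_month <- NA_real_
  if (config$death_rate > 0) {
    tdeath <- stats::rexp(n, config$death_rate) * 12
    died <- tdeath < baseline$censor_month
    baseline$death_month[died] <- tdeath[died]
  }

  agec <- baseline$age - ctr["age"]
  sizec <- baseline$size - ctr["size"]
  durc <- baseline$duration - ctr["duration"]
  ce <- config$covariate_effects
  lp_cov_cost <- ce$cost["age"] * agec + ce$cost["size"] * sizec +
    ce$cost["duration"] * durc + config$site_effects$cost[baseline$site]
  lp_cov_eq5d <- ce$eq5d["age"] * agec + ce$eq5d["size"] * sizec +
    ce$eq5d["duration"] * durc + config$site_effects$eq5d[baseline$site]

  subj_c <- stats::rnorm(n, 0, config$subject_sd_cost)
  subj_e <- stats::rnorm(n, 0, config$subject_sd_eq5d)
  death_week <- baseline$death_month * 52 / 12

  b <- sch$period_bounds
  np <- length(b) - 1L
  costs <- expand.grid(patient_id = seq_len(n), period = seq_len(np))
  costs <- costs[order(costs$patient_id, costs$period), ]
  rownames(costs) <- NULL
  costs$week_start <- b[costs$period]
  costs$week_end <- b[costs$period + 1L]
  i <- costs$patient_id
  t <- costs$period
  mu <- config$cost_intercepts[t] + lp_cov_cost[i] +
    config$cost_effects[t] * baseline$treat[i] + subj_c[i]
  y <- mu + stats::rnorm(nrow(costs), 0, config$resid_sd_cost)
  floored <- y < 0
  y[floored] <- 0
  dead <- !is.na(death_week[i]) & costs$week_start >= death_week[i]
  y[dead] <- 0
  costs$cost <- y
  costs$observed <- TRUE
  costs$miss_design <- FALSE

  wk <- sch$eq5d_weeks
  eq5d <- expand.grid(patient_id = seq_len(n), week = wk)
  eq5d <- eq5d[order(eq5d$patient_id, eq5d$week), ]
  rownames(eq5d) <- NULL
  i <- eq5d$patient_id
  wname <- as.character(eq5d$week)
  # arm difference at week w is baseline_diff (w = 0) or delta_w (w > 0)
  treat_eff <- ifelse(eq5d$week == 0, config$eq5d_effects$baseline_diff,
                      config$eq5d_effects$delta[wname])
  mu <- config$eq5d_intercepts[wname] + lp_cov_eq5d[i] +
    treat_eff * baseline$treat[i] + subj_e[i]
  u <- mu + stats::rnorm(nrow(eq5d), 0, config$resid_sd_eq5d)
  clamped <- u < -0.594 | u > 1
  u <- pmin(pmax(u, -0.594), 1)
  dead <- !is.na(death_week[i]) & eq5d$week >= death_week[i]
  u[dead] <- 0
  eq5d$utility <- unname(u)
  eq5d$observed <- TRUE
  eq5d$miss_design <- FALSE

  out <- list(baseline = baseline, costs = costs, eq5d = eq5d,
              schedule = sch, config = config, shadow = NULL)
  class(out) <- "trial_data"
  attr(out, "floor_rate") <- mean(floored)
  attr(out, "clamp_rate") <- mean(clamped)
  out
}

#' Impose design-driven and MAR missingness on a complete trial
#'
#' Two layers, applied in order.
#' \emph{Structural} (deterministic given recruitment date): items whose
#' period/week closes after the patient's administrative censoring week are
#' missing by design; among post-year-1 EQ-5D weeks at most one is retained —
#' the latest grid week not exceeding the censoring week (the "telephone"
#' follow-up). \emph{Stochastic MAR}: every remaining item (except baseline
#' EQ-5D and post-death zeros) is set missing with probability
#' \code{plogis} of the configured linear predictor in treatment, centred
#' baseline covariates, site, time in years, and optionally the most recent
#' still-observed utility (an observed-outcome-dependent mechanism).
#'
#' The true complete tables are retained in the \code{shadow} element for
#' recovery testing; estimators only see the masked tables.
#'
#' @param data a complete \code{trial_data}.
#' @param config the generating [trial_config()] (supplies the logit).
#' @param seed seed for the stochastic layer; default derives one from
#'   \code{config$seed} when that is set.
#' @param telephone_rule apply the single-late-follow-up pruning (default
#'   TRUE).
#' @param layers which layers to apply: subset of
#'   \code{c("structural", "stochastic")}.
#' @return The masked \code{trial_data}; unobserved cells have value NA and
#'   \code{observed = FALSE}, design-driven ones additionally
#'   \code{miss_design = TRUE}.
#' @export
impose_missingness <- function(data, config = data$config, seed = NULL,
                               telephone_rule = TRUE,
                               layers = c("structural", "stochastic")) {
  stopifnot(inherits(data, "trial_data"))
  layers <- match.arg(layers, several.ok = TRUE)
  if (is.null(data$shadow)) {
    data$shadow <- list(costs = data$costs, eq5d = data$eq5d)
  }
  bl <- data$baseline
  censor_week <- bl$censor_month * 52 / 12
  death_week <- bl$death_month * 52 / 12
  ml <- config$missing_logit
  ctr <- config$centres

  if ("structural" %in% layers) {
    i <- data$costs$patient_id
    des <- data$costs$week_end > censor_week[i] &
      !(!is.na(death_week[i]) & data$costs$week_start >= death_week[i])
    data$costs$miss_design <- data$costs$miss_design | des
    data$costs$observed <- data$costs$observed & !des

    i <- data$eq5d$patient_id
    des <- data$eq5d$week > censor_week[i]
    if (telephone_rule) {
      late <- data$eq5d$week > 52
      # telephone week: latest grid week <= censoring week, per patient
      wk <- data$schedule$eq5d_weeks
      tel <- vapply(censor_week, function(cw) {
        ok <- wk[wk > 52 & wk <= cw]
        if (length(ok)) max(ok) else NA_integer_
      }, numeric(1))
      des <- des | (late & (is.na(tel[i]) | data$eq5d$week != tel[i]))
    }
    des <- des & !(!is.na(death_week[i]) & data$eq5d$week >= death_week[i])
    data$eq5d$miss_design <- data$eq5d$miss_design | des
    data$eq5d$observed <- data$eq5d$observed & !des
  }

  if ("stochastic" %in% layers) {
    if (is.null(seed) && !is.null(config$seed)) {
      seed <- (config$seed + 500009L) %% .Machine$integer.max
    }
    if (!is.null(seed)) set.seed(seed)
    lp_base <- ml_coef(ml, "treat") * bl$treat +
      ml_coef(ml, "duration") * (bl$duration - ctr["duration"]) +
      ml_coef(ml, "age") * (bl$age - ctr["age"]) +
      ml_coef(ml, "size") * (bl$size - ctr["size"]) +
      ml_coef(ml, "site", rep(0, config$n_sites))[bl$site]

    icost <- ml_coef(ml, "intercept_cost", ml_coef(ml, "intercept", -Inf))
    i <- data$costs$patient_id
    elig <- data$costs$observed &
      !(!is.na(death_week[i]) & data$costs$week_start >= death_week[i])
    lp <- icost + lp_base[i] +
      ml_coef(ml, "time_years") * data$costs$week_end / 52
    hit <- elig & stats::runif(nrow(data$costs)) < stats::plogis(lp)
    data$costs$observed[hit] <- FALSE

    ieq <- ml_coef(ml, "intercept_eq5d", ml_coef(ml, "intercept", -Inf))
    g_pu <- ml_coef(ml, "prev_utility")
    g_put <- ml_coef(ml, "prev_utility_treat")
    wk <- sort(unique(data$eq5d$week))
    # sequential sweep so the outcome-history term conditions only on
    # values still observed after earlier decisions (keeps the mechanism MAR)
    last_obs <- data$eq5d$utility[data$eq5d$week == 0]
    names(last_obs) <- data$eq5d$patient_id[data$eq5d$week == 0]
    for (w in wk[wk > 0]) {
      rows <- which(data$eq5d$week == w)
      i <- data$eq5d$patient_id[rows]
      elig <- data$eq5d$observed[rows] &
        !(!is.na(death_week[i]) & w >= death_week[i])
      uprev <- last_obs[as.character(i)] - 0.65
      uprev[is.na(uprev)] <- 0
      lp <- ieq + lp_base[i] + ml_coef(ml, "time_years") * w / 52 +
        g_pu * uprev + g_put * uprev * bl$treat[i]
      hit <- elig & stats::runif(length(rows)) < stats::plogis(lp)
      data$eq5d$observed[rows[hit]] <- FALSE
      now_obs <- data$eq5d$observed[rows]
      last_obs[as.character(i[now_obs])] <- data$eq5d$utility[rows[now_obs]]
    }
  }

  data$costs$cost[!data$costs$observed] <- NA_real_
  data$eq5d$utility[!data$eq5d$observed] <- NA_real_
  data
}

#' Generate a trial and impose its missingness in one call
#'
#' @inheritParams generate_complete
#' @param ... passed to [impose_missingness()].
#' @export
simulate_trial <- function(config, ...) {
  impose_missingness(generate_complete(config), config, ...)
}

#' Shadow truth of a masked trial
#'
#' Returns the complete (pre-masking) dataset retained by
#' [impose_missingness()], for recovery testing only.
#' @param data a masked \code{trial_data}.
#' @export
shadow_truth <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  if (is.null(data$shadow)) return(data)
  out <- data
  out$costs <- data$shadow$costs
  out$eq5d <- data$shadow$eq5d
  out$shadow <- NULL
  out
}

#' Write a trial dataset as delimited tables
#'
#' Writes \code{baseline.csv}, \code{costs_long.csv} and
#' \code{eq5d_long.csv} (comma-separated, header row, missing cells empty)
#' to a directory. The shadow truth is not written.
#' @param data a \code{trial_data}.
#' @param dir output directory (created if needed).
#' @export
write_trial <- function(data, dir) {
  stopifnot(inherits(data, "trial_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data$costs, file.path(dir, "costs_long.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data$eq5d, file.path(dir, "eq5d_long.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a trial dataset written by [write_trial()]
#' @param dir directory holding the three tables.
#' @return a \code{trial_data} (no shadow truth).
#' @export
read_trial <- function(dir) {
  baseline <- utils::read.csv(file.path(dir, "baseline.csv"))
  costs <- utils::read.csv(file.path(dir, "costs_long.csv"))
  eq5d <- utils::read.csv(file.path(dir, "eq5d_long.csv"))
  out <- list(baseline = baseline, costs = costs, eq5d = eq5d,
              schedule = default_schedule(), config = NULL, shadow = NULL)
  class(out) <- "trial_data"
  out
}
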