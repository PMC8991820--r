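#' Long-format panel for the repeated-measures models
#'
#' Assembles the unbalanced panel of observed items for one outcome. For the
#' cost outcome every patient additionally contributes a week-0 row with
#' value 0 (cost accrued before randomisation is zero by construction), so
#' the treatment-by-week interaction at week t is directly the incremental
#' cost in period t. For EQ-5D the week-0 row is the observed baseline
#' utility. Baseline covariates are centred at their sample means; site is a
#' factor; week is a factor with baseline (0) as reference.
#'
#' @param data a \code{trial_data}.
#' @param outcome \code{"cost"} or \code{"eq5d"}.
#' @return data.frame with columns \code{patient_id}, \code{y}, \code{week}
#'   (factor), \code{treat}, \code{duration}, \code{age}, \code{size},
#'   \code{site}.
#' @export
long_panel <- function(data, outcome = c("cost", "eq5d")) {
  stopifnot(inherits(data, "trial_data"))
  outcome <- match.arg(outcome)
  bl <- data$baseline
  if (outcome == "cost") {
    obs <- data$costs[data$costs$observed, ]
    df <- data.frame(patient_id = c(bl$patient_id, obs$patient_id),
                     week = c(rep(0L, nrow(bl)), obs$week_end),
                     y = c(rep(0, nrow(bl)), obs$cost))
    lev <- c(0L, data$schedule$period_bounds[-1])
  } else {
    obs <- data$eq5d[data$eq5d$observed, ]
    df <- data.frame(patient_id = obs$patient_id, week = obs$week,
                     y = obs$utility)
    lev <- data$schedule$eq5d_weeks
  }
  i <- match(df$patient_id, bl$patient_id)
  df$treat <- bl$treat[i]
  df$duration <- bl$duration[i] - mean(bl$duration)
  df$age <- bl$age[i] - mean(bl$age)
  df$size <- bl$size[i] - mean(bl$size)
  df$site <- factor(bl$site[i])
  df$week <- factor(df$week, levels = lev)
  df <- df[order(df$patient_id, as.integer(as.character(df$week))), ]
  rownames(df) <- NULL
  df
}

rm_formula <- function(df) {
  fml <- y ~ treat + duration + age + size + site + week + treat:week
  if (nlevels(droplevels(df$site)) < 2) {
    fml <- y ~ treat + duration + age + size + week + treat:week
  }
  fml
}

new_repeated_fit <- function(method, outcome, beta, vcov, subject_sd,
                             resid_sd, absorbed, schedule, n_obs, n_subj,
                             model = NULL) {
  out <- list(method = method, outcome = outcome, beta = beta, vcov = vcov,
              subject_sd = subject_sd, resid_sd = resid_sd,
              absorbed = absorbed, schedule = schedule, n_obs = n_obs,
              n_subj = n_subj, model = model)
  class(out) <- "repeated_fit"
  out
}

#' Random-intercept repeated-measures model (RMM)
#'
#' REML fit of the outcome on treatment, centred baseline covariates, site,
#' week (factor) and the treatment-by-week interaction, with a random
#' patient intercept. The interaction coefficients are the arm differences
#' at each week relative to baseline.
#'
#' @param data a \code{trial_data}.
#' @param outcome \code{"cost"} or \code{"eq5d"}.
#' @param reml use REML (default) or ML.
#' @return a \code{repeated_fit}: \code{beta} (fixed effects), \code{vcov},
#'   \code{subject_sd}, \code{resid_sd}, grouping sizes and the schedule.
#' @export
fit_rmm <- function(data, outcome = c("cost", "eq5d"), reml = TRUE) {
  outcome <- match.arg(outcome)
  df <- long_panel(data, outcome)
  df$week <- droplevels(df$week)
  fml <- update(rm_formula(df), . ~ . + (1 | patient_id))
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = df, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("failed to converge", msgs))) {
    stop("RMM fit failed to converge: ", paste(msgs, collapse = "; "))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_repeated_fit("rmm", outcome,
                   beta = lme4::fixef(fit),
                   vcov = as.matrix(stats::vcov(fit)),
                   subject_sd = vc$sdcor[vc$grp == "patient_id"],
                   resid_sd = vc$sdcor[vc$grp == "Residual"],
                   absorbed = character(),
                   schedule = data$schedule,
                   n_obs = nrow(df),
                   n_subj = length(unique(df$patient_id)),
                   model = fit)
}

#' Within (fixed-effects) repeated-measures model (RMFE)
#'
#' Subject-demeaned least squares: every column of the design and the
#' outcome are centred within patient, which absorbs the patient intercepts
#' and all time-invariant regressors (treatment main effect, covariates,
#' site). Week effects and the treatment-by-week interaction remain
#' estimable. The covariance matrix is cluster-robust by patient
#' (CR1 small-sample correction).
#'
#' @inheritParams fit_rmm
#' @return a \code{repeated_fit}; \code{absorbed} names the regressors
#'   removed by the within transform, whose coefficients are not estimable.
#' @export
fit_rmfe <- function(data, outcome = c("cost", "eq5d")) {
  outcome <- match.arg(outcome)
  df <- long_panel(data, outcome)
  df$week <- droplevels(df$week)
  X <- stats::model.matrix(rm_formula(df), df)
  id <- df$patient_id
  tab <- table(id)
  if (mean(tab == 1) > 0.5) {
    warning("majority of subjects have a single observation; ",
            "they contribute nothing to the within estimator")
  }
  gm <- function(v) stats::ave(v, id)
  Xd <- apply(X, 2, function(col) col - gm(col))
  yd <- df$y - gm(df$y)
  within_var <- apply(Xd, 2, function(col) sum(col^2))
  keep <- within_var > 1e-8 * nrow(Xd)
  absorbed <- colnames(X)[!keep]
  Xk <- Xd[, keep, drop = FALSE]
  # drop columns aliased after the within transform (e.g. an interaction
  # carried by a single sparsely observed week)
  qx <- qr(Xk)
  if (qx$rank < ncol(Xk)) {
    aliased <- colnames(Xk)[qx$pivot[-seq_len(qx$rank)]]
    absorbed <- c(absorbed, aliased)
    Xk <- Xk[, setdiff(colnames(Xk), aliased), drop = FALSE]
  }
  fit <- stats::lm(yd ~ Xk - 1)
  names(fit$coefficients) <- colnames(Xk)
  V <- sandwich::vcovCL(fit, cluster = id, type = "HC1")
  dimnames(V) <- list(colnames(Xk), colnames(Xk))
  beta <- stats::coef(fit)
  names(beta) <- colnames(Xk)
  # residual SD with df corrected for the absorbed patient means
  G <- length(tab)
  rdf <- nrow(Xk) - ncol(Xk) - G
  resid_sd <- if (rdf > 0) sqrt(sum(stats::resid(fit)^2) / rdf) else NA_real_
  new_repeated_fit("rmfe", outcome, beta = beta, vcov = V,
                   subject_sd = NA_real_, resid_sd = resid_sd,
                   absorbed = absorbed, schedule = data$schedule,
                   n_obs = nrow(df), n_subj = G, model = fit)
}

#' @export
print.repeated_fit <- function(x, ...) {
  cat(toupper(x$method), "fit of", x$outcome, ":", x$n_obs,
      "observations on", x$n_subj, "subjects\n")
  if (!is.na(x$subject_sd)) cat("subject SD:", signif(x$subject_sd, 4), " ")
  cat("residual SD:", signif(x$resid_sd, 4), "\n")
  if (length(x$absorbed)) {
    cat("absorbed (time-invariant):", paste(x$absorbed, collapse = ", "),
        "\n")
  }
  invisible(x)
}

# linear-combination estimate w'beta with variance w'Vw, over named
# coefficients; names absent from the fit (absorbed) get weight dropped
lincom <- function(fit, w) {
  nm <- intersect(names(w), names(fit$beta))
  est <- sum(w[nm] * fit$beta[nm])
  v <- fit$vcov[nm, nm, drop = FALSE]
  list(est = est, var = drop(w[nm] %*% v %*% w[nm]), se = NA)
}

#' Incremental total cost from a repeated-measures cost fit
#'
#' Adds up the treatment-by-period interaction coefficients over all periods
#' closing within the horizon, each discounted at the period midpoint;
#' the variance is the corresponding quadratic form of the coefficient
#' covariance.
#'
#' @param fit a \code{repeated_fit} on the cost outcome.
#' @param horizon horizon in years (1, 3 or 5).
#' @param rate annual discount rate.
#' @return list with \code{est} (GBP), \code{var}, \code{se}.
#' @export
incremental_cost_total <- function(fit, horizon, rate = 0.035) {
  stopifnot(inherits(fit, "repeated_fit"), fit$outcome == "cost")
  b <- fit$schedule$period_bounds
  idx <- which(b[-1] <= horizon * 52)
  wkend <- b[idx + 1]
  fitted_weeks <- sub("^treat:week", "",
                      grep("^treat:week", names(fit$beta), value = TRUE))
  if (!all(as.character(wkend) %in% fitted_weeks)) {
    stop("horizon extends beyond the fitted weeks")
  }
  w <- stats::setNames(discount_factor((b[idx] + b[idx + 1]) / 2, rate),
                       paste0("treat:week", wkend))
  out <- lincom(fit, w)
  out$se <- sqrt(out$var)
  out
}

#' Incremental total QALYs from a repeated-measures EQ-5D fit
#'
#' Trapezium-rule combination of the arm differences at each scheduled week:
#' the difference at week 0 is the treatment main effect and at week t the
#' main effect plus the interaction coefficient. For the within estimator
#' the main effect is absorbed and enters as 0 (randomisation guarantees
#' balance at baseline in expectation).
#'
#' @param fit a \code{repeated_fit} on the EQ-5D outcome.
#' @param horizon horizon in years.
#' @param rate annual discount rate applied to QALY segments (0 for
#'   undiscounted QALYs).
#' @return list with \code{est} (QALYs), \code{var}, \code{se}.
#' @export
incremental_qaly_total <- function(fit, horizon, rate = 0.035) {
  stopifnot(inherits(fit, "repeated_fit"), fit$outcome == "eq5d")
  wks <- fit$schedule$eq5d_weeks
  wks <- wks[wks <= horizon * 52]
  fitted_weeks <- sub("^treat:week", "",
                      grep("^treat:week", names(fit$beta), value = TRUE))
  if (!all(as.character(wks[wks > 0]) %in% fitted_weeks)) {
    stop("horizon extends beyond the fitted weeks")
  }
  a <- wks[-length(wks)]
  bwk <- wks[-1]
  segw <- 0.5 * (bwk - a) / 52 * discount_factor((a + bwk) / 2, rate)
  # trapezium weight of each grid point = sum of its half-segment weights
  ptw <- stats::setNames(numeric(length(wks)), as.character(wks))
  for (s in seq_along(segw)) {
    ptw[as.character(a[s])] <- ptw[as.character(a[s])] + segw[s]
    ptw[as.character(bwk[s])] <- ptw[as.character(bwk[s])] + segw[s]
  }
  w <- stats::setNames(ptw, ifelse(wks == 0, "treat",
                                   paste0("treat:week", wks)))
  # the main effect enters the arm difference at every week
  w["treat"] <- sum(ptw)
  out <- lincom(fit, w)
  out$se <- sqrt(out$var)
  out
}

#' Cluster bootstrap of incremental cost and QALYs
#'
#' Resamples patients with replacement, stratified by arm, refits the cost
#' and EQ-5D repeated-measures models on each replicate and returns the
#' paired incremental totals. Replicates whose fits fail (or fail to
#' converge) are logged and redrawn; more than 5 percent failures aborts.
#'
#' @param data a \code{trial_data}.
#' @param horizon horizon in years.
#' @param B number of bootstrap replicates (>= 100 for CEAC use; smaller
#'   values allowed for smoke checks).
#' @param seed integer seed.
#' @param method \code{"rmm"} or \code{"rmfe"}.
#' @param rate discount rate for costs.
#' @param qaly_rate discount rate for QALYs (defaults to \code{rate}).
#' @return a \code{B x 2} matrix with columns \code{delta_cost},
#'   \code{delta_qaly}; attribute \code{failures} counts redrawn replicates.
#' @export
bootstrap_cea <- function(data, horizon, B = 1000, seed = 1,
                          method = c("rmm", "rmfe"), rate = 0.035,
                          qaly_rate = rate) {
  stopifnot(inherits(data, "trial_data"))
  method <- match.arg(method)
  set.seed(seed)
  bl <- data$baseline
  ids_by_arm <- split(bl$patient_id, bl$treat)
  fitter <- if (method == "rmm") fit_rmm else fit_rmfe
  draws <- matrix(NA_real_, B, 2,
                  dimnames = list(NULL, c("delta_cost", "delta_qaly")))
  failures <- 0L
  max_fail <- ceiling(0.05 * B)
  b <- 1L
  while (b <= B) {
    ids <- unlist(lapply(ids_by_arm, function(v) {
      sample(v, length(v), replace = TRUE)
    }), use.names = FALSE)
    rs <- resample_trial(data, ids)
    res <- tryCatch({
      fc <- fitter(rs, "cost")
      fq <- fitter(rs, "eq5d")
      c(incremental_cost_total(fc, horizon, rate)$est,
        incremental_qaly_total(fq, horizon, qaly_rate)$est)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > max_fail) {
        stop("more than 5% of bootstrap replicates failed (",
             failures, " failures)")
      }
      next
    }
    draws[b, ] <- res
    b <- b + 1L
  }
  attr(draws, "failures") <- failures
  draws
}

# rebuild a trial_data from a resampled id vector, assigning fresh ids so
# duplicated patients are distinct clusters
resample_trial <- function(data, ids) {
  new_id <- seq_along(ids)
  bl <- data$baseline[match(ids, data$baseline$patient_id), ]
  bl$patient_id <- new_id
  rownames(bl) <- NULL
  take <- function(tab) {
    idx <- split(seq_len(nrow(tab)), tab$patient_id)
    rows <- idx[as.character(ids)]
    out <- tab[unlist(rows, use.names = FALSE), ]
    out$patient_id <- rep(new_id, lengths(rows))
    rownames(out) <- NULL
    out
  }
  out <- list(baseline = bl, costs = take(data$costs),
              eq5d = take(data$eq5d), schedule = data$schedule,
              config = data$config, shadow = NULL)
  class(out) <- "trial_data"
  out
}
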