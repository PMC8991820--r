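#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost incremental mean cost (GBP).
#' @param delta_qaly incremental mean QALYs.
#' @return list with \code{type} (\code{"ratio"}, \code{"dominant"} —
#'   cheaper and more effective, \code{"dominated"} — dearer and less
#'   effective, or \code{"undefined"} when the QALY difference is zero),
#'   \code{value} (GBP/QALY, NA unless a ratio) and \code{label} (printable).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    out <- list(type = "undefined", value = NA_real_, label = "undefined")
  } else if (delta_cost < 0 && delta_qaly > 0) {
    out <- list(type = "dominant", value = NA_real_, label = "Dominant")
  } else if (delta_cost > 0 && delta_qaly < 0) {
    out <- list(type = "dominated", value = NA_real_, label = "Dominated")
  } else {
    v <- delta_cost / delta_qaly
    out <- list(type = "ratio", value = v, label = format(round(v)))
  }
  out
}

#' Parametric cost-effectiveness acceptability curve
#'
#' Probability that the incremental net monetary benefit
#' \eqn{\lambda \Delta Q - \Delta C} is positive, under a bivariate normal
#' distribution of \eqn{(\Delta C, \Delta Q)}:
#' \eqn{\Phi((\lambda\mu_Q-\mu_C)/\sqrt{\lambda^2\sigma_Q^2
#' - 2\lambda\sigma_{CQ} + \sigma_C^2})}.
#'
#' @param delta length-2 vector (cost, qaly).
#' @param vcov 2 x 2 covariance of (cost, qaly).
#' @param lambda_grid willingness-to-pay thresholds (GBP/QALY).
#' @return numeric vector of probabilities along the grid; where the
#'   net-benefit variance is exactly zero the probability is 0/1 by the
#'   sign of the mean (0.5 at exactly zero).
#' @export
ceac_parametric <- function(delta, vcov,
                            lambda_grid = seq(0, 50000, by = 500)) {
  vcov <- as.matrix(vcov)
  ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) stop("vcov is not PSD")
  mu <- lambda_grid * delta[2] - delta[1]
  v <- lambda_grid^2 * vcov[2, 2] - 2 * lambda_grid * vcov[1, 2] +
    vcov[1, 1]
  v <- pmax(v, 0)
  out <- ifelse(v > 0, stats::pnorm(mu / sqrt(v)),
                ifelse(mu > 0, 1, ifelse(mu < 0, 0, 0.5)))
  out
}

#' Bootstrap cost-effectiveness acceptability curve
#'
#' Fraction of paired bootstrap draws with positive net monetary benefit at
#' each threshold.
#'
#' @param draws matrix of draws with columns (cost, qaly).
#' @inheritParams ceac_parametric
#' @export
ceac_bootstrap <- function(draws, lambda_grid = seq(0, 50000, by = 500)) {
  stopifnot(nrow(draws) >= 1)
  vapply(lambda_grid, function(l) {
    mean(l * draws[, 2] - draws[, 1] > 0)
  }, numeric(1))
}

# evaluate both repeated-measures incremental totals at several horizons
# from a single pair of fits
rm_point <- function(fit_cost, fit_eq5d, horizons, rate, qaly_rate) {
  t(vapply(horizons, function(h) {
    c(cost = incremental_cost_total(fit_cost, h, rate)$est,
      qaly = incremental_qaly_total(fit_eq5d, h, qaly_rate)$est)
  }, numeric(2)))
}

bootstrap_cea_multi <- function(data, horizons, B, seed, method, rate,
                                qaly_rate) {
  set.seed(seed)
  bl <- data$baseline
  ids_by_arm <- split(bl$patient_id, bl$treat)
  fitter <- if (method == "rmm") fit_rmm else fit_rmfe
  draws <- array(NA_real_, c(B, 2, length(horizons)),
                 dimnames = list(NULL, c("cost", "qaly"), horizons))
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
      rm_point(fc, fq, horizons, rate, qaly_rate)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > max_fail) {
        stop("more than 5% of bootstrap replicates failed")
      }
      next
    }
    draws[b, , ] <- t(res)
    b <- b + 1L
  }
  attr(draws, "failures") <- failures
  draws
}

summary_row <- function(method, horizon, n_used, delta, vcov_or_se,
                        ci, icer_label, ceac_thr) {
  data.frame(method = method, horizon = horizon, n_used = n_used,
             delta_cost = delta[1], cost_se = vcov_or_se[1],
             cost_ci_low = ci[1, 1], cost_ci_high = ci[1, 2],
             delta_qaly = delta[2], qaly_se = vcov_or_se[2],
             qaly_ci_low = ci[2, 1], qaly_ci_high = ci[2, 2],
             icer = icer_label, ceac_30k = ceac_thr,
             stringsAsFactors = FALSE)
}

normal_ci <- function(delta, se) {
  cbind(delta - 1.96 * se, delta + 1.96 * se)
}

#' Run and compare the missing-data strategies
#'
#' Runs each requested method at each horizon with seeds derived from one
#' master seed and returns a comparison table (incremental cost and QALYs
#' with SEs and 95\% CIs, ICER with dominance labels, CEAC value at the
#' reference threshold) plus the full CEAC curves. Parametric methods (CCA,
#' MI, BPA) get normal-theory CIs and parametric CEACs; the
#' repeated-measures methods get percentile bootstrap CIs and bootstrap
#' CEACs.
#'
#' @param data a \code{trial_data}.
#' @param horizons horizons in years (subset of 1, 3, 5).
#' @param methods subset of
#'   \code{c("rmm", "rmfe", "cca", "milr", "mipmm", "bpa")}.
#' @param seed master seed.
#' @param rate,qaly_rate discount rates.
#' @param B bootstrap replicates for rmm/rmfe.
#' @param mice_M,mice_cycles MI settings.
#' @param bpa_iterations,bpa_burnin MCMC length for the Bayesian model.
#' @param lambda_grid CEAC thresholds; \code{lambda_ref} the reported one.
#' @return list with \code{summary} (one row per method x horizon; a
#'   failed method is recorded with NA estimates and the error message in
#'   \code{note}), \code{ceac} (long data.frame: method, horizon, lambda,
#'   probability) and \code{config} (the run settings).
#' @export
compare_methods <- function(data, horizons = c(1, 3, 5),
                            methods = c("rmm", "rmfe", "cca", "milr",
                                        "mipmm", "bpa"),
                            seed = 1, rate = 0.035, qaly_rate = rate,
                            B = 1000, mice_M = 40, mice_cycles = 20,
                            bpa_iterations = 10000, bpa_burnin = 2000,
                            lambda_grid = seq(0, 50000, by = 500),
                            lambda_ref = 30000) {
  stopifnot(inherits(data, "trial_data"))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  ceacs <- list()
  notes <- character()
  lam_i <- which.min(abs(lambda_grid - lambda_ref))

  add <- function(row, curve, method, note = "") {
    row$note <- note
    rows[[length(rows) + 1]] <<- row
    if (!is.null(curve)) {
      ceacs[[length(ceacs) + 1]] <<- data.frame(
        method = method, horizon = row$horizon, lambda = lambda_grid,
        probability = curve)
    }
  }
  fail_row <- function(method, horizon, msg) {
    r <- summary_row(method, horizon, NA_integer_, c(NA, NA), c(NA, NA),
                     matrix(NA, 2, 2), NA_character_, NA_real_)
    add(r, NULL, method, note = msg)
  }

  for (m in c("rmm", "rmfe")) {
    if (!m %in% methods) next
    res <- tryCatch({
      fitter <- if (m == "rmm") fit_rmm else fit_rmfe
      fc <- fitter(data, "cost")
      fq <- fitter(data, "eq5d")
      pts <- rm_point(fc, fq, horizons, rate, qaly_rate)
      dr <- bootstrap_cea_multi(data, horizons, B,
                                seed + match(m, c("rmm", "rmfe")) * 101L,
                                m, rate, qaly_rate)
      list(pts = pts, dr = dr, n = fc$n_subj)
    }, error = function(e) e)
    for (hi in seq_along(horizons)) {
      if (inherits(res, "error")) {
        fail_row(m, horizons[hi], conditionMessage(res))
        next
      }
      d <- res$pts[hi, ]
      dh <- res$dr[, , hi]
      se <- apply(dh, 2, stats::sd)
      ci <- t(apply(dh, 2, stats::quantile, c(0.025, 0.975)))
      curve <- ceac_bootstrap(dh, lambda_grid)
      add(summary_row(m, horizons[hi], res$n, d, se, ci,
                      icer(d[1], d[2])$label, curve[lam_i]), curve, m)
    }
  }

  if ("cca" %in% methods) {
    for (h in horizons) {
      res <- tryCatch(cca_fit(data, h, rate, qaly_rate),
                      error = function(e) e)
      if (inherits(res, "error")) {
        fail_row("cca", h, conditionMessage(res))
        next
      }
      se <- sqrt(diag(res$delta_vcov))
      curve <- ceac_parametric(res$delta, res$delta_vcov, lambda_grid)
      add(summary_row("cca", h, res$n_used, res$delta, se,
                      normal_ci(res$delta, se),
                      icer(res$delta[1], res$delta[2])$label,
                      curve[lam_i]), curve, "cca")
    }
  }

  for (m in c("milr", "mipmm")) {
    if (!m %in% methods) next
    imput <- if (m == "milr") "linreg" else "pmm"
    cfg <- mice_config(M = mice_M, cycles = mice_cycles, imputer = imput,
                       seed = seed + 7919L *
                         match(m, c("milr", "mipmm")))
    completed <- tryCatch(mice_impute(data, cfg), error = function(e) e)
    for (h in horizons) {
      res <- if (inherits(completed, "error")) completed else tryCatch({
        fits <- lapply(completed, estimate_per_dataset, horizon = h,
                       rate = rate, qaly_rate = qaly_rate)
        rubin_pool(fits, nu_com = fits[[1]]$n_used -
                     length(fits[[1]]$xnames))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fail_row(m, h, conditionMessage(res))
        next
      }
      curve <- ceac_parametric(res$qbar, res$T, lambda_grid)
      add(summary_row(m, h, nrow(data$baseline), res$qbar, res$se,
                      cbind(res$ci_low, res$ci_high),
                      icer(res$qbar[1], res$qbar[2])$label,
                      curve[lam_i]), curve, m)
    }
  }

  if ("bpa" %in% methods) {
    for (h in horizons) {
      res <- tryCatch(
        bpa_fit(data, h,
                bpa_config(iterations = bpa_iterations,
                           burnin = bpa_burnin, seed = seed + 17L),
                rate, qaly_rate),
        error = function(e) e)
      if (inherits(res, "error")) {
        fail_row("bpa", h, conditionMessage(res))
        next
      }
      se <- sqrt(diag(res$delta_vcov))
      curve <- ceac_parametric(res$delta, res$delta_vcov, lambda_grid)
      add(summary_row("bpa", h, res$n_used, res$delta, se,
                      normal_ci(res$delta, se),
                      icer(res$delta[1], res$delta[2])$label,
                      curve[lam_i]), curve, "bpa")
    }
  }

  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary,
       ceac = if (length(ceacs)) do.call(rbind, ceacs) else NULL,
       config = list(horizons = horizons, methods = methods, seed = seed,
                     rate = rate, qaly_rate = qaly_rate, B = B,
                     mice_M = mice_M, mice_cycles = mice_cycles,
                     bpa_iterations = bpa_iterations,
                     bpa_burnin = bpa_burnin, lambda_ref = lambda_ref))
}
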