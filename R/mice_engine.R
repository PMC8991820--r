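#' Configuration for multiple imputation by chained equations
#'
#' @param M number of imputations (default 40).
#' @param cycles chained-equation sweeps per imputed dataset (default 20).
#' @param imputer \code{"linreg"} (proper Bayesian linear regression,
#'   posterior-predictive draws) or \code{"pmm"} (predictive mean matching).
#' @param k_donors donor-pool size for PMM (default 10).
#' @param predictors baseline columns used as imputation-model covariates;
#'   site expands to dummies, \code{"eq5d0"} means the observed week-0
#'   utility.
#' @param seed master seed; per-imputation seeds are
#'   \code{seed + m * 1009} so the M runs are independent and reproducible.
#' @export
mice_config <- function(M = 40, cycles = 20,
                        imputer = c("linreg", "pmm"), k_donors = 10,
                        predictors = c("treat", "age", "duration", "size",
                                       "site", "ethnicity", "diabetes",
                                       "dvt_history", "trial_leg", "eq5d0"),
                        seed = 1) {
  imputer <- match.arg(imputer)
  stopifnot(M >= 2, cycles >= 1, k_donors >= 1)
  structure(list(M = M, cycles = cycles, imputer = imputer,
                 k_donors = k_donors, predictors = predictors, seed = seed),
            class = "mice_config")
}

# wide layout: one row per patient, one column per longitudinal variable
# (each period cost, each post-baseline EQ-5D week), in schedule order
mice_wide <- function(data) {
  bl <- data$baseline
  ids <- bl$patient_id
  b <- data$schedule$period_bounds
  np <- length(b) - 1L
  wk <- data$schedule$eq5d_weeks
  vars <- rbind(
    data.frame(name = paste0("cost_p", seq_len(np)), type = "cost",
               index = seq_len(np), week = b[-1]),
    data.frame(name = paste0("eq5d_w", wk[wk > 0]), type = "eq5d",
               index = match(wk[wk > 0], wk), week = wk[wk > 0])
  )
  vars <- vars[order(vars$week, vars$type), ]
  rownames(vars) <- NULL
  Y <- matrix(NA_real_, length(ids), nrow(vars),
              dimnames = list(ids, vars$name))
  obs <- matrix(FALSE, length(ids), nrow(vars),
                dimnames = list(ids, vars$name))
  cc <- data$costs
  ri <- match(cc$patient_id, ids)
  ci <- match(paste0("cost_p", cc$period), vars$name)
  Y[cbind(ri, ci)] <- cc$cost
  obs[cbind(ri, ci)] <- cc$observed
  ee <- data$eq5d[data$eq5d$week > 0, ]
  ri <- match(ee$patient_id, ids)
  ci <- match(paste0("eq5d_w", ee$week), vars$name)
  Y[cbind(ri, ci)] <- ee$utility
  obs[cbind(ri, ci)] <- ee$observed
  Y[!obs] <- NA_real_
  list(Y = Y, obs = obs, vars = vars, ids = ids)
}

mice_baseline_design <- function(data, predictors) {
  bl <- data$baseline
  cols <- list()
  for (p in predictors) {
    if (p == "eq5d0") {
      cols$eq5d0 <- baseline_eq5d0(data)
    } else if (p == "site") {
      mm <- stats::model.matrix(~ factor(site), bl)[, -1, drop = FALSE]
      for (j in seq_len(ncol(mm))) cols[[paste0("site", j + 1)]] <- mm[, j]
    } else if (p %in% names(bl)) {
      cols[[p]] <- bl[[p]]
    }
  }
  do.call(cbind, cols)
}

# proper Bayesian linear-regression draw: residual variance from its scaled
# inverse-chi-square posterior, coefficients from their conditional normal
bayes_lm_draw <- function(y, X) {
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  Xk <- X[, keep, drop = FALSE]
  qx <- qr(Xk)
  beta_hat <- qr.coef(qx, y)
  res <- y - Xk %*% beta_hat
  df <- length(y) - ncol(Xk)
  if (df <= 0) stop("imputation model has no residual degrees of freedom")
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qx)
  z <- stats::rnorm(ncol(Xk))
  beta_draw <- beta_hat + sqrt(sigma2) * backsolve(R, z)
  list(keep = keep, beta_hat = beta_hat, beta_draw = beta_draw,
       sigma = sqrt(sigma2))
}

#' Predictive-mean-matching draw for one incomplete variable
#'
#' Type-2 matching: predictions for the incomplete cases use a Bayesian
#' posterior draw of the regression coefficients, predictions for the
#' observed cases use the least-squares fit; each incomplete case receives
#' the observed value of one donor drawn uniformly from the \code{k}
#' observed cases nearest in predicted value (ties at the k-th distance are
#' all included).
#'
#' @param y_obs observed values of the target variable.
#' @param X_obs,X_mis design rows for observed and incomplete cases.
#' @param k donor-pool size.
#' @return numeric vector of imputed values, one per row of \code{X_mis};
#'   every value is a member of \code{y_obs}.
#' @export
pmm_impute <- function(y_obs, X_obs, X_mis, k = 10) {
  if (length(y_obs) < k) stop("need at least k observed cases")
  d <- bayes_lm_draw(y_obs, X_obs)
  pred_obs <- drop(X_obs[, d$keep, drop = FALSE] %*% d$beta_hat)
  pred_mis <- drop(X_mis[, d$keep, drop = FALSE] %*% d$beta_draw)
  vapply(pred_mis, function(p) {
    dist <- abs(pred_obs - p)
    kth <- sort(dist, partial = k)[k]
    pool <- which(dist <= kth + 1e-12)
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

run_one_imputation <- function(wide, P, cfg) {
  Y <- wide$Y
  obs <- wide$obs
  incomplete <- colnames(Y)[colSums(!obs) > 0]
  for (v in incomplete) {
    n_obs <- sum(obs[, v])
    if (n_obs < max(20, cfg$k_donors + 5)) {
      stop("too few observed cases (", n_obs, ") to impute ", v)
    }
  }
  # initial fill: simple random sampling with replacement from observed
  for (v in incomplete) {
    mis <- !obs[, v]
    Y[mis, v] <- sample(Y[obs[, v], v], sum(mis), replace = TRUE)
  }
  vars <- wide$vars
  for (cycle in seq_len(cfg$cycles)) {
    for (v in incomplete) {
      mis <- !obs[, v]
      others <- setdiff(colnames(Y), v)
      # a sparsely observed target cannot support the full design: keep the
      # baseline predictors and the longitudinal variables nearest in time
      # until a comfortable residual df remains
      budget <- sum(obs[, v]) - 10L - 1L - ncol(P)
      if (budget < length(others)) {
        dw <- abs(vars$week[match(others, vars$name)] -
                    vars$week[vars$name == v])
        others <- others[order(dw)][seq_len(max(budget, 2L))]
      }
      X <- cbind(`(Intercept)` = 1, Y[, others, drop = FALSE], P)
      if (cfg$imputer == "pmm") {
        Y[mis, v] <- pmm_impute(Y[obs[, v], v],
                                X[obs[, v], , drop = FALSE],
                                X[mis, , drop = FALSE], cfg$k_donors)
      } else {
        d <- bayes_lm_draw(Y[obs[, v], v], X[obs[, v], , drop = FALSE])
        mu <- drop(X[mis, d$keep, drop = FALSE] %*% d$beta_draw)
        Y[mis, v] <- mu + stats::rnorm(sum(mis), 0, d$sigma)
      }
    }
  }
  Y
}

fill_trial <- function(data, wide, Y) {
  out <- data
  cc <- out$costs
  key <- paste0("cost_p", cc$period)
  ri <- match(cc$patient_id, wide$ids)
  vals <- Y[cbind(ri, match(key, colnames(Y)))]
  imput <- !cc$observed
  cc$cost[imput] <- vals[imput]
  cc$imputed <- imput
  cc$observed <- TRUE
  out$costs <- cc
  ee <- out$eq5d
  late <- ee$week > 0
  key <- paste0("eq5d_w", ee$week[late])
  ri <- match(ee$patient_id[late], wide$ids)
  vals <- Y[cbind(ri, match(key, colnames(Y)))]
  imput <- !ee$observed
  ee$utility[late][imput[late]] <- vals[imput[late]]
  ee$imputed <- imput
  ee$observed <- TRUE
  out$eq5d <- ee
  out$shadow <- data$shadow
  out
}

#' Multiple imputation by chained equations
#'
#' Imputes every missing period cost and EQ-5D value. Variables are visited
#' in schedule order (earliest first); within each of \code{cycles} sweeps,
#' each incomplete variable is regressed on all other longitudinal variables
#' (current filled-in values) plus the configured baseline predictors, and
#' its missing entries are replaced by proper posterior-predictive draws
#' (linreg) or donor values (PMM). Design-driven missing cells (beyond a
#' patient's follow-up) are imputed too: that is how imputation-based
#' analyses recover horizons beyond individual follow-up. Observed cells
#' are never altered.
#'
#' @param data a \code{trial_data} with missingness.
#' @param cfg a [mice_config()].
#' @return list of M completed \code{trial_data} objects; imputed cells are
#'   flagged in an \code{imputed} column.
#' @export
mice_impute <- function(data, cfg = mice_config()) {
  stopifnot(inherits(data, "trial_data"), inherits(cfg, "mice_config"))
  wide <- mice_wide(data)
  P <- mice_baseline_design(data, cfg$predictors)
  lapply(seq_len(cfg$M), function(m) {
    set.seed((cfg$seed + m * 1009L) %% .Machine$integer.max)
    Y <- run_one_imputation(wide, P, cfg)
    fill_trial(data, wide, Y)
  })
}

#' Bivariate estimate from one completed dataset
#'
#' Passive totals ([assemble_aggregate()]) followed by the shared-regressor
#' bivariate regression on all patients.
#'
#' @param completed a completed \code{trial_data} from [mice_impute()].
#' @param horizon horizon in years.
#' @param rate,qaly_rate discount rates.
#' @return a \code{fit_result}.
#' @export
estimate_per_dataset <- function(completed, horizon, rate = 0.035,
                                 qaly_rate = rate) {
  agg <- assemble_aggregate(completed, horizon, rate, qaly_rate)
  bivariate_fit(agg, completed$baseline, baseline_eq5d0(completed),
                drop_incomplete = FALSE)
}

#' Pool M estimates by Rubin's rules
#'
#' Combines M per-imputation estimates: the pooled point estimate is the
#' mean, the total variance is the within-imputation variance plus
#' \eqn{(1 + 1/M)} times the between-imputation variance, degrees of
#' freedom follow Barnard--Rubin, and per-coefficient diagnostics are the
#' fraction of missing information (FMI), the Monte-Carlo error of the
#' pooled estimate \eqn{\sqrt{B/M}}, and the relative efficiency deficit
#' FMI/M.
#'
#' @param estimates either a list of \code{fit_result} objects (their
#'   \code{delta} / \code{delta_vcov} are pooled) or a list of numeric
#'   vectors.
#' @param variances when \code{estimates} are plain vectors: list of
#'   matching covariance matrices (or variance scalars).
#' @param nu_com complete-data degrees of freedom for the Barnard--Rubin
#'   small-sample adjustment; \code{Inf} (default) gives the classic
#'   large-sample df.
#' @return object of class \code{pooled_estimate}: \code{qbar}, matrices
#'   \code{W}, \code{B}, \code{T}, and per-coefficient \code{se},
#'   \code{df}, \code{fmi}, \code{mce}, \code{efficiency_loss},
#'   \code{ci_low}, \code{ci_high}, \code{M}.
#' @export
rubin_pool <- function(estimates, variances = NULL, nu_com = Inf) {
  M <- length(estimates)
  if (M < 2) stop("need at least M = 2 estimates to pool")
  if (inherits(estimates[[1]], "fit_result")) {
    variances <- lapply(estimates, `[[`, "delta_vcov")
    estimates <- lapply(estimates, `[[`, "delta")
  }
  Q <- do.call(rbind, lapply(estimates, as.numeric))
  colnames(Q) <- names(estimates[[1]])
  p <- ncol(Q)
  Vs <- lapply(variances, function(v) {
    v <- as.matrix(v)
    if (!isTRUE(all.equal(dim(v), c(p, p)))) {
      if (length(v) == p) v <- diag(as.numeric(v), p) else
        stop("non-conformable variance for pooling")
    }
    v
  })
  qbar <- colMeans(Q)
  W <- Reduce(`+`, Vs) / M
  B <- stats::cov(Q)
  Tm <- W + (1 + 1 / M) * B
  bjj <- diag(B)
  wjj <- diag(W)
  tjj <- diag(Tm)
  r <- (1 + 1 / M) * bjj / wjj
  lambda <- (1 + 1 / M) * bjj / tjj
  nu_old <- ifelse(lambda > 0, (M - 1) / lambda^2, Inf)
  if (is.finite(nu_com)) {
    nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    df <- nu_old * nu_obs / (nu_old + nu_obs)
  } else {
    df <- nu_old
  }
  fmi <- (r + 2 / (df + 3)) / (r + 1)
  se <- sqrt(tjj)
  tq <- ifelse(is.finite(df), stats::qt(0.975, df), stats::qnorm(0.975))
  out <- list(qbar = qbar, W = W, B = B, T = Tm, se = se, df = df,
              fmi = fmi, mce = sqrt(bjj / M), efficiency_loss = fmi / M,
              ci_low = qbar - tq * se, ci_high = qbar + tq * se, M = M)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat("Rubin-pooled estimate over M =", x$M, "imputations\n")
  print(round(cbind(estimate = x$qbar, se = x$se, ci_low = x$ci_low,
                    ci_high = x$ci_high, fmi = x$fmi, mce = x$mce), 5))
  invisible(x)
}

#' Full multiple-imputation analysis at a horizon
#'
#' Imputes, estimates the bivariate regression on each completed set, and
#' pools the incremental cost and QALY by Rubin's rules.
#'
#' @inheritParams mice_impute
#' @inheritParams estimate_per_dataset
#' @return list with \code{pooled} (a \code{pooled_estimate} over
#'   \code{(delta cost, delta QALY)}), \code{delta}, \code{delta_vcov}
#'   (the Rubin total-variance matrix), \code{fits} (per-imputation
#'   \code{fit_result}s), \code{n_used}.
#' @export
mi_fit <- function(data, horizon, cfg = mice_config(), rate = 0.035,
                   qaly_rate = rate) {
  completed <- mice_impute(data, cfg)
  fits <- lapply(completed, estimate_per_dataset, horizon = horizon,
                 rate = rate, qaly_rate = qaly_rate)
  pooled <- rubin_pool(fits, nu_com = fits[[1]]$n_used -
                         length(fits[[1]]$xnames))
  list(method = if (cfg$imputer == "pmm") "mipmm" else "milr",
       pooled = pooled, delta = pooled$qbar, delta_vcov = pooled$T,
       fits = fits, n_used = fits[[1]]$n_used, cfg = cfg)
}
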