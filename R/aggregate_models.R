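#' Design matrix for the aggregate-outcome regressions
#'
#' Intercept, baseline EQ-5D, treatment, centred duration/age/size and site
#' dummies — the regressor set shared by the cost and QALY equations.
#' @keywords internal
aggregate_design <- function(baseline, eq5d0, include_eq5d0 = TRUE) {
  df <- data.frame(
    eq5d0 = eq5d0 - mean(eq5d0),
    treat = baseline$treat,
    duration = baseline$duration - mean(baseline$duration),
    age = baseline$age - mean(baseline$age),
    size = baseline$size - mean(baseline$size),
    site = factor(baseline$site)
  )
  fml <- ~ eq5d0 + treat + duration + age + size + site
  if (!include_eq5d0) fml <- ~ treat + duration + age + size + site
  if (nlevels(droplevels(df$site)) < 2) fml <- update(fml, . ~ . - site)
  stats::model.matrix(fml, df)
}

baseline_eq5d0 <- function(data) {
  w0 <- data$eq5d[data$eq5d$week == 0, ]
  w0$utility[match(data$baseline$patient_id, w0$patient_id)]
}

#' Bivariate normal regression of total cost and total QALY
#'
#' Fits the aggregate-level model: each patient's discounted total cost and
#' total QALY regressed on baseline EQ-5D, treatment, duration, age, size
#' and site. Because both equations share the same regressors, the
#' seemingly-unrelated-regressions estimator reduces to per-equation least
#' squares; the joint covariance of all coefficients is the Kronecker
#' product of the residual covariance of (cost, QALY) with the shared
#' inverse Gram matrix. The treatment coefficients are the incremental mean
#' cost and QALY.
#'
#' @param outcomes aggregate-outcome table from [assemble_aggregate()].
#' @param baseline the baseline table of the same trial.
#' @param eq5d0 baseline utility per patient (same order as
#'   \code{baseline}); required unless \code{include_eq5d0 = FALSE}.
#' @param drop_incomplete drop patients with a missing total (complete-case
#'   behaviour); if FALSE, any missing total is an error.
#' @param include_eq5d0 include baseline EQ-5D as a covariate.
#' @return object of class \code{fit_result}: \code{coef} (p x 2 matrix,
#'   columns cost and qaly), \code{vcov} (2p x 2p, cost block first),
#'   \code{sigma} (2 x 2 residual covariance), \code{delta} = (dC, dQ),
#'   \code{delta_vcov} (2 x 2), \code{n_used}.
#' @export
bivariate_fit <- function(outcomes, baseline, eq5d0 = NULL,
                          drop_incomplete = FALSE, include_eq5d0 = TRUE) {
  stopifnot(nrow(outcomes) == nrow(baseline))
  if (include_eq5d0 && is.null(eq5d0)) {
    stop("eq5d0 is required when include_eq5d0 = TRUE")
  }
  complete <- outcomes$cost_complete & outcomes$qaly_complete
  if (drop_incomplete) {
    keep <- complete
  } else {
    if (!all(complete)) {
      stop("missing totals present; use drop_incomplete = TRUE or an ",
           "imputation-based method")
    }
    keep <- rep(TRUE, nrow(outcomes))
  }
  bl <- baseline[keep, , drop = FALSE]
  X <- aggregate_design(bl, if (include_eq5d0) eq5d0[keep] else rep(0, sum(keep)),
                        include_eq5d0)
  Y <- cbind(cost = outcomes$total_cost[keep],
             qaly = outcomes$total_qaly[keep])
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) stop("too few complete cases (", n, ") for ", p,
                      " regressors")
  qx <- qr(X)
  if (qx$rank < p) {
    stop("singular design; aliased columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))
  }
  B <- qr.coef(qx, Y)
  E <- Y - X %*% B
  sigma <- crossprod(E) / (n - p)
  XtXinv <- chol2inv(qr.R(qx))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  V <- kronecker(sigma, XtXinv,
                 make.dimnames = TRUE)
  ti <- which(colnames(X) == "treat")
  delta <- c(cost = unname(B[ti, "cost"]), qaly = unname(B[ti, "qaly"]))
  dv <- sigma * XtXinv[ti, ti]
  dimnames(dv) <- list(c("cost", "qaly"), c("cost", "qaly"))
  out <- list(method = if (drop_incomplete) "cca" else "bivariate",
              coef = B, vcov = V, sigma = sigma, n_used = n,
              delta = delta, delta_vcov = dv, xnames = colnames(X))
  class(out) <- "fit_result"
  out
}

#' Complete-case analysis at a horizon
#'
#' Assembles aggregate totals from a (possibly incomplete) trial dataset,
#' drops every patient with any missing period cost or EQ-5D value within
#' the horizon, and runs the bivariate regression on the remainder.
#'
#' @param data a \code{trial_data}.
#' @param horizon horizon in years.
#' @param rate discount rate for costs.
#' @param qaly_rate discount rate for QALYs (defaults to \code{rate}).
#' @return a \code{fit_result} with \code{n_used} the complete-case count.
#' @export
cca_fit <- function(data, horizon, rate = 0.035, qaly_rate = rate) {
  agg <- assemble_aggregate(data, horizon, rate, qaly_rate)
  bivariate_fit(agg, data$baseline, baseline_eq5d0(data),
                drop_incomplete = TRUE)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Bivariate outcome regression (", x$method, "), n = ", x$n_used,
      "\n", sep = "")
  cat(sprintf("  delta cost: %.2f (SE %.2f)\n", x$delta["cost"],
              sqrt(x$delta_vcov["cost", "cost"])))
  cat(sprintf("  delta QALY: %.4f (SE %.4f)\n", x$delta["qaly"],
              sqrt(x$delta_vcov["qaly", "qaly"])))
  invisible(x)
}

#' Configuration for the Bayesian selection model
#'
#' @param prior_precision normal-prior precision for the regression
#'   coefficients of the (standardized) outcome equations; the default
#'   0.001 is vague, and sensitivity analyses vary it up to 0.01.
#' @param chains number of MCMC chains (>= 2, for convergence diagnosis).
#' @param iterations post-burn-in iterations per chain.
#' @param burnin adaptation + burn-in iterations.
#' @param seed integer seed (per-chain RNG seeds are derived from it).
#' @param rhat_threshold split-chain potential-scale-reduction limit above
#'   which the fit errors out.
#' @param include_missingness_model also fit the logistic submodels of the
#'   missingness indicators (auxiliary models, with follow-up length as an
#'   extra covariate). Under MAR with distinct parameters these do not move
#'   the outcome posterior; the flag exists to verify that.
#' @export
bpa_config <- function(prior_precision = 0.001, chains = 2,
                       iterations = 10000, burnin = 2000, seed = 1,
                       rhat_threshold = 1.05,
                       include_missingness_model = TRUE) {
  stopifnot(chains >= 2, iterations > 0, burnin > 0)
  if (prior_precision > 1 || prior_precision <= 0) {
    warning("prior_precision outside the usual vague range (0, 1]")
  }
  structure(list(prior_precision = prior_precision, chains = chains,
                 iterations = iterations, burnin = burnin, seed = seed,
                 rhat_threshold = rhat_threshold,
                 include_missingness_model = include_missingness_model),
            class = "bpa_config")
}

bpa_model_string <- function(include_missingness_model) {
  core <- "
model {
  muC <- X %*% betaC
  muQ <- X %*% betaQ
  for (i in 1:N) {
    yC[i] ~ dnorm(muC[i], tauC)
    yQ[i] ~ dnorm(muQ[i] + lam * (yC[i] - muC[i]), tauQ)
  }
  for (j in 1:P) {
    betaC[j] ~ dnorm(0, prec_beta)
    betaQ[j] ~ dnorm(0, prec_beta)
  }
  lam ~ dnorm(0, 0.01)
  tauC ~ dgamma(0.01, 0.01)
  tauQ ~ dgamma(0.01, 0.01)
"
  aux <- "
  zC <- Z %*% gC
  zQ <- Z %*% gQ
  for (i in 1:N) {
    mC[i] ~ dbern(pC[i])
    logit(pC[i]) <- zC[i]
    mQ[i] ~ dbern(pQ[i])
    logit(pQ[i]) <- zQ[i]
  }
  for (j in 1:PZ) {
    gC[j] ~ dnorm(0, 0.1)
    gQ[j] ~ dnorm(0, 0.1)
  }
"
  paste0(core, if (include_missingness_model) aux else "", "\n}\n")
}

#' Bayesian selection model with missing totals as parameters
#'
#' Joint MCMC model of the aggregate outcomes and their missingness. Total
#' cost and total QALY follow the bivariate normal regression on the shared
#' Eq.-style regressor set; every unobserved total is a stochastic node
#' drawn from its conditional distribution given the observed partner
#' outcome, the covariates and the current parameters. Logistic submodels of
#' the missingness indicators (with follow-up length as an additional
#' covariate) complete the selection factorisation; under MAR with distinct
#' priors they leave the outcome posterior unchanged. Outcomes are
#' standardized internally, so coefficient priors are scale-free; estimates
#' are returned on the original scales.
#'
#' @param data a \code{trial_data}.
#' @param horizon horizon in years.
#' @param config a [bpa_config()].
#' @param rate,qaly_rate discount rates.
#' @return object of class \code{bpa_fit}: \code{delta} (posterior means of
#'   (dC, dQ)), \code{delta_vcov} (posterior covariance), \code{draws}
#'   (matrix of posterior draws, all chains pooled), \code{rhat},
#'   \code{n_used} (always all patients), \code{config}.
#' @export
bpa_fit <- function(data, horizon, config = bpa_config(), rate = 0.035,
                    qaly_rate = rate) {
  stopifnot(inherits(data, "trial_data"), inherits(config, "bpa_config"))
  agg <- assemble_aggregate(data, horizon, rate, qaly_rate)
  bl <- data$baseline
  X <- aggregate_design(bl, baseline_eq5d0(data))
  yC <- ifelse(agg$cost_complete, agg$total_cost, NA_real_)
  yQ <- ifelse(agg$qaly_complete, agg$total_qaly, NA_real_)
  mC <- as.integer(is.na(yC))
  mQ <- as.integer(is.na(yQ))
  sC <- stats::sd(yC, na.rm = TRUE)
  mCbar <- mean(yC, na.rm = TRUE)
  sQ <- stats::sd(yQ, na.rm = TRUE)
  mQbar <- mean(yQ, na.rm = TRUE)
  jd <- list(yC = (yC - mCbar) / sC, yQ = (yQ - mQbar) / sQ,
             X = X, N = nrow(X), P = ncol(X),
             prec_beta = config$prior_precision)
  if (config$include_missingness_model) {
    fy <- bl$censor_month / 12
    Z <- cbind(X, follow_years = fy - mean(fy))
    jd <- c(jd, list(mC = mC, mQ = mQ, Z = Z, PZ = ncol(Z)))
  }
  inits <- lapply(seq_len(config$chains), function(k) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (config$seed * 7 + k * 1013L) %% 2147483647L)
  })
  jm <- rjags::jags.model(
    textConnection(bpa_model_string(config$include_missingness_model)),
    data = jd, inits = inits, n.chains = config$chains, quiet = TRUE)
  update(jm, config$burnin, progress.bar = "none")
  ti <- which(colnames(X) == "treat")
  samp <- rjags::coda.samples(
    jm, c(paste0("betaC[", ti, "]"), paste0("betaQ[", ti, "]"), "lam"),
    n.iter = config$iterations, progress.bar = "none")
  gd <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
  rhat <- gd$psrf[, "Point est."]
  if (any(rhat > config$rhat_threshold, na.rm = TRUE)) {
    stop("MCMC not converged: max scale-reduction ",
         round(max(rhat, na.rm = TRUE), 3), "; trace means by chain: ",
         paste(round(sapply(samp, function(ch) mean(ch[, 1])), 3),
               collapse = ", "))
  }
  dm <- do.call(rbind, lapply(samp, as.matrix))
  draws <- cbind(cost = dm[, paste0("betaC[", ti, "]")] * sC,
                 qaly = dm[, paste0("betaQ[", ti, "]")] * sQ)
  out <- list(method = "bpa",
              delta = colMeans(draws),
              delta_vcov = stats::cov(draws),
              draws = draws,
              rhat = rhat,
              n_used = nrow(X),
              config = config)
  class(out) <- "bpa_fit"
  out
}

#' @export
print.bpa_fit <- function(x, ...) {
  cat("Bayesian selection model, n =", x$n_used, "\n")
  cat(sprintf("  delta cost: %.2f (post. SD %.2f)\n", x$delta["cost"],
              sqrt(x$delta_vcov["cost", "cost"])))
  cat(sprintf("  delta QALY: %.4f (post. SD %.4f)\n", x$delta["qaly"],
              sqrt(x$delta_vcov["qaly", "qaly"])))
  cat("  max Rhat:", round(max(x$rhat, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Conditional moments of one outcome given the observed partner
#'
#' For a bivariate normal (cost, QALY) with means \code{mu} and covariance
#' \code{sigma}, the distribution of the missing component given the
#' observed one is normal with mean
#' \eqn{\mu_1 + \sigma_{12}/\sigma_{22} (y_2 - \mu_2)} and variance
#' \eqn{\sigma_{11} - \sigma_{12}^2/\sigma_{22}}. This is the conditional
#' from which the selection model draws a missing total when its partner is
#' observed.
#'
#' @param mu length-2 mean vector (missing component first).
#' @param sigma 2 x 2 covariance (same ordering).
#' @param partner_value observed value of the second component.
#' @return list with \code{mean} and \code{var}.
#' @export
conditional_outcome_moments <- function(mu, sigma, partner_value) {
  stopifnot(length(mu) == 2, all(dim(sigma) == c(2, 2)))
  list(mean = mu[1] + sigma[1, 2] / sigma[2, 2] * (partner_value - mu[2]),
       var = sigma[1, 1] - sigma[1, 2]^2 / sigma[2, 2])
}
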