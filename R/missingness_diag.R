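#' Cross-tabulate aggregate missingness at a horizon
#'
#' The four-cell pattern of (cost, EQ-5D) completeness at the patient level:
#' complete/complete, complete cost with missing EQ-5D, missing cost with
#' complete EQ-5D, and both missing.
#'
#' @param outcomes an aggregate-outcome table from [assemble_aggregate()].
#' @return data.frame with columns \code{pattern}, \code{n}, \code{pct};
#'   counts sum to the number of patients and percentages to 100.
#' @export
pattern_table <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0) {
    stop("empty outcome table")
  }
  cc <- outcomes$cost_complete
  qc <- outcomes$qaly_complete
  n <- c(sum(cc & qc), sum(cc & !qc), sum(!cc & qc), sum(!cc & !qc))
  data.frame(
    pattern = c("complete cost, complete EQ-5D",
                "complete cost, missing EQ-5D",
                "missing cost, complete EQ-5D",
                "missing cost, missing EQ-5D"),
    n = n,
    pct = 100 * n / nrow(outcomes)
  )
}

#' Item-level logistic model of missingness
#'
#' Fits, by maximum likelihood, the probability that a scheduled cost or
#' EQ-5D item is missing as a logistic function of treatment, ulcer duration,
#' age, ulcer size (all centred at sample means), site (factor) and
#' assessment week (factor). Baseline EQ-5D (week 0) is excluded: baseline
#' data are never missing.
#'
#' @param data a \code{trial_data}.
#' @param target \code{"cost"} or \code{"eq5d"}: which item stream to model.
#' @param week_as_factor model week as a factor (default, as in the
#'   diagnostic regression) or as a linear term in years (useful when some
#'   weeks are all-missing by design).
#' @return object of class \code{missingness_fit}: list with \code{gamma}
#'   (coefficients), \code{se}, \code{wald} (z statistics), \code{fit}
#'   (the underlying glm), \code{converged}, and \code{separation} (TRUE
#'   when quasi-separation was detected).
#' @export
fit_missingness_logit <- function(data, target = c("cost", "eq5d"),
                                  week_as_factor = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  target <- match.arg(target)
  bl <- data$baseline
  if (target == "cost") {
    df <- data.frame(patient_id = data$costs$patient_id,
                     week = data$costs$week_end,
                     miss = !data$costs$observed)
  } else {
    keep <- data$eq5d$week > 0
    df <- data.frame(patient_id = data$eq5d$patient_id[keep],
                     week = data$eq5d$week[keep],
                     miss = !data$eq5d$observed[keep])
  }
  if (all(df$miss) || !any(df$miss)) {
    stop("need at least one missing and one observed item to fit the logit")
  }
  i <- match(df$patient_id, bl$patient_id)
  df$treat <- bl$treat[i]
  df$duration <- bl$duration[i] - mean(bl$duration)
  df$age <- bl$age[i] - mean(bl$age)
  df$size <- bl$size[i] - mean(bl$size)
  df$site <- factor(bl$site[i])
  df$weekv <- if (week_as_factor) factor(df$week) else df$week / 52

  fml <- miss ~ treat + duration + age + size + site + weekv
  if (nlevels(df$site) < 2) fml <- update(fml, . ~ . - site)
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  p <- stats::fitted(fit)
  separation <- any(p > 1 - 1e-8 | p < 1e-8) ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (separation) {
    warning("quasi-separation detected in the missingness logit; ",
            "coefficients reported but unreliable")
  }
  sm <- summary(fit)$coefficients
  out <- list(gamma = stats::coef(fit),
              se = sm[, "Std. Error"],
              wald = sm[, "z value"],
              fit = fit,
              converged = fit$converged,
              separation = separation,
              target = target)
  class(out) <- "missingness_fit"
  out
}

#' @export
print.missingness_fit <- function(x, ...) {
  cat("Item-level missingness logit (", x$target, ")\n", sep = "")
  print(round(cbind(estimate = x$gamma, se = x$se, z = x$wald), 4))
  if (x$separation) cat("NOTE: quasi-separation detected\n")
  invisible(x)
}
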