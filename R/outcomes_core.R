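#' Discount multiplier for an item observed at a given week
#'
#' Items are discounted by completed year at the interval midpoint:
#' the multiplier is \eqn{1/(1+r)^y} with \eqn{y = \lfloor w_{mid}/52 \rfloor},
#' so everything inside the first year is undiscounted and, e.g., a cost
#' accrued during year 2 is discounted by one full year.
#'
#' @param week_mid numeric vector of interval midpoints, in weeks from
#'   randomisation.
#' @param rate annual discount rate as a fraction (default 0.035).
#' @return numeric vector of multipliers in (0, 1].
#' @export
discount_factor <- function(week_mid, rate = 0.035) {
  stopifnot(rate >= 0)
  y <- floor(week_mid / 52)
  1 / (1 + rate)^y
}

#' Discounted total cost for one patient
#'
#' Sums discounted period costs over all periods closing within the horizon.
#' The total is \code{NA} (with the complete flag \code{FALSE}) if any
#' constituent period cost is missing — whether by design (follow-up ended
#' before the horizon) or item non-response: a cost total cannot skip a
#' period.
#'
#' @param costs numeric vector of period costs indexed by period (1..16);
#'   \code{NA} marks a missing period.
#' @param horizon time horizon in years (1, 3 or 5 on the default
#'   schedule).
#' @param rate annual discount rate.
#' @param schedule follow-up schedule, see [default_schedule()].
#' @return list with \code{total} (GBP or NA) and \code{complete} (logical).
#' @export
total_cost <- function(costs, horizon, rate = 0.035,
                       schedule = default_schedule()) {
  b <- schedule$period_bounds
  idx <- which(b[-1] <= horizon * 52)
  x <- costs[idx]
  if (anyNA(x)) {
    return(list(total = NA_real_, complete = FALSE))
  }
  mid <- (b[idx] + b[idx + 1]) / 2
  list(total = sum(x * discount_factor(mid, rate)), complete = TRUE)
}

#' Discounted QALYs by the trapezium rule
#'
#' The QALY total over a horizon is the area under the utility curve across
#' the patient's scheduled assessment weeks, taking utility linear between
#' consecutive points: a segment from week a to week b contributes
#' \eqn{0.5 (u_a + u_b) (b-a)/52}, optionally discounted at the segment
#' midpoint.
#'
#' The weeks supplied are the patient's own schedule (under the trial
#' design a patient is scheduled at weeks 0/6/26/52 plus at most one late
#' telephone week, so a late segment may span more than a year). The total
#' is computable only when the horizon week itself is one of the scheduled
#' weeks and every scheduled utility up to the horizon is observed;
#' otherwise the result is missing.
#'
#' @param utilities numeric vector of utility indices named by scheduled
#'   week (e.g. \code{c("0" = 0.5, "6" = 0.6, ...)}); \code{NA} marks a
#'   scheduled-but-missing value.
#' @param horizon time horizon in years; the horizon week is
#'   \code{52 * horizon}.
#' @param rate annual discount rate applied to QALYs (set 0 for a
#'   costs-only discounting convention).
#' @return list with \code{total} (QALYs or NA) and \code{complete}.
#' @export
qaly_trapezium <- function(utilities, horizon, rate = 0.035) {
  wks <- as.numeric(names(utilities))
  if (anyNA(wks)) stop("utilities must be named by week")
  o <- order(wks)
  wks <- wks[o]
  utilities <- utilities[o]
  hw <- horizon * 52
  keep <- wks <= hw
  if (!any(wks == hw) || anyNA(utilities[keep])) {
    return(list(total = NA_real_, complete = FALSE))
  }
  u <- utilities[keep]
  w <- wks[keep]
  a <- w[-length(w)]
  b <- w[-1]
  seg <- 0.5 * (u[-length(u)] + u[-1]) * (b - a) / 52
  disc <- discount_factor((a + b) / 2, rate)
  list(total = sum(seg * disc), complete = TRUE)
}

#' Per-patient aggregate outcomes at a horizon
#'
#' Applies [total_cost()] and [qaly_trapezium()] to every patient. A
#' patient's utility grid consists of the cells that are observed (including
#' imputed ones in a completed dataset) or scheduled-but-missing; cells that
#' are missing by design (after administrative censoring, or late weeks
#' pruned by the telephone rule) are not part of the grid. Items after a
#' patient's death are zero (assigned at generation), so death does not
#' create missingness.
#'
#' @param data a \code{trial_data} object, see [generate_complete()].
#' @param horizon time horizon in years (1, 3 or 5).
#' @param rate annual discount rate; applied to both costs and QALYs by
#'   default (set \code{qaly_rate = 0} to discount costs only).
#' @param qaly_rate discount rate for QALYs; defaults to \code{rate}.
#' @return A data.frame with one row per patient: \code{patient_id},
#'   \code{horizon}, \code{total_cost}, \code{total_qaly},
#'   \code{cost_complete}, \code{qaly_complete}.
#' @export
assemble_aggregate <- function(data, horizon, rate = 0.035,
                               qaly_rate = rate) {
  stopifnot(inherits(data, "trial_data"))
  horizon_week(horizon, data$schedule)
  schedule <- data$schedule
  ids <- data$baseline$patient_id
  b <- schedule$period_bounds
  np <- length(b) - 1L

  cost_m <- matrix(NA_real_, nrow = length(ids), ncol = np,
                   dimnames = list(ids, NULL))
  cc <- data$costs
  cost_m[cbind(match(cc$patient_id, ids), cc$period)] <-
    ifelse(cc$observed, cc$cost, NA_real_)

  wk <- schedule$eq5d_weeks
  ee <- data$eq5d
  u_m <- matrix(NA_real_, nrow = length(ids), ncol = length(wk),
                dimnames = list(ids, as.character(wk)))
  sched_m <- matrix(FALSE, nrow = length(ids), ncol = length(wk),
                    dimnames = list(ids, as.character(wk)))
  ri <- match(ee$patient_id, ids)
  ci <- match(ee$week, wk)
  u_m[cbind(ri, ci)] <- ifelse(ee$observed, ee$utility, NA_real_)
  des <- if (is.null(ee$miss_design)) rep(FALSE, nrow(ee)) else ee$miss_design
  sched_m[cbind(ri, ci)] <- ee$observed | !des

  out <- data.frame(patient_id = ids, horizon = horizon,
                    total_cost = NA_real_, total_qaly = NA_real_,
                    cost_complete = FALSE, qaly_complete = FALSE)
  for (i in seq_along(ids)) {
    tc <- total_cost(cost_m[i, ], horizon, rate, schedule)
    tq <- qaly_trapezium(u_m[i, sched_m[i, ]], horizon, qaly_rate)
    out$total_cost[i] <- tc$total
    out$cost_complete[i] <- tc$complete
    out$total_qaly[i] <- tq$total
    out$qaly_complete[i] <- tq$complete
  }
  out
}
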