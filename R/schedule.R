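#' Default follow-up schedule
#'
#' The assessment grid used throughout: costs are apportioned into 16 discrete
#' periods (12 approximately monthly periods over the first year, then yearly
#' periods up to year 5, i.e. week 260), and the EQ-5D utility index is
#' scheduled at baseline, 6 weeks, 6 months and 12 months, plus yearly grid
#' points (weeks 104--260) of which a patient contributes at most one late
#' "telephone" follow-up.
#'
#' @return A list with components \code{period_bounds} (integer vector of 17
#'   period boundary weeks, starting at 0), \code{eq5d_weeks} (integer vector
#'   of 8 scheduled utility weeks) and \code{horizon_weeks} (named vector
#'   mapping the supported horizons in years to their closing week).
#' @export
default_schedule <- function() {
  list(
    period_bounds = c(0L, 4L, 8L, 13L, 17L, 22L, 26L, 30L, 35L, 39L, 43L,
                      48L, 52L, 104L, 156L, 208L, 260L),
    eq5d_weeks = c(0L, 6L, 26L, 52L, 104L, 156L, 208L, 260L),
    horizon_weeks = c("1" = 52L, "3" = 156L, "5" = 260L)
  )
}

#' @keywords internal
horizon_week <- function(horizon, schedule = default_schedule()) {
  hw <- schedule$horizon_weeks[as.character(horizon)]
  if (is.na(hw)) {
    stop("horizon must be one of ", paste(names(schedule$horizon_weeks),
                                          collapse = ", "), " years")
  }
  unname(hw)
}

# periods whose closing boundary falls within the horizon
periods_in_horizon <- function(horizon, schedule = default_schedule()) {
  hw <- horizon_week(horizon, schedule)
  which(schedule$period_bounds[-1] <= hw)
}

eq5d_weeks_in_horizon <- function(horizon, schedule = default_schedule()) {
  hw <- horizon_week(horizon, schedule)
  schedule$eq5d_weeks[schedule$eq5d_weeks <= hw]
}
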