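# Irrigation: gravimetric field-capacity calibration, treatment watering
# schedules, water dispensing and the water-loss trait. Throughout,
# 1 g of added water is taken as 1 ml dispensed (density 1).

#' Default irrigation parameters
#'
#' Pot-weight anchors of the glasshouse protocol: all pots at 5200 g in
#' early growth, control raised to 5300 g (90% FC) from the initial
#' branching day onward, stress targets 4400 g (40% FC) and 4600 g
#' (50% FC), two-week holds, and recovery by 150 ml/day back to 5300 g.
#' `expected_daily_loss` (g/day) is the planning figure used to predict
#' how long the withholding drawdown takes, so hold windows can be placed
#' on a fixed calendar.
#'
#' @param early_weight,control_weight,stress_weight_40,stress_weight_50
#'   Target pot weights in g.
#' @param hold_days Stress-hold duration (days).
#' @param recovery_rate Recovery ramp rate (ml/day).
#' @param expected_daily_loss Planning evapotranspiration (g/day).
#' @param n_days Season length in days.
#' @return A named list.
#' @export
irrigation_params <- function(early_weight = 5200, control_weight = 5300,
                              stress_weight_40 = 4400, stress_weight_50 = 4600,
                              hold_days = 14, recovery_rate = 150,
                              expected_daily_loss = 180, n_days = 146) {
  list(early_weight = early_weight, control_weight = control_weight,
       stress_weight_40 = stress_weight_40, stress_weight_50 = stress_weight_50,
       hold_days = hold_days, recovery_rate = recovery_rate,
       expected_daily_loss = expected_daily_loss, n_days = n_days)
}

#' Pot weight at a field-capacity fraction
#'
#' Gravimetric calibration: pots are saturated and drained (wet weight),
#' then oven-dried (dry weight); the pot weight at a fraction `f` of field
#' capacity is `mean(dry) + f * (mean(wet) - mean(dry))`.
#'
#' @param cal A data frame with numeric columns `wet` and `dry` (one row
#'   per calibration pot; wet >= dry).
#' @param fraction Field-capacity fraction in \[0, 1\].
#' @return Pot weight in g.
#' @examples
#' cal <- data.frame(wet = rep(5000, 8), dry = rep(3000, 8))
#' field_capacity_weight(cal, 0.5) # 4000
#' @export
field_capacity_weight <- function(cal, fraction) {
  if (!is.data.frame(cal) || !nrow(cal) ||
      !all(c("wet", "dry") %in% names(cal))) {
    stop_invalid("`cal` must be a non-empty data frame with `wet` and `dry`")
  }
  if (any(cal$wet < cal$dry)) stop_invalid("wet weights must be >= dry weights")
  check_scalar_number(fraction, "fraction", min = 0, max = 1)
  mean(cal$dry) + fraction * (mean(cal$wet) - mean(cal$dry))
}

# One stress episode: drawdown (target at stress weight while the pot dries
# down), a fixed-length hold, then an arithmetic recovery ramp.
episode_phases <- function(start_day, stress_w, from_w, params) {
  drawdown <- ceiling((from_w - stress_w) / params$expected_daily_loss)
  ramp <- seq(stress_w + params$recovery_rate, params$control_weight,
              by = params$recovery_rate)
  if (!length(ramp) || ramp[length(ramp)] < params$control_weight) {
    ramp <- c(ramp, params$control_weight)  # final (possibly smaller) step
  }
  tibble(
    day = start_day + seq_len(drawdown + params$hold_days + length(ramp)) - 1,
    target = c(rep(stress_w, drawdown + params$hold_days), ramp),
    phase = c(rep("drawdown", drawdown), rep("hold", params$hold_days),
              rep("recovery", length(ramp)))
  )
}

#' Watering schedule for a treatment
#'
#' Builds the per-day target pot weights of one treatment: all pots at the
#' early-stage weight before the initial-branching day, control pots at
#' the control weight from then on; stress treatments withhold water until
#' the stress target, hold it for two weeks, then recover by
#' `recovery_rate` ml/day back to the control weight (the final step
#' clamps rather than overshoots). `IB50FL50` runs two such episodes, at
#' initial branching and at flowering.
#'
#' @param treatment One of `TREATMENTS`.
#' @param ib_day,fl_day Stage days (`ib_day < fl_day`).
#' @param params An [irrigation_params()] list.
#' @return A tibble of class `watering_plan`: `day`, `target` (g),
#'   `phase`, plus `treatment`, `ib_day`, `fl_day` attributes.
#' @export
treatment_schedule <- function(treatment, ib_day = 66, fl_day = 100,
                               params = irrigation_params()) {
  if (!treatment %in% TREATMENTS) {
    stop_invalid(paste("unknown treatment:", treatment))
  }
  if (ib_day >= fl_day) stop_invalid("`ib_day` must be < `fl_day`")
  plan <- tibble(
    day = seq_len(params$n_days),
    target = ifelse(seq_len(params$n_days) < ib_day,
                    params$early_weight, params$control_weight),
    phase = ifelse(seq_len(params$n_days) < ib_day, "early", "control")
  )
  episodes <- switch(treatment,
    C = list(),
    IB40 = list(list(start = ib_day, w = params$stress_weight_40)),
    FL40 = list(list(start = fl_day, w = params$stress_weight_40)),
    IB50FL50 = list(list(start = ib_day, w = params$stress_weight_50),
                    list(start = fl_day, w = params$stress_weight_50))
  )
  for (ep in episodes) {
    ph <- episode_phases(ep$start, ep$w, params$control_weight, params)
    ph <- ph[ph$day <= params$n_days, ]
    plan$target[ph$day] <- ph$target
    plan$phase[ph$day] <- ph$phase
  }
  structure(plan, class = c("watering_plan", class(plan)),
            treatment = treatment, ib_day = ib_day, fl_day = fl_day)
}

#' Water to dispense
#'
#' `max(0, target - current)` in ml (1 g = 1 ml): watering tops the pot up
#' to the target and never removes water (withholding = dispensing zero).
#'
#' @param current,target Pot weights in g (> 0).
#' @return Millilitres to add.
#' @export
water_to_add <- function(current, target) {
  if (any(current <= 0) || any(target <= 0)) {
    stop_invalid("weights must be positive")
  }
  pmax(0, target - current)
}

#' Simulate a pot-weight series under a watering plan
#'
#' Daily loop: the pot loses a stochastic daily amount (truncated normal,
#' `evap_model = list(mean, sd)`), is weighed (`before`), watered up to the
#' day's target (never beyond it), and weighed again (`after`). During
#' withholding phases no water is added until the pot reaches the stress
#' target.
#'
#' @param plan A [treatment_schedule()] plan.
#' @param evap_model List with `mean` and `sd` of daily water loss (g).
#' @param seed Integer seed.
#' @param start_weight Initial pot weight (default: day-1 target).
#' @return A tibble of class `pot_weight_series`: `day`, `target`,
#'   `before`, `after`, `water_added`.
#' @export
generate_pot_weight_series <- function(plan, evap_model = list(mean = 180, sd = 10),
                                       seed = 1, start_weight = NULL) {
  if (!nrow(plan)) stop_invalid("`plan` must be non-empty")
  if (evap_model$mean < 0 || evap_model$sd < 0) {
    stop_invalid("evaporation parameters must be non-negative")
  }
  n <- nrow(plan)
  start_weight <- start_weight %||% plan$target[1]
  with_seed(seed, {
    loss <- pmax(0, rnorm(n, evap_model$mean, evap_model$sd))
    before <- after <- added <- numeric(n)
    weight <- start_weight
    for (t in seq_len(n)) {
      before[t] <- if (t == 1) weight else after[t - 1] - loss[t]
      added[t] <- water_to_add(before[t], plan$target[t])
      after[t] <- before[t] + added[t]
    }
    structure(
      tibble(day = plan$day, target = plan$target,
             before = before, after = after, water_added = added),
      class = c("pot_weight_series", class(tibble())))
  })
}

#' Daily water loss from a pot-weight series
#'
#' The water-loss trait: `loss(t) = after(t-1) - before(t)`, i.e. the
#' weight lost between consecutive watering visits. The first day has no
#' predecessor and is absent from the output.
#'
#' @param series A [generate_pot_weight_series()] tibble (columns `day`,
#'   `before`, `after`), at least two days, chronological.
#' @return A tibble `(day, loss)` in g/day.
#' @export
compute_water_loss <- function(series) {
  if (nrow(series) < 2) stop_invalid("need at least two days")
  if (any(diff(series$day) <= 0)) stop_invalid("series must be chronological")
  tibble(day = series$day[-1],
         loss = series$after[-nrow(series)] - series$before[-1])
}
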