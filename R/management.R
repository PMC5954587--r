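# Management operations: irrigation scheduling, harvest, pruning, tillage.

#' Default management plan
#'
#' @return Named list: irrigation mode (`"none"`, `"auto"` or `"events"`),
#'   auto-rule interval (d) and fraction, irrigation season (day-of-year
#'   window), explicit `events` (data frame `date`, `mm`), wetted surface
#'   fraction, harvest day, pruning settings and tillage events.
#' @export
default_management <- function() {
  list(
    irrigation_mode = "none",
    irrigation_interval = 7,     # d, auto rule
    irrigation_fraction = 1.0,   # fraction of max-ET deficit replaced
    irrigation_season = c(91, 304), # DOY window for the auto rule
    irrigation_events = NULL,    # data.frame(date, mm)
    wetted_fraction = 0.1,
    harvest_doy = 349,
    pruning_interval = 0,        # years; 0 disables
    pruning_doy = 40,
    f_prune = 0.25,
    residue_fate = "incorporate", # or "export"
    tillage_events = NULL        # data.frame(doy, cn) or (doy, dcn)
  )
}

#' Irrigation depth for one day
#'
#' Explicit mode returns the depth listed for the date; auto mode returns
#' `fraction * max(0, deficit)` on interval days inside the irrigation
#' season, where the deficit accumulator tracks maximum ET minus effective
#' rainfall since the last irrigation.
#'
#' @param plan Management plan list.
#' @param date Current date (`Date`).
#' @param doy Day of year.
#' @param deficit Current ET-deficit accumulator (mm).
#' @param days_since_irr Days since the last irrigation.
#' @return List with `irr` (mm) and `reset` (should the accumulator reset?).
#' @export
schedule_irrigation <- function(plan, date, doy, deficit, days_since_irr) {
  mode <- plan$irrigation_mode
  if (mode == "none") return(list(irr = 0, reset = FALSE))
  if (mode == "events") {
    ev <- plan$irrigation_events
    if (is.null(ev)) return(list(irr = 0, reset = FALSE))
    if (any(ev$mm < 0)) stop("config error: negative irrigation depth")
    hit <- as.Date(ev$date) == date
    if (any(hit)) return(list(irr = sum(ev$mm[hit]), reset = TRUE))
    return(list(irr = 0, reset = FALSE))
  }
  if (mode == "auto") {
    in_season <- doy >= plan$irrigation_season[1] &&
      doy <= plan$irrigation_season[2]
    if (in_season && days_since_irr >= plan$irrigation_interval) {
      return(list(irr = plan$irrigation_fraction * max(0, deficit),
                  reset = TRUE))
    }
    return(list(irr = 0, reset = FALSE))
  }
  stop("config error: unknown irrigation mode '", mode, "'")
}

#' Harvest the fruit crop
#'
#' Removes the fruit biomass, reports dry and oil yield, and archives the
#' fruit-number record for next season's bearing recurrence.
#'
#' @param state A `tree_carbon`.
#' @param oil_ratio Oil content per unit fruit dry matter.
#' @return List with `y_dry`, `y_oil` (g m-2) and updated `state`.
#' @export
apply_harvest <- function(state, oil_ratio = 0.42) {
  y_dry <- state$fruits
  y_oil <- oil_ratio * y_dry
  state$fruits <- 0
  state$fn_prev <- state$fn
  state$fn <- 0
  list(y_dry = y_dry, y_oil = y_oil, state = state)
}

#' Prune the canopy
#'
#' Leaves, all shoot cohorts and branches are reduced by `f_prune`; the
#' removed biomass is either routed to the soil fresh pool or exported.
#'
#' @param state A `tree_carbon`.
#' @param f_prune Fraction removed (0-1).
#' @param residue_fate `"incorporate"` or `"export"`.
#' @return List with updated `state`, `residue_dm` (g DM m-2) and
#'   `incorporated` flag.
#' @export
apply_pruning <- function(state, f_prune, residue_fate = "incorporate") {
  if (f_prune < 0 || f_prune > 1) stop("config error: f_prune outside [0,1]")
  removed <- f_prune * (state$leaves + sum(state$shoots) + state$branches)
  state$leaves <- state$leaves * (1 - f_prune)
  state$shoots <- state$shoots * (1 - f_prune)
  state$branches <- state$branches * (1 - f_prune)
  list(state = state, residue_dm = removed,
       incorporated = identical(residue_fate, "incorporate"))
}

#' Apply a tillage event to a soil zone's curve number
#'
#' An event sets (`cn`) or offsets (`dcn`) the zone curve number; the
#' result is clamped to (0, 100] with a warning.
#'
#' @param zone A `soil_zone`.
#' @param event One-row list/data frame with `cn` or `dcn`.
#' @return Updated zone.
#' @export
apply_tillage <- function(zone, event) {
  cn <- if (!is.null(event$cn) && !is.na(event$cn)) event$cn
  else zone$cn + event$dcn
  if (cn > 100 || cn <= 0) {
    warning("tillage: CN ", round(cn, 1), " clamped into (0, 100]")
    cn <- min(100, max(1, cn))
  }
  zone$cn <- cn
  zone
}
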