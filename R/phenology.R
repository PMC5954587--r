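# Dormancy, chilling, budbreak, flowering and reproductive thermal time.

#' Default phenology parameters
#'
#' Chilling effectiveness is triangular (full credit at the optimum, zero
#' at the bounds); flowering follows a two-phase chilling/forcing scheme;
#' fruit growth onset and maturity are thermal-time thresholds.
#'
#' @return Named list of parameters.
#' @export
default_pheno_params <- function() {
  list(
    chill_t_min = 0,        # degC, lower bound of effectiveness
    chill_t_opt = 7,        # degC, optimum
    chill_t_max = 14,       # degC, upper bound
    chill_requirement = 45, # chill-day equivalents
    dormancy_start_doy = 305, # dormancy induction in autumn
    forcing_base = 9.1,     # degC, base for post-release forcing
    forcing_requirement = 450, # degCd to flowering
    budbreak_t_threshold = 10, # degC, 7-day trailing mean
    budbreak_window = 7,    # d
    fruit_onset_gdd = 150,  # degCd from flowering to fruit-growth onset
    maturity_gdd = 2400,    # degCd from flowering to maturity
    tt_base = 10            # degC, base for reproductive thermal time
  )
}

#' Initialise a phenology state
#' @param params Phenology parameter list.
#' @return List of class `pheno_state`.
#' @export
pheno_state <- function(params = default_pheno_params()) {
  structure(list(
    chill = 0, dormant = TRUE, growth_active = FALSE,
    flowering_doy = NA_integer_, forcing = 0, tt_flowering = 0,
    fruit_active = FALSE, mature = FALSE,
    temp_window = numeric(0), params = params
  ), class = "pheno_state")
}

# Triangular chilling effectiveness (0-1) of a temperature.
chill_effectiveness <- function(temp, p) {
  eff <- numeric(length(temp))
  up <- temp >= p$chill_t_min & temp <= p$chill_t_opt
  dn <- temp > p$chill_t_opt & temp <= p$chill_t_max
  eff[up] <- (temp[up] - p$chill_t_min) / (p$chill_t_opt - p$chill_t_min)
  eff[dn] <- (p$chill_t_max - temp[dn]) / (p$chill_t_max - p$chill_t_opt)
  eff
}

#' Accumulate chilling over the sub-daily steps of one day
#'
#' Each step contributes its effectiveness weighted by the step length in
#' days; a full day at the optimum adds one chill-day. Dormancy is released
#' when the accumulated units reach the requirement.
#'
#' @param state A `pheno_state`.
#' @param step_temps Sub-daily temperatures (degC).
#' @param step_dt Step lengths (h).
#' @return Updated state.
#' @export
accumulate_chilling <- function(state, step_temps, step_dt) {
  p <- state$params
  if (!state$dormant) return(state)
  state$chill <- state$chill +
    sum(chill_effectiveness(step_temps, p) * step_dt / 24)
  if (state$chill >= p$chill_requirement) state$dormant <- FALSE
  state
}

#' Advance phenology by one day
#'
#' Handles dormancy induction (autumn), chilling-release bookkeeping done in
#' [accumulate_chilling()], post-release forcing to flowering, budbreak
#' (trailing-mean temperature threshold), fruit-growth onset and maturity.
#'
#' @param state A `pheno_state`.
#' @param doy Day of year.
#' @param tmean Daily mean temperature (degC).
#' @param harvested Logical; a harvest event today forces fruit growth to
#'   cease.
#' @return Updated state.
#' @export
advance_phenology <- function(state, doy, tmean, harvested = FALSE) {
  p <- state$params
  # autumn dormancy induction resets the cycle
  if (doy == p$dormancy_start_doy) {
    state$dormant <- TRUE
    state$chill <- 0
    state$growth_active <- FALSE
    state$flowering_doy <- NA_integer_
    state$forcing <- 0
    state$mature <- FALSE
  }
  if (harvested) state$fruit_active <- FALSE
  state$temp_window <- c(utils::tail(state$temp_window,
                                     p$budbreak_window - 1), tmean)
  if (!state$dormant) {
    if (!state$growth_active &&
        mean(state$temp_window) > p$budbreak_t_threshold) {
      state$growth_active <- TRUE
    }
    if (is.na(state$flowering_doy)) {
      state$forcing <- state$forcing + max(0, tmean - p$forcing_base)
      if (state$forcing >= p$forcing_requirement) {
        state$flowering_doy <- doy
        state$tt_flowering <- 0
      }
    } else if (!state$mature) {
      state$tt_flowering <- state$tt_flowering + max(0, tmean - p$tt_base)
      if (!state$fruit_active && !harvested &&
          state$tt_flowering >= p$fruit_onset_gdd &&
          state$tt_flowering < p$maturity_gdd) {
        state$fruit_active <- TRUE
      }
      if (state$tt_flowering >= p$maturity_gdd) {
        state$mature <- TRUE
        state$fruit_active <- FALSE
      }
    }
  }
  state
}

#' Flowering date from a daily temperature series
#'
#' Two-phase model: phase 1 accumulates chilling (triangular effectiveness
#' of the daily mean) until the requirement is met; phase 2 accumulates
#' forcing degree-days above the base until the forcing requirement is
#' reached. Returns the day of year of flowering, or `NA` if never reached.
#'
#' @param tmean Daily mean temperatures for one season, starting at the
#'   dormancy induction date.
#' @param doys Day-of-year for each entry.
#' @param params Phenology parameter list.
#' @return Flowering day-of-year or `NA`.
#' @export
flowering_date <- function(tmean, doys, params = default_pheno_params()) {
  p <- params
  chill <- 0
  forcing <- 0
  released <- FALSE
  for (i in seq_along(tmean)) {
    if (!released) {
      chill <- chill + chill_effectiveness(tmean[i], p)
      if (chill >= p$chill_requirement) released <- TRUE
    } else {
      forcing <- forcing + max(0, tmean[i] - p$forcing_base)
      if (forcing >= p$forcing_requirement) return(doys[i])
    }
  }
  NA_integer_
}
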