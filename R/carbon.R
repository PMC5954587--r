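# Daily carbon economy: assimilate pool, respiration, fruit-priority
# allocation, alternate bearing, senescence, frost/heat damage, soil carbon.
#
# Units: biomass in g DM m-2 ground; substrate/assimilate pool in
# g CH2O m-2; carbon fluxes in g C m-2 d-1 (DM carries 0.45 g C g-1 by
# default, CH2O exactly 0.4 g C g-1).

C_PER_CH2O <- 12 / 30

#' Default growth, allocation and stress parameters
#' @return Named list (see source comments for units).
#' @export
default_growth_params <- function() {
  list(
    # partitioning of post-fruit substrate (sum to 1, incl. reserve share)
    part_leaf = 0.28, part_shoot = 0.12, part_branch = 0.16,
    part_coarse = 0.12, part_fine = 0.22, part_reserve = 0.10,
    # production values, g DM per g CH2O substrate
    pv_leaf = 0.69, pv_shoot = 0.69, pv_branch = 0.69,
    pv_coarse = 0.69, pv_fine = 0.72, pv_fruit = 0.60,
    # maintenance coefficients at 20 degC, g CH2O g-1 DM d-1
    km_leaf = 0.008, km_shoot = 0.002, km_branch = 0.0004,
    km_coarse = 0.0004, km_fine = 0.008, km_fruit = 0.003,
    q10_resp = 2, t_ref_resp = 20,
    # turnover (d-1)
    leaf_turnover = 0.0011, fine_turnover = 0.004,
    # morphology
    sla = 0.0055,           # m2 g-1
    srl = 12,               # m g-1
    dm_to_c = 0.45,         # g C g-1 DM
    # fruits and alternate bearing
    oil_ratio = 0.42,       # g oil g-1 fruit DM
    mean_fruit_mass = 0.8,  # g DM per fruit at maturity
    fruit_pot_rate = 4e-4,  # g DM fruit-1 degCd-1
    fruit_photo_coef = 0.0015, # g CH2O g-1 fruit DM d-1 while growing
    p_fruit_max = 0.6,      # source-limited cap on the fruit share of pool
    fn_a = 1.5,             # fruits per node (recurrence gain)
    fn_b = 0.9,             # negative feedback on previous fruit number
    nodes_per_g_shoot = 10, # nodes per g of new shoot DM
    # reserves
    remob_cap = 0.05,       # daily fraction of reserves available
    # stress
    frost_t_onset = -7, frost_t_full = -14,   # degC
    heat_t_threshold = 38, heat_reduction = 0.07, # per flowering-window day
    heat_window = 10        # days after flowering counted as the window
  )
}

#' Default soil carbon parameters (two-pool model)
#' @return Named list.
#' @export
default_soilc_params <- function() {
  list(
    k_fresh = 0.02,   # d-1 at reference temperature and moisture
    k_humus = 5e-5,   # d-1
    humification = 0.2, # fraction of fresh-pool decay routed to humus
    q10 = 2, t_ref = 20,
    init_fresh = 50, init_humus = 4000  # g C m-2
  )
}

#' Construct a tree carbon state
#'
#' @param leaves,branches,coarse_roots,fruits Biomass (g DM m-2 ground).
#' @param shoots Length-3 vector of shoot cohort biomass (ages 1-3 yr).
#' @param fine_roots Matrix (zones x layers) of fine-root biomass.
#' @param reserves Reserve pool (g CH2O m-2).
#' @param fn Fruit number (fruits m-2).
#' @param fn_prev,nodes_prev Previous-season records for the bearing
#'   recurrence.
#' @return List of class `tree_carbon`.
#' @export
tree_carbon_state <- function(leaves, shoots, branches, coarse_roots,
                              fine_roots, fruits = 0, reserves = 50,
                              fn = 0, fn_prev = 0, nodes_prev = 0) {
  stopifnot(length(shoots) == 3, all(shoots >= 0), leaves >= 0,
            branches >= 0, coarse_roots >= 0, all(fine_roots >= 0),
            fruits >= 0, reserves >= 0)
  structure(list(
    leaves = leaves, shoots = shoots, branches = branches,
    coarse_roots = coarse_roots, fine_roots = fine_roots,
    fruits = fruits, reserves = reserves,
    fn = fn, fn_prev = fn_prev, nodes_prev = nodes_prev,
    nodes_this_season = 0, heat_hits = 0
  ), class = "tree_carbon")
}

# total standing biomass (g DM m-2)
total_biomass <- function(state) {
  state$leaves + sum(state$shoots) + state$branches +
    state$coarse_roots + sum(state$fine_roots) + state$fruits
}

#' Maintenance respiration over one day
#'
#' Sum over organs and sub-daily steps of `km * biomass * Q10^((T-Tref)/10)`.
#'
#' @param state A `tree_carbon`.
#' @param step_temps Sub-daily temperatures (degC).
#' @param step_dt Step lengths (h).
#' @param params Growth parameter list.
#' @return Maintenance respiration (g CH2O m-2 d-1).
#' @export
maintenance_respiration <- function(state, step_temps, step_dt,
                                    params = default_growth_params()) {
  p <- params
  base <- p$km_leaf * state$leaves + p$km_shoot * sum(state$shoots) +
    p$km_branch * state$branches + p$km_coarse * state$coarse_roots +
    p$km_fine * sum(state$fine_roots) + p$km_fruit * state$fruits
  tfac <- sum(p$q10_resp^((step_temps - p$t_ref_resp) / 10) * step_dt) / 24
  base * tfac
}

#' Daily assimilate pool
#'
#' Pool = gross assimilation + fruit photosynthesis - maintenance
#' respiration; a negative balance is drawn from reserves (floored at 0,
#' leaving a starvation deficit with no growth).
#'
#' @param a_gross_ch2o Daily gross assimilation (g CH2O m-2).
#' @param state A `tree_carbon`.
#' @param resp_m Maintenance respiration (g CH2O m-2).
#' @param fruit_active Is fruit growth active (enables fruit
#'   photosynthesis)?
#' @param params Growth parameter list.
#' @return List with `pool` (g CH2O available for growth), `fruit_photo`,
#'   `reserve_draw`, `starved` flag and updated `state`.
#' @export
daily_assimilate_pool <- function(a_gross_ch2o, state, resp_m,
                                  fruit_active = FALSE,
                                  params = default_growth_params()) {
  p <- params
  fruit_photo <- if (fruit_active) p$fruit_photo_coef * state$fruits else 0
  balance <- a_gross_ch2o + fruit_photo - resp_m
  reserve_draw <- 0
  unpaid <- 0
  if (balance < 0) {
    reserve_draw <- min(-balance, state$reserves)
    state$reserves <- state$reserves - reserve_draw
    unpaid <- -balance - reserve_draw  # respiration demand the tree cannot meet
    balance <- 0
  }
  list(pool = balance, fruit_photo = fruit_photo,
       reserve_draw = reserve_draw, starved = unpaid > 0, unpaid = unpaid,
       state = state)
}

#' Fruit number from the previous season's records
#'
#' Linear recurrence `FN = max(0, a * nodes_prev - b * FN_prev)`, then
#' reduced multiplicatively for each day of the flowering window on which
#' the maximum temperature exceeded the heat threshold.
#'
#' @param fn_prev Previous-season fruit number (m-2).
#' @param nodes_prev Previous-season node production (m-2).
#' @param heat_days Number of hot days in the flowering window.
#' @param params Growth parameter list.
#' @return Fruit number (fruits m-2).
#' @export
determine_fruit_number <- function(fn_prev, nodes_prev, heat_days = 0,
                                   params = default_growth_params()) {
  p <- params
  fn <- max(0, p$fn_a * nodes_prev - p$fn_b * fn_prev)
  fn * max(0, 1 - p$heat_reduction)^heat_days
}

#' Allocate the daily assimilate pool to growth
#'
#' Fruits are the priority sink: their substrate demand (potential growth
#' over today's thermal time divided by the fruit production value) is met
#' up to a source-limited cap on the pool. The remainder is split by fixed
#' vegetative coefficients (including an explicit reserve share); during
#' vegetative rest, everything goes to reserves. Substrate is conserved:
#' sum(growth_i / PV_i) + surplus-to-reserves = pool.
#'
#' @param pool Available substrate (g CH2O m-2).
#' @param state A `tree_carbon`.
#' @param fn Fruit number (m-2).
#' @param dtt Today's reproductive thermal time increment (degCd).
#' @param growth_active Vegetative growth active?
#' @param fruit_active Fruit growth active?
#' @param params Growth parameter list.
#' @return List: `growth` (named organ DM increments), `resp_g` (g CH2O),
#'   `to_reserves` (g CH2O), `fruit_sink_limited` flag.
#' @export
allocate_growth <- function(pool, state, fn, dtt, growth_active,
                            fruit_active, params = default_growth_params()) {
  p <- params
  coefs <- c(leaf = p$part_leaf, shoot = p$part_shoot, branch = p$part_branch,
             coarse = p$part_coarse, fine = p$part_fine,
             reserve = p$part_reserve)
  if (sum(coefs) > 1 + 1e-9) stop("config error: partitioning sum > 1")
  growth <- c(leaf = 0, shoot = 0, branch = 0, coarse = 0, fine = 0, fruit = 0)
  resp_g <- 0
  to_reserves <- 0
  s_fruit <- 0
  sink_limited <- FALSE
  if (pool <= 0) {
    return(list(growth = growth, resp_g = 0, to_reserves = 0,
                fruit_sink_limited = FALSE))
  }
  if (fruit_active && fn > 0) {
    demand_dm <- fn * p$fruit_pot_rate * dtt
    demand_sub <- demand_dm / p$pv_fruit
    s_fruit <- min(demand_sub, p$p_fruit_max * pool)
    sink_limited <- s_fruit >= demand_sub - 1e-12
    growth["fruit"] <- s_fruit * p$pv_fruit
    resp_g <- resp_g + s_fruit * (1 - p$pv_fruit)
  }
  rest <- pool - s_fruit
  if (growth_active) {
    pv <- c(leaf = p$pv_leaf, shoot = p$pv_shoot, branch = p$pv_branch,
            coarse = p$pv_coarse, fine = p$pv_fine)
    sub <- rest * coefs[names(pv)]
    growth[names(pv)] <- sub * pv
    resp_g <- resp_g + sum(sub * (1 - pv))
    to_reserves <- rest * coefs["reserve"]
  } else {
    to_reserves <- rest
  }
  list(growth = growth, resp_g = resp_g,
       to_reserves = as.numeric(to_reserves),
       fruit_sink_limited = sink_limited)
}

#' First-order senescence of leaves and fine roots
#'
#' @param state A `tree_carbon`.
#' @param params Growth parameter list.
#' @return List with updated `state` and `litter` (named DM fluxes).
#' @export
senescence_turnover <- function(state, params = default_growth_params()) {
  p <- params
  leaf_litter <- p$leaf_turnover * state$leaves
  fine_litter_mat <- p$fine_turnover * state$fine_roots
  state$leaves <- state$leaves - leaf_litter
  state$fine_roots <- state$fine_roots - fine_litter_mat
  list(state = state,
       litter = c(leaf = leaf_litter, fine = sum(fine_litter_mat)))
}

#' Age shoot cohorts at the year boundary
#'
#' Cohorts age by one year; the cohort passing three years transfers its
#' biomass to branches. Woody biomass is conserved.
#'
#' @param state A `tree_carbon`.
#' @return Updated state.
#' @export
shoots_to_branches <- function(state) {
  state$branches <- state$branches + state$shoots[3]
  state$shoots <- c(0, state$shoots[1], state$shoots[2])
  state
}

#' Frost defoliation
#'
#' The defoliated fraction rises linearly from 0 at `frost_t_onset` to 1 at
#' `frost_t_full`.
#'
#' @param state A `tree_carbon`.
#' @param tmin Daily minimum temperature (degC).
#' @param params Growth parameter list.
#' @return List with updated `state` and `litter` (leaf DM).
#' @export
frost_defoliation <- function(state, tmin, params = default_growth_params()) {
  p <- params
  frac <- if (tmin >= p$frost_t_onset) 0
  else if (tmin <= p$frost_t_full) 1
  else (p$frost_t_onset - tmin) / (p$frost_t_onset - p$frost_t_full)
  litter <- frac * state$leaves
  state$leaves <- state$leaves - litter
  list(state = state, litter = litter, fraction = frac)
}

#' Distribute fine-root growth over zones and layers
#'
#' Layer weights are proportional to soil volume times a water-availability
#' factor `(theta - theta_ll) / (theta_ul - theta_ll)` clamped to [0, 1];
#' if all weights vanish, volume-only weights are used.
#'
#' @param increment Total fine-root DM increment (g m-2 ground).
#' @param zones List of `soil_zone` objects.
#' @return Matrix (zones x layers) of DM increments summing to `increment`.
#' @export
distribute_fine_root_growth <- function(increment, zones) {
  if (increment < 0) stop("validation error: negative increment")
  nl <- nrow(zones[[1]]$layers)
  vol <- matrix(0, length(zones), nl)
  avail <- matrix(0, length(zones), nl)
  for (zi in seq_along(zones)) {
    ly <- zones[[zi]]$layers
    vol[zi, ] <- zones[[zi]]$frac * ly$dz
    avail[zi, ] <- pmin(1, pmax(0, (ly$theta - ly$theta_ll) /
                                  (ly$theta_ul - ly$theta_ll)))
  }
  w <- vol * avail
  if (sum(w) <= 0) w <- vol
  w / sum(w) * increment
}

#' Root length density profile from fine-root biomass
#'
#' `Lv = biomass * SRL / soil volume`, converted to cm cm-3.
#'
#' @param fine_roots Matrix (zones x layers) of DM (g m-2 ground).
#' @param zones List of `soil_zone` objects.
#' @param srl Specific root length (m g-1).
#' @return Matrix (zones x layers) of Lv (cm cm-3).
#' @export
root_length_density <- function(fine_roots, zones, srl = 12) {
  nl <- nrow(zones[[1]]$layers)
  lv <- matrix(0, length(zones), nl)
  for (zi in seq_along(zones)) {
    ly <- zones[[zi]]$layers
    volume <- zones[[zi]]$frac * ly$dz          # m3 soil per m2 ground
    lv[zi, ] <- ifelse(volume > 0,
                       fine_roots[zi, ] * srl / volume / 1e4, 0)
  }
  lv
}

#' One day of the two-pool soil carbon balance
#'
#' First-order decomposition of the fresh-residue and humus pools, each
#' modified by a Q10 temperature factor and a moisture factor reduced
#' towards both dryness and saturation; a humification fraction of the
#' fresh-pool decay transfers to humus, the rest is heterotrophic
#' respiration. Carbon is conserved.
#'
#' @param pools List with `fresh` and `humus` (g C m-2).
#' @param litter_c Today's litter/residue input (g C m-2), to the fresh
#'   pool.
#' @param soil_temp Soil temperature (degC).
#' @param wetness Relative saturation theta/theta_sat (0-1).
#' @param params Soil carbon parameter list.
#' @return List with updated `pools` and `resp_h` (g C m-2 d-1).
#' @export
soil_carbon_step <- function(pools, litter_c, soil_temp, wetness,
                             params = default_soilc_params()) {
  p <- params
  ftemp <- p$q10^((soil_temp - p$t_ref) / 10)
  fmoist <- max(0.05, min(1, 4 * wetness * (1 - wetness)))
  pools$fresh <- pools$fresh + litter_c
  d_fresh <- min(pools$fresh, p$k_fresh * ftemp * fmoist * pools$fresh)
  d_humus <- min(pools$humus, p$k_humus * ftemp * fmoist * pools$humus)
  to_humus <- p$humification * d_fresh
  resp_h <- (d_fresh - to_humus) + d_humus
  pools$fresh <- pools$fresh - d_fresh
  pools$humus <- pools$humus + to_humus - d_humus
  list(pools = pools, resp_h = resp_h)
}

#' Ecosystem respiration and net ecosystem exchange
#'
#' `RESP_eco = RESP_M + RESP_g + RESP_H`; `NEE = RESP_eco - A` (positive =
#' carbon source to the atmosphere).
#'
#' @param a_gross_c Gross assimilation (g C m-2 d-1).
#' @param resp_m_c,resp_g_c,resp_h_c Respiration components (g C m-2 d-1).
#' @return List with `resp_eco` and `nee` (g C m-2 d-1).
#' @export
ecosystem_fluxes <- function(a_gross_c, resp_m_c, resp_g_c, resp_h_c) {
  resp_eco <- resp_m_c + resp_g_c + resp_h_c
  list(resp_eco = resp_eco, nee = resp_eco - a_gross_c)
}

#' Reserve remobilization for a demand surplus
#'
#' Remobilized substrate is the unmet demand, capped at a daily fraction of
#' the reserve pool.
#'
#' @param reserves Reserve pool (g CH2O m-2).
#' @param demand Substrate demand (g CH2O m-2 d-1).
#' @param supply Substrate already available (g CH2O m-2 d-1).
#' @param cap Daily remobilizable fraction of reserves.
#' @return Remobilized amount (g CH2O m-2 d-1).
#' @export
remobilize_reserves <- function(reserves, demand, supply, cap = 0.05) {
  min(cap * reserves, max(0, demand - supply))
}
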