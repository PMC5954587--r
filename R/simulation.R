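# Orchard state initialization, the daily loop across all process modules,
# and run-level orchestration with water and carbon closure audits.

#' Default simulation configuration
#'
#' Nested named list with every tunable parameter of the simulator:
#' site (latitude, CO2, sub-daily steps), orchard geometry and allometry,
#' soil profile and hydrology, SPAC and gas exchange, phenology, growth
#' and allocation, soil carbon, and management. Units are documented in
#' the block-level defaults functions.
#'
#' @return Configuration list.
#' @export
default_config <- function() {
  list(
    latitude = 37.8,
    n_steps = 24,
    co2 = 400,
    start_year = 2001,
    years = 3,
    spacing = c(7, 3.5),
    tree_height = 4,
    crown_base = 0.8,
    max_height = 6,
    init = list(
      gc = 0.30,
      lv = c(0.6, 0.5, 0.3, 0.1),  # cm cm-3 per layer (both zones)
      prior_ydry = 400,            # g DM m-2, year before simulation
      reserve_frac = 0.15          # initial reserves per unit leaf+shoot DM
    ),
    allometry = list(shoot_to_leaf = 0.35, branch_to_leaf = 2.2,
                     coarse_to_leaf = 1.1),
    soil = list(
      dz = c(0.2, 0.3, 0.5, 1.0),
      theta_ul = 0.23, theta_ll = 0.07, theta_sat = 0.42,
      theta_init = 0.23,
      shc = "fair",
      cn_table = c(poor = 86, fair = 80, good = 74),
      cn_gc_reduction = 10,
      swcon = 0.4, diff_coef = 0.05,
      u_stage1 = 9, alpha_soil = 3.5, airdry_frac = 0.5,
      microadvection = 1.3,
      albedo = 0.15,
      precip_partition = "equal_depth"
    ),
    canopy = list(
      sla = 0.0055, lad = 1.8, r_zx = 1.2,
      c_int = 0.4, g_fun = 0.5, scatter = 0.1,
      par_fraction = 0.45, ngrid = 12
    ),
    spac = default_spac_params(),
    pheno = default_pheno_params(),
    growth = default_growth_params(),
    soilc = default_soilc_params(),
    management = default_management(),
    kc_max_et = c(0.30, 0.55)  # maximum-ET crop coefficient: a + b * GC
  )
}

#' Read / write a configuration file (YAML)
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Initialize the orchard state
#'
#' Crown radii are inverted from the initial ground cover; leaf biomass
#' from crown volume, LAD and SLA; woody organs from allometric ratios;
#' fine roots from the initial root length density profile; the
#' fruit-number recurrence is seeded from the prior-year dry yield; and
#' phenology is pre-run on the preceding three months of temperatures.
#'
#' @param config Configuration list.
#' @param prerun_tmean Daily mean temperatures (degC) of the >= 90 days
#'   preceding January 1 of the start year.
#' @return Orchard state list.
#' @export
initialize_state <- function(config, prerun_tmean) {
  cf <- config
  if (missing(prerun_tmean) || is.null(prerun_tmean) ||
      length(prerun_tmean) < 90) {
    stop("initialization error: >= 90 days of pre-run temperatures required")
  }
  area_tree <- prod(cf$spacing)
  density <- 1 / area_tree
  gw <- cf$growth

  # geometry from initial ground cover
  a_h <- sqrt(cf$init$gc / (pi * density))
  if (a_h > min(cf$spacing) / 2 + 1e-9) {
    stop("geometry error: initial GC incompatible with tree spacing")
  }
  a_v <- cf$canopy$r_zx * a_h
  vol <- 4 / 3 * pi * a_h^2 * a_v
  lai <- vol * cf$canopy$lad * density
  leaves <- lai / gw$sla

  # soil zones
  wf <- cf$management$wetted_fraction
  nl <- length(cf$soil$dz)
  lv <- rep_len(cf$init$lv, nl)
  cn_base <- cf$soil$cn_table[[cf$soil$shc]]
  zones <- list(
    dry = soil_zone(1 - wf, cf$soil$dz, cf$soil$theta_init, cf$soil$theta_ul,
                    cf$soil$theta_ll, cf$soil$theta_sat, lv, cn_base),
    wet = soil_zone(wf, cf$soil$dz, cf$soil$theta_init, cf$soil$theta_ul,
                    cf$soil$theta_ll, cf$soil$theta_sat, lv, cn_base)
  )

  # fine roots inverted from Lv (mass = Lv * volume / SRL)
  fine <- matrix(0, 2, nl)
  for (zi in 1:2) {
    fine[zi, ] <- lv * 1e4 * cf$soil$dz * zones[[zi]]$frac / gw$srl
  }

  shoots_total <- cf$allometry$shoot_to_leaf * leaves
  fn_prev <- cf$init$prior_ydry / gw$mean_fruit_mass
  nodes_prev <- fn_prev * (1 + gw$fn_b) / gw$fn_a  # neutral recurrence seed
  carbon <- tree_carbon_state(
    leaves = leaves, shoots = rep(shoots_total / 3, 3),
    branches = cf$allometry$branch_to_leaf * leaves,
    coarse_roots = cf$allometry$coarse_to_leaf * leaves,
    fine_roots = fine,
    reserves = cf$init$reserve_frac * (leaves + shoots_total),
    fn = 0, fn_prev = fn_prev, nodes_prev = nodes_prev)

  geom <- update_crown_geometry(leaves, gw$sla, cf$canopy$lad, cf$canopy$r_zx,
                                cf$spacing, cf$crown_base, cf$max_height)

  # phenology pre-run on the preceding months
  pheno <- pheno_state(cf$pheno)
  npre <- length(prerun_tmean)
  doys <- as.integer(format(seq(as.Date(sprintf("%d-01-01", cf$start_year)) - npre,
                                by = "day", length.out = npre), "%j"))
  for (i in seq_len(npre)) {
    pheno <- advance_phenology(pheno, doys[i], prerun_tmean[i])
    pheno <- accumulate_chilling(pheno, prerun_tmean[i], 24)
  }

  list(
    zones = zones, carbon = carbon, geom = geom, pheno = pheno,
    canopy_store = 0,
    soilc = list(fresh = cf$soilc$init_fresh, humus = cf$soilc$init_humus),
    soil_temp = mean(utils::tail(prerun_tmean, 7)),
    et_deficit = 0, days_since_irr = 999,
    f_diff_cache = NULL, f_diff_lai = -1,
    pruning_year_counter = 0,
    harvested_today = FALSE
  )
}

# carbon stock of the whole system, g C m-2
.system_carbon <- function(state, dm_to_c) {
  total_biomass(state$carbon) * dm_to_c +
    state$carbon$reserves * C_PER_CH2O +
    state$soilc$fresh + state$soilc$humus
}

#' Advance the simulation by one day
#'
#' Fixed process order: weather disaggregation, phenology, management
#' events, canopy interception and wet-canopy evaporation, per-zone runoff
#' / infiltration / drainage, the diurnal SPAC + gas-exchange loop, soil
#' evaporation, the carbon economy, geometry and root updates, soil
#' carbon, and the closure audits.
#'
#' @param state Orchard state (from [initialize_state()]).
#' @param day One-row daily weather record.
#' @param config Configuration list.
#' @return List with updated `state` and a named numeric `output` vector.
#' @export
step_day <- function(state, day, config) {
  cf <- config
  gw <- cf$growth
  date <- as.Date(day$date)
  doy <- as.integer(format(date, "%j"))
  tmean <- (day$tmax + day$tmin) / 2
  dm_to_c <- gw$dm_to_c

  c_before <- .system_carbon(state, dm_to_c)
  s_before <- sum(vapply(state$zones, function(z) z$frac * zone_storage_mm(z),
                         numeric(1))) + state$canopy_store

  steps <- disaggregate_day(day, cf$n_steps, cf$latitude,
                            cf$canopy$par_fraction)

  # --- phenology -----------------------------------------------------------
  state$pheno <- accumulate_chilling(state$pheno, steps$temp, steps$dt)
  harvested_today <- doy == cf$management$harvest_doy
  pheno_prev_tt <- state$pheno$tt_flowering
  flowering_before <- state$pheno$flowering_doy
  state$pheno <- advance_phenology(state$pheno, doy, tmean, harvested_today)
  dtt <- state$pheno$tt_flowering - pheno_prev_tt
  # fruit number is fixed at flowering from last season's records
  if (is.na(flowering_before) && !is.na(state$pheno$flowering_doy)) {
    state$carbon$fn <- determine_fruit_number(state$carbon$fn_prev,
                                              state$carbon$nodes_prev,
                                              heat_days = 0, gw)
  }
  # heat stress during the flowering window trims the fruit number
  if (!is.na(state$pheno$flowering_doy) &&
      doy >= state$pheno$flowering_doy &&
      doy <= state$pheno$flowering_doy + gw$heat_window &&
      day$tmax > gw$heat_t_threshold) {
    state$carbon$fn <- state$carbon$fn * (1 - gw$heat_reduction)
  }

  # --- management events ---------------------------------------------------
  mg <- cf$management
  exported_c <- 0
  litter_dm <- 0
  y_dry <- NA_real_; y_oil <- NA_real_
  if (!is.null(mg$tillage_events)) {
    te <- mg$tillage_events
    for (k in which(te$doy == doy)) {
      for (zn in names(state$zones)) {
        state$zones[[zn]] <- apply_tillage(state$zones[[zn]], te[k, ])
      }
    }
  }
  irr_dec <- schedule_irrigation(mg, date, doy, state$et_deficit,
                                 state$days_since_irr)
  irr <- irr_dec$irr                     # mm, ground-area basis
  if (irr_dec$reset) {
    state$et_deficit <- 0
    state$days_since_irr <- 0
  } else {
    state$days_since_irr <- state$days_since_irr + 1
  }
  if (doy == 1) {
    state$carbon <- shoots_to_branches(state$carbon)
    state$carbon$nodes_this_season <- 0
    state$pruning_year_counter <- state$pruning_year_counter + 1
  }
  if (mg$pruning_interval > 0 && doy == mg$pruning_doy &&
      state$pruning_year_counter %% mg$pruning_interval == 0) {
    pr <- apply_pruning(state$carbon, mg$f_prune, mg$residue_fate)
    state$carbon <- pr$state
    if (pr$incorporated) litter_dm <- litter_dm + pr$residue_dm
    else exported_c <- exported_c + pr$residue_dm * dm_to_c
  }
  if (harvested_today) {
    hv <- apply_harvest(state$carbon, gw$oil_ratio)
    y_dry <- hv$y_dry; y_oil <- hv$y_oil
    state$carbon <- hv$state
    state$carbon$nodes_prev <- state$carbon$nodes_this_season
    exported_c <- exported_c + y_dry * dm_to_c
  }

  # --- interception and wet-canopy evaporation -----------------------------
  lai <- state$geom$lai
  ic <- intercept_rainfall(day$rain, state$canopy_store, lai, cf$canopy$c_int)
  state$canopy_store <- ic$stored
  ra <- aerodynamic_resistance(day$wind, cf$tree_height)
  ecan <- 0
  canopy_wet <- logical(nrow(steps))
  for (i in seq_len(nrow(steps))) {
    ev <- evaporate_intercepted(state$canopy_store, steps[i, ], ra)
    ecan <- ecan + ev$ecan
    canopy_wet[i] <- ev$transpiration_blocked
    state$canopy_store <- ev$stored
  }

  # --- per-zone runoff, infiltration, drainage -----------------------------
  depths <- partition_effective_precip(ic$p_eff,
                                       vapply(state$zones, `[[`, numeric(1), "frac"))
  runoff <- 0; drainage <- 0
  infil <- numeric(2)
  for (zi in 1:2) {
    z <- state$zones[[zi]]
    cn_eff <- effective_curve_number(z, state$geom$gc, cf$soil)
    ro <- curve_number_runoff(depths[zi], cn_eff)
    dr <- drain_and_redistribute(z, ro$infiltration,
                                 irr = if (zi == 2 && z$frac > 0) irr / z$frac else 0,
                                 swcon = cf$soil$swcon,
                                 diff_coef = cf$soil$diff_coef)
    state$zones[[zi]] <- dr$zone
    infil[zi] <- ro$infiltration
    runoff <- runoff + z$frac * ro$runoff
    drainage <- drainage + z$frac * dr$drainage
  }

  # --- radiation partition and the diurnal SPAC loop -----------------------
  par_inc_daily <- sum((steps$par_beam + steps$par_diff) * steps$dt * 3600) *
    0.2188e-6                            # MJ PAR m-2
  ep <- 0; a_mol <- 0; ipar_daily <- 0
  psi_leaf_min <- NA_real_; psi_collar_min <- NA_real_
  if (lai > 0) {
    if (abs(state$geom$lai - state$f_diff_lai) > 0.02 * max(state$f_diff_lai, 0.01) ||
        is.null(state$f_diff_cache)) {
      state$f_diff_cache <- diffuse_interception_fraction(state$geom,
                                                          cf$canopy$g_fun)
      state$f_diff_lai <- state$geom$lai
    }
    radpart <- intercept_radiation(state$geom, steps, cf$canopy$g_fun,
                                   cf$canopy$scatter, cf$canopy$ngrid,
                                   f_diff = state$f_diff_cache)
    ipar_daily <- sum(radpart$ipar * steps$dt * 3600) * 0.2188e-6
    paths <- build_hydraulic_paths(state$zones, state$soil_temp, cf$spac)
    if (nrow(paths) > 0) {
      r_x <- plant_xylem_resistance(cf$tree_height, state$geom$a_h,
                                    cf$spac$sapwood_area,
                                    state$geom$density,
                                    cf$spac$vessel_diameter,
                                    cf$spac$vessel_density)
      dwc <- diurnal_water_carbon(steps, radpart, paths, r_x, cf$co2,
                                  canopy_wet, cf$spac)
      a_mol <- dwc$a_gross_mol
      psi_leaf_min <- dwc$psi_leaf_min
      psi_collar_min <- dwc$psi_collar_min
      # withdraw RWU from the profiles (capped at availability)
      ep <- 0
      for (zi in 1:2) {
        sel <- paths$zone == zi
        if (!any(sel)) next
        req <- numeric(nrow(state$zones[[zi]]$layers))
        req[paths$layer[sel]] <- dwc$rwu_mm[sel] / state$zones[[zi]]$frac
        ex <- extract_rwu(state$zones[[zi]], req, cf$soil$airdry_frac)
        state$zones[[zi]] <- ex$zone
        ep <- ep + state$zones[[zi]]$frac * sum(ex$extracted)
      }
    }
  }

  # --- soil evaporation ----------------------------------------------------
  e_pot <- potential_soil_evaporation(day, cf$soil$albedo)
  transmitted <- if (par_inc_daily > 0) {
    max(0, 1 - ipar_daily / par_inc_daily)
  } else 1
  es <- 0
  for (zi in 1:2) {
    mf <- if (zi == 2) cf$soil$microadvection else 1
    se <- soil_evaporation(state$zones[[zi]], e_pot, transmitted,
                           infiltration = infil[zi] +
                             (if (zi == 2 && state$zones[[zi]]$frac > 0)
                                irr / state$zones[[zi]]$frac else 0),
                           microadvection = mf,
                           u_stage1 = cf$soil$u_stage1,
                           alpha = cf$soil$alpha_soil,
                           airdry_frac = cf$soil$airdry_frac)
    state$zones[[zi]] <- se$zone
    es <- es + state$zones[[zi]]$frac * se$es
  }

  # --- maximum-ET accumulator for auto irrigation --------------------------
  kc <- cf$kc_max_et[1] + cf$kc_max_et[2] * state$geom$gc
  max_et <- kc * reference_et0(day)
  state$et_deficit <- max(0, state$et_deficit + max_et - ic$p_eff)

  # --- carbon economy ------------------------------------------------------
  a_ch2o <- a_mol * 30
  resp_m <- maintenance_respiration(state$carbon, steps$temp, steps$dt, gw)
  ap <- daily_assimilate_pool(a_ch2o, state$carbon, resp_m,
                              state$pheno$fruit_active, gw)
  state$carbon <- ap$state
  pool <- ap$pool
  resp_m <- resp_m - ap$unpaid  # starvation: unpayable respiration not emitted
  # remobilization: only when the fruit demand exceeds today's supply
  remob <- 0
  if (state$pheno$fruit_active && state$carbon$fn > 0) {
    demand_sub <- state$carbon$fn * gw$fruit_pot_rate * dtt / gw$pv_fruit
    if (demand_sub > pool) {
      remob <- min(gw$remob_cap * state$carbon$reserves, demand_sub - pool)
      state$carbon$reserves <- state$carbon$reserves - remob
      pool <- pool + remob
    }
  }
  al <- allocate_growth(pool, state$carbon, state$carbon$fn, dtt,
                        state$pheno$growth_active, state$pheno$fruit_active, gw)
  state$carbon$leaves <- state$carbon$leaves + al$growth[["leaf"]]
  state$carbon$shoots[1] <- state$carbon$shoots[1] + al$growth[["shoot"]]
  state$carbon$branches <- state$carbon$branches + al$growth[["branch"]]
  state$carbon$coarse_roots <- state$carbon$coarse_roots + al$growth[["coarse"]]
  state$carbon$fruits <- state$carbon$fruits + al$growth[["fruit"]]
  state$carbon$reserves <- state$carbon$reserves + al$to_reserves
  state$carbon$nodes_this_season <- state$carbon$nodes_this_season +
    gw$nodes_per_g_shoot * al$growth[["shoot"]]
  if (al$growth[["fine"]] > 0) {
    inc <- distribute_fine_root_growth(al$growth[["fine"]], state$zones)
    state$carbon$fine_roots <- state$carbon$fine_roots + inc
  }
  sn <- senescence_turnover(state$carbon, gw)
  state$carbon <- sn$state
  litter_dm <- litter_dm + sum(sn$litter)
  fr <- frost_defoliation(state$carbon, day$tmin, gw)
  state$carbon <- fr$state
  litter_dm <- litter_dm + fr$litter

  # --- geometry and root length update -------------------------------------
  state$geom <- update_crown_geometry(state$carbon$leaves, gw$sla,
                                      cf$canopy$lad, cf$canopy$r_zx,
                                      cf$spacing, cf$crown_base, cf$max_height)
  lv_mat <- root_length_density(state$carbon$fine_roots, state$zones, gw$srl)
  for (zi in 1:2) state$zones[[zi]]$layers$lv <- lv_mat[zi, ]

  # --- soil carbon ---------------------------------------------------------
  state$soil_temp <- 0.8 * state$soil_temp + 0.2 * tmean
  wet_top <- sum(vapply(state$zones, function(z)
    z$frac * z$layers$theta[1] / z$layers$theta_sat[1], numeric(1)))
  sc <- soil_carbon_step(state$soilc, litter_dm * dm_to_c, state$soil_temp,
                         wet_top, cf$soilc)
  state$soilc <- sc$pools
  resp_h_c <- sc$resp_h

  # --- closure audits ------------------------------------------------------
  s_after <- sum(vapply(state$zones, function(z) z$frac * zone_storage_mm(z),
                        numeric(1))) + state$canopy_store
  et <- ep + es + ecan
  water_resid <- (day$rain + irr) - (runoff + drainage + et) -
    (s_after - s_before)
  if (abs(water_resid) > 1e-6) {
    stop("water closure violation on ", format(date), ": residual ",
         signif(water_resid, 4), " mm (P=", day$rain, " Irr=", irr,
         " Rf=", signif(runoff, 4), " D=", signif(drainage, 4),
         " ET=", signif(et, 4), ")")
  }
  a_c <- a_mol * 12 + ap$fruit_photo * C_PER_CH2O
  resp_m_c <- resp_m * C_PER_CH2O
  growth_dm <- sum(al$growth)
  substrate_spent <- pool - al$to_reserves
  resp_g_c <- C_PER_CH2O * substrate_spent - dm_to_c * growth_dm
  c_after <- .system_carbon(state, dm_to_c)
  carbon_resid <- a_c - (resp_m_c + resp_g_c + resp_h_c) - exported_c -
    (c_after - c_before)
  if (abs(carbon_resid) > 1e-6) {
    stop("carbon closure violation on ", format(date), ": residual ",
         signif(carbon_resid, 4), " g C m-2")
  }

  ecof <- ecosystem_fluxes(a_c, resp_m_c, resp_g_c, resp_h_c)
  output <- c(
    doy = doy, rain = day$rain, irr = irr, ep = ep, es = es, ecan = ecan,
    et = et, runoff = runoff, drainage = drainage,
    theta_dry = mean(state$zones$dry$layers$theta),
    theta_wet = mean(state$zones$wet$layers$theta),
    psi_leaf_min = psi_leaf_min, psi_collar_min = psi_collar_min,
    a_gross_c = a_c, resp_m_c = resp_m_c, resp_g_c = resp_g_c,
    resp_h_c = resp_h_c, resp_eco_c = ecof$resp_eco, nee_c = ecof$nee,
    lai = state$geom$lai, gc = state$geom$gc,
    leaves = state$carbon$leaves, shoots = sum(state$carbon$shoots),
    branches = state$carbon$branches, coarse_roots = state$carbon$coarse_roots,
    fine_roots = sum(state$carbon$fine_roots), fruits = state$carbon$fruits,
    reserves = state$carbon$reserves, fn = state$carbon$fn,
    ipar_mj = ipar_daily, par_inc_mj = par_inc_daily,
    growth_active = as.numeric(state$pheno$growth_active),
    fruit_active = as.numeric(state$pheno$fruit_active),
    dormant = as.numeric(state$pheno$dormant),
    y_dry = y_dry, y_oil = y_oil,
    storage_mm = s_after,
    water_resid = water_resid, carbon_resid = carbon_resid,
    exported_c = exported_c
  )
  list(state = state, output = output)
}

#' Run a multi-year simulation
#'
#' @param config Configuration list ([default_config()]).
#' @param weather Daily weather table covering January 1 of the start year
#'   through the end of the last simulated year.
#' @param prerun_tmean Daily mean temperatures of the >= 90 days before the
#'   start (see [initialize_state()]); if `NULL` and `weather` starts
#'   before January 1 of `config$start_year`, the preceding days of
#'   `weather` are used.
#' @return List with `daily` (data frame, one row per day), `annual`
#'   (data frame of annual summaries) and the final `state`.
#' @export
run_simulation <- function(config, weather, prerun_tmean = NULL) {
  cf <- config
  start <- as.Date(sprintf("%d-01-01", cf$start_year))
  end <- as.Date(sprintf("%d-12-31", cf$start_year + cf$years - 1))
  if (is.null(prerun_tmean)) {
    pre <- weather[weather$date < start, ]
    if (nrow(pre) >= 90) {
      prerun_tmean <- (utils::tail(pre, 120)$tmax + utils::tail(pre, 120)$tmin) / 2
    }
  }
  wx <- weather[weather$date >= start & weather$date <= end, ]
  if (nrow(wx) < as.integer(end - start) + 1) {
    stop("input error: weather does not cover the configured years")
  }
  state <- initialize_state(cf, prerun_tmean)

  nd <- nrow(wx)
  out <- NULL
  for (i in seq_len(nd)) {
    sd <- step_day(state, wx[i, ], cf)
    state <- sd$state
    if (is.null(out)) {
      out <- matrix(NA_real_, nd, length(sd$output),
                    dimnames = list(NULL, names(sd$output)))
    }
    out[i, ] <- sd$output
  }
  daily <- data.frame(date = wx$date, out)

  yr <- as.integer(format(daily$date, "%Y"))
  annual <- do.call(rbind, lapply(split(daily, yr), function(d) {
    data.frame(
      year = as.integer(format(d$date[1], "%Y")),
      rain = sum(d$rain), irrigation = sum(d$irr),
      et = sum(d$et), ep = sum(d$ep), es = sum(d$es), ecan = sum(d$ecan),
      runoff = sum(d$runoff), drainage = sum(d$drainage),
      a_gross_c = sum(d$a_gross_c), resp_eco_c = sum(d$resp_eco_c),
      nee_c = sum(d$nee_c),
      ipar_mj = sum(d$ipar_mj),
      y_dry = if (any(!is.na(d$y_dry))) sum(d$y_dry, na.rm = TRUE) else 0,
      y_oil = if (any(!is.na(d$y_oil))) sum(d$y_oil, na.rm = TRUE) else 0,
      lai_end = d$lai[nrow(d)],
      water_resid = sum(d$water_resid), carbon_resid = sum(d$carbon_resid)
    )
  }))
  rownames(annual) <- NULL
  list(daily = daily, annual = annual, state = state)
}
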