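# Two-zone multilayer soil water balance: canopy interception, curve-number
# runoff, tipping-bucket drainage/redistribution, two-stage soil evaporation.

#' Construct the state of one soil zone
#'
#' A zone (dry or wetted surface compartment) carries an ordered set of
#' layers, a curve number, and the bookkeeping needed by the two-stage soil
#' evaporation model.
#'
#' @param frac Surface fraction of the zone (0-1).
#' @param dz Layer thicknesses (m).
#' @param theta Initial volumetric water contents (m3 m-3), recycled.
#' @param theta_ul,theta_ll,theta_sat Field capacity, wilting point and
#'   saturation water contents (m3 m-3), recycled across layers.
#' @param lv Root length densities (cm cm-3), recycled.
#' @param cn Curve number (0-100].
#' @return A list with class `soil_zone`.
#' @export
soil_zone <- function(frac, dz, theta, theta_ul = 0.23, theta_ll = 0.07,
                      theta_sat = 0.42, lv = 0.5, cn = 75) {
  n <- length(dz)
  layers <- data.frame(dz = dz,
                       theta = rep_len(theta, n),
                       theta_ul = rep_len(theta_ul, n),
                       theta_ll = rep_len(theta_ll, n),
                       theta_sat = rep_len(theta_sat, n),
                       lv = rep_len(lv, n))
  stopifnot(all(layers$theta_ll < layers$theta_ul),
            all(layers$theta_ul < layers$theta_sat),
            all(layers$theta >= 0), all(layers$theta <= layers$theta_sat),
            all(dz > 0), all(layers$lv >= 0))
  if (cn <= 0 || cn > 100) stop("config error: CN must be in (0, 100]")
  structure(list(frac = frac, layers = layers, cn = cn,
                 sumes1 = 0, sumes2 = 0, t2 = 0),
            class = "soil_zone")
}

# Total stored water in a zone profile, mm (per zone area).
zone_storage_mm <- function(zone) {
  with(zone$layers, sum(theta * dz) * 1000)
}

#' Intercept rainfall in the canopy store
#'
#' The canopy acts as a capacitor of capacity `c_int * LAI` (mm); rainfall
#' fills it and the remainder is effective precipitation.
#'
#' @param p Precipitation (mm d-1).
#' @param stored Current stored water (mm).
#' @param lai Leaf area index (m2 m-2).
#' @param c_int Storage capacity per unit LAI (mm), default 0.4.
#' @return List with `p_eff`, `p_int` and updated `stored`.
#' @export
intercept_rainfall <- function(p, stored, lai, c_int = 0.4) {
  if (p < 0) stop("validation error: negative precipitation")
  capacity <- c_int * lai
  p_int <- min(p, max(0, capacity - stored))
  list(p_eff = p - p_int, p_int = p_int, stored = stored + p_int)
}

#' Aerodynamic resistance of the orchard canopy
#'
#' Log-profile form over a rough tree canopy: displacement height 0.65 h,
#' momentum roughness 0.1 h, scalar roughness z0m/7.4.
#'
#' @param wind Wind speed at reference height (m s-1), floored at 0.3.
#' @param tree_height Canopy height (m).
#' @param zref Reference height (m), default 10.
#' @return Aerodynamic resistance (s m-1).
#' @export
aerodynamic_resistance <- function(wind, tree_height = 4, zref = 10) {
  u <- pmax(wind, 0.3)
  d <- 0.65 * tree_height
  z0m <- 0.1 * tree_height
  z0h <- z0m / 7.4
  log((zref - d) / z0m) * log((zref - d) / z0h) / (0.41^2 * u)
}

# Penman-Monteith latent flux (mm per step of dt hours) for a surface with
# canopy resistance rc (s m-1) given available energy rn (W m-2).
penman_monteith_mm <- function(rn, temp, vpd, ra, rc, dt_hours) {
  delta <- svp_slope(temp)              # kPa K-1
  gamma <- 0.0667                       # kPa K-1
  rho_cp <- 1208                        # J m-3 K-1 (1.2 kg m-3 * 1006 J kg-1 K-1)
  lambda <- 2.45e6                      # J kg-1
  le <- (delta * pmax(rn, 0) + rho_cp * vpd / ra) /
    (delta + gamma * (1 + rc / ra))     # W m-2
  pmax(0, le) / lambda * dt_hours * 3600  # kg m-2 = mm
}

#' Evaporate intercepted water from the canopy store
#'
#' Potential rate from Penman-Monteith with null canopy resistance;
#' evaporation is capped by the stored amount. While any water remains in
#' the store, tree transpiration is blocked.
#'
#' @param stored Stored canopy water (mm).
#' @param step One sub-daily step row from [disaggregate_day()].
#' @param ra Aerodynamic resistance (s m-1).
#' @param rad_fraction Fraction of global radiation absorbed by the canopy.
#' @return List with `ecan` (mm), updated `stored`, and
#'   `transpiration_blocked` (flag for the step).
#' @export
evaporate_intercepted <- function(stored, step, ra, rad_fraction = 0.7) {
  if (stored <= 0) {
    return(list(ecan = 0, stored = 0, transpiration_blocked = FALSE))
  }
  rn <- rad_fraction * step$rad
  pot <- penman_monteith_mm(rn, step$temp, step$vpd, ra, rc = 0,
                            dt_hours = step$dt)
  ecan <- min(pot, stored)
  list(ecan = ecan, stored = stored - ecan,
       transpiration_blocked = TRUE)
}

#' Partition effective precipitation between the two soil zones
#'
#' Each zone receives the same depth on its own area, so the area-weighted
#' volume equals the orchard-level effective precipitation.
#'
#' @param p_eff Effective precipitation (mm).
#' @param fracs Zone surface fractions; must sum to 1.
#' @return Vector of per-zone depths (mm).
#' @export
partition_effective_precip <- function(p_eff, fracs) {
  if (abs(sum(fracs) - 1) > 1e-9) {
    stop("config error: zone fractions must sum to 1")
  }
  rep(p_eff, length(fracs))
}

#' SCS curve-number runoff
#'
#' Potential retention S = 25400/CN - 254 (mm); runoff is zero up to the
#' initial abstraction 0.2 S and follows the standard quadratic beyond it.
#'
#' @param depth Water depth reaching the soil surface (mm).
#' @param cn Curve number (0-100].
#' @return List with `runoff` and `infiltration` (mm).
#' @export
curve_number_runoff <- function(depth, cn) {
  if (cn <= 0 || cn > 100) stop("config error: CN must be in (0, 100]")
  if (depth < 0) stop("validation error: negative depth")
  s <- 25400 / cn - 254
  rf <- if (depth <= 0.2 * s) 0 else (depth - 0.2 * s)^2 / (depth + 0.8 * s)
  list(runoff = rf, infiltration = depth - rf)
}

# Effective curve number: base CN (tabulated by soil hydrological condition)
# reduced by canopy ground cover, then adjusted for antecedent moisture with
# the standard AMC I/III conversions using the mean wetness of the top two
# layers (three linear classes).
effective_curve_number <- function(zone, gc, params) {
  cn2 <- zone$cn - params$cn_gc_reduction * gc
  cn2 <- min(100, max(30, cn2))
  top <- utils::head(zone$layers, 2)
  w <- mean((top$theta - top$theta_ll) / (top$theta_ul - top$theta_ll))
  if (w < 1 / 3) {
    cn2 / (2.281 - 0.01281 * cn2)
  } else if (w > 2 / 3) {
    cn2 / (0.427 + 0.00573 * cn2)
  } else cn2
}

#' Tipping-bucket drainage and redistribution for one zone
#'
#' Infiltrating water cascades from the top layer downwards: each layer
#' holds water up to saturation (the excess passes straight through, so no
#' layer ever exceeds saturation) and drains `swcon * (theta - theta_ul) *
#' dz` per day to the layer below; the bottom outflow leaves the profile
#' as drainage. A diffusive pass then moves water between adjacent layers
#' below field capacity, towards the drier layer. Mass is conserved.
#'
#' @param zone A `soil_zone`.
#' @param infiltration Infiltrating depth (mm, zone-area basis).
#' @param irr Irrigation depth (mm); only sensible for the wetted zone.
#' @param swcon Drainage rate constant (d-1), default 0.4.
#' @param diff_coef Redistribution coefficient (d-1), default 0.05.
#' @return List with the updated `zone` and `drainage` (mm).
#' @export
drain_and_redistribute <- function(zone, infiltration, irr = 0, swcon = 0.4,
                                   diff_coef = 0.05) {
  if (infiltration < 0 || irr < 0) stop("validation error: negative input")
  ly <- zone$layers
  n <- nrow(ly)
  # single top-down pass: each layer receives the flux from above, holds
  # water up to saturation (excess passes through immediately), and drains
  # swcon x (theta - theta_ul); the receiving layer handles its own excess
  # so it never exceeds saturation. Bottom outflow leaves the profile.
  flow <- infiltration + irr
  for (i in seq_len(n)) {
    mm <- 1000 * ly$dz[i]
    theta_in <- ly$theta[i] + flow / mm
    passthrough <- max(0, theta_in - ly$theta_sat[i]) * mm
    theta_in <- min(theta_in, ly$theta_sat[i])
    drain <- swcon * max(0, theta_in - ly$theta_ul[i]) * mm
    ly$theta[i] <- theta_in - drain / mm
    flow <- passthrough + drain
  }
  drainage <- flow
  # diffusive redistribution below field capacity
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      w1 <- (ly$theta[i] - ly$theta_ll[i]) / (ly$theta_ul[i] - ly$theta_ll[i])
      w2 <- (ly$theta[i + 1] - ly$theta_ll[i + 1]) /
        (ly$theta_ul[i + 1] - ly$theta_ll[i + 1])
      if (w1 > 1 || w2 > 1) next
      move <- diff_coef * (w1 - w2) *
        min(ly$dz[i], ly$dz[i + 1]) * 1000 *
        mean(c(ly$theta_ul[i] - ly$theta_ll[i],
               ly$theta_ul[i + 1] - ly$theta_ll[i + 1]))
      if (move > 0) {
        move <- min(move, max(0, (ly$theta[i] - ly$theta_ll[i]) *
                                ly$dz[i] * 1000))
      } else {
        move <- -min(-move, max(0, (ly$theta[i + 1] - ly$theta_ll[i + 1]) *
                                  ly$dz[i + 1] * 1000))
      }
      ly$theta[i] <- ly$theta[i] - move / (1000 * ly$dz[i])
      ly$theta[i + 1] <- ly$theta[i + 1] + move / (1000 * ly$dz[i + 1])
    }
  }
  if (any(ly$theta < -1e-12 | ly$theta > ly$theta_sat + 1e-9)) {
    stop("internal consistency error: layer theta outside [0, theta_sat]")
  }
  zone$layers <- ly
  list(zone = zone, drainage = drainage)
}

#' Potential soil evaporation from daily weather (Penman-FAO type)
#'
#' Radiation/aerodynamic combination estimate of the evaporative demand at
#' the soil surface, before reduction for canopy shading.
#'
#' @param day One-row daily weather record.
#' @param albedo Soil albedo, default 0.15.
#' @return Potential evaporation (mm d-1).
#' @export
potential_soil_evaporation <- function(day, albedo = 0.15) {
  tmean <- (day$tmax + day$tmin) / 2
  delta <- svp_slope(tmean)
  gamma <- 0.0667
  rn <- (1 - albedo) * day$srad - 1.0   # MJ m-2 d-1, crude net longwave
  rn <- max(0, rn)
  es <- (sat_vapor_pressure(day$tmax) + sat_vapor_pressure(day$tmin)) / 2
  vpd <- max(0, es - day$ea)
  erad <- delta / (delta + gamma) * rn / 2.45          # mm d-1
  eaero <- gamma / (delta + gamma) * 6.43 * (1 + 0.536 * day$wind) * vpd / 2.45
  max(0, erad + eaero)
}

#' Two-stage soil evaporation for one zone
#'
#' Stage 1 (energy-limited): the potential rate times the fraction of
#' radiation transmitted to the soil, times a microadvection factor (>= 1)
#' for the wetted zone. After cumulative stage-1 evaporation exceeds
#' `u_stage1`, stage 2 (soil-limited) follows the square-root-of-time law
#' `alpha * (sqrt(t) - sqrt(t-1))`. Wetting events push the stage counters
#' back. Water is extracted from the top layer, spilling to the second,
#' never below the air-dry limit.
#'
#' @param zone A `soil_zone`.
#' @param e_pot Potential soil evaporation (mm d-1) for the day.
#' @param transmitted Fraction of radiation reaching the soil (0-1).
#' @param infiltration Today's infiltration (mm), used to reset the stages.
#' @param microadvection Microadvective enhancement factor (>= 1).
#' @param u_stage1 Stage-1 cumulative limit (mm), default 9.
#' @param alpha Stage-2 coefficient (mm d-1/2), default 3.5.
#' @param airdry_frac Air-dry limit as a fraction of wilting point.
#' @return List with `es` (mm d-1) and the updated `zone`.
#' @export
soil_evaporation <- function(zone, e_pot, transmitted, infiltration = 0,
                             microadvection = 1, u_stage1 = 9, alpha = 3.5,
                             airdry_frac = 0.5) {
  # rewetting rolls the stage counters back
  if (infiltration > 0) {
    if (infiltration >= zone$sumes2) {
      rem <- infiltration - zone$sumes2
      zone$sumes2 <- 0
      zone$t2 <- 0
      zone$sumes1 <- max(0, zone$sumes1 - rem)
    } else {
      zone$sumes2 <- zone$sumes2 - infiltration
      zone$t2 <- (zone$sumes2 / alpha)^2
    }
  }
  demand <- e_pot * transmitted * microadvection
  if (zone$sumes1 < u_stage1) {
    es <- min(demand, u_stage1 - zone$sumes1)
    zone$sumes1 <- zone$sumes1 + es
    if (es < demand) {  # crossed into stage 2 the same day
      zone$t2 <- zone$t2 + 1
      es2 <- min(demand - es, alpha * (sqrt(zone$t2) - sqrt(zone$t2 - 1)))
      zone$sumes2 <- zone$sumes2 + es2
      es <- es + es2
    }
  } else {
    zone$t2 <- zone$t2 + 1
    es <- min(demand, alpha * (sqrt(zone$t2) - sqrt(zone$t2 - 1)))
    zone$sumes2 <- zone$sumes2 + es
  }
  # extract from the top layers down to air-dry
  ly <- zone$layers
  remaining <- es
  for (i in seq_len(min(2, nrow(ly)))) {
    airdry <- airdry_frac * ly$theta_ll[i]
    avail <- max(0, (ly$theta[i] - airdry) * ly$dz[i] * 1000)
    take <- min(remaining, avail)
    ly$theta[i] <- ly$theta[i] - take / (1000 * ly$dz[i])
    remaining <- remaining - take
    if (remaining <= 0) break
  }
  es <- es - remaining  # unextractable demand is not evaporated
  zone$layers <- ly
  list(es = es, zone = zone)
}

#' Remove root water uptake from a zone profile
#'
#' Uptake is capped per layer at the water available above the air-dry
#' limit (and efflux at the room below saturation), so the returned
#' `extracted` vector is what actually left the profile.
#'
#' @param zone A `soil_zone`.
#' @param rwu_layers Requested uptake per layer (mm, zone-area basis);
#'   negative values (hydraulic redistribution efflux) add water.
#' @param airdry_frac Air-dry limit as a fraction of wilting point.
#' @return List with the updated `zone` and the `extracted` depths (mm).
#' @export
extract_rwu <- function(zone, rwu_layers, airdry_frac = 0.5) {
  ly <- zone$layers
  airdry <- airdry_frac * ly$theta_ll
  avail <- pmax(0, (ly$theta - airdry) * ly$dz * 1000)
  room <- pmax(0, (ly$theta_sat - ly$theta) * ly$dz * 1000)
  extracted <- pmin(rwu_layers, avail)
  extracted <- pmax(extracted, -room)
  ly$theta <- ly$theta - extracted / (1000 * ly$dz)
  zone$layers <- ly
  list(zone = zone, extracted = extracted)
}

#' Penman-Monteith reference evapotranspiration (daily)
#'
#' FAO-56-type reference ET0 from daily weather, used as the basis of the
#' maximum-ET accumulator for automatic irrigation scheduling.
#'
#' @param day One-row daily weather record.
#' @return Reference ET0 (mm d-1).
#' @export
reference_et0 <- function(day) {
  tmean <- (day$tmax + day$tmin) / 2
  delta <- svp_slope(tmean)
  gamma <- 0.0667
  rn <- max(0, 0.77 * day$srad - 2.0)   # MJ m-2 d-1, bulk net radiation
  es <- (sat_vapor_pressure(day$tmax) + sat_vapor_pressure(day$tmin)) / 2
  vpd <- max(0, es - day$ea)
  u2 <- max(0.3, day$wind)
  (0.408 * delta * rn + gamma * 900 / (tmean + 273) * u2 * vpd) /
    (delta + gamma * (1 + 0.34 * u2))
}

#' One day of the water balance for a single zone
#'
#' Orchestrates the zone-level fluxes in order: runoff, infiltration,
#' drainage and redistribution, soil evaporation, root water uptake. The
#' closure identity `delta storage = infiltration + irr - drainage - es -
#' rwu` is checked to 1e-6 mm.
#'
#' @param zone A `soil_zone`.
#' @param p_eff Effective precipitation depth on the zone (mm).
#' @param irr Irrigation depth on the zone (mm); bypasses runoff.
#' @param e_pot Potential soil evaporation (mm d-1).
#' @param transmitted Radiation fraction reaching the soil.
#' @param rwu_layers Root water uptake per layer (mm, zone basis).
#' @param gc Canopy ground cover (for the curve-number adjustment).
#' @param soil_params Soil parameter block (see [default_config()]).
#' @param microadvection Microadvective factor for the evaporation stage 1.
#' @return List with `zone` (updated) and `fluxes` (named: p_eff, runoff,
#'   infiltration, drainage, es, rwu, delta_storage).
#' @export
zone_water_step <- function(zone, p_eff, irr = 0, e_pot = 0, transmitted = 1,
                            rwu_layers = 0, gc = 0,
                            soil_params = default_config()$soil,
                            microadvection = 1) {
  s0 <- zone_storage_mm(zone)
  cn_eff <- effective_curve_number(zone, gc, soil_params)
  ro <- curve_number_runoff(p_eff, cn_eff)
  dr <- drain_and_redistribute(zone, ro$infiltration, irr,
                               soil_params$swcon, soil_params$diff_coef)
  zone <- dr$zone
  se <- soil_evaporation(zone, e_pot, transmitted,
                         infiltration = ro$infiltration + irr,
                         microadvection = microadvection,
                         u_stage1 = soil_params$u_stage1,
                         alpha = soil_params$alpha_soil,
                         airdry_frac = soil_params$airdry_frac)
  zone <- se$zone
  req <- rep_len(rwu_layers, nrow(zone$layers))
  ex <- extract_rwu(zone, req, soil_params$airdry_frac)
  zone <- ex$zone
  rwu <- sum(ex$extracted)
  runoff <- ro$runoff
  ds <- zone_storage_mm(zone) - s0
  resid <- (ro$infiltration + irr) -
    (dr$drainage + se$es + rwu) - ds
  if (abs(resid) > 1e-6) {
    stop("internal error: zone water closure residual ", signif(resid, 4),
         " mm (infil=", signif(ro$infiltration, 4), " D=",
         signif(dr$drainage, 4), " Es=", signif(se$es, 4),
         " RWU=", signif(rwu, 4), ")")
  }
  list(zone = zone,
       fluxes = c(p_eff = p_eff, runoff = runoff,
                  infiltration = ro$infiltration,
                  drainage = dr$drainage, es = se$es, rwu = rwu,
                  delta_storage = ds))
}
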