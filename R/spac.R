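# Soil-plant-atmosphere hydraulic network coupled to sunlit/shaded leaf
# gas exchange. Resistances are on a ground-area basis in
# MPa s m2 mmol-1; fluxes in mmol H2O m-2 ground s-1.

MMOL_TO_MM <- 1.8e-5       # kg (= mm) per mmol H2O
PATM_KPA <- 101.3

#' Campbell soil water retention
#'
#' `psi = psi_e * (theta / theta_sat)^(-b)`.
#'
#' @param theta Volumetric water content (m3 m-3), > 0.
#' @param theta_sat Saturation water content.
#' @param psi_e Air-entry potential (MPa, < 0).
#' @param b Campbell exponent (> 0).
#' @return Soil water potential (MPa).
#' @export
soil_water_potential <- function(theta, theta_sat, psi_e = -0.0015, b = 4) {
  if (any(theta <= 0)) stop("domain error: theta must be > 0")
  psi_e * (theta / theta_sat)^(-b)
}

# Campbell unsaturated conductivity (same molar-hydraulic units as k_sat).
unsat_conductivity <- function(theta, theta_sat, k_sat, b) {
  k_sat * (theta / theta_sat)^(2 * b + 3)
}

#' Soil-to-root-surface resistance of one layer
#'
#' Single-root (Gardner/Cowan) form on a ground-area basis:
#' `ln(d / r_root) / (2 pi k(theta) Lv dz frac)` with half-distance between
#' roots `d = (pi Lv)^(-1/2)`. Infinite (excluded path) when `lv` is zero.
#'
#' @param theta,theta_sat Water content and saturation (m3 m-3).
#' @param lv Root length density (cm cm-3).
#' @param dz Layer thickness (m).
#' @param frac Zone surface fraction (ground-area weighting).
#' @param k_sat Saturated conductivity (mmol m-1 s-1 MPa-1), texture-based.
#' @param b Campbell exponent.
#' @param r_root Mean fine-root radius (m).
#' @return Resistance (MPa s m2 mmol-1), `Inf` if no roots.
#' @export
layer_soil_resistance <- function(theta, theta_sat, lv, dz, frac = 1,
                                  k_sat = 5e4, b = 4, r_root = 2.5e-4) {
  if (lv <= 0) return(Inf)
  lv_m <- lv * 1e4                       # cm cm-3 -> m m-3
  d <- (pi * lv_m)^(-1 / 2)
  k <- unsat_conductivity(theta, theta_sat, k_sat, b)
  log(max(d / r_root, 1.0001)) / (2 * pi * k * lv_m * dz * frac)
}

#' Root radial resistance of one layer
#'
#' Inverse of (permeability x root surface area per unit ground area), with
#' the permeability reduced by soil dryness and by low temperature.
#'
#' @param lv Root length density (cm cm-3).
#' @param dz Layer thickness (m).
#' @param frac Zone surface fraction.
#' @param theta,theta_ll,theta_ul Water contents for the dryness factor.
#' @param temp Soil temperature (degC).
#' @param permeability Radial permeability (mmol m-2 root s-1 MPa-1).
#' @param r_root Fine-root radius (m).
#' @param t_ref Reference temperature (degC); below it a Q10-type
#'   (viscosity-like) factor < 1 applies.
#' @param q10 Temperature sensitivity of the permeability.
#' @return Resistance (MPa s m2 mmol-1), `Inf` if no roots.
#' @export
layer_root_resistance <- function(lv, dz, frac = 1, theta = NULL,
                                  theta_ll = 0.07, theta_ul = 0.23,
                                  temp = 20, permeability = 1.0,
                                  r_root = 2.5e-4, t_ref = 20, q10 = 1.5) {
  if (lv <= 0) return(Inf)
  lv_m <- lv * 1e4
  sa <- 2 * pi * r_root * lv_m * dz * frac   # m2 root m-2 ground
  f_theta <- 1
  if (!is.null(theta)) {
    thresh <- theta_ll + 0.5 * (theta_ul - theta_ll)
    f_theta <- min(1, max(0.05, (theta - theta_ll) / (thresh - theta_ll)))
  }
  f_temp <- min(1, q10^((temp - t_ref) / 10))
  1 / (permeability * f_theta * f_temp * sa)
}

#' Xylem (root collar to canopy) resistance
#'
#' Hagen-Poiseuille conductance of the vessel population per unit sapwood,
#' scaled by the path length (tree height plus mean crown radius) and
#' converted to a ground-area resistance through the planting density.
#'
#' @param tree_height Height (m).
#' @param crown_radius Mean crown radius (m), added to the path length.
#' @param sapwood_area Sapwood cross-section per tree (m2).
#' @param density Trees per m2 ground.
#' @param vessel_diameter Mean vessel diameter (m).
#' @param vessel_density Vessels per m2 of sapwood.
#' @return Resistance (MPa s m2 mmol-1).
#' @export
plant_xylem_resistance <- function(tree_height = 4, crown_radius = 1.5,
                                   sapwood_area = 0.01, density = 1 / 24.5,
                                   vessel_diameter = 30e-6,
                                   vessel_density = 60e6) {
  stopifnot(tree_height > 0, sapwood_area > 0, density > 0)
  eta <- 1.002e-9                         # MPa s, water viscosity at 20 degC
  k_spec <- vessel_density * pi * vessel_diameter^4 / (128 * eta)  # m2 s-1 MPa-1
  k_molar <- k_spec * 5.551e7             # mmol m-1 s-1 MPa-1 per m2 sapwood
  path <- tree_height + crown_radius
  cond_ground <- k_molar * sapwood_area / path * density
  1 / cond_ground
}

#' Build the hydraulic branch table for the current soil state
#'
#' One branch per rooted layer per zone: soil water potential (with a
#' gravity offset of 0.01 MPa per metre of lift to the collar), and the
#' series soil + root resistance. Layers without roots are excluded.
#'
#' @param zones List of `soil_zone` objects.
#' @param temp Mean soil temperature (degC) for the root permeability.
#' @param params SPAC parameter list (see [default_config()] `$spac`).
#' @return Data frame with `zone`, `layer`, `psi` (MPa), `resistance`
#'   (MPa s m2 mmol-1) and `frac`.
#' @export
build_hydraulic_paths <- function(zones, temp, params) {
  rows <- list()
  for (zi in seq_along(zones)) {
    z <- zones[[zi]]
    depth <- cumsum(z$layers$dz) - z$layers$dz / 2
    for (li in seq_len(nrow(z$layers))) {
      ly <- z$layers[li, ]
      if (ly$lv <= 0) next
      theta <- max(ly$theta, 1e-4)
      psi <- soil_water_potential(theta, ly$theta_sat, params$psi_e, params$b) -
        0.01 * (depth[li] + params$collar_height)
      rs <- layer_soil_resistance(theta, ly$theta_sat, ly$lv, ly$dz, z$frac,
                                  params$k_sat, params$b, params$r_root)
      rr <- layer_root_resistance(ly$lv, ly$dz, z$frac, theta,
                                  ly$theta_ll, ly$theta_ul, temp,
                                  params$root_permeability, params$r_root,
                                  params$root_t_ref, params$root_q10)
      rows[[length(rows) + 1]] <- data.frame(zone = zi, layer = li, psi = psi,
                                             resistance = rs + rr,
                                             frac = z$frac)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(zone = integer(), layer = integer(), psi = numeric(),
                      resistance = numeric(), frac = numeric()))
  }
  do.call(rbind, rows)
}

#' Solve the soil-plant hydraulic network for a transpiration demand
#'
#' Parallel soil branches join at the collar node; by Kirchhoff's law the
#' collar potential solves `sum_i (psi_i - psi_collar) / R_i = Ep`, giving
#' a closed form. Branch flows are returned; with `allow_efflux = FALSE`,
#' branches that would lose water are excluded iteratively.
#'
#' @param psi Branch soil water potentials (MPa).
#' @param resistance Branch resistances (MPa s m2 mmol-1).
#' @param r_x Xylem resistance collar-to-leaf (MPa s m2 mmol-1).
#' @param ep Transpiration demand (mmol m-2 ground s-1), >= 0.
#' @param allow_efflux Allow negative branch flows (hydraulic
#'   redistribution)?
#' @return List with `psi_collar`, `psi_leaf`, `rwu` (per branch,
#'   mmol m-2 s-1; `sum(rwu) == ep`) and `supply_limited` flag
#'   (psi_leaf below -10 MPa).
#' @export
solve_soil_plant_network <- function(psi, resistance, r_x, ep,
                                     allow_efflux = TRUE) {
  keep <- is.finite(resistance) & resistance > 0
  if (!any(keep)) stop("no finite hydraulic path to the soil")
  if (ep < 0) stop("validation error: ep must be >= 0")
  active <- keep
  repeat {
    g <- 1 / resistance[active]
    psi_collar <- (sum(psi[active] * g) - ep) / sum(g)
    rwu <- numeric(length(psi))
    rwu[active] <- (psi[active] - psi_collar) / resistance[active]
    if (allow_efflux || all(rwu >= -1e-15)) break
    drop <- active & rwu < 0
    if (!any(drop) || sum(active & !drop) == 0) break
    active <- active & !drop
  }
  psi_leaf <- psi_collar - ep * r_x
  list(psi_collar = psi_collar, psi_leaf = psi_leaf, rwu = rwu,
       supply_limited = psi_leaf < -10)
}

# --- leaf biochemistry -----------------------------------------------------

# Arrhenius temperature scaling relative to 25 degC.
arrhenius <- function(k25, ha, tleaf) {
  k25 * exp(ha * (tleaf - 25) / (298.15 * 8.314 * (tleaf + 273.15)))
}

# Farquhar-type gross assimilation (umol CO2 m-2 s-1) at given Ci; returns
# the minimum of the Rubisco- and RuBP-regeneration-limited rates.
gross_assimilation <- function(ci, par_abs, tleaf, p) {
  vcmax <- arrhenius(p$vcmax25, 65330, tleaf)
  jmax <- arrhenius(p$jmax25, 43540, tleaf)
  gstar <- arrhenius(42.75, 37830, tleaf)
  kc <- arrhenius(404.9, 79430, tleaf)
  ko <- arrhenius(278.4, 36380, tleaf)
  km <- kc * (1 + 210 / ko)
  ii <- p$alpha_q * par_abs
  j <- (ii + jmax - sqrt((ii + jmax)^2 - 4 * p$theta_j * ii * jmax)) /
    (2 * p$theta_j)
  wc <- vcmax * pmax(0, ci - gstar) / (ci + km)
  wj <- j / 4 * pmax(0, ci - gstar) / (ci + 2 * gstar)
  list(a = pmin(wc, wj), gstar = gstar, rd = p$rd_frac * vcmax)
}

# Logistic water-potential downregulation factor for stomata: ~1 above
# psi_onset, ~0 below psi_closure.
psi_factor <- function(psi_leaf, psi_onset, psi_closure) {
  psi50 <- (psi_onset + psi_closure) / 2
  sf <- 2 * log(19) / (psi_onset - psi_closure)
  1 / (1 + exp(sf * (psi50 - psi_leaf)))
}

#' Default SPAC and gas-exchange parameters
#' @return Named list of parameters with units in the comments of the
#'   source; all exposed through the simulation config.
#' @export
default_spac_params <- function() {
  list(
    psi_e = -0.0015,        # MPa, air-entry potential
    b = 4,                  # Campbell exponent
    k_sat = 5e4,            # mmol m-1 s-1 MPa-1, saturated conductivity
    r_root = 2.5e-4,        # m, fine-root radius
    root_permeability = 1.0, # mmol m-2 root s-1 MPa-1
    root_t_ref = 20,        # degC
    root_q10 = 1.5,
    collar_height = 0.3,    # m, lift from soil surface to collar node
    sapwood_area = 0.01,    # m2 per tree
    vessel_diameter = 30e-6, # m
    vessel_density = 60e6,  # vessels m-2 sapwood
    vcmax25 = 90,           # umol m-2 s-1
    jmax25 = 162,           # umol m-2 s-1
    alpha_q = 0.24,         # mol e- per mol photon
    theta_j = 0.9,
    rd_frac = 0.015,        # Rd as fraction of Vcmax
    gs_min = 0.01,          # mol m-2 s-1
    a1 = 6,                 # stomatal slope
    d0 = 1.5,               # kPa, VPD sensitivity
    psi_onset = -1.5,       # MPa, stomatal downregulation onset
    psi_closure = -4.5,     # MPa, near-complete closure
    ci_init_frac = 0.7,
    damping = 0.5,
    ci_tol = 0.1,           # umol mol-1
    psi_tol = 0.005,        # MPa
    max_iter = 300,
    allow_efflux = TRUE
  )
}

#' Coupled gas exchange for a single leaf class
#'
#' C3 biochemistry (Rubisco- and RuBP-limited rates) coupled to a stomatal
#' conductance that responds to assimilation, VPD and a leaf-water-potential
#' downregulation factor, iterated to a fixed point over the intercellular
#' CO2 concentration. Errors out on non-convergence.
#'
#' @param par_abs Absorbed PAR (umol m-2 leaf s-1).
#' @param tleaf Leaf temperature (degC; taken equal to air).
#' @param vpd Vapor pressure deficit (kPa).
#' @param ca Atmospheric CO2 (umol mol-1).
#' @param psi_leaf Leaf water potential (MPa) for the downregulation.
#' @param params Parameter list as [default_spac_params()].
#' @return List with `a_gross`, `a_net` (umol m-2 s-1), `gs` (mol m-2 s-1),
#'   `ci` (umol mol-1), `e_leaf` (mol H2O m-2 leaf s-1) and `psi_leaf`.
#' @export
leaf_gas_exchange <- function(par_abs, tleaf, vpd, ca, psi_leaf = 0,
                              params = default_spac_params()) {
  if (ca <= 0) stop("validation error: ca must be > 0")
  p <- params
  if (par_abs <= 0) {
    gs <- p$gs_min
    return(list(a_gross = 0, a_net = 0, gs = gs, ci = ca,
                e_leaf = 1.6 * gs * vpd / PATM_KPA, psi_leaf = psi_leaf))
  }
  fpsi <- psi_factor(psi_leaf, p$psi_onset, p$psi_closure)
  ci <- p$ci_init_frac * ca
  damp <- p$damping
  delta_prev <- 0
  for (it in seq_len(p$max_iter)) {
    bio <- gross_assimilation(ci, par_abs, tleaf, p)
    an <- bio$a - bio$rd
    gs <- p$gs_min + p$a1 * pmax(0, an) * fpsi /
      ((ca - bio$gstar) * (1 + vpd / p$d0))
    ci_new <- min(max(ca - 1.6 * an / gs, 0), ca)
    delta <- ci_new - ci
    # sign-flip adaptive damping: the map can two-cycle near closure
    if (delta * delta_prev < 0) damp <- max(0.05, damp * 0.5)
    else damp <- min(p$damping, damp * 1.2)
    delta_prev <- delta
    ci <- ci + damp * delta
    if (abs(delta) < p$ci_tol) {
      bio <- gross_assimilation(ci, par_abs, tleaf, p)
      an <- bio$a - bio$rd
      return(list(a_gross = bio$a, a_net = an, gs = gs, ci = ci,
                  e_leaf = 1.6 * gs * vpd / PATM_KPA, psi_leaf = psi_leaf))
    }
  }
  stop("gas exchange iteration did not converge; last residual ",
       signif(delta, 3), " umol mol-1")
}

#' Diurnal coupled water-carbon solution for one day
#'
#' For every sub-daily step, the hydraulic network and the sunlit/shaded
#' gas exchange are solved jointly by a damped fixed-point iteration over
#' intercellular CO2 (per class) and leaf water potential (shared), all
#' steps simultaneously. Steps where the canopy is wet contribute no
#' transpiration. Daily totals are obtained by step integration.
#'
#' @param steps Sub-daily weather from [disaggregate_day()].
#' @param radpart Radiation partition from [intercept_radiation()].
#' @param paths Hydraulic branch table from [build_hydraulic_paths()].
#' @param r_x Xylem resistance (MPa s m2 mmol-1).
#' @param ca Atmospheric CO2 (umol mol-1).
#' @param canopy_wet Logical per step: transpiration blocked.
#' @param params SPAC parameter list.
#' @return List with `ep_mm` (daily transpiration), `a_gross_mol` (daily
#'   gross assimilation, mol CO2 m-2 ground), `rwu_mm` (per branch, mm,
#'   ground-area basis), `psi_leaf_min`, `psi_collar_min` (MPa) and
#'   `gs_mean` (daytime mean stomatal conductance of sunlit leaves).
#' @export
diurnal_water_carbon <- function(steps, radpart, paths, r_x, ca,
                                 canopy_wet = rep(FALSE, nrow(steps)),
                                 params = default_spac_params()) {
  p <- params
  ns <- nrow(steps)
  nb <- nrow(paths)
  if (nb == 0) stop("no hydraulic path: profile has no rooted layers")
  g <- 1 / paths$resistance
  sg <- sum(g)
  spg <- sum(paths$psi * g)

  lai_mat <- cbind(radpart$lai_sun, radpart$lai_shade)   # ns x 2
  q_mat <- cbind(radpart$q_sun, radpart$q_shade)
  vpd <- steps$vpd
  tleaf <- steps$temp

  ci <- matrix(p$ci_init_frac * ca, ns, 2)
  psi_leaf <- rep((spg - 0) / sg, ns)
  ep <- numeric(ns)
  a_gross <- matrix(0, ns, 2)
  gs <- matrix(p$gs_min, ns, 2)
  lit <- q_mat > 0

  # outer fixed point over psi_leaf (shared per step) with per-step
  # sign-flip adaptive damping; inner fixed point over Ci per leaf class
  # at frozen fpsi. The gs-psi feedback is a decreasing scalar map per
  # step and two-cycles without the adaptive damping.
  solve_ci <- function(ci, fpsi) {
    d_prev <- matrix(0, ns, 2)
    damp <- matrix(p$damping, ns, 2)
    for (k in 1:120) {
      an <- matrix(0, ns, 2)
      for (cl in 1:2) {
        bio <- gross_assimilation(ci[, cl], q_mat[, cl], tleaf, p)
        a_gross[, cl] <<- ifelse(lit[, cl], bio$a, 0)
        an[, cl] <- ifelse(lit[, cl], bio$a - bio$rd, 0)
        gs[, cl] <<- p$gs_min + p$a1 * pmax(0, an[, cl]) * fpsi /
          ((ca - bio$gstar) * (1 + vpd / p$d0))
      }
      d <- pmin(pmax(ca - 1.6 * an / gs, 0), ca) - ci
      if (max(abs(d)) < p$ci_tol) return(ci + d)
      flip <- d * d_prev < 0
      damp[flip] <- pmax(0.05, damp[flip] * 0.5)
      damp[!flip] <- pmin(p$damping, damp[!flip] * 1.2)
      ci <- ci + damp * d
      d_prev <- d
    }
    stop("gas exchange (Ci) iteration did not converge; residual ",
         signif(max(abs(d)), 3), " umol mol-1")
  }

  psi_damp <- rep(p$damping, ns)
  d_psi_prev <- numeric(ns)
  for (it in seq_len(p$max_iter)) {
    fpsi <- psi_factor(psi_leaf, p$psi_onset, p$psi_closure)
    ci <- solve_ci(ci, fpsi)
    e_leaf <- 1.6 * gs * vpd / PATM_KPA          # mol m-2 leaf s-1
    ep_new <- rowSums(e_leaf * lai_mat) * 1000   # mmol m-2 ground s-1
    ep_new[canopy_wet] <- 0
    psi_collar <- (spg - ep_new) / sg
    d_psi <- (psi_collar - ep_new * r_x) - psi_leaf
    ep <- ep_new
    if (max(abs(d_psi)) < p$psi_tol) break
    flip <- d_psi * d_psi_prev < 0
    psi_damp[flip] <- pmax(0.05, psi_damp[flip] * 0.5)
    psi_damp[!flip] <- pmin(p$damping, psi_damp[!flip] * 1.2)
    psi_leaf <- psi_leaf + psi_damp * d_psi
    d_psi_prev <- d_psi
    if (it == p$max_iter) {
      stop("diurnal SPAC iteration did not converge; psi residual ",
           signif(max(abs(d_psi)), 3), " MPa")
    }
  }

  psi_collar <- (spg - ep) / sg
  dt_s <- steps$dt * 3600
  ep_mm <- sum(ep * dt_s) * MMOL_TO_MM
  # branch flows per step: (psi_i - psi_collar_s) * g_i
  rwu_mm <- as.numeric(outer(paths$psi, rep(1, ns)) -
                         matrix(psi_collar, nb, ns, byrow = TRUE))
  rwu_mm <- matrix(rwu_mm, nb, ns) * g
  rwu_mm <- rowSums(sweep(rwu_mm, 2, dt_s, `*`)) * MMOL_TO_MM
  a_mol <- sum(rowSums(a_gross * lai_mat) * dt_s) * 1e-6
  day <- steps$sin_elev > 0
  list(ep_mm = ep_mm, a_gross_mol = a_mol, rwu_mm = rwu_mm,
       psi_leaf_min = min(psi_leaf), psi_collar_min = min(psi_collar),
       gs_mean = if (any(day)) mean(gs[day, 1]) else p$gs_min,
       ep_steps = ep, psi_leaf_steps = psi_leaf)
}
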