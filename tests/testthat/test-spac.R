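test_that("Campbell retention and conductivity behave as closed forms", {
  expect_equal(soil_water_potential(0.42, 0.42, -0.003, 5), -0.003)
  expect_equal(soil_water_potential(0.21, 0.42, -0.003, 5), -0.003 * 2^5)
  th <- seq(0.05, 0.42, 0.01)
  psi <- soil_water_potential(th, 0.42, -0.0015, 4)
  expect_true(all(diff(psi) > 0))  # wetter = less negative
  expect_error(soil_water_potential(0, 0.42), "theta must be > 0")
})

test_that("soil and root resistances follow their stated forms", {
  expect_identical(layer_soil_resistance(0.2, 0.42, 0, 0.3), Inf)
  # closed-form oracle
  lv <- 0.5; dz <- 0.3; frac <- 0.9; ks <- 5e4; b <- 4; rr <- 2.5e-4
  lv_m <- lv * 1e4
  d <- (pi * lv_m)^(-0.5)
  k <- ks * (0.2 / 0.42)^(2 * b + 3)
  expect_equal(layer_soil_resistance(0.2, 0.42, lv, dz, frac, ks, b, rr),
               log(d / rr) / (2 * pi * k * lv_m * dz * frac))
  rs <- vapply(seq(0.1, 0.4, 0.02), function(th)
    layer_soil_resistance(th, 0.42, lv, dz), numeric(1))
  expect_true(all(diff(rs) < 0))   # wetter soil conducts better

  # root resistance: reference temperature and wet soil leave factors at 1
  r_ref <- layer_root_resistance(0.5, 0.3, 1, theta = 0.23, temp = 20)
  sa <- 2 * pi * 2.5e-4 * 0.5 * 1e4 * 0.3
  expect_equal(r_ref, 1 / (1 * sa))
  # halving Lv doubles the resistance
  expect_equal(layer_root_resistance(0.25, 0.3, 1, theta = 0.23, temp = 20),
               2 * r_ref, tolerance = 1e-12)
  # joint theta and temperature factors multiply
  thr <- 0.07 + 0.5 * (0.23 - 0.07)
  f_th <- (0.10 - 0.07) / (thr - 0.07)
  f_t <- 1.5^((10 - 20) / 10)
  expect_equal(layer_root_resistance(0.5, 0.3, 1, theta = 0.10, temp = 10),
               r_ref / (f_th * f_t), tolerance = 1e-12)
})

test_that("xylem resistance scales with height and sapwood", {
  r1 <- plant_xylem_resistance(4, 0, 0.01, 1 / 24.5)
  expect_equal(plant_xylem_resistance(8, 0, 0.01, 1 / 24.5), 2 * r1,
               tolerance = 1e-12)
  expect_equal(plant_xylem_resistance(4, 0, 0.02, 1 / 24.5), r1 / 2,
               tolerance = 1e-12)
  # closed form: Hagen-Poiseuille conductance inverted to ground basis
  eta <- 1.002e-9
  kspec <- 60e6 * pi * (30e-6)^4 / (128 * eta) * 5.551e7
  expect_equal(r1, 1 / (kspec * 0.01 / 4 / 24.5), tolerance = 1e-9)
})

test_that("network solution matches a dense linear solve", {
  # trivial cases
  r <- solve_soil_plant_network(rep(-0.05, 3), rep(1, 3), r_x = 0.2, ep = 0)
  expect_equal(r$psi_collar, -0.05)
  expect_equal(r$rwu, rep(0, 3))
  r2 <- solve_soil_plant_network(c(-0.1, -0.1), c(2, 2), 0.2, ep = 4)
  expect_equal(r2$rwu[1], r2$rwu[2])
  expect_equal(sum(r2$rwu), 4, tolerance = 1e-12)

  # random networks up to 20 branches vs dense Kirchhoff solve with the
  # collar and leaf as interior nodes
  set.seed(7)
  for (k in 1:20) {
    nb <- sample(2:20, 1)
    psi <- -runif(nb, 0.01, 2)
    res <- runif(nb, 0.2, 10)
    rx <- runif(1, 0.05, 0.5)
    ep <- runif(1, 0, 5)
    sol <- solve_soil_plant_network(psi, res, rx, ep)
    # dense solve: interior nodes (collar, leaf); soil nodes Dirichlet
    g <- 1 / res
    gx <- 1 / rx
    lap <- matrix(c(sum(g) + gx, -gx, -gx, gx), 2, 2)
    rhs <- c(sum(psi * g), -ep)
    dense <- solve(lap, rhs)
    expect_equal(sol$psi_collar, dense[1], tolerance = 1e-8)
    expect_equal(sol$psi_leaf, dense[2], tolerance = 1e-8)
    expect_equal(sol$rwu, (psi - dense[1]) * g, tolerance = 1e-8)
    expect_lt(abs(sum(sol$rwu) - ep), 1e-9)
  }

  # efflux clamp: no negative flows when disallowed, closure preserved
  sol <- solve_soil_plant_network(c(-0.05, -3), c(1, 1), 0.2, 1,
                                  allow_efflux = FALSE)
  expect_true(all(sol$rwu >= 0))
  expect_equal(sum(sol$rwu), 1, tolerance = 1e-12)
  expect_error(solve_soil_plant_network(-1, Inf, 0.2, 1), "no finite")
})

test_that("leaf gas exchange reproduces its limiting cases", {
  p <- default_spac_params()
  dark <- leaf_gas_exchange(0, 20, 1.5, 400, 0, p)
  expect_equal(dark$a_gross, 0)
  expect_equal(dark$gs, p$gs_min)

  # gs -> infinity: Ci -> Ca and A' approaches the Rubisco-limited closed
  # form (Jmax raised so carboxylation is binding)
  p2 <- p; p2$a1 <- 1e7; p2$jmax25 <- 1e4
  g <- leaf_gas_exchange(2000, 25, 1.5, 400, 0, p2)
  a_rubisco <- 90 * (400 - 42.75) / (400 + 404.9 * (1 + 210 / 278.4))
  expect_equal(g$ci, 400, tolerance = 0.5)
  expect_equal(g$a_gross, a_rubisco, tolerance = 0.02 * a_rubisco)

  # doubling Ca under Rubisco limitation: A' up, gs not up
  p3 <- p; p3$jmax25 <- 1e4
  g1 <- leaf_gas_exchange(2000, 25, 1.5, 400, 0, p3)
  g2 <- leaf_gas_exchange(2000, 25, 1.5, 800, 0, p3)
  expect_gt(g2$a_gross, g1$a_gross)
  expect_lte(g2$gs, g1$gs + 1e-9)

  # water stress downregulates conductance
  gw <- leaf_gas_exchange(1500, 25, 1.5, 400, 0, p)
  gd <- leaf_gas_exchange(1500, 25, 1.5, 400, -4.4, p)
  expect_lt(gd$gs, 0.2 * gw$gs)
  expect_error(leaf_gas_exchange(1000, 25, 1.5, 0), "ca must be > 0")
})

test_that("stomatal downregulation factor hits its anchor points", {
  f <- olivesim:::psi_factor(c(0, -1.5, -3, -4.5, -8), -1.5, -4.5)
  expect_gt(f[1], 0.98)
  expect_equal(f[2], 0.95, tolerance = 0.01)
  expect_equal(f[3], 0.5, tolerance = 1e-9)
  expect_equal(f[4], 0.05, tolerance = 0.01)
  expect_lt(f[5], 0.01)
})

test_that("the diurnal loop closes Kirchhoff and responds to drying", {
  day <- make_day()
  steps <- disaggregate_day(day, 24, 37.8)
  geom <- test_geom(240)
  rp <- intercept_radiation(geom, steps)
  zones <- list(dry = make_zone(0.9, theta = 0.20), wet = make_zone(0.1, theta = 0.20))
  paths <- build_hydraulic_paths(zones, 20, default_spac_params())
  rx <- plant_xylem_resistance(4, geom$a_h, 0.01, geom$density)
  dwc <- diurnal_water_carbon(steps, rp, paths, rx, 400)
  expect_gt(dwc$ep_mm, 0.5)
  expect_gt(dwc$a_gross_mol, 0.05)
  # Kirchhoff closure integrated over the day
  expect_lt(abs(sum(dwc$rwu_mm) - dwc$ep_mm), 1e-9)
  # independent re-integration of the step series
  expect_equal(dwc$ep_mm, sum(dwc$ep_steps * steps$dt * 3600) * 1.8e-5,
               tolerance = 1e-12)

  # drying the soil never increases transpiration
  dryzones <- list(dry = make_zone(0.9, theta = 0.10), wet = make_zone(0.1, theta = 0.10))
  dpaths <- build_hydraulic_paths(dryzones, 20, default_spac_params())
  ddwc <- diurnal_water_carbon(steps, rp, dpaths, rx, 400)
  expect_lte(ddwc$ep_mm, dwc$ep_mm)
  expect_lt(ddwc$psi_leaf_min, dwc$psi_leaf_min)

  # wet canopy suppresses transpiration on flagged steps
  wet <- rep(TRUE, 24)
  wdwc <- diurnal_water_carbon(steps, rp, paths, rx, 400, canopy_wet = wet)
  expect_equal(wdwc$ep_mm, 0, tolerance = 1e-12)

  # dark day: no assimilation
  nosun <- disaggregate_day(make_day(srad = 0.01), 24, 37.8)
  rp0 <- intercept_radiation(geom, nosun)
  ndwc <- diurnal_water_carbon(nosun, rp0, paths, rx, 400)
  expect_lt(ndwc$a_gross_mol, 1e-3)

  # sunlit leaves assimilate at least as much as shaded ones per unit area
  mid <- which.max(rp$q_sun)
  gs_sun <- leaf_gas_exchange(rp$q_sun[mid], steps$temp[mid], steps$vpd[mid],
                              400, 0)
  gs_sh <- leaf_gas_exchange(rp$q_shade[mid], steps$temp[mid], steps$vpd[mid],
                             400, 0)
  expect_gte(gs_sun$a_gross, gs_sh$a_gross)
})
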