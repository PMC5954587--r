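test_that("canopy interception follows the capacitor rule", {
  expect_equal(intercept_rainfall(10, 0, lai = 0)$p_eff, 10)
  r0 <- intercept_rainfall(0, 0.2, lai = 2)
  expect_equal(r0$p_int, 0)
  expect_equal(r0$stored, 0.2)
  # min() oracle: capacity 0.4 * 2 = 0.8, empty store
  r <- intercept_rainfall(10, 0, lai = 2, c_int = 0.4)
  expect_equal(r$p_int, min(10, 0.4 * 2))
  expect_equal(r$p_eff, 10 - r$p_int)
  expect_equal(r$stored, r$p_int)
  expect_error(intercept_rainfall(-1, 0, 1), "negative")
})

test_that("wet-canopy evaporation matches an independent Penman-Monteith", {
  step <- list(rad = 500, temp = 25, vpd = 1.8, dt = 1)
  ra <- aerodynamic_resistance(2, 4)
  # independently coded PM with rc = 0 on the same inputs
  delta <- 4098 * (0.6108 * exp(17.27 * 25 / (25 + 237.3))) / (25 + 237.3)^2
  le <- (delta * 0.7 * 500 + 1208 * 1.8 / ra) / (delta + 0.0667)
  expected <- le / 2.45e6 * 3600
  ev <- evaporate_intercepted(10, step, ra)
  expect_equal(ev$ecan, expected, tolerance = 1e-10)
  expect_true(ev$transpiration_blocked)
  # exhaustion: stored below potential demand empties the store
  ev2 <- evaporate_intercepted(0.01, step, ra)
  expect_equal(ev2$ecan, 0.01)
  expect_equal(ev2$stored, 0)
  # empty store: nothing evaporates, transpiration not blocked
  ev3 <- evaporate_intercepted(0, step, ra)
  expect_equal(ev3$ecan, 0)
  expect_false(ev3$transpiration_blocked)
})

test_that("effective precipitation partition conserves volume", {
  expect_error(partition_effective_precip(5, c(0.6, 0.3)), "sum to 1")
  for (fw in c(0, 0.2, 0.5)) {
    fr <- c(1 - fw, fw)
    d <- partition_effective_precip(8, fr)
    expect_equal(sum(fr * d), 8)
    expect_equal(d, rep(8, 2))
  }
})

test_that("curve-number runoff matches the closed form and is monotone", {
  expect_equal(curve_number_runoff(0, 75)$runoff, 0)
  expect_equal(curve_number_runoff(30, 100)$runoff, 30)  # impervious limit
  s <- 25400 / 75 - 254
  expect_equal(curve_number_runoff(50, 75)$runoff,
               (50 - 0.2 * s)^2 / (50 + 0.8 * s))
  expect_equal(curve_number_runoff(50, 75)$infiltration,
               50 - curve_number_runoff(50, 75)$runoff)
  expect_error(curve_number_runoff(10, 0), "CN")
  expect_error(curve_number_runoff(10, 101), "CN")
  # monotone in depth (fixed CN) and in CN (fixed depth)
  rf_d <- vapply(seq(0, 80, 4), function(d) curve_number_runoff(d, 80)$runoff,
                 numeric(1))
  expect_true(all(diff(rf_d) >= 0))
  rf_cn <- vapply(seq(40, 100, 5), function(cn)
    curve_number_runoff(40, cn)$runoff, numeric(1))
  expect_true(all(diff(rf_cn) >= 0))
})

test_that("tipping-bucket drainage conserves mass and respects limits", {
  z <- make_zone(theta = 0.23)  # at field capacity
  r <- drain_and_redistribute(z, 0, swcon = 0.4)
  expect_equal(r$zone$layers$theta, z$layers$theta)
  expect_equal(r$drainage, 0)

  # swcon = 1 with infiltration above the UL storage: layers end at UL,
  # remainder drains (bucket arithmetic oracle); no redistribution noise
  z <- make_zone(theta = 0.23)
  cap_to_sat <- sum((0.42 - 0.23) * z$layers$dz) * 1000
  infil <- cap_to_sat + 25
  r <- drain_and_redistribute(z, infil, swcon = 1, diff_coef = 0)
  expect_equal(r$zone$layers$theta, rep(0.23, 3), tolerance = 1e-12)
  expect_equal(r$drainage, infil, tolerance = 1e-9)

  # conservation on random inputs
  set.seed(1)
  for (k in 1:25) {
    z <- make_zone(theta = runif(1, 0.08, 0.4))
    z$layers$theta <- runif(3, 0.08, 0.40)
    before <- sum(z$layers$theta * z$layers$dz) * 1000
    infil <- runif(1, 0, 60)
    r <- drain_and_redistribute(z, infil, swcon = runif(1, 0.1, 1))
    after <- sum(r$zone$layers$theta * r$zone$layers$dz) * 1000
    expect_lt(abs(infil - r$drainage - (after - before)), 1e-9)
    expect_true(all(r$zone$layers$theta <= 0.42 + 1e-12))
    # no drainage when nothing exceeds field capacity
    if (all(r$zone$layers$theta < 0.23)) {
      r2 <- drain_and_redistribute(r$zone, 0)
      expect_equal(r2$drainage, 0)
    }
  }
})

test_that("two-stage soil evaporation follows the stage rules", {
  day <- make_day()
  e_pot <- potential_soil_evaporation(day)
  expect_gt(e_pot, 2)
  # calm dark day: near-zero demand
  dark <- make_day(srad = 0.01, wind = 0, tmax = 10, tmin = 8, ea = 1.2)
  expect_lt(potential_soil_evaporation(dark), 0.3)

  # stage 1 after a large wetting equals potential x shading x advection
  z <- make_zone(theta = 0.23)
  se <- soil_evaporation(z, e_pot, transmitted = 0.6, infiltration = 30,
                         microadvection = 1.2)
  expect_equal(se$es, min(e_pot * 0.6 * 1.2, 9), tolerance = 1e-12)

  # stage 2: sqrt-time closed form with alpha = 3.5
  z <- make_zone(theta = 0.23)
  z$sumes1 <- 9  # stage-1 exhausted
  es_t <- numeric(4)
  for (t in 1:4) {
    se <- soil_evaporation(z, 50, 1, 0, u_stage1 = 9, alpha = 3.5)
    es_t[t] <- se$es
    z <- se$zone
  }
  expect_equal(es_t[4] / es_t[1], (sqrt(4) - sqrt(3)) / (sqrt(1) - sqrt(0)),
               tolerance = 1e-9)
  expect_equal(es_t, 3.5 * (sqrt(1:4) - sqrt(0:3)), tolerance = 1e-9)

  # extraction never draws the top layers below air-dry
  z <- make_zone(theta = 0.04)  # just above air-dry = 0.035
  se <- soil_evaporation(z, 50, 1, 0)
  expect_true(all(se$zone$layers$theta >= 0.5 * 0.07 - 1e-12))
})

test_that("wetted-zone evaporation exceeds dry under microadvection", {
  zd <- make_zone(theta = 0.23)
  zw <- make_zone(theta = 0.23)
  ed <- soil_evaporation(zd, 5, 0.7, infiltration = 30, microadvection = 1)$es
  ew <- soil_evaporation(zw, 5, 0.7, infiltration = 30, microadvection = 1.3)$es
  expect_gte(ew, ed)
})

test_that("root uptake extraction caps at availability", {
  z <- make_zone(theta = 0.08)
  avail <- (0.08 - 0.5 * 0.07) * z$layers$dz * 1000
  ex <- extract_rwu(z, avail + 5)
  expect_equal(ex$extracted, avail, tolerance = 1e-12)
  expect_true(all(ex$zone$layers$theta >= 0.5 * 0.07 - 1e-12))
  # efflux capped at saturation room
  z <- make_zone(theta = 0.41)
  ex <- extract_rwu(z, rep(-100, 3))
  expect_true(all(ex$zone$layers$theta <= 0.42 + 1e-12))
})

test_that("zone water step closes the balance over random forcing", {
  set.seed(99)
  z <- make_zone(frac = 1, theta = 0.2)
  total_in <- 0; total_out <- 0
  s0 <- sum(z$layers$theta * z$layers$dz) * 1000
  for (d in 1:100) {
    p <- if (runif(1) < 0.25) rgamma(1, 0.8, scale = 10) else 0
    r <- zone_water_step(z, p_eff = p, irr = 0, e_pot = runif(1, 0.5, 6),
                         transmitted = 0.7,
                         rwu_layers = runif(3, 0, 0.8), gc = 0.3)
    z <- r$zone
    total_in <- total_in + p
    total_out <- total_out + sum(r$fluxes[c("runoff", "drainage", "es", "rwu")])
    expect_true(all(z$layers$theta >= 0.5 * 0.07 - 1e-9))
    expect_true(all(z$layers$theta <= 0.42 + 1e-9))
  }
  s1 <- sum(z$layers$theta * z$layers$dz) * 1000
  expect_lt(abs(total_in - total_out - (s1 - s0)), 0.01)
})

test_that("irrigation reaches only the wetted zone's profile", {
  dry <- make_zone(frac = 0.9, theta = 0.15)
  wet <- make_zone(frac = 0.1, theta = 0.15)
  rd <- zone_water_step(dry, p_eff = 0, irr = 0)
  rw <- zone_water_step(wet, p_eff = 0, irr = 30)
  expect_equal(rd$zone$layers$theta, dry$layers$theta, tolerance = 1e-12)
  expect_gt(sum(rw$zone$layers$theta), sum(wet$layers$theta))
})
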