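# Shared fixtures: small weather/day constructors, soil zones, and memoised
# long simulations reused across acceptance blocks.

make_day <- function(date = "2001-06-21", tmax = 32, tmin = 16, ea = 1.4,
                     srad = 28, wind = 2, rain = 0) {
  data.frame(date = as.Date(date), tmax = tmax, tmin = tmin, ea = ea,
             srad = srad, wind = wind, rain = rain)
}

make_zone <- function(frac = 1, dz = c(0.2, 0.3, 0.5), theta = 0.20,
                      lv = 0.5, cn = 75) {
  soil_zone(frac, dz, theta, theta_ul = 0.23, theta_ll = 0.07,
            theta_sat = 0.42, lv = lv, cn = cn)
}

test_geom <- function(leaf_biomass = 240) {
  update_crown_geometry(leaf_biomass, 0.0055, 1.8, 1.2, c(7, 3.5), 0.8, 6)
}

# memoised expensive simulations shared between test blocks
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, fun(), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# 12-year irrigated run: closure, bearing, RUE checks
long_irrigated_run <- function() {
  cached("long_irrigated", function() {
    wx <- generate_synthetic_weather(7, 13, start_year = 2000)
    cf <- default_config()
    cf$start_year <- 2001
    cf$years <- 12
    cf$management$irrigation_mode <- "auto"
    run_simulation(cf, wx)
  })
}

# matched 3-year full / deficit irrigation pair on identical weather
irrigation_pair <- function() {
  cached("irrigation_pair", function() {
    wx <- generate_synthetic_weather(11, 4, start_year = 2000)
    cf <- default_config()
    cf$start_year <- 2001
    cf$years <- 3
    cf$management$irrigation_mode <- "auto"
    full <- run_simulation(cf, wx)
    cf$management$irrigation_fraction <- 0.25
    deficit <- run_simulation(cf, wx)
    list(full = full, deficit = deficit)
  })
}
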