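# Daily weather forcing: IO, validation, solar geometry, sub-daily
# disaggregation and a seeded synthetic Mediterranean generator.

WEATHER_COLUMNS <- c("date", "tmax", "tmin", "ea", "srad", "wind", "rain")

#' Read a daily weather table
#'
#' Reads a CSV file with columns `date,tmax,tmin,ea,srad,wind,rain` (ISO
#' dates; temperatures in degC, vapor pressure in kPa, solar radiation in
#' MJ m-2 d-1, wind in m s-1, rain in mm d-1) and validates it: the seven
#' columns must be present, dates contiguous, and every row must satisfy
#' `tmax >= tmin`, `rain >= 0`, `wind >= 0` and `ea >= 0`.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with one row per calendar day, `date` as `Date`.
#' @export
read_weather_table <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(WEATHER_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("weather format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  df <- df[WEATHER_COLUMNS]
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("weather format error: unparseable date(s)")
  validate_weather(df)
  df
}

#' Write a daily weather table
#'
#' Inverse of [read_weather_table()]; the written file round-trips.
#'
#' @param weather Data frame as returned by [read_weather_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(weather, path) {
  out <- weather[WEATHER_COLUMNS]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_weather <- function(df) {
  bad <- which(df$tmax < df$tmin)
  if (length(bad) > 0) {
    stop("weather validation error: tmax < tmin at row ", bad[1])
  }
  for (col in c("rain", "wind", "ea")) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0) {
      stop("weather validation error: negative ", col, " at row ", bad[1])
    }
  }
  if (nrow(df) > 1) {
    gaps <- which(diff(as.integer(df$date)) != 1L)
    if (length(gaps) > 0) {
      stop("weather gap error: non-contiguous dates after row ", gaps[1],
           " (", df$date[gaps[1]], ")")
    }
  }
  invisible(df)
}

#' Solar geometry for a latitude and day of year
#'
#' Standard declination / hour-angle astronomy: solar declination, sunset
#' hour angle, daylength and extraterrestrial radiation.
#'
#' @param latitude Latitude in decimal degrees; must satisfy |lat| < 66.5.
#' @param doy Day of year (1-366).
#' @return List with `latitude_rad`, `declination` (rad), `daylength` (h),
#'   `sunset_hour_angle` (rad) and `ra` (extraterrestrial radiation,
#'   MJ m-2 d-1).
#' @export
solar_geometry <- function(latitude, doy) {
  if (abs(latitude) >= 66.5) {
    stop("unsupported latitude: ", latitude, " (polar day/night not handled)")
  }
  phi <- latitude * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  list(latitude_rad = phi, declination = decl, daylength = 24 * ws / pi,
       sunset_hour_angle = ws, ra = ra)
}

# Sine of solar elevation at fractional hour-of-day (solar time).
solar_elevation_sin <- function(phi, decl, hour) {
  omega <- pi * (hour - 12) / 12
  sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(omega)
}

# Solar azimuth (rad, 0 = south) at fractional hour-of-day.
solar_azimuth <- function(phi, decl, hour) {
  omega <- pi * (hour - 12) / 12
  sinb <- solar_elevation_sin(phi, decl, hour)
  cosb <- sqrt(pmax(0, 1 - sinb^2))
  caz <- (sinb * sin(phi) - sin(decl)) / pmax(1e-9, cosb * cos(phi))
  az <- acos(pmin(1, pmax(-1, caz)))
  ifelse(omega < 0, -az, az)
}

#' Saturation vapor pressure (kPa) at air temperature (degC)
#' @param t Temperature in degC.
#' @export
sat_vapor_pressure <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

# Slope of the saturation curve (kPa K-1).
svp_slope <- function(t) 4098 * sat_vapor_pressure(t) / (t + 237.3)^2

# Daily diffuse fraction of global radiation from the clearness index
# (piecewise correlation; configurable override through `diffuse_fraction`).
diffuse_fraction_from_kt <- function(kt) {
  ifelse(kt <= 0.07, 1,
    ifelse(kt <= 0.35, 1 - 2.3 * (kt - 0.07)^2,
      ifelse(kt <= 0.75, 1.33 - 1.46 * kt, 0.23)))
}

#' Disaggregate one day of weather into sub-daily steps
#'
#' Temperature follows a sine from sunrise (anchored at `tmin`) to a peak at
#' 14:00 solar time (anchored at `tmax`), then an exponential night decay
#' back towards `tmin`. Global radiation is distributed proportionally to
#' the sine of solar elevation so that the integral over the day reproduces
#' the daily total exactly; vapor pressure and wind are held constant.
#'
#' @param day One-row data frame (or list) with the daily weather fields.
#' @param n Number of equal sub-daily steps covering the 24-h day.
#' @param latitude Latitude in decimal degrees.
#' @param par_fraction PAR fraction of global shortwave (default 0.45).
#' @param diffuse_fraction Optional fixed diffuse fraction; if `NULL` it is
#'   derived from the daily clearness index.
#' @return Data frame with one row per step: `hour` (step centre, solar
#'   time), `dt` (step length, h), `temp` (degC), `vpd` (kPa), `rad`
#'   (global, W m-2), `par_beam` and `par_diff` (umol m-2 s-1),
#'   `sin_elev`, `azimuth` (rad) and `wind` (m s-1).
#' @export
disaggregate_day <- function(day, n, latitude, par_fraction = 0.45,
                             diffuse_fraction = NULL) {
  if (n < 1) stop("parameter error: n must be >= 1")
  doy <- as.integer(format(as.Date(day$date), "%j"))
  geo <- solar_geometry(latitude, doy)
  dt <- 24 / n
  hour <- (seq_len(n) - 0.5) * dt
  sinb <- solar_elevation_sin(geo$latitude_rad, geo$declination, hour)
  az <- solar_azimuth(geo$latitude_rad, geo$declination, hour)

  # temperature
  tsr <- 12 - geo$daylength / 2
  tss <- 12 + geo$daylength / 2
  tpk <- 14
  amp <- day$tmax - day$tmin
  if (n == 1) {
    temp <- (day$tmax + day$tmin) / 2
  } else {
    temp <- numeric(n)
    dayi <- hour >= tsr & hour <= tss
    temp[dayi] <- day$tmin + amp *
      sin(pi / 2 * (hour[dayi] - tsr) / (tpk - tsr))
    tset <- day$tmin + amp * sin(pi / 2 * (tss - tsr) / (tpk - tsr))
    nightlen <- 24 - geo$daylength
    tnight <- ifelse(hour > tss, hour - tss, hour + 24 - tss)
    ni <- !dayi
    temp[ni] <- day$tmin + (tset - day$tmin) *
      exp(-2.5 * tnight[ni] / max(nightlen, 1e-6))
  }

  # radiation: weights proportional to positive solar elevation, normalised
  w <- pmax(0, sinb)
  if (sum(w) <= 0) w <- rep(1, n)
  w <- w / sum(w)
  rad_mj <- day$srad * w                       # MJ m-2 per step
  rad <- rad_mj * 1e6 / (dt * 3600)            # W m-2

  if (is.null(diffuse_fraction)) {
    kt <- if (geo$ra > 0) day$srad / geo$ra else 0
    fd <- diffuse_fraction_from_kt(min(max(kt, 0), 1))
  } else {
    fd <- diffuse_fraction
  }
  par_tot <- par_fraction * rad * 4.57         # umol m-2 s-1
  vpd <- pmax(0, sat_vapor_pressure(temp) - day$ea)

  data.frame(hour = hour, dt = dt, temp = temp, vpd = vpd, rad = rad,
             par_beam = par_tot * (1 - fd), par_diff = par_tot * fd,
             sin_elev = sinb, azimuth = az, wind = rep(day$wind, n))
}

#' Default climate parameters for the synthetic weather generator
#'
#' Emulates a semi-arid Mediterranean site: ~600 mm mean annual rainfall
#' concentrated in autumn-spring, hot dry summers, annual temperature and
#' radiation sinusoids with autocorrelated noise.
#'
#' @return Named list of generator parameters.
#' @export
default_climate <- function() {
  list(
    latitude = 37.8,        # decimal degrees
    tmean_annual = 17.5,    # degC
    tmean_amplitude = 8.5,  # degC, seasonal half-amplitude
    tmean_phase_doy = 197,  # day of warmest mean temperature
    dtr_mean = 11,          # mean diurnal temperature range, degC
    dtr_wet = 6,            # diurnal range on rain days, degC
    temp_ar1 = 0.6,         # day-to-day autocorrelation of the anomaly
    temp_sd = 2.2,          # sd of daily anomaly, degC
    rain_annual = 600,      # target mean annual rainfall, mm
    rain_prob_mean = 0.24,  # mean daily probability of a wet day
    rain_prob_amplitude = 0.85, # seasonal modulation (1 = fully dry summer)
    rain_prob_phase_doy = 15,   # wettest time of year
    rain_shape = 0.75,      # gamma shape of daily amounts
    clear_transmission = 0.72,  # clear-day fraction of extraterrestrial
    wet_transmission = 0.35,    # rain-day fraction
    trans_sd = 0.07,
    wind_mean = 2.0,        # m s-1
    wind_sdlog = 0.4,
    dewpoint_offset = 1.5,  # dewpoint approx tmin - offset, degC
    co2 = 400               # umol mol-1
  )
}

#' Generate synthetic daily weather
#'
#' Deterministic for a fixed seed. Temperature and radiation follow
#' seasonal sinusoids with AR(1) noise; rainfall from a seasonal
#' occurrence/gamma-amount process whose expected annual total equals
#' `climate$rain_annual`; vapor pressure from a dewpoint tied to `tmin`.
#' The caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param years Number of full calendar years to generate.
#' @param climate Parameter list as from [default_climate()].
#' @param start_year First calendar year (default 2001).
#' @return Daily weather data frame (see [read_weather_table()]).
#' @export
generate_synthetic_weather <- function(seed, years, climate = default_climate(),
                                       start_year = 2001) {
  if (years < 1) stop("parameter error: years must be >= 1")
  p <- utils::modifyList(default_climate(), climate)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))

  # temperature: seasonal mean + AR(1) anomaly
  seas <- p$tmean_annual + p$tmean_amplitude *
    cos(2 * pi * (doy - p$tmean_phase_doy) / 365)
  anom <- numeric(nd)
  innov <- stats::rnorm(nd, 0, p$temp_sd * sqrt(1 - p$temp_ar1^2))
  anom[1] <- stats::rnorm(1, 0, p$temp_sd)
  for (i in 2:nd) anom[i] <- p$temp_ar1 * anom[i - 1] + innov[i]
  tmean <- seas + anom

  # rainfall occurrence/amounts; expected annual total = rain_annual
  pwet <- pmin(0.95, pmax(0, p$rain_prob_mean *
    (1 + p$rain_prob_amplitude * cos(2 * pi * (doy - p$rain_prob_phase_doy) / 365))))
  wet <- stats::runif(nd) < pwet
  amount_mean <- p$rain_annual / (365.25 * mean(pmin(0.95, pmax(0, p$rain_prob_mean *
    (1 + p$rain_prob_amplitude * cos(2 * pi * ((1:365) - p$rain_prob_phase_doy) / 365))))))
  rain <- ifelse(wet,
                 stats::rgamma(nd, shape = p$rain_shape,
                               scale = amount_mean / p$rain_shape), 0)

  dtr <- ifelse(wet, p$dtr_wet, p$dtr_mean)
  tmax <- tmean + dtr / 2
  tmin <- tmean - dtr / 2

  ra <- vapply(doy, function(d) solar_geometry(p$latitude, d)$ra, numeric(1))
  trans <- ifelse(wet, p$wet_transmission, p$clear_transmission) +
    stats::rnorm(nd, 0, p$trans_sd)
  trans <- pmin(0.78, pmax(0.1, trans))
  srad <- ra * trans

  wind <- stats::rlnorm(nd, log(p$wind_mean) - p$wind_sdlog^2 / 2, p$wind_sdlog)
  ea <- pmin(sat_vapor_pressure(tmin), sat_vapor_pressure(tmin - p$dewpoint_offset))
  ea <- pmax(0.05, ea)

  df <- data.frame(date = dates, tmax = tmax, tmin = tmin, ea = ea,
                   srad = srad, wind = wind, rain = rain)
  validate_weather(df)
  df
}
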