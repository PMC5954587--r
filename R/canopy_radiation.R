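# Spheroidal crown geometry and radiation interception with neighbor
# shading on a regular planting grid.

#' Update crown geometry from leaf biomass
#'
#' Leaf area follows from biomass times SLA; crown volume from a constant
#' leaf area density (LAD); the spheroid radii from the volume with a fixed
#' vertical-to-horizontal ratio. The horizontal radius is capped at half the
#' smaller spacing (and total height at `max_height`); if capped, LAD is
#' recomputed so the leaf area is preserved.
#'
#' @param leaf_biomass Leaf dry biomass (g DM m-2 ground).
#' @param sla Specific leaf area (m2 g-1).
#' @param lad Leaf area density (m2 m-3).
#' @param r_zx Vertical-to-horizontal crown radius ratio.
#' @param spacing Numeric length-2: row and in-row spacing (m).
#' @param crown_base Height of crown base (m).
#' @param max_height Maximum total tree height (m).
#' @return List of class `crown_geometry`: `a_h`, `a_v` (m), `lad`, `lai`,
#'   `gc`, `crown_base`, `spacing`, `density` (trees m-2), `volume` (m3).
#' @export
update_crown_geometry <- function(leaf_biomass, sla = 0.0055, lad = 1.8,
                                  r_zx = 1.2, spacing = c(7, 3.5),
                                  crown_base = 0.8, max_height = 6) {
  area_tree <- prod(spacing)
  density <- 1 / area_tree
  leaf_area_ground <- leaf_biomass * sla        # m2 leaf m-2 ground = LAI
  vol <- leaf_area_ground * area_tree / lad     # m3 per tree
  a_h <- (3 * vol / (4 * pi * r_zx))^(1 / 3)
  # caps from spacing and height
  a_h_max <- min(spacing) / 2
  a_v_max <- max(0.1, (max_height - crown_base) / 2)
  a_h <- min(a_h, a_h_max, a_v_max / r_zx)
  a_v <- r_zx * a_h
  vol_capped <- 4 / 3 * pi * a_h^2 * a_v
  lad_eff <- if (vol_capped > 0) leaf_area_ground * area_tree / vol_capped else lad
  structure(list(
    a_h = a_h, a_v = a_v, lad = lad_eff, lai = leaf_area_ground,
    gc = min(1, pi * a_h^2 * density), crown_base = crown_base,
    spacing = spacing, density = density, volume = vol_capped
  ), class = "crown_geometry")
}

# Path lengths (m) through a spheroidal crown for rays from ground points
# towards a direction. Vectorised over points. Crown centre at (xc, yc, zc),
# semi-axes (a, a, b); direction given by sin of elevation and azimuth.
spheroid_path_length <- function(px, py, sin_elev, azimuth, xc, yc, zc, a, b) {
  cos_elev <- sqrt(max(0, 1 - sin_elev^2))
  ux <- cos_elev * sin(azimuth)
  uy <- cos_elev * cos(azimuth)
  uz <- sin_elev
  # scaled space: divide x,y by a and z by b
  sx <- (px - xc) / a
  sy <- (py - yc) / a
  sz <- (0 - zc) / b
  vx <- ux / a; vy <- uy / a; vz <- uz / b
  A <- vx^2 + vy^2 + vz^2               # scalar: direction only
  B <- 2 * (sx * vx + sy * vy + sz * vz)
  C <- sx^2 + sy^2 + sz^2 - 1
  disc <- B^2 - 4 * A * C
  hit <- disc > 0
  path <- numeric(length(px))
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    s1 <- (-B[hit] - sq) / (2 * A)
    s2 <- (-B[hit] + sq) / (2 * A)
    # only the part of the chord above the ground point (s >= 0)
    s1 <- pmax(s1, 0)
    path[hit] <- pmax(0, s2 - s1)
  }
  path
}

# Regular quadrature grid over one ground cell plus the neighbor tree
# offsets whose crowns can shade it.
.interception_grid <- function(spacing, ngrid) {
  gx <- (seq_len(ngrid) - 0.5) / ngrid * spacing[1] - spacing[1] / 2
  gy <- (seq_len(ngrid) - 0.5) / ngrid * spacing[2] - spacing[2] / 2
  expand.grid(x = gx, y = gy)
}

# Fraction of a beam from (sin_elev, azimuth) intercepted by the canopy,
# per unit ground area, by deterministic quadrature over one planting cell
# with neighbor crowns included.
beam_interception_fraction <- function(geom, sin_elev, azimuth, g_fun = 0.5,
                                       ngrid = 12, neighbor_rings = 2) {
  if (sin_elev <= 0 || geom$lai <= 0 || geom$a_h <= 0) return(0)
  pts <- .interception_grid(geom$spacing, ngrid)
  zc <- geom$crown_base + geom$a_v
  offs <- expand.grid(i = -neighbor_rings:neighbor_rings,
                      j = -neighbor_rings:neighbor_rings)
  # skip lattice trees whose ground shadow cannot reach this cell
  cos_elev <- sqrt(max(0, 1 - sin_elev^2))
  cot_elev <- cos_elev / sin_elev
  shx <- -cot_elev * zc * sin(azimuth)
  shy <- -cot_elev * zc * cos(azimuth)
  reach <- geom$a_h + (geom$a_v + geom$a_h) * cot_elev + 1
  keep <- abs(offs$i * geom$spacing[1] + shx) <= geom$spacing[1] / 2 + reach &
          abs(offs$j * geom$spacing[2] + shy) <= geom$spacing[2] / 2 + reach
  keep[offs$i == 0 & offs$j == 0] <- TRUE
  offs <- offs[keep, , drop = FALSE]
  total_path <- numeric(nrow(pts))
  for (k in seq_len(nrow(offs))) {
    total_path <- total_path + spheroid_path_length(
      pts$x, pts$y, sin_elev, azimuth,
      xc = offs$i[k] * geom$spacing[1], yc = offs$j[k] * geom$spacing[2],
      zc = zc, a = geom$a_h, b = geom$a_v)
  }
  mean(1 - exp(-g_fun * geom$lad * total_path))
}

#' Diffuse interception fraction of the canopy
#'
#' Integrates the beam interception model over the sky hemisphere using a
#' uniform-overcast discretisation (three elevation bands, four azimuths).
#'
#' @param geom A `crown_geometry`.
#' @param g_fun Leaf projection coefficient (0.5 = spherical).
#' @param ngrid Ground-cell quadrature resolution.
#' @return Fraction of incident diffuse radiation intercepted.
#' @export
diffuse_interception_fraction <- function(geom, g_fun = 0.5, ngrid = 8) {
  if (geom$lai <= 0) return(0)
  elevs <- c(15, 45, 75) * pi / 180
  wts <- c(0.178, 0.514, 0.308)  # UOC sky: weights of the three bands
  azs <- c(0, 0.5, 1, 1.5) * pi / 2
  f <- 0
  for (i in seq_along(elevs)) {
    fi <- mean(vapply(azs, function(az) {
      beam_interception_fraction(geom, sin(elevs[i]), az, g_fun, ngrid,
                                 neighbor_rings = 2)
    }, numeric(1)))
    f <- f + wts[i] * fi
  }
  f
}

#' Partition radiation over the canopy for one or more sub-daily steps
#'
#' Computes intercepted PAR and the sunlit/shaded decomposition for each
#' step. Sunlit leaf area follows from beam interception
#' (`f_beam * sin_elev / G`, capped at LAI); shaded leaves receive diffuse
#' and a single scattering correction.
#'
#' @param geom A `crown_geometry`.
#' @param steps Data frame from [disaggregate_day()].
#' @param g_fun Leaf projection coefficient.
#' @param scatter Scattering correction factor on intercepted beam
#'   redistributed to shaded leaves (default 0.1).
#' @param ngrid Ground-cell quadrature resolution.
#' @param f_diff Optional precomputed diffuse interception fraction.
#' @return Data frame (one row per step): `f_beam`, `ipar`
#'   (umol m-2 ground s-1), `lai_sun`, `lai_shade`, `q_sun`, `q_shade`
#'   (absorbed PAR per unit leaf area, umol m-2 s-1).
#' @export
intercept_radiation <- function(geom, steps, g_fun = 0.5, scatter = 0.1,
                                ngrid = 12, f_diff = NULL) {
  n <- nrow(steps)
  if (is.null(f_diff)) f_diff <- diffuse_interception_fraction(geom, g_fun)
  out <- data.frame(f_beam = numeric(n), ipar = numeric(n),
                    lai_sun = numeric(n), lai_shade = numeric(n),
                    q_sun = numeric(n), q_shade = numeric(n))
  if (geom$lai <= 0) {
    out$lai_shade <- 0
    return(out)
  }
  for (i in seq_len(n)) {
    sb <- steps$sin_elev[i]
    fb <- if (sb > 0 && steps$par_beam[i] > 0) {
      beam_interception_fraction(geom, sb, steps$azimuth[i], g_fun, ngrid)
    } else 0
    ib <- steps$par_beam[i] * fb
    id <- steps$par_diff[i] * f_diff
    lai_sun <- if (sb > 0) min(geom$lai, fb * sb / g_fun) else 0
    lai_shade <- geom$lai - lai_sun
    q_d <- id / geom$lai
    q_scat <- scatter * ib / geom$lai
    out$f_beam[i] <- fb
    out$ipar[i] <- ib + id
    out$lai_sun[i] <- lai_sun
    out$lai_shade[i] <- lai_shade
    out$q_sun[i] <- (if (sb > 0) steps$par_beam[i] * g_fun / sb else 0) +
      q_d + q_scat
    out$q_shade[i] <- q_d + q_scat
  }
  out
}

#' Monte-Carlo ray-casting interception oracle
#'
#' Independent estimate of the beam interception fraction by casting random
#' rays upward from the ground cell through the replicated crown lattice.
#' Used to validate the quadrature model.
#'
#' @param geom A `crown_geometry`.
#' @param sin_elev,azimuth Beam direction.
#' @param nrays Number of random rays.
#' @param g_fun Leaf projection coefficient.
#' @param seed RNG seed for reproducibility.
#' @return Estimated intercepted fraction of the beam.
#' @export
ray_casting_interception <- function(geom, sin_elev, azimuth, nrays = 1e5,
                                     g_fun = 0.5, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  px <- stats::runif(nrays, -geom$spacing[1] / 2, geom$spacing[1] / 2)
  py <- stats::runif(nrays, -geom$spacing[2] / 2, geom$spacing[2] / 2)
  zc <- geom$crown_base + geom$a_v
  total <- numeric(nrays)
  for (i in -2:2) for (j in -2:2) {
    total <- total + spheroid_path_length(px, py, sin_elev, azimuth,
                                          i * geom$spacing[1],
                                          j * geom$spacing[2],
                                          zc, geom$a_h, geom$a_v)
  }
  mean(1 - exp(-g_fun * geom$lad * total))
}
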