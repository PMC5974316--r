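# Daily photochemical VOC emission potential mu_photo at the air/sea
# interface: mu_photo = t_sun * UV * F_surfactant * k_g on SML-covered
# ocean cells, zero elsewhere.

#' Photochemistry configuration
#'
#' Parameters of the emission-potential model.
#'
#' @param wind_limit Wind-speed limit for SML persistence, m s-1 (8, 10 or
#'   13 span the supported climatological range).
#' @param c_max_surfactant Normalising surfactant concentration,
#'   ug Teq L-1; the eutrophic mean (663) by default, so that
#'   `F_surfactant = 1` in the most productive waters.
#' @param u_lab Laboratory flow speed the gas-transfer factor is normalised
#'   to, m s-1 (a 200 mL min-1 interfacial flow scaled to 10 m height by a
#'   log wind profile).
#' @param a_kg,b_kg Coefficients of the cubic gas-transfer parameterisation
#'   `a + b * U10^3`.
#' @param multiply_t_sun If `TRUE` (default), day length multiplies the UV
#'   irradiance as a separate factor. Set `FALSE` when the UV input is
#'   already a daily dose, to avoid double counting.
#' @return A `photochem_config` list.
#' @export
photochem_config <- function(wind_limit = 13, c_max_surfactant = 663,
                             u_lab = 5.31e-2, a_kg = 8.2, b_kg = 0.014,
                             multiply_t_sun = TRUE) {
  if (c_max_surfactant <= 1)
    stop("`c_max_surfactant` must exceed 1 (logarithm must be positive)")
  if (u_lab <= 0) stop("`u_lab` must be positive")
  structure(list(wind_limit = wind_limit,
                 c_max_surfactant = c_max_surfactant, u_lab = u_lab,
                 a_kg = a_kg, b_kg = b_kg,
                 multiply_t_sun = isTRUE(multiply_t_sun)),
            class = "photochem_config")
}

#' Surfactant correction factor
#'
#' Photochemical VOC production decays logarithmically with decreasing
#' surfactant concentration; normalising to the maximum observed
#' concentration gives `F = ln(c) / ln(c_max)`, a fraction in (0, 1] that
#' equals 1 only at `c = c_max`. At the oligotrophic mean (320 ug Teq L-1)
#' this reduces emissions by about 11%, at the mesotrophic mean (502) by
#' about 4%.
#'
#' @param c_surfactant Surfactant concentration, ug Teq L-1 (vectorised;
#'   must lie in `(1, c_max]`).
#' @param c_max Normalising concentration, ug Teq L-1.
#' @return Dimensionless fraction(s); `NA` passes through.
#' @export
f_surfactant <- function(c_surfactant, c_max = 663) {
  if (c_max <= 1) stop("`c_max` must exceed 1")
  bad <- !is.na(c_surfactant) & (c_surfactant <= 1 | c_surfactant > c_max)
  if (any(bad))
    stop("domain error: surfactant concentration must lie in (1, c_max]")
  log(c_surfactant) / log(c_max)
}

#' Wind-dependent gas-transfer enhancement
#'
#' Cubic gas-transfer parameterisation normalised to laboratory flow
#' conditions: `k_g = (a + b*U10^3) / (a + b*U_lab^3)`. The constant term
#' keeps transfer (and hence predicted emissions) non-zero at zero wind; at
#' the 13 m s-1 SML limit the enhancement reaches a factor of about 4.75.
#'
#' @param u10 10-m wind speed, m s-1 (vectorised, non-negative; `NA` passes
#'   through).
#' @param cfg A [photochem_config()].
#' @return Dimensionless enhancement factor(s).
#' @export
k_g <- function(u10, cfg = photochem_config()) {
  if (any(u10 < 0, na.rm = TRUE))
    stop("domain error: wind speed must be non-negative")
  (cfg$a_kg + cfg$b_kg * u10^3) / (cfg$a_kg + cfg$b_kg * cfg$u_lab^3)
}

#' Day length from solar geometry
#'
#' Daylight duration at mid-month from the standard sunrise-equation
#' geometry: solar declination `delta = 23.44 deg * sin(2*pi*(284 + n)/365)`
#' with `n` the day of year, hour angle `cos(w0) = -tan(lat) * tan(delta)`
#' clamped for polar day (24 h) and polar night (0 h).
#'
#' @param lat Latitude in degrees (vectorised), `|lat| <= 90`.
#' @param month Month 1..12 (scalar or recycled against `lat`).
#' @return Day length in seconds.
#' @export
day_length <- function(lat, month) {
  if (any(abs(lat) > 90)) stop("latitude out of range")
  stopifnot(all(month %in% 1:12))
  mid_doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + mid_doy[month]) / 365)
  cosw <- -tan(lat * pi / 180) * tan(decl)
  cosw <- pmin(1, pmax(-1, cosw))
  acos(cosw) / pi * 86400
}

#' Pointwise daily photochemical emission potential
#'
#' Product of day length, UV irradiance, surfactant correction and
#' gas-transfer enhancement on SML-covered cells; exactly zero where the
#' interface is uncovered (photochemically inactive).
#'
#' @param t_sun Day length, s.
#' @param uv UV-a + UV-b irradiance, mW cm-2.
#' @param f_surf Surfactant correction fraction.
#' @param kg Gas-transfer enhancement factor.
#' @param covered Logical SML coverage.
#' @return Potential in mW s cm-2 day-1 (vectorised).
#' @export
mu_photo <- function(t_sun, uv, f_surf, kg, covered) {
  for (x in list(t_sun, uv, f_surf, kg))
    if (any(x < 0, na.rm = TRUE))
      stop("all factors of the emission potential must be non-negative")
  out <- t_sun * uv * f_surf * kg
  out[!covered] <- 0
  out
}

#' Gridded emission-potential field
#'
#' Composes the full per-cell chain on co-registered monthly fields:
#' NPP -> trophic state -> surfactant concentration -> `F_surfactant`;
#' wind -> SML mask and `k_g`; latitude/month -> day length; then
#' `mu_photo` per cell and month. Land cells are missing; uncovered ocean
#' cells are exactly zero.
#'
#' @param uv `monthly_field`, UV-a + UV-b irradiance in mW cm-2.
#' @param wind `monthly_field`, 10-m wind speed in m s-1.
#' @param npp `monthly_field`, NPP in g C m-2 day-1 (missing over land).
#' @param grid `global_grid` the fields are registered on.
#' @param cfg A [photochem_config()].
#' @return A `potential_field` with elements `mu` (`monthly_field`,
#'   mW s cm-2 day-1), `covered`, `trophic`, `grid`, `config`.
#' @export
potential_field <- function(uv, wind, npp, grid = global_grid(),
                            cfg = photochem_config()) {
  for (f in list(uv, wind, npp)) check_registration(f, grid)

  trophic <- classify_trophic(npp)
  fs <- f_surfactant(surfactant_concentration(trophic)$values,
                     cfg$c_max_surfactant)
  covered <- sml_mask(wind, cfg$wind_limit)
  kg <- k_g(wind$values, cfg)

  nlat <- length(grid$lat); nlon <- length(grid$lon)
  tsun <- array(0, c(12L, nlat, nlon))
  for (m in 1:12)
    tsun[m, , ] <- matrix(day_length(grid$lat, m), nlat, nlon)
  if (!cfg$multiply_t_sun) tsun[] <- 1

  mu <- mu_photo(tsun, uv$values, fs, kg, covered$values)
  land <- aperm(array(!grid$ocean_mask, c(nlat, nlon, 12L)), c(3, 1, 2))
  mu[land] <- NA_real_

  structure(list(
    mu = monthly_field(mu, "mu_photo", "mW s cm-2 day-1", grid$lat, grid$lon),
    covered = covered, trophic = trophic, grid = grid, config = cfg
  ), class = "potential_field")
}

#' Seasonal means of a monthly field
#'
#' Averages months into the four seasons Jan-Mar, Apr-Jun, Jul-Sep and
#' Oct-Dec used for the seasonal potential maps.
#'
#' @param field `monthly_field` (or a `potential_field`, whose `mu` is used).
#' @return Array `4 x nlat x nlon` with season names `JFM`, `AMJ`, `JAS`,
#'   `OND` on the first dimension.
#' @export
seasonal_mean <- function(field) {
  if (inherits(field, "potential_field")) field <- field$mu
  stopifnot(inherits(field, "monthly_field"))
  seasons <- list(JFM = 1:3, AMJ = 4:6, JAS = 7:9, OND = 10:12)
  out <- array(NA_real_, c(4L, dim(field$values)[2:3]),
               dimnames = list(names(seasons), NULL, NULL))
  for (s in seq_along(seasons))
    out[s, , ] <- apply(field$values[seasons[[s]], , , drop = FALSE],
                        c(2, 3), mean)
  out
}
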