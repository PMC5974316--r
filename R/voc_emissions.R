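# Species-resolved VOC emission fluxes and global totals:
# VOC_ambient = VOC_lab * mu_photo.

AVOGADRO <- 6.02214076e23
DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)  # no-leap
CARBON_MASS <- 12.011

#' VOC species description
#'
#' @param name Species name.
#' @param voc_lab_low,voc_lab_high Range of the laboratory photochemical
#'   production rate, molecules mW-1 s-1; `0 < low <= high`.
#' @param molar_mass g mol-1.
#' @param k_oh OH rate constant, cm3 molecule-1 s-1 (optional, `NA` if
#'   unknown).
#' @param unsaturated Logical; unsaturated species feed the SOA box model.
#' @param n_carbon Carbon atoms per molecule (for carbon-mass totals).
#' @return A `voc_species` list.
#' @export
species <- function(name, voc_lab_low, voc_lab_high, molar_mass,
                    k_oh = NA_real_, unsaturated = FALSE,
                    n_carbon = NA_real_) {
  if (!(voc_lab_low > 0 && voc_lab_low <= voc_lab_high))
    stop("need 0 < voc_lab_low <= voc_lab_high")
  stopifnot(molar_mass > 0)
  structure(list(name = name, voc_lab_low = voc_lab_low,
                 voc_lab_high = voc_lab_high, molar_mass = molar_mass,
                 k_oh = k_oh, unsaturated = unsaturated,
                 n_carbon = n_carbon),
            class = "voc_species")
}

#' Built-in species registry
#'
#' Laboratory production rates for isoprene are direct interfacial
#' photochemistry measurements (3.71e7 to 6.19e7 molecules mW-1 s-1). For
#' acetone and acetaldehyde only ambient flux ranges are available
#' (0.58-1.1e14 and 0.20-0.60e14 molecules cm-2 day-1); their `voc_lab`
#' entries are back-derived placeholders obtained by dividing those fluxes
#' by a reference emission potential of 5.67e4 mW s cm-2 day-1, and are
#' flagged as such in the `source` column.
#'
#' @return `data.frame`, one row per species.
#' @export
species_registry <- function() {
  mu_ref <- 5.67e4
  data.frame(
    name = c("isoprene", "acetone", "acetaldehyde"),
    voc_lab_low = c(3.71e7, 0.58e14 / mu_ref, 0.20e14 / mu_ref),
    voc_lab_high = c(6.19e7, 1.10e14 / mu_ref, 0.60e14 / mu_ref),
    molar_mass = c(68.12, 58.08, 44.05),
    k_oh = c(1.0e-10, 1.8e-13, 1.5e-11),
    unsaturated = c(TRUE, FALSE, FALSE),
    n_carbon = c(5, 3, 2),
    source = c("laboratory", "back-derived", "back-derived"),
    stringsAsFactors = FALSE
  )
}

#' Look up a registry species
#'
#' @param name Species name present in [species_registry()].
#' @return A `voc_species`.
#' @export
registry_species <- function(name) {
  reg <- species_registry()
  i <- match(name, reg$name)
  if (is.na(i)) stop(sprintf("unknown species '%s'", name))
  species(reg$name[i], reg$voc_lab_low[i], reg$voc_lab_high[i],
          reg$molar_mass[i], reg$k_oh[i], reg$unsaturated[i],
          reg$n_carbon[i])
}

#' Pointwise VOC emission flux
#'
#' `VOC_ambient = VOC_lab * mu_photo`: the laboratory production rate per
#' unit irradiance (molecules mW-1 s-1) times the daily emission potential
#' (mW s cm-2 day-1) gives an ambient flux in molecules cm-2 day-1.
#'
#' @param mu Emission potential (vectorised), mW s cm-2 day-1.
#' @param voc_lab Laboratory production rate, molecules mW-1 s-1.
#' @return Flux, molecules cm-2 day-1.
#' @export
voc_flux <- function(mu, voc_lab) {
  if (any(mu < 0, na.rm = TRUE) || any(voc_lab < 0))
    stop("emission potential and production rate must be non-negative")
  mu * voc_lab
}

#' Gridded flux fields for a species
#'
#' @param potential A `potential_field`.
#' @param sp A `voc_species` (or registry name).
#' @return List of two `monthly_field`s, `low` and `high`, in
#'   molecules cm-2 day-1.
#' @export
flux_field <- function(potential, sp) {
  stopifnot(inherits(potential, "potential_field"))
  if (is.character(sp)) sp <- registry_species(sp)
  mk <- function(rate, tag)
    monthly_field(voc_flux(potential$mu$values, rate),
                  paste0("flux_", sp$name, "_", tag),
                  "molecules cm-2 day-1",
                  potential$mu$lat, potential$mu$lon)
  list(low = mk(sp$voc_lab_low, "low"), high = mk(sp$voc_lab_high, "high"),
       species = sp)
}

#' Regional flux range
#'
#' Mean emission potential over a region and period times the laboratory
#' production-rate range: the machinery behind site-by-site comparisons of
#' calculated against observed fluxes.
#'
#' @param potential A `potential_field`.
#' @param sp A `voc_species` or registry name.
#' @param lat_range,lon_range Region bounds, degrees.
#' @param months Month subset.
#' @param area_weighted Passed to [extract_region()].
#' @return Named numeric `c(low, high)`, molecules cm-2 day-1.
#' @export
regional_flux_range <- function(potential, sp, lat_range, lon_range,
                                months = 1:12, area_weighted = TRUE) {
  stopifnot(inherits(potential, "potential_field"))
  if (is.character(sp)) sp <- registry_species(sp)
  mu_mean <- extract_region(potential$mu, potential$grid, lat_range,
                            lon_range, months, area_weighted)
  c(low = voc_flux(mu_mean, sp$voc_lab_low),
    high = voc_flux(mu_mean, sp$voc_lab_high))
}

#' Global annual emission total
#'
#' Integrates a daily flux field over ocean area and a 365-day no-leap
#' calendar and converts molecules to teragrams:
#' `sum(flux * area_cm2 * days) / N_A * M / 1e12`.
#'
#' @param flux `monthly_field`, molecules cm-2 day-1.
#' @param grid `global_grid`.
#' @param molar_mass g mol-1.
#' @return Tg yr-1.
#' @export
global_annual_total <- function(flux, grid, molar_mass) {
  check_registration(flux, grid)
  area_cm2 <- grid$cell_area * 1e4
  area_cm2[!grid$ocean_mask] <- 0
  molecules <- 0
  for (m in 1:12) {
    v <- flux$values[m, , , drop = TRUE]
    v[is.na(v)] <- 0
    molecules <- molecules + DAYS_IN_MONTH[m] * sum(v * area_cm2)
  }
  molecules / AVOGADRO * molar_mass / 1e12
}

#' Annual total range for one species
#'
#' @param potential A `potential_field`.
#' @param sp A `voc_species` or registry name.
#' @return Named numeric `c(low, high)`, Tg yr-1.
#' @export
annual_total_range <- function(potential, sp) {
  if (is.character(sp)) sp <- registry_species(sp)
  ff <- flux_field(potential, sp)
  c(low = global_annual_total(ff$low, potential$grid, sp$molar_mass),
    high = global_annual_total(ff$high, potential$grid, sp$molar_mass))
}

#' Global carbon-mass emission total
#'
#' Carbon-mass-weighted sum of the annual totals of a lumped species table:
#' each species contributes its compound-mass total multiplied by its carbon
#' mass fraction `12.011 * n_carbon / molar_mass`.
#'
#' @param potential A `potential_field`.
#' @param registry Species table as from [species_registry()] (needs
#'   `n_carbon`).
#' @return Named numeric `c(low, high)`, Tg C yr-1.
#' @export
total_carbon_emissions <- function(potential, registry = species_registry()) {
  lo <- hi <- 0
  for (i in seq_len(nrow(registry))) {
    sp <- species(registry$name[i], registry$voc_lab_low[i],
                  registry$voc_lab_high[i], registry$molar_mass[i],
                  registry$k_oh[i], registry$unsaturated[i],
                  registry$n_carbon[i])
    cf <- CARBON_MASS * sp$n_carbon / sp$molar_mass
    tot <- annual_total_range(potential, sp)
    lo <- lo + cf * tot[["low"]]
    hi <- hi + cf * tot[["high"]]
  }
  c(low = lo, high = hi)
}
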