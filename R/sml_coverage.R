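# Trophic classification, surfactant assignment and wind-limited
# sea-surface-microlayer (SML) coverage.

TROPHIC_LEVELS <- c("oligotrophic", "mesotrophic", "eutrophic")
SURFACTANT_BY_TROPHIC <- c(oligotrophic = 320, mesotrophic = 502,
                           eutrophic = 663)  # ug Teq L-1

#' Trophic classification from net primary production
#'
#' Classifies each cell/month by NPP (g C m-2 day-1):
#' oligotrophic below 0.4, mesotrophic from 0.4 to 1.2 (both boundaries
#' inclusive to the mesotrophic class), eutrophic above 1.2. Cells with
#' missing NPP (land, no retrieval) are undefined.
#'
#' @param npp `monthly_field` of NPP in g C m-2 day-1, non-negative.
#' @return A `trophic_map`: integer codes 1/2/3 (`NA` undefined) with the
#'   level names in `$levels`.
#' @export
classify_trophic <- function(npp) {
  stopifnot(inherits(npp, "monthly_field"))
  if (any(npp$values < 0, na.rm = TRUE))
    stop("validation error: NPP must be non-negative where defined")
  v <- npp$values
  codes <- array(NA_integer_, dim(v))
  codes[!is.na(v)] <- 2L                 # mesotrophic: 0.4 <= NPP <= 1.2
  codes[!is.na(v) & v < 0.4] <- 1L
  codes[!is.na(v) & v > 1.2] <- 3L
  structure(list(codes = codes, levels = TROPHIC_LEVELS,
                 lat = npp$lat, lon = npp$lon),
            class = "trophic_map")
}

#' @export
print.trophic_map <- function(x, ...) {
  tab <- table(factor(x$levels[x$codes], levels = x$levels))
  cat("<trophic_map>", paste(names(tab), tab, collapse = ", "),
      sprintf("(undefined %d)\n", sum(is.na(x$codes))))
  invisible(x)
}

#' Surfactant concentration assigned by trophic state
#'
#' Maps trophic classes to mean observed surfactant concentrations in
#' Triton X equivalents: 320 (oligotrophic), 502 (mesotrophic) and
#' 663 ug Teq L-1 (eutrophic). Undefined cells stay missing.
#'
#' @param trophic A `trophic_map`.
#' @return `monthly_field` of surfactant concentration, ug Teq L-1.
#' @export
surfactant_concentration <- function(trophic) {
  stopifnot(inherits(trophic, "trophic_map"))
  v <- array(SURFACTANT_BY_TROPHIC[trophic$codes], dim(trophic$codes))
  monthly_field(v, "c_surfactant", "ug Teq L-1", trophic$lat, trophic$lon)
}

#' Wind-limited SML coverage mask
#'
#' A cell/month is SML-covered when the 10-m wind speed does not exceed the
#' chosen limit; strictly exceeding winds disrupt the microlayer by wave
#' breaking. Wind exactly at the limit counts as covered. Missing wind
#' (land) is uncovered.
#'
#' @param wind `monthly_field` of 10-m wind speed, m s-1, non-negative.
#' @param limit Wind-speed limit in m s-1; the supported climatological range
#'   of microlayer persistence is spanned by 8, 10 and 13 m s-1.
#' @return `monthly_field` of logicals (`TRUE` = covered).
#' @export
sml_mask <- function(wind, limit) {
  stopifnot(inherits(wind, "monthly_field"))
  if (!is.numeric(limit) || length(limit) != 1L || !is.finite(limit) ||
      limit <= 0)
    stop("validation error: `limit` must be a positive wind speed")
  if (any(wind$values < 0, na.rm = TRUE))
    stop("validation error: wind speed must be non-negative")
  covered <- !is.na(wind$values) & wind$values <= limit
  monthly_field(covered, sprintf("sml_covered_%g", limit), "boolean",
                wind$lat, wind$lon)
}

#' Area fraction of ocean covered by SMLs
#'
#' Area-weighted fraction of the ocean covered by the mask, averaged over
#' the selected months.
#'
#' @param mask Logical `monthly_field` from [sml_mask()].
#' @param grid `global_grid`.
#' @param months Integer subset of 1..12.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(mask, grid, months = 1:12) {
  check_registration(mask, grid)
  stopifnot(all(months %in% 1:12))
  a_ocean <- grid$cell_area
  a_ocean[!grid$ocean_mask] <- 0
  covered <- 0
  for (m in months) {
    mm <- mask$values[m, , , drop = TRUE]
    covered <- covered + sum(a_ocean[mm])
  }
  covered / (length(months) * sum(a_ocean))
}

#' Per-month coverage summary
#'
#' Convenience table of coverage fractions for each month and wind limit,
#' as exported by the `coverage` command.
#'
#' @param wind `monthly_field` of 10-m wind speed.
#' @param grid `global_grid`.
#' @param limits Numeric vector of wind limits, m s-1.
#' @return `data.frame` with columns `month`, `limit_m_s`, `coverage`.
#' @export
coverage_table <- function(wind, grid, limits = c(8, 10, 13)) {
  rows <- expand.grid(month = 1:12, limit_m_s = limits)
  rows$coverage <- mapply(function(m, l)
    coverage_fraction(sml_mask(wind, l), grid, months = m),
    rows$month, rows$limit_m_s)
  rows
}
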