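# Grid definition, regridding and regional aggregation for monthly
# global climatologies.

EARTH_RADIUS_M <- 6.371e6

#' Monthly gridded field
#'
#' Container for a named monthly climatology: a `(12, nlat, nlon)` array of
#' values on a rectilinear latitude/longitude grid, with `NA` marking missing
#' cells (land, no-retrieval, ...). All pipeline functions consume and
#' produce this class.
#'
#' @param values Numeric (or logical) array with dimensions
#'   `c(12, length(lat), length(lon))`. `NA` marks missing cells; non-missing
#'   values must be finite.
#' @param name Short variable name, e.g. `"uv"`, `"wind"`, `"npp"`.
#' @param units Units string (non-empty), e.g. `"mW cm-2"`, `"m s-1"`.
#' @param lat,lon Strictly monotone increasing cell-centre coordinates in
#'   degrees north / degrees east.
#' @return An object of class `monthly_field`.
#' @export
monthly_field <- function(values, name, units, lat, lon) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (month, lat, lon)")
  if (dim(values)[1] != 12L)
    stop("first dimension of `values` must have length 12 (months)")
  if (dim(values)[2] != length(lat) || dim(values)[3] != length(lon))
    stop("`values` dimensions do not match `lat`/`lon` lengths")
  if (!is.character(units) || length(units) != 1L || !nzchar(units))
    stop("`units` must be a non-empty string")
  check_monotone(lat, "lat")
  check_monotone(lon, "lon")
  if (is.numeric(values) && any(!is.finite(values) & !is.na(values)))
    stop("non-missing values must be finite")
  structure(
    list(values = values, name = name, units = units,
         lat = as.numeric(lat), lon = as.numeric(lon)),
    class = "monthly_field"
  )
}

check_monotone <- function(x, label) {
  if (length(x) > 1L && any(diff(x) <= 0))
    stop(sprintf("coordinate `%s` must be strictly monotone increasing", label))
  invisible(TRUE)
}

#' @export
print.monthly_field <- function(x, ...) {
  cat(sprintf("<monthly_field> %s [%s]  %d x %d x %d\n",
              x$name, x$units, dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3]))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  lat %.1f..%.1f  lon %.1f..%.1f  range %.4g..%.4g  missing %.1f%%\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              rng[1], rng[2], 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Rectilinear grid from coordinates
#'
#' Builds a grid object carrying cell-centre coordinates, per-cell spherical
#' surface areas and an ocean mask. [global_grid()] is the 1-degree
#' specialisation used throughout the pipeline.
#'
#' @param lat,lon Strictly monotone increasing cell-centre coordinates
#'   (degrees).
#' @param ocean_mask Logical `length(lat) x length(lon)` matrix, `TRUE` for
#'   ocean. Defaults to all-ocean.
#' @return An object of class `global_grid` with fields `lat`, `lon`,
#'   `cell_area` (m^2 matrix) and `ocean_mask`.
#' @export
make_grid <- function(lat, lon, ocean_mask = NULL) {
  check_monotone(lat, "lat")
  check_monotone(lon, "lon")
  if (is.null(ocean_mask))
    ocean_mask <- matrix(TRUE, length(lat), length(lon))
  if (!identical(dim(ocean_mask), c(length(lat), length(lon))))
    stop("`ocean_mask` dimensions do not match `lat`/`lon`")
  g <- structure(
    list(lat = as.numeric(lat), lon = as.numeric(lon),
         ocean_mask = ocean_mask),
    class = "global_grid"
  )
  g$cell_area <- cell_areas(g)
  g
}

#' Global 1-degree grid
#'
#' The standard working grid: 180 x 360 cell centres at half-degree offsets
#' (-89.5..89.5 degrees north, -179.5..179.5 degrees east). By default it
#' carries the synthetic pseudo-continent ocean mask (about 70% ocean, total
#' ocean area within 5% of 3.6e14 m^2), so that the whole pipeline is
#' exercisable without shoreline data; pass a real mask for production runs.
#'
#' @param ocean_mask 180 x 360 logical matrix (`TRUE` = ocean), or `NULL` for
#'   the synthetic mask.
#' @return A `global_grid` object.
#' @export
global_grid <- function(ocean_mask = synthetic_ocean_mask()) {
  make_grid(seq(-89.5, 89.5, by = 1), seq(-179.5, 179.5, by = 1), ocean_mask)
}

#' Synthetic pseudo-continent ocean mask
#'
#' Deterministic latitude/longitude rectangles standing in for the major
#' land masses. The resulting ocean fraction is about 70% of the Earth's
#' surface, close to the real ocean area, which is what the coverage and
#' global-integration machinery cares about; shorelines are intentionally
#' crude.
#'
#' @return 180 x 360 logical matrix, `TRUE` over ocean.
#' @export
synthetic_ocean_mask <- function() {
  lat <- seq(-89.5, 89.5, by = 1)
  lon <- seq(-179.5, 179.5, by = 1)
  rects <- list(                 # lat1, lat2, lon1, lon2
    c(-55, 12, -81, -53),        # south-america-like
    c(12, 68, -110, -73),        # north-america-like
    c(-34, 34, -14, 40),         # africa-like
    c(42, 65, 5, 48),            # europe-like
    c(6, 66, 54, 128),           # asia-like
    c(-38, -12, 114, 152),       # australia-like
    c(-90, -75, -180, 180),      # antarctica-like
    c(60, 80, -52, -26)          # greenland-like
  )
  land <- matrix(FALSE, 180, 360)
  for (r in rects)
    land[lat >= r[1] & lat <= r[2], lon >= r[3] & lon <= r[4]] <- TRUE
  !land
}

#' Spherical cell areas
#'
#' Area of each grid cell on a sphere of radius 6371 km:
#' `A(lat) = R^2 * dphi * dlambda * cos(lat)`, with `dphi`/`dlambda` the
#' local coordinate spacings in radians.
#'
#' @param grid A `global_grid`.
#' @return Matrix of areas in m^2, `nlat x nlon`.
#' @export
cell_areas <- function(grid) {
  dphi <- coord_spacing(grid$lat) * pi / 180
  dlam <- coord_spacing(grid$lon) * pi / 180
  a_lat <- EARTH_RADIUS_M^2 * dphi * cos(grid$lat * pi / 180)
  outer(a_lat, dlam)
}

# spacing per cell; single-cell grids get spacing 1 degree
coord_spacing <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  d <- diff(x)
  c(d[1], (d[-1] + d[-(n - 1)]) / 2, d[n - 1])[seq_len(n)]
}

#' Bilinear regridding of a monthly field
#'
#' Regrids a native-resolution field to a target grid by bilinear
#' interpolation in latitude and longitude, month by month. Weights over
#' missing stencil points are renormalised so that a target cell becomes
#' missing only when its entire 2 x 2 stencil is missing; this keeps coastal
#' cells alive when interpolating from coarse products. Target points
#' outside the source coordinate range are clamped to the boundary (constant
#' extrapolation).
#'
#' Interpolation is exact on fields affine in lat/lon and never overshoots
#' the local stencil extrema.
#'
#' @param field `monthly_field` on its native grid.
#' @param target Target `global_grid`.
#' @return `monthly_field` on the target grid.
#' @export
regrid_linear <- function(field, target) {
  stopifnot(inherits(field, "monthly_field"), inherits(target, "global_grid"))
  check_monotone(field$lat, "source lat")
  check_monotone(field$lon, "source lon")

  bw_lat <- bracket_weights(field$lat, target$lat)
  bw_lon <- bracket_weights(field$lon, target$lon)
  nlat <- length(target$lat); nlon <- length(target$lon)

  I0 <- matrix(bw_lat$i0, nlat, nlon); I1 <- matrix(bw_lat$i1, nlat, nlon)
  J0 <- matrix(bw_lon$i0, nlat, nlon, byrow = TRUE)
  J1 <- matrix(bw_lon$i1, nlat, nlon, byrow = TRUE)
  WL <- matrix(bw_lat$w, nlat, nlon)      # weight of i1
  WJ <- matrix(bw_lon$w, nlat, nlon, byrow = TRUE)

  w <- list((1 - WL) * (1 - WJ), (1 - WL) * WJ, WL * (1 - WJ), WL * WJ)
  ij <- list(cbind(c(I0), c(J0)), cbind(c(I0), c(J1)),
             cbind(c(I1), c(J0)), cbind(c(I1), c(J1)))

  out <- array(NA_real_, c(12L, nlat, nlon))
  for (m in 1:12) {
    V <- field$values[m, , , drop = TRUE]
    if (!is.matrix(V)) V <- matrix(V, length(field$lat), length(field$lon))
    num <- matrix(0, nlat, nlon); den <- matrix(0, nlat, nlon)
    for (k in 1:4) {
      v <- matrix(V[ij[[k]]], nlat, nlon)
      ok <- !is.na(v)
      num[ok] <- num[ok] + (w[[k]] * v)[ok]
      den[ok] <- den[ok] + w[[k]][ok]
    }
    res <- num / den
    res[den == 0] <- NA_real_
    out[m, , ] <- res
  }
  monthly_field(out, field$name, field$units, target$lat, target$lon)
}

# bracketing source indices and the weight of the upper neighbour for each
# target coordinate, clamped to the source range
bracket_weights <- function(src, tgt) {
  n <- length(src)
  if (n == 1L)
    return(list(i0 = rep(1L, length(tgt)), i1 = rep(1L, length(tgt)),
                w = rep(0, length(tgt))))
  i0 <- findInterval(tgt, src, rightmost.closed = TRUE)
  i0 <- pmin(pmax(i0, 1L), n - 1L)
  i1 <- i0 + 1L
  w <- (tgt - src[i0]) / (src[i1] - src[i0])
  list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
}

#' Area-weighted regional mean
#'
#' Mean of a field over a latitude/longitude box and a set of months,
#' restricted to non-missing ocean cells. Weighting by spherical cell area
#' is the default; set `area_weighted = FALSE` for a plain average.
#'
#' @param field `monthly_field` co-registered with `grid`.
#' @param grid `global_grid`.
#' @param lat_range,lon_range Length-2 numeric bounds (inclusive).
#' @param months Integer subset of 1..12.
#' @param area_weighted Logical.
#' @return Scalar mean.
#' @export
extract_region <- function(field, grid, lat_range = c(-90, 90),
                           lon_range = c(-180, 180), months = 1:12,
                           area_weighted = TRUE) {
  check_registration(field, grid)
  stopifnot(all(months %in% 1:12))
  ilat <- which(grid$lat >= min(lat_range) & grid$lat <= max(lat_range))
  ilon <- which(grid$lon >= min(lon_range) & grid$lon <= max(lon_range))
  if (length(ilat) == 0L || length(ilon) == 0L)
    stop("empty region: no grid cells inside the requested box")

  v <- field$values[months, ilat, ilon, drop = FALSE]
  w0 <- if (area_weighted) grid$cell_area[ilat, ilon, drop = FALSE]
        else matrix(1, length(ilat), length(ilon))
  w0[!grid$ocean_mask[ilat, ilon, drop = FALSE]] <- 0
  w <- aperm(array(w0, c(length(ilat), length(ilon), length(months))),
             c(3, 1, 2))
  w[is.na(v)] <- 0
  if (sum(w) == 0)
    stop("empty region: no non-missing ocean cells in the requested box/months")
  sum(w * v, na.rm = TRUE) / sum(w)
}

check_registration <- function(field, grid) {
  if (!isTRUE(all.equal(field$lat, grid$lat)) ||
      !isTRUE(all.equal(field$lon, grid$lon)))
    stop("registration error: field coordinates do not match the grid")
  invisible(TRUE)
}
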