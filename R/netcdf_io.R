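# NetCDF reader/writer for monthly fields (CF-style: month/lat/lon
# dimensions with units attributes).

#' Write a monthly field to NetCDF
#'
#' Dimensions `lon`, `lat`, `month` (1..12), one float variable carrying the
#' field's units attribute; missing cells become the variable's fill value.
#'
#' @param field A `monthly_field`.
#' @param path Output file path.
#' @param varname Variable name (defaults to the field name).
#' @param attributes Optional named list of global attributes (e.g. the
#'   generator seed).
#' @return `path`, invisibly.
#' @export
write_monthly_netcdf <- function(field, path, varname = field$name,
                                 attributes = list()) {
  stopifnot(inherits(field, "monthly_field"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dmon <- ncdf4::ncdim_def("month", "month of climatological year", 1:12)
  var <- ncdf4::ncvar_def(varname, field$units, list(dlon, dlat, dmon),
                          missval = 1e30, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(field$values, c(3, 2, 1)))
  for (a in names(attributes))
    ncdf4::ncatt_put(nc, 0, a, as.character(attributes[[a]]))
  invisible(path)
}

# recognised unit spellings and conversions to the pipeline's conventions
normalise_units <- function(u) {
  u <- tolower(gsub("[\\^*]", "", u))
  u <- gsub("/", " ", u)
  gsub("[[:space:]]+", " ", trimws(u))
}

unit_conversion <- function(from, to) {
  f <- normalise_units(from); t <- normalise_units(to)
  if (f == t) return(1)
  table <- list(
    c("w m-2", "mw cm-2", 0.1),
    c("mw m-2", "mw cm-2", 1e-4),
    c("mg c m-2 day-1", "g c m-2 day-1", 1e-3),
    c("knots", "m s-1", 0.514444)
  )
  for (row in table)
    if (f == row[1] && t == row[2]) return(as.numeric(row[3]))
  stop(sprintf("unit mismatch: file has '%s', expected '%s' (no known conversion)",
               from, to))
}

#' Read a monthly field from NetCDF
#'
#' Reads a `(lon, lat, month)` variable, checks/converts its units,
#' rotates 0..360 longitudes to the internal -180..180 convention, and
#' optionally regrids to a target grid via [regrid_linear()].
#'
#' @param path NetCDF file.
#' @param varname Variable to read.
#' @param units_expected Units the returned field must be in; compatible
#'   units found in the file (e.g. `W m-2` for `mW cm-2`) are converted,
#'   incompatible ones raise an error.
#' @param target_grid Optional `global_grid` to regrid onto.
#' @return A `monthly_field`.
#' @export
read_monthly_netcdf <- function(path, varname, units_expected = NULL,
                                target_grid = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!varname %in% names(nc$var))
    stop(sprintf("variable '%s' not found in %s (has: %s)", varname, path,
                 paste(names(nc$var), collapse = ", ")))

  dimnm <- sapply(nc$var[[varname]]$dim, function(d) d$name)
  get_dim <- function(cands) {
    i <- which(dimnm %in% cands)
    if (length(i) != 1)
      stop(sprintf("expected one of (%s) among dimensions (%s)",
                   paste(cands, collapse = ","), paste(dimnm, collapse = ",")))
    i
  }
  ilon <- get_dim(c("lon", "longitude", "x"))
  ilat <- get_dim(c("lat", "latitude", "y"))
  imon <- get_dim(c("month", "time", "t"))
  lon <- nc$var[[varname]]$dim[[ilon]]$vals
  lat <- nc$var[[varname]]$dim[[ilat]]$vals

  v <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  v <- aperm(v, c(imon, ilat, ilon))
  if (dim(v)[1] != 12L) stop("expected a 12-month climatology")

  if (any(diff(lat) < 0)) {       # north-to-south files
    lat <- rev(lat); v <- v[, rev(seq_along(lat)), , drop = FALSE]
  }
  if (max(lon) > 180) {           # rotate 0..360 to -180..180
    lon2 <- ifelse(lon > 180, lon - 360, lon)
    o <- order(lon2)
    lon <- lon2[o]; v <- v[, , o, drop = FALSE]
  }

  units <- ncdf4::ncatt_get(nc, varname, "units")
  units_str <- if (isTRUE(units$hasatt)) units$value else ""
  if (!is.null(units_expected)) {
    fac <- unit_conversion(units_str, units_expected)
    v <- v * fac
    units_str <- units_expected
  }
  field <- monthly_field(v, varname,
                         if (nzchar(units_str)) units_str else "unknown",
                         lat, lon)
  if (!is.null(target_grid) &&
      !(isTRUE(all.equal(field$lat, target_grid$lat)) &&
        isTRUE(all.equal(field$lon, target_grid$lon))))
    field <- regrid_linear(field, target_grid)
  field
}
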