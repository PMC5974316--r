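# Small in-code fixtures shared across the suite.

# tiny rectilinear grid with arbitrary coordinates, all-ocean by default
tiny_grid <- function(lat = c(-0.5, 0.5), lon = c(-0.5, 0.5),
                      ocean_mask = NULL) {
  make_grid(lat, lon, ocean_mask)
}

# constant monthly field on a grid
const_field <- function(value, grid, name = "x", units = "unitless") {
  monthly_field(array(value, c(12L, length(grid$lat), length(grid$lon))),
                name, units, grid$lat, grid$lon)
}

# field whose values are a function of (month, lat, lon)
fun_field <- function(f, grid, name = "x", units = "unitless") {
  v <- array(0, c(12L, length(grid$lat), length(grid$lon)))
  for (m in 1:12)
    v[m, , ] <- outer(grid$lat, grid$lon,
                      Vectorize(function(la, lo) f(m, la, lo)))
  monthly_field(v, name, units, grid$lat, grid$lon)
}

# independent scalar bilinear interpolation oracle (plain formula, loops)
bilinear_oracle <- function(src_lat, src_lon, V, lat0, lon0) {
  clamp_idx <- function(x, grid) {
    i <- max(which(grid <= x + 1e-12), 1)
    min(i, length(grid) - 1)
  }
  i <- clamp_idx(lat0, src_lat); j <- clamp_idx(lon0, src_lon)
  tx <- (lat0 - src_lat[i]) / (src_lat[i + 1] - src_lat[i])
  ty <- (lon0 - src_lon[j]) / (src_lon[j + 1] - src_lon[j])
  tx <- min(max(tx, 0), 1); ty <- min(max(ty, 0), 1)
  (1 - tx) * (1 - ty) * V[i, j] + (1 - tx) * ty * V[i, j + 1] +
    tx * (1 - ty) * V[i + 1, j] + tx * ty * V[i + 1, j + 1]
}

# brute-force partitioning oracle: dense scan over the absorbing mass
partition_oracle <- function(totals, cstar, seed) {
  f <- function(ca) seed + sum(totals / (1 + cstar / ca))
  lo <- max(seed, 1e-12); hi <- seed + sum(totals)
  grid1 <- exp(seq(log(lo), log(hi + 1e-12), length.out = 20000))
  r1 <- abs(vapply(grid1, f, 0) - grid1)
  c0 <- grid1[which.min(r1)]
  grid2 <- seq(c0 * 0.99, c0 * 1.01, length.out = 20000)
  r2 <- abs(vapply(grid2, f, 0) - grid2)
  ca <- grid2[which.min(r2)]
  sum(totals / (1 + cstar / ca))
}

# reference box-model scenario of the remote-marine worked case
reference_box_run <- function(duration_h = 12, dt_s = 60, cfg = vbs_config()) {
  box_run(e_flux = 4.1e9, mbl_height_m = 600, c_poa = 0.4,
          temperature_c = 20, cfg = cfg, duration_h = duration_h,
          dt_s = dt_s)
}
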