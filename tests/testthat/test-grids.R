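test_that("cell areas follow the spherical formula and close the sphere", {
  g <- global_grid()
  # equatorial cell: R^2 * (pi/180)^2 * cos(0.5 deg)
  a_eq <- 6.371e6^2 * (pi / 180)^2 * cos(0.5 * pi / 180)
  expect_equal(g$cell_area[which(g$lat == 0.5), 1], a_eq, tolerance = 1e-12)
  expect_equal(a_eq / 1.23e10, 1, tolerance = 0.01)
  # polar-to-equator ratio is the cosine ratio
  expect_equal(g$cell_area[which(g$lat == 89.5), 1] /
                 g$cell_area[which(g$lat == 0.5), 1],
               cos(89.5 * pi / 180) / cos(0.5 * pi / 180), tolerance = 1e-12)
  # closure: total area = 4 pi R^2 within 0.1%
  expect_equal(sum(g$cell_area), 4 * pi * 6.371e6^2, tolerance = 1e-3)
})

test_that("synthetic ocean mask has realistic ocean area", {
  g <- global_grid()
  ocean_area <- sum(g$cell_area[g$ocean_mask])
  expect_lt(abs(ocean_area - 3.6e14) / 3.6e14, 0.05)
  expect_equal(sum(g$cell_area[g$ocean_mask]) / sum(g$cell_area), 0.70,
               tolerance = 0.02)
})

test_that("monthly_field validates shape, units and finiteness", {
  g <- tiny_grid()
  expect_error(monthly_field(array(1, c(11, 2, 2)), "x", "u", g$lat, g$lon),
               "12")
  expect_error(const_field(1, g, units = ""), "units")
  bad <- array(1, c(12, 2, 2)); bad[1, 1, 1] <- Inf
  expect_error(monthly_field(bad, "x", "u", g$lat, g$lon), "finite")
  expect_error(make_grid(c(2, 1), c(0, 1)), "monotone")
})

test_that("regridding reproduces constants and affine fields exactly", {
  src <- tiny_grid(lat = seq(-88.75, 88.75, by = 2.5),
                   lon = seq(-178.75, 178.75, by = 2.5))
  tgt <- global_grid()
  expect_equal(regrid_linear(const_field(3.7, src), tgt)$values,
               const_field(3.7, tgt)$values)
  a <- 0.31
  lin <- fun_field(function(m, la, lo) a * la, src)
  out <- regrid_linear(lin, tgt)
  interior <- tgt$lat >= min(src$lat) & tgt$lat <= max(src$lat)
  expect_equal(out$values[5, interior, 10], a * tgt$lat[interior],
               tolerance = 1e-12)
})

test_that("regridding matches a scalar bilinear oracle and never overshoots", {
  src_lat <- seq(0, 10, by = 2.5); src_lon <- seq(0, 10, by = 2.5)
  V <- outer(seq_along(src_lat), seq_along(src_lon),
             function(i, j) (i + j) %% 2)       # checkerboard
  src <- monthly_field(aperm(array(V, c(5, 5, 12)), c(3, 1, 2)),
                       "chk", "u", src_lat, src_lon)
  tgt <- make_grid(seq(0.5, 9.5, by = 1), seq(0.5, 9.5, by = 1))
  out <- regrid_linear(src, tgt)
  expect_true(all(out$values >= 0 & out$values <= 1))
  for (i in c(1, 4, 7)) for (j in c(2, 5, 9))
    expect_equal(out$values[3, i, j],
                 bilinear_oracle(src_lat, src_lon, V, tgt$lat[i], tgt$lon[j]),
                 tolerance = 1e-12)
})

test_that("regridding renormalises weights over missing stencil points", {
  src_lat <- c(0, 1); src_lon <- c(0, 1)
  V <- array(NA_real_, c(12, 2, 2))
  V[, 1, 1] <- 2; V[, 2, 1] <- 4            # right column all missing
  src <- monthly_field(V, "x", "u", src_lat, src_lon)
  tgt <- make_grid(0.5, 0.5)
  out <- regrid_linear(src, tgt)
  expect_equal(out$values[1, 1, 1], 3)      # mean of the two valid corners
  src_all_na <- monthly_field(array(NA_real_, c(12, 2, 2)), "x", "u",
                              src_lat, src_lon)
  expect_true(all(is.na(regrid_linear(src_all_na, tgt)$values)))
  expect_error(regrid_linear(
    structure(list(values = V, name = "x", units = "u",
                   lat = c(1, 0), lon = src_lon), class = "monthly_field"),
    tgt), "monotone")
})

test_that("regional means average correctly and reject empty selections", {
  g <- tiny_grid(lat = c(0.5, 1.5), lon = c(0.5))
  f <- fun_field(function(m, la, lo) ifelse(la < 1, 2, 4), g)
  # equal areas up to cos(lat); unweighted gives exactly 3
  expect_equal(extract_region(f, g, c(0, 2), c(0, 1), area_weighted = FALSE), 3)
  expect_equal(extract_region(f, g, c(0, 2), c(0, 1)), 3, tolerance = 1e-4)
  expect_equal(extract_region(const_field(7.7, g), g, c(0, 2), c(0, 1)), 7.7)
  # mean bounded by selected extremes
  expect_gt(extract_region(f, g, c(0, 2), c(0, 1)), 2)
  expect_lt(extract_region(f, g, c(0, 2), c(0, 1)), 4)
  expect_error(extract_region(f, g, c(50, 60), c(0, 1)), "empty region")
  expect_error(extract_region(const_field(NA_real_, g), g, c(0, 2), c(0, 1)),
               "empty region")
})
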