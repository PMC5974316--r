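test_that("surfactant correction matches ln(c)/ln(c_max) and its bounds", {
  expect_equal(f_surfactant(663, 663), 1.0)
  expect_equal(f_surfactant(320, 663), log(320) / log(663))
  expect_equal(f_surfactant(320, 663), 0.888, tolerance = 1e-3)
  expect_equal(f_surfactant(502, 663), 0.957, tolerance = 1e-3)
  cs <- seq(2, 663, length.out = 50)
  expect_true(all(f_surfactant(cs, 663) > 0 & f_surfactant(cs, 663) <= 1))
  expect_true(all(diff(f_surfactant(cs, 663)) > 0))  # monotone in c
  expect_equal(sum(f_surfactant(cs, 663) == 1), 1)   # only at c_max
  expect_error(f_surfactant(1, 663), "domain")
  expect_error(f_surfactant(700, 663), "domain")
})

test_that("gas-transfer factor is normalised, non-zero at calm and ~4.75 at 13", {
  cfg <- photochem_config()
  expect_equal(k_g(cfg$u_lab, cfg), 1.0)
  expect_equal(k_g(0, cfg), 1.0, tolerance = 1e-6)  # non-zero at zero wind
  expect_gt(k_g(0, cfg), 0.999)
  expect_equal(k_g(13, cfg), (8.2 + 0.014 * 13^3) / (8.2 + 0.014 * 5.31e-2^3))
  expect_equal(k_g(13, cfg), 4.75, tolerance = 1e-3)
  expect_error(k_g(-1, cfg), "domain")
})

test_that("day length follows the sunrise-equation geometry", {
  # independent oracle: plain transcription of the sunrise equation
  oracle <- function(lat, doy) {
    d <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
    x <- min(1, max(-1, -tan(lat * pi / 180) * tan(d)))
    acos(x) / pi * 86400
  }
  expect_equal(day_length(0, 3), 43200)
  expect_equal(day_length(0, 9), 43200)
  expect_equal(day_length(80, 12), 0)          # polar night
  expect_equal(day_length(-80, 12), 86400)     # polar day
  expect_equal(day_length(45, 6), oracle(45, 166))
  expect_equal(day_length(45, 6) / 5.6e4, 1, tolerance = 0.01)
  expect_equal(day_length(c(-30, 60), 4), c(oracle(-30, 105), oracle(60, 105)))
  expect_error(day_length(95, 1), "latitude")
})

test_that("pointwise potential is the product of its factors, gated by coverage", {
  expect_equal(mu_photo(4.32e4, 2.0, 0.888, 1.0, TRUE), 7.672e4,
               tolerance = 1e-3)
  expect_equal(mu_photo(4.32e4, 0, 0.888, 1.0, TRUE), 0)
  expect_equal(mu_photo(4.32e4, 2.0, 0.888, 3.2, FALSE), 0)
  expect_error(mu_photo(-1, 1, 1, 1, TRUE), "non-negative")
})

test_that("gridded potential composes the chain cell by cell", {
  g <- tiny_grid(lat = c(0.5, 45.5), lon = c(10.5, 20.5))
  uv <- const_field(2.0, g, "uv", "mW cm-2")
  wind <- fun_field(function(m, la, lo) ifelse(lo < 15, 5, 14), g,
                    "wind", "m s-1")
  npp <- const_field(0.2, g, "npp", "g C m-2 day-1")   # oligotrophic
  pf <- potential_field(uv, wind, npp, g, photochem_config(wind_limit = 13))
  cfg <- photochem_config()
  # covered cell: hand-computed product
  expect_equal(pf$mu$values[3, 1, 1],
               day_length(0.5, 3) * 2.0 * f_surfactant(320, 663) *
                 k_g(5, cfg))
  expect_true(all(pf$mu$values[, , 2] == 0))   # wind above limit
  expect_error(potential_field(uv, wind, const_field(0.2, tiny_grid()), g),
               "registration")
})

test_that("potential is monotone in the wind limit and zero without UV or wind", {
  g <- global_grid()
  clim <- synth_climatology(synth_config(seed = 11), g)
  pf <- function(l) potential_field(clim$uv, clim$wind, clim$npp, g,
                                    photochem_config(wind_limit = l))$mu$values
  p8 <- pf(8); p13 <- pf(13)
  ok <- !is.na(p8)
  expect_true(all(p13[ok] >= p8[ok]))
  expect_true(all(p8[ok] >= 0))
  # storms everywhere -> no potential anywhere
  gale <- const_field(20, g, "wind", "m s-1")
  pg <- potential_field(clim$uv, gale, clim$npp, g)$mu$values
  expect_true(all(pg[!is.na(pg)] == 0))
})

test_that("day-length switch turns the t_sun factor off", {
  g <- tiny_grid()
  uv <- const_field(2.0, g, "uv", "mW cm-2")
  wind <- const_field(5, g, "wind", "m s-1")
  npp <- const_field(2.0, g, "npp", "g C m-2 day-1")
  with_t <- potential_field(uv, wind, npp, g, photochem_config())
  without <- potential_field(uv, wind, npp, g,
                             photochem_config(multiply_t_sun = FALSE))
  expect_equal(with_t$mu$values[1, 1, 1] / without$mu$values[1, 1, 1],
               day_length(g$lat[1], 1))
})

test_that("seasonal means aggregate the right month blocks", {
  g <- tiny_grid()
  f <- fun_field(function(m, la, lo) m, g)
  s <- seasonal_mean(f)
  expect_equal(unname(s[, 1, 1]), c(2, 5, 8, 11))
  expect_equal(rownames(s), c("JFM", "AMJ", "JAS", "OND"))
})
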