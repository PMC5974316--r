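test_that("saturation concentrations shift with temperature as configured", {
  expect_equal(cstar_at_t(0:2, 300), 10^(0:2))            # reference T
  expect_equal(cstar_at_t(0:2, 250, use_dhvap = FALSE), 10^(0:2))
  # full Clausius-Clapeyron expression at 288 K, 30 kJ/mol
  expected <- (300 / 288) * exp((30000 / 8.314462618) * (1 / 300 - 1 / 288))
  expect_equal(cstar_at_t(0, 288), expected)
  expect_equal(cstar_at_t(0, 288), 0.63, tolerance = 0.01)
  expect_lt(cstar_at_t(0, 288), 1)   # colder -> less volatile
  expect_error(cstar_at_t(0, -5), "temperature_k")
})

test_that("vbs_config validates yields and bin ordering", {
  expect_error(vbs_config(alpha = rep(0.1, 3)), "equal length")
  expect_error(vbs_config(alpha = c(rep(0, 9), -0.1)), "non-negative")
  expect_error(vbs_config(log10_cstar_300k = c(1, 1, 2),
                          alpha = c(0, 0, 0)), "increasing")
})

test_that("partitioning solves the single-bin closed form exactly", {
  # supersaturated: C_OA = total - C*
  eq <- partition_equilibrium(2, 1, 0)
  expect_equal(eq$c_oa_secondary, 1)
  expect_equal(eq$gas, 1)
  # subsaturated: nothing condenses without a seed
  eq2 <- partition_equilibrium(0.5, 1, 0)
  expect_equal(eq2$c_oa_secondary, 0)
  expect_equal(eq2$gas, 0.5)
  # all-zero totals
  eq3 <- partition_equilibrium(rep(0, 10), 10^(-3:6), 0.4)
  expect_equal(eq3$particle, rep(0, 10))
})

test_that("partitioning matches a brute-force absorbing-mass scan", {
  set.seed(42)
  cstar <- 10^(-3:6)
  for (rep in 1:20) {
    totals <- runif(10, 0, 2) * 10^runif(10, -2, 1)
    seed_abs <- runif(1, 1e-3, 1)
    eq <- partition_equilibrium(totals, cstar, seed_abs)
    oracle <- partition_oracle(totals, cstar, seed_abs)
    expect_equal(eq$c_oa_secondary, oracle, tolerance = 1e-4)
    # conservation, bounds, monotone xi
    expect_equal(eq$gas + eq$particle, totals, tolerance = 1e-12)
    expect_true(all(eq$xi >= 0 & eq$xi <= 1))
    expect_true(all(diff(eq$xi) <= 0))   # decreasing in C*
  }
})

test_that("box stepping follows the explicit update and conserves mass", {
  cfg <- vbs_config()
  s0 <- box_state(0.4)
  # nothing in, nothing happens
  s <- box_step(s0, 60, 0, 6e4, cfg)
  expect_equal(s$c_voc, 0)
  expect_equal(sum(s$gas) + sum(s$particle), 0)
  # one step from zero: C_voc = dt * E / h
  s1 <- box_step(s0, 60, 4.1e9, 6e4, cfg)
  expect_equal(s1$c_voc, 60 * 4.1e9 / 6e4)
  # mass closure per step: product increase = sum(alpha) * oxidised mass
  s2 <- box_step(s1, 60, 4.1e9, 6e4, cfg)
  k <- cfg$k_oh * cfg$c_oh
  dm <- 60 * k * s1$c_voc * cfg$mw_voc / 6.02214076e23 * 1e12
  expect_equal(sum(s2$gas) + sum(s2$particle),
               sum(s1$gas) + sum(s1$particle) + sum(cfg$alpha) * dm)
  # stability guard
  expect_error(box_step(s0, 1e4, 4.1e9, 6e4, vbs_config(k_oh = 1e-9)),
               "step-size")
})

test_that("the precursor approaches its analytic steady state monotonically", {
  ts <- reference_box_run(duration_h = 12, dt_s = 60)
  css <- steady_state_voc(4.1e9, 600)
  expect_true(all(diff(ts$c_voc) >= 0))
  expect_true(all(ts$c_voc <= css * (1 + 1e-9)))
  i8 <- which.min(abs(ts$t_h - 8))
  expect_equal(ts$c_voc[i8], css, tolerance = 0.01)   # plateau within 1%
  expect_equal(css, 4.15e8, tolerance = 0.01)
  # dOA never decreases under constant emission
  expect_true(all(diff(ts$doa) >= -1e-15))
})

test_that("halving the time step changes 12-h outputs by < 0.5%", {
  a <- reference_box_run(dt_s = 60)
  b <- reference_box_run(dt_s = 30)
  rel <- function(x, y) abs(x - y) / max(abs(y), 1e-30)
  expect_lt(rel(a$c_voc[nrow(a)], b$c_voc[nrow(b)]), 0.005)
  da <- a$doa[nrow(a)]; db <- b$doa[nrow(b)]
  if (db > 0) expect_lt(rel(da, db), 0.005)
})

test_that("mixing-ratio conversion follows the ideal gas law", {
  expect_equal(mixing_ratio(0), 0)
  n_air <- 101325 / (1.380649e-23 * 293.15) * 1e-6
  expect_equal(n_air, 2.50e19, tolerance = 0.002)
  expect_equal(mixing_ratio(4.15e8, 293.15), 4.15e8 / n_air * 1e12)
  expect_equal(mixing_ratio(4.15e8, 293.15), 16.6, tolerance = 0.01)
  expect_error(mixing_ratio(1, -3), "temperature_k")
})

test_that("contribution map responds to emissions and mixing height", {
  g <- tiny_grid(lat = c(0.5, 10.5), lon = c(0.5))
  uv <- const_field(2, g, "uv", "mW cm-2")
  wind <- const_field(5, g, "wind", "m s-1")
  npp <- const_field(2, g, "npp", "g C m-2 day-1")
  pf <- potential_field(uv, wind, npp, g)
  cfg <- vbs_config(poa_in_absorbing_mass = TRUE)

  m <- soa_contribution_map(pf, poa = 0.4, mbl_height_m = 600, cfg = cfg,
                            stride = 1, dt_s = 300)
  expect_equal(nrow(m), 2)
  expect_true(all(m$oa_increase_pct >= 0))
  # zero potential -> zero contribution
  zero_pf <- pf; zero_pf$mu$values[] <- 0
  m0 <- soa_contribution_map(zero_pf, cfg = cfg, stride = 1, dt_s = 300)
  expect_true(all(m0$oa_increase_pct == 0))
  # shallower mixed layer concentrates the products
  m_shallow <- soa_contribution_map(pf, poa = 0.4, mbl_height_m = 300,
                                    cfg = cfg, stride = 1, dt_s = 300)
  expect_true(all(m_shallow$doa >= m$doa))
  expect_gt(sum(m_shallow$doa), sum(m$doa))
})
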