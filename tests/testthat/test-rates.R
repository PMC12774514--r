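test_that("nitrification rate evaluates the tracer equation", {
  # C0 = 0, Ct = 12 nmol N, F = 0.5, dT = 24 h -> 24 nmol N L-1 d-1
  rec <- incubation_records("A", 50, "ammonium", "control",
                            f_substrate = 0.5, delta_t = 24,
                            c0_nox15 = 0, ct_nox15 = 12, dc45 = 0.1,
                            dc46 = 0.1)
  expect_equal(nitrification_rate(rec), 24.0)
  # no production
  rec$ct_nox15 <- rec$c0_nox15 <- 3
  expect_equal(nitrification_rate(rec), 0)
  # inverse scaling in F
  rec$ct_nox15 <- 12; rec$c0_nox15 <- 0
  r05 <- nitrification_rate(rec)
  rec$f_substrate <- 0.9
  expect_equal(nitrification_rate(rec), r05 * 0.5 / 0.9)
  rec$f_substrate <- 0
  expect_error(nitrification_rate(rec), "f_substrate")
})

test_that("N2O production rate counts labeled atoms with the day factor", {
  # dC45 = 0.5, dC46 = 0.25, F = 1, dT = 24 h -> 1.0 pmol N L-1 d-1
  rec <- incubation_records("A", 50, "ammonium", "control",
                            f_substrate = 1, delta_t = 24,
                            c0_nox15 = 0, ct_nox15 = 1,
                            dc45 = 0.5, dc46 = 0.25)
  expect_equal(n2o_production_rate(rec), 1.0)
  rec$dc45 <- rec$dc46 <- 0
  expect_equal(n2o_production_rate(rec), 0)
  # atom counting: pure double-labeled production is twice pure hybrid
  hyb <- dbl <- rec
  hyb$dc45 <- 0.8; dbl$dc46 <- 0.8
  expect_equal(n2o_production_rate(dbl), 2 * n2o_production_rate(hyb))
  # rates are linear in the numerator and scale with 24/delta_t
  rec$dc45 <- 0.5; rec$dc46 <- 0.25; rec$delta_t <- 12
  expect_equal(n2o_production_rate(rec), 2.0)
})

test_that("hybrid fraction is the molecule-basis 45N2O share", {
  rec <- incubation_records("A", 50, "ammonium", "control", 1, 24, 0, 1,
                            dc45 = 3, dc46 = 1)
  expect_equal(hybrid_fraction(rec), 0.75)
  rec$dc46 <- 0
  expect_equal(hybrid_fraction(rec), 1.0)
  rec$dc46 <- 3
  expect_equal(hybrid_fraction(rec), 0.5)
  rec$dc45 <- rec$dc46 <- 0
  expect_error(hybrid_fraction(rec), "undefined")
})

test_that("yield harmonizes units and behaves monotonically", {
  expect_equal(n2o_yield(1.0, 0), 0)
  expect_equal(n2o_yield(1.0, 1000), 0.5)  # 1000 pmol N = 1 nmol N
  expect_equal(n2o_yield(1.0, 10), 0.01 / 1.01)  # 0.009901...
  expect_error(n2o_yield(0, 0), "undefined")
  y <- n2o_yield(2, c(5, 10, 20, 40))
  expect_true(all(diff(y) > 0) && all(y >= 0 & y < 1))
})

test_that("LOD censoring flags at and below the thresholds", {
  rates <- compute_rates(tiny_incubation())
  rates$r_nitr <- c(0.01)
  rates$r_n2o <- c(0.30)
  flagged <- censor_lod(rates)
  expect_true(flagged$below_lod_nitr)    # 0.01 <= 0.015
  expect_false(flagged$below_lod_n2o)    # 0.30 > 0.25
  # boundary: exactly at the LOD is censored
  rates$r_nitr <- 0.015; rates$r_n2o <- 0.25
  flagged <- censor_lod(rates)
  expect_true(flagged$below_lod_nitr && flagged$below_lod_n2o)
  rates$r_nitr <- 0.015 + 1e-12; rates$r_n2o <- 0.25 + 1e-12
  flagged <- censor_lod(rates)
  expect_false(flagged$below_lod_nitr || flagged$below_lod_n2o)
})

test_that("depth integration matches closed forms and is order-invariant", {
  # constant 1 nmol L-1 d-1 over 0-100 m -> 100 umol m-2 d-1
  expect_equal(depth_integrate(c(0, 50, 100), c(1, 1, 1), 0, 100), 100)
  # linear ramp 0 -> 2 over 0-100 m -> 100
  expect_equal(depth_integrate(c(0, 100), c(0, 2), 0, 100), 100)
  # constant extrapolation beyond the measured profile
  expect_equal(depth_integrate(c(20, 80), c(1, 1), 0, 100), 100)
  # order invariance
  expect_equal(depth_integrate(c(80, 0, 20, 100), c(3, 1, 2, 1), 0, 100),
               depth_integrate(c(0, 20, 80, 100), c(1, 2, 3, 1), 0, 100))
  expect_error(depth_integrate(50, 1, 0, 100), "insufficient")
  expect_error(depth_integrate(c(0, 50), c(1, 1), 100, 0), "z_top")
})

test_that("depth integration is additive over profiles", {
  set.seed(9)
  d <- sort(runif(6, 0, 100))
  a <- runif(6); b <- runif(6)
  expect_equal(depth_integrate(d, a + b, 0, 100),
               depth_integrate(d, a, 0, 100) + depth_integrate(d, b, 0, 100))
})

test_that("substrate contribution is the urea share", {
  expect_equal(substrate_contribution(1, 1), 0.5)
  expect_equal(substrate_contribution(3, 0), 0)
  expect_equal(substrate_contribution(3, 1), 0.25)
  expect_error(substrate_contribution(0, 0), "zero total")
})

test_that("station-level integrated contributions exclude censored bottles", {
  inc <- rbind(
    tiny_incubation(r_nitr = 1, r_n2o = 10, depth = 5),
    tiny_incubation(r_nitr = 3, r_n2o = 30, depth = 100))
  inc2 <- inc
  inc2$substrate <- "urea"
  inc2$ct_nox15 <- inc$ct_nox15 / 3       # urea rates one third of ammonium
  rates <- compute_rates(rbind(inc, inc2))
  out <- integrated_contributions(rates, "r_nitr", 0, 100)
  expect_equal(out$urea_fraction, 0.25, tolerance = 1e-9)
})
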