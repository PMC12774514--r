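test_that("generators are deterministic: same seed, byte-identical CSV", {
  tr <- synthetic_truth(seed = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(gen_isotopomer_profile(tr, seed = 5), p1)
  write_records_csv(gen_isotopomer_profile(tr, seed = 5), p2)
  expect_identical(readLines(p1), readLines(p2))
  write_records_csv(gen_paired_experiment(tr, seed = 5), p1)
  write_records_csv(gen_paired_experiment(tr, seed = 5), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noise-free profile recovers the microbial endmember exactly", {
  tr <- synthetic_truth(seed = 2)
  prof <- gen_isotopomer_profile(tr, noise_scale = 0, seed = 2)
  for (s in c("d15n_bulk", "d18o", "sp")) {
    fit <- suppressWarnings(fit_keeling(prof, s, "surface"))  # perfect fit
    expect_equal(fit$intercept, unname(tr$delta_micro[s]), tolerance = 1e-9)
  }
  # subsurface records sit exactly on the forward model
  sub <- prof[prof$layer == "subsurface", ]
  for (s in c("d15n_bulk", "d18o", "sp")) {
    expect_equal(sub[[s]], rep(unname(tr$delta_micro[s]), nrow(sub)),
                 tolerance = 1e-12)
  }
  expect_error(gen_isotopomer_profile(tr, n_depths = 3), "n_depths")
})

test_that("noise-free incubations invert to the true rates", {
  tr <- synthetic_truth(seed = 3)
  inc <- gen_incubation_series(tr, noise_sd = c(nox = 0, n2o = 0), seed = 3)
  rates <- compute_rates(inc)
  merged <- merge(rates, tr$rates, by = c("depth", "substrate"),
                  suffixes = c("", "_true"))
  expect_equal(merged$r_nitr, merged$r_nitr_true, tolerance = 1e-9)
  expect_equal(merged$r_n2o, merged$r_n2o_true, tolerance = 1e-9)
  expect_equal(unique(round(hybrid_fraction(inc), 9)), tr$hybrid)
})

test_that("all-hybrid truth generates no double-labeled N2O", {
  tr <- synthetic_truth(hybrid = 1, seed = 4)
  inc <- gen_incubation_series(tr, noise_sd = c(nox = 0, n2o = 0), seed = 4)
  expect_true(all(inc$dc46 == 0))
  expect_true(all(inc$dc45 > 0))
})

test_that("a truth below the detection limit is flagged on recovery", {
  rates_df <- expand.grid(depth = c(5, 25), substrate = "ammonium",
                          stringsAsFactors = FALSE)
  rates_df$r_nitr <- 0.010       # below the 0.015 nitrification LOD
  rates_df$r_n2o <- 0.10         # below the 0.25 N2O LOD
  tr <- synthetic_truth(rates = rates_df, stations = c("A", "B"), seed = 6)
  inc <- gen_incubation_series(tr, noise_sd = c(nox = 0, n2o = 0), seed = 6)
  rec <- compute_rates(inc)
  expect_true(all(rec$below_lod_nitr))
  expect_true(all(rec$below_lod_n2o))
})

test_that("label conservation guard trips on impossible rates", {
  rates_df <- data.frame(depth = 50, substrate = "ammonium",
                         r_nitr = 1e6, r_n2o = 10)
  tr <- synthetic_truth(rates = rates_df, seed = 7)
  expect_error(gen_incubation_series(tr, seed = 7), "labeled substrate pool")
})

test_that("paired generator hits the configured effects exactly at zero noise", {
  tr0 <- synthetic_truth(
    effects = list(nitrification = c(ammonium = 0, urea = 0),
                   n2o_production = c(ammonium = 0, urea = 0)), seed = 8)
  inc <- gen_paired_experiment(tr0, seed = 8, sdlog_station = 0,
                               sdlog_effect = 0, noise_sd = c(nox = 0, n2o = 0))
  pr <- suppressMessages(paired_responses(compute_rates(inc), "nitrification"))
  expect_equal(pr$pct_change, rep(0, nrow(pr)), tolerance = 1e-9)

  tr50 <- synthetic_truth(
    effects = list(nitrification = c(ammonium = -50, urea = -50),
                   n2o_production = c(ammonium = 0, urea = 0)), seed = 9)
  inc <- gen_paired_experiment(tr50, seed = 9, sdlog_station = 0,
                               sdlog_effect = 0, noise_sd = c(nox = 0, n2o = 0))
  pr <- suppressMessages(paired_responses(compute_rates(inc), "nitrification"))
  expect_equal(median(pr$pct_change), -50, tolerance = 1e-9)
})

test_that("truth serializes to JSON alongside the data", {
  tr <- synthetic_truth(seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$f), tr$f, tolerance = 1e-12)
  expect_equal(back$r, tr$r)
  expect_equal(back$hybrid, tr$hybrid)
})
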