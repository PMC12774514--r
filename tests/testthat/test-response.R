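test_that("percent change is exact and signs are as documented", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 5), -50)
  expect_equal(percent_change(10, 16.19), 61.9)
  # identity: percent_change(c, c * (1 + x)) == 100 x
  for (x in c(-0.9, -0.219, 0, 0.359, 2.5)) {
    expect_equal(percent_change(7, 7 * (1 + x)), 100 * x)
  }
  expect_error(percent_change(0, 5), "control")
})

test_that("median/IQR use linear interpolation and ignore order", {
  out <- median_iqr(c(-10, -20, -30))
  expect_equal(out, c(median = -20, q1 = -25, q3 = -15))
  expect_equal(median_iqr(c(-30, -10, -20)), out)
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_error(median_iqr(numeric(0)), ">= 1")
})

test_that("bootstrap CI is reproducible, bounded and degenerate-safe", {
  x <- c(-31, -22, -18, -12, -9, -45, -27, -3)
  ci1 <- bootstrap_median_ci(x, 2000, seed = 4)
  ci2 <- bootstrap_median_ci(x, 2000, seed = 4)
  expect_identical(ci1, ci2)
  expect_gte(ci1[["lower"]], min(x))
  expect_lte(ci1[["upper"]], max(x))
  expect_lte(ci1[["lower"]], ci1[["upper"]])
  # constant sample: zero-width interval
  expect_equal(unname(bootstrap_median_ci(rep(3.3, 10), 500, seed = 1)),
               c(3.3, 3.3))
  expect_error(bootstrap_median_ci(x, 50), "n_resamples")
  expect_error(bootstrap_median_ci(1), ">= 2")
})

test_that("leave-one-station-out matches hand enumeration", {
  resp <- data.frame(station_id = c("A", "B", "C"),
                     pct_change = c(-10, -20, -60))
  out <- leave_one_station_out(resp)
  expect_equal(out$medians$median[match(c("A", "B", "C"),
                                        out$medians$left_out)],
               c(-40, -35, -15))
  expect_equal(out$spread, c(min = -40, max = -15))
  # homogeneity: identical stations leave the median unchanged
  same <- data.frame(station_id = rep(c("A", "B", "C"), 2),
                     pct_change = -25)
  expect_true(all(leave_one_station_out(same)$medians$median == -25))
  # permutation invariance of the multiset of leave-out medians
  perm <- resp[c(3, 1, 2), ]
  expect_setequal(leave_one_station_out(perm)$medians$median,
                  out$medians$median)
  expect_error(leave_one_station_out(resp[1, ]), ">= 2 distinct")
})

test_that("pairing joins on keys and drops censored or unpaired records", {
  ctl <- compute_rates(rbind(
    tiny_incubation(r_nitr = 2, depth = 5),
    tiny_incubation(r_nitr = 2, depth = 50),
    tiny_incubation(r_nitr = 0.001, depth = 100)))  # below LOD
  trt <- compute_rates(rbind(
    tiny_incubation(r_nitr = 1, depth = 5, treatment = "acidified"),
    tiny_incubation(r_nitr = 3, depth = 50, treatment = "acidified"),
    tiny_incubation(r_nitr = 2, depth = 100, treatment = "acidified"),
    tiny_incubation(r_nitr = 2, depth = 200, treatment = "acidified")))
  rates <- rbind(ctl, trt)
  expect_message(pr <- paired_responses(rates, "nitrification"),
                 "dropped 1 unpaired record")
  expect_identical(nrow(pr), 2L)            # censored pair excluded
  expect_identical(attr(pr, "n_censored"), 1L)
  expect_equal(sort(pr$pct_change), c(-50, 50))
})

test_that("response summary ties the pieces together", {
  set.seed(21)
  resp <- data.frame(
    station_id = rep(sprintf("S%d", 1:4), each = 4),
    pct_change = rnorm(16, -20, 5))
  s <- summarize_response(resp, n_resamples = 1000, seed = 3)
  expect_identical(s$n, 16L)
  expect_true(s$ci95[["lower"]] <= s$median & s$median <= s$ci95[["upper"]])
  expect_identical(nrow(s$loso$medians), 4L)
  s_station <- summarize_response(resp, n_resamples = 1000, seed = 3,
                                  by = "station")
  expect_identical(s_station$n, 4L)
})
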