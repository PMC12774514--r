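test_that("forward model satisfies its closed-form identities", {
  tab <- default_endmembers()
  # pure source at r = 1 returns that endmember exactly
  expect_equal(forward_model(c(1, 0, 0, 0), 1, tab),
               c(tab$mean["aN", ]), tolerance = 1e-12)
  # equal mix at r = 1 is the arithmetic mean of the endmembers
  expect_equal(forward_model(rep(0.25, 4), 1, tab),
               colMeans(tab$mean), tolerance = 1e-12)
  # Rayleigh term: mixture 10 with mu = -5 at r = 0.5
  one <- endmember_table(rbind(A = c(d15n_bulk = 10, d18o = 10, sp = 10),
                               B = c(d15n_bulk = 10, d18o = 10, sp = 10)),
                         rbind(A = c(0, 0, 0), B = c(0, 0, 0)),
                         mu = c(d15n_bulk = -5, d18o = -5, sp = -5),
                         mu_sd = c(d15n_bulk = 0, d18o = 0, sp = 0))
  expect_equal(unname(forward_model(c(0.5, 0.5), 0.5, one)["d15n_bulk"]),
               10 - 5 * log(0.5), tolerance = 1e-9)  # 13.4657...
})

test_that("forward model rejects off-simplex fractions and invalid r", {
  tab <- default_endmembers()
  expect_error(forward_model(c(0.5, 0.6, -0.1, 0), 1, tab), "simplex")
  expect_error(forward_model(c(0.3, 0.3, 0.3, 0.3), 1, tab), "simplex")
  expect_error(forward_model(c(1, 0, 0, 0), 0, tab), "r must be")
  expect_error(forward_model(c(1, 0, 0, 0), 1.01, tab), "r must be")
})

test_that("Rayleigh sensitivity: d F / d ln(r) equals mu", {
  tab <- default_endmembers()
  f <- c(0.4, 0.3, 0.2, 0.1)
  h <- 1e-6
  for (r in c(0.3, 0.6, 0.9)) {
    fd <- (forward_model(f, exp(log(r) + h), tab) -
             forward_model(f, exp(log(r) - h), tab)) / (2 * h)
    expect_equal(fd, tab$mu, tolerance = 1e-8)
  }
})

test_that("log posterior matches an independently summed term oracle", {
  tab <- default_endmembers()
  obs <- mixing_observation(c(d15n_bulk = -40, d18o = 33, sp = 24))
  priors <- prior_config(dirichlet_alpha = c(2, 1, 1, 1), r_min = 0.2)
  term_oracle <- function(p) {
    E <- tab$mean + tab$sd * p$zE
    mu <- tab$mu + tab$mu_sd * p$zmu
    pred <- drop(crossprod(E, p$f)) + mu * log(p$r)
    lik <- sum(dnorm(obs$values, pred, obs$sigma, log = TRUE))
    alpha <- c(2, 1, 1, 1)
    dir <- sum((alpha - 1) * log(p$f)) + lgamma(sum(alpha)) -
      sum(lgamma(alpha))
    lik + dir + log(1 / (1 - 0.2)) +
      sum(dnorm(p$zE, log = TRUE)) + sum(dnorm(p$zmu, log = TRUE))
  }
  set.seed(31)
  for (i in 1:5) {
    e <- rexp(4)
    p1 <- list(f = e / sum(e), r = runif(1, 0.25, 1),
               zE = matrix(rnorm(12), 4), zmu = rnorm(3))
    e <- rexp(4)
    p2 <- list(f = e / sum(e), r = runif(1, 0.25, 1),
               zE = matrix(rnorm(12), 4), zmu = rnorm(3))
    expect_equal(log_posterior(p1, obs, tab, priors) -
                   log_posterior(p2, obs, tab, priors),
                 term_oracle(p1) - term_oracle(p2), tolerance = 1e-10)
  }
})

test_that("log posterior is -Inf outside the support", {
  tab <- default_endmembers()
  obs <- mixing_observation(c(d15n_bulk = -40, d18o = 33, sp = 24))
  expect_identical(log_posterior(list(f = c(0.5, 0.6, -0.1, 0), r = 1),
                                 obs, tab), -Inf)
  expect_identical(log_posterior(list(f = rep(0.25, 4), r = 0.05),
                                 obs, tab), -Inf)
})

test_that("pure-source likelihood is maximal at the true source", {
  tab <- default_endmembers()
  obs <- mixing_observation(c(tab$mean["aN", ]))
  lp <- vapply(1:4, function(i) {
    f <- numeric(4); f[i] <- 1
    log_posterior(list(f = f, r = 1), obs, tab)
  }, numeric(1))
  expect_identical(which.max(lp), 1L)
})

test_that("sampler is deterministic given the seed and closes the simplex", {
  tab <- default_endmembers()
  obs <- mixing_observation(c(d15n_bulk = -40, d18o = 33, sp = 24))
  cfg <- mcmc_config(chains = 2, iter = 1000, seed = 99)
  p1 <- suppressWarnings(sample_posterior(obs, tab, cfg))
  p2 <- suppressWarnings(sample_posterior(obs, tab, cfg))
  expect_identical(p1$draws, p2$draws)
  fsum <- rowSums(p1$draws[, 1:4])
  expect_true(all(abs(fsum - 1) <= 1e-12))
  expect_true(all(p1$draws[, "r"] > 0 & p1$draws[, "r"] <= 1))
  expect_true(p1$acceptance_rate > 0)
})

test_that("an observation at a pure endmember concentrates on that source", {
  # pure-source limit: with reduction constrained to be minor (the mixture-
  # only limit), an observation at E_aN pins f_aN. With reduction fully free
  # the Rayleigh term opens an exact-fit ridge away from the corner — that
  # behaviour is characterized in the acceptance suite (criterion 4 note).
  tab <- collapse_endmembers(default_endmembers())
  obs <- mixing_observation(c(tab$mean["aN", ]),
                            sigma = c(d15n_bulk = 0.1, d18o = 0.1, sp = 0.1))
  post <- suppressWarnings(sample_posterior(
    obs, tab, mcmc_config(chains = 2, iter = 6000, seed = 12),
    priors = prior_config(r_min = 0.95)))
  expect_gt(post$summary$mean[post$summary$parameter == "f_aN"], 0.8)
})

test_that("pathway relabelling permutes posterior summaries (MC tolerance)", {
  tab <- default_endmembers()
  perm <- c("nD", "bD", "aN", "bN")
  tabp <- endmember_table(tab$mean[perm, ], tab$sd[perm, ], tab$mu,
                          tab$mu_sd)
  obs <- mixing_observation(c(d15n_bulk = -40, d18o = 33, sp = 24))
  p1 <- suppressWarnings(sample_posterior(
    obs, tab, mcmc_config(chains = 4, iter = 20000, seed = 5)))
  p2 <- suppressWarnings(sample_posterior(
    obs, tabp, mcmc_config(chains = 4, iter = 20000, seed = 6)))
  m1 <- setNames(p1$summary$mean, p1$summary$parameter)
  m2 <- setNames(p2$summary$mean, p2$summary$parameter)
  expect_lt(max(abs(m1[paste0("f_", perm)] - m2[paste0("f_", perm)])), 0.025)
})

test_that("parameter recovery over random truths has MAE <= 0.12", {
  tab <- default_endmembers()
  set.seed(42)
  maes <- replicate(20, {
    e <- rexp(4)
    f <- e / sum(e)
    r <- runif(1, 0.1, 1)
    vals <- forward_model(f, r, tab) + rnorm(3, 0, ANALYTICAL_SIGMA)
    post <- suppressWarnings(sample_posterior(
      mixing_observation(vals), tab,
      mcmc_config(chains = 2, iter = 4000, seed = sample.int(1e6, 1))))
    mean(abs(post$summary$mean[1:4] - f))
  })
  expect_lte(mean(maes), 0.12)
})

test_that("grid oracle validates its inputs and respects symmetry", {
  tab <- table3()
  obs <- mixing_observation(c(d15n_bulk = -40, d18o = 30, sp = 20))
  expect_error(grid_posterior_oracle(obs, tab, grid_step = 0.1),
               "grid too coarse")
  # observation equidistant from two identical-prior endmembers
  sym <- collapse_endmembers(endmember_table(
    rbind(A = c(d15n_bulk = -10, d18o = 20, sp = 10),
          B = c(d15n_bulk = 10, d18o = 40, sp = 30)),
    rbind(A = c(0, 0, 0), B = c(0, 0, 0)),
    mu = c(d15n_bulk = 0, d18o = 0, sp = 0),
    mu_sd = c(d15n_bulk = 0, d18o = 0, sp = 0)))
  obs_mid <- mixing_observation(c(d15n_bulk = 0, d18o = 30, sp = 20))
  g <- grid_posterior_oracle(obs_mid, sym, 0.02, r_fixed = 1)
  expect_equal(unname(g$means["f_A"]), unname(g$means["f_B"]),
               tolerance = 0.01)
})

test_that("dataset apportionment aggregates per-sample summaries", {
  tab <- default_endmembers()
  rec <- data.frame(station_id = "A", depth = 50,
                    d15n_bulk = -40, d18o = 33, sp = 24,
                    sigma_d15n_bulk = 0.2, sigma_d18o = 0.5, sigma_sp = 1)
  app <- suppressWarnings(
    apportion_dataset(rec, tab, mcmc_config(chains = 2, iter = 2000,
                                            seed = 8)))
  f_an_sample <- app$samples$mean[app$samples$parameter == "f_aN"]
  f_an_overall <- app$overall$mean[app$overall$parameter == "f_aN"]
  expect_equal(f_an_overall, f_an_sample)
  expect_error(apportion_dataset(rec[0, ], tab), "no records")
})
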