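# Shared fixtures, built in code at test time.

ANALYTICAL_SIGMA <- c(d15n_bulk = 0.2, d18o = 0.5, sp = 1.0)

# exact two-pool surface profile: d_obs linear in 1/C by construction
two_pool_profile <- function(delta_micro = c(d15n_bulk = -10, d18o = 30,
                                             sp = 20),
                             atm = list(d15n_bulk = 6.3, d18o = 44.4,
                                        sp = 18.7, c_n2o = 7),
                             c_micro = seq(0.5, 5, length.out = 12),
                             layer = "surface") {
  c_obs <- atm$c_n2o + c_micro
  sig <- lapply(c("d15n_bulk", "d18o", "sp"), function(s) {
    (atm[[s]] * atm$c_n2o + delta_micro[[s]] * c_micro) / c_obs
  })
  isotopomer_profile(
    station_id = "T1", depth = seq_along(c_obs), layer = layer,
    c_n2o = c_obs, d15n_bulk = sig[[1]], d18o = sig[[2]], sp = sig[[3]])
}

tiny_incubation <- function(r_nitr = 2, r_n2o = 20, f = 0.8, dt = 24,
                            h = 0.75, treatment = "control",
                            station = "T1", depth = 50, replicate = 1L) {
  m <- r_n2o * f * dt / 24 / (2 - h)
  incubation_records(
    station_id = station, depth = depth, substrate = "ammonium",
    treatment = treatment, f_substrate = f, delta_t = dt,
    c0_nox15 = 0, ct_nox15 = r_nitr * f * dt / 24,
    dc45 = h * m, dc46 = (1 - h) * m, replicate = replicate)
}

# reduced endmember tables for oracle comparisons
table3 <- function(collapsed = TRUE) {
  tab <- default_endmembers()
  out <- endmember_table(tab$mean[c("aN", "nD", "bD"), ],
                         tab$sd[c("aN", "nD", "bD"), ],
                         tab$mu, tab$mu_sd)
  if (collapsed) collapse_endmembers(out) else out
}
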