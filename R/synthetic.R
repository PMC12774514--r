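# Synthetic data with recorded ground truth, emulating the statistical
# structure the analysis assumes: two-pool surface mixing for Keeling
# recovery, forward-model subsurface signatures for unmixing, tracer
# incubation bookkeeping for rate recovery, and paired control/acidified
# experiments with configured median effect sizes.

#' Ground truth for the synthetic scenario
#'
#' The defaults state the emulated cruise: eight stations, depths 5/25/50/100
#' m, triplicate 24-h incubations, 0.5 umol N L-1 tracer additions, an
#' archaeal-dominated source mixture, and the acidification effect sizes used
#' as generator defaults (-21.9% ammonium / +61.9% urea nitrification;
#' +35.9% / +38.0% N2O production).
#'
#' @param f named source fractions over the pathway set (simplex).
#' @param r residual unreduced N2O fraction in (0, 1].
#' @param table an `"endmember_table"` providing the endmember point values.
#' @param atm atmospheric pool: per-signal deltas (permil) and the
#'   atmospheric-equilibrium concentration `c_n2o` (nmol L-1).
#' @param stations station labels.
#' @param depths incubation depths, m.
#' @param rates data.frame (`depth`, `substrate`, `r_nitr` nmol N L-1 d-1,
#'   `r_n2o` pmol N L-1 d-1) of true control rates; defaults rise with depth
#'   to realistic oligotrophic maxima (~3.2 ammonium / ~0.9 urea nmol L-1
#'   d-1) with sub-percent N2O yields.
#' @param hybrid molecule-basis hybrid (45N2O) fraction of labeled N2O.
#' @param f_substrate 15N atom fraction of the substrate pool at t0.
#' @param substrate_pool_nmol total substrate pool, nmol N L-1 (tracer +
#'   ambient), used for the label-conservation guard.
#' @param effects list of per-metric named percent effects of acidification.
#' @param seed integer seed recorded with the truth.
#' @return a list of class `"synthetic_truth"`; `delta_micro` (the forward-
#'   model microbial signature implied by `f`, `r` and the table means) is
#'   computed and stored.
#' @export
synthetic_truth <- function(f = c(aN = 0.7, bN = 0.1, nD = 0.1, bD = 0.1),
                            r = 0.9,
                            table = default_endmembers(),
                            atm = list(d15n_bulk = 6.3, d18o = 44.4,
                                       sp = 18.7, c_n2o = 7.0),
                            stations = c("F01", "F02", "E01", "E02", "E03",
                                         "E04", "E05", "E06"),
                            depths = c(5, 25, 50, 100),
                            rates = NULL,
                            hybrid = 0.85,
                            f_substrate = 500 / 600,
                            substrate_pool_nmol = 600,
                            effects = list(
                              nitrification = c(ammonium = -21.9, urea = 61.9),
                              n2o_production = c(ammonium = 35.9, urea = 38.0)),
                            seed = 1L) {
  stopifnot(inherits(table, "endmember_table"))
  f <- f[table$pathways]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-9 || any(f < 0)) {
    stop("f must be a simplex over the table's pathways", call. = FALSE)
  }
  if (r <= 0 || r > 1) stop("r must be in (0, 1]", call. = FALSE)
  if (hybrid < 0 || hybrid > 1) stop("hybrid must be in [0, 1]", call. = FALSE)
  if (is.null(rates)) {
    grid <- expand.grid(depth = depths, substrate = c("ammonium", "urea"),
                        stringsAsFactors = FALSE)
    base <- ifelse(grid$substrate == "ammonium",
                   0.2 + 3.0 * (grid$depth / 100)^1.2,
                   0.05 + 0.85 * (grid$depth / 100))
    yield <- ifelse(grid$substrate == "ammonium", 0.0056, 0.0072)
    rates <- data.frame(grid, r_nitr = base,
                        r_n2o = yield / (1 - yield) * base * 1000)
  }
  structure(list(f = f, r = r, table = table, atm = atm,
                 delta_micro = forward_model(f, r, table),
                 stations = stations, depths = depths, rates = rates,
                 hybrid = hybrid, f_substrate = f_substrate,
                 substrate_pool_nmol = substrate_pool_nmol,
                 effects = effects, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Serialize a synthetic truth next to its dataset
#'
#' @param truth a `"synthetic_truth"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- truth
  out$table <- list(pathways = truth$table$pathways,
                    mean = as.data.frame(truth$table$mean),
                    sd = as.data.frame(truth$table$sd),
                    mu = as.list(truth$table$mu),
                    mu_sd = as.list(truth$table$mu_sd))
  # named vectors serialize as JSON objects, not bare arrays
  out$f <- as.list(truth$f)
  out$delta_micro <- as.list(truth$delta_micro)
  out$effects <- lapply(truth$effects, as.list)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Generate an isotopocule depth profile with known truth
#'
#' Surface records (depths 0-20 m) mix a fixed atmospheric pool with
#' increasing microbial additions whose signature is the truth's
#' `delta_micro`, so the observed signals are exactly linear in 1/[N2O] and a
#' Keeling fit on the surface layer recovers `delta_micro` (to numerical
#' precision at `noise_scale = 0`). Subsurface records carry the pure
#' forward-model signature plus noise at the analytical precisions (scaled by
#' `noise_scale`). Per-site d15N values are reconstructed from bulk and SP as
#' `alpha/beta = bulk +/- SP/2`.
#'
#' @param truth a [synthetic_truth()].
#' @param n_depths number of surface records, `>= 4`.
#' @param noise_scale multiplier on the analytical precisions (0 = noise-free).
#' @param seed integer seed; the generator is deterministic given
#'   (parameters, seed).
#' @param n_subsurface number of subsurface records (cycled over the truth's
#'   stations and 25-100 m depths).
#' @return an `"n2o_profile"` table with the truth attached as
#'   `attr(, "truth")`.
#' @export
gen_isotopomer_profile <- function(truth, n_depths = 24L, noise_scale = 1,
                                   seed = truth$seed, n_subsurface = 8L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_depths < 4L) stop("n_depths must be >= 4", call. = FALSE)
  set.seed(seed)
  sig <- DEFAULT_SIGMA * noise_scale
  noise <- function(n, s) if (s > 0) stats::rnorm(n, 0, s) else numeric(n)

  c_atm <- truth$atm$c_n2o
  c_micro <- seq(0.3, 6, length.out = n_depths)
  c_obs <- c_atm + c_micro
  surf <- data.frame(
    station_id = rep_len(truth$stations, n_depths),
    depth = seq(0, 20, length.out = n_depths), layer = "surface",
    c_n2o = c_obs, stringsAsFactors = FALSE)
  for (s in SIGNALS) {
    surf[[s]] <- (truth$atm[[s]] * c_atm + truth$delta_micro[[s]] * c_micro) /
      c_obs + noise(n_depths, sig[[s]])
  }

  subdepth <- rep_len(c(25, 50, 75, 100), n_subsurface)
  sub <- data.frame(
    station_id = rep_len(truth$stations, n_subsurface),
    depth = subdepth, layer = "subsurface",
    c_n2o = c_atm + 1 + 5 * subdepth / 100, stringsAsFactors = FALSE)
  for (s in SIGNALS) {
    sub[[s]] <- truth$delta_micro[[s]] + noise(n_subsurface, sig[[s]])
  }

  df <- rbind(surf, sub)
  df$d15n_alpha <- df$d15n_bulk + df$sp / 2
  df$d15n_beta <- df$d15n_bulk - df$sp / 2
  df$sigma_d15n_bulk <- DEFAULT_SIGMA[["d15n_bulk"]]
  df$sigma_d18o <- DEFAULT_SIGMA[["d18o"]]
  df$sigma_sp <- DEFAULT_SIGMA[["sp"]]
  out <- validate_profile(df)
  attr(out, "truth") <- truth
  out
}

# Convert true rates to the incubation bookkeeping of one bottle set.
# Labeled N2O-N accumulated over dt hours: L = r_n2o * F * dt/24 (pmol N);
# split into molecules by the hybrid fraction h: m45 = h*M, m46 = (1-h)*M,
# with M = L / (2 - h) so that m45 + 2*m46 = L.
rates_to_bottles <- function(rows, truth, delta_t, noise_sd, n_replicates) {
  if (is.null(rows$replicate)) {
    idx <- rep(seq_len(nrow(rows)), each = n_replicates)
    rows <- rows[idx, , drop = FALSE]
    rows$replicate <- rep_len(seq_len(n_replicates), nrow(rows))
  }
  n <- nrow(rows)
  idx <- seq_len(n)
  r_nitr <- rows$r_nitr[idx]
  r_n2o <- rows$r_n2o[idx]
  ct_true <- r_nitr * truth$f_substrate * delta_t / 24
  labeled_cap <- truth$f_substrate * truth$substrate_pool_nmol
  if (any(ct_true > labeled_cap)) {
    stop("generated 15N transfer exceeds the labeled substrate pool",
         call. = FALSE)
  }
  m <- r_n2o * truth$f_substrate * delta_t / 24 / (2 - truth$hybrid)
  gnoise <- function(s) if (s > 0) stats::rnorm(n, 0, s) else numeric(n)
  incubation_records(
    station_id = rows$station_id[idx], depth = rows$depth[idx],
    substrate = rows$substrate[idx], treatment = rows$treatment[idx],
    f_substrate = truth$f_substrate, delta_t = delta_t,
    c0_nox15 = gnoise(noise_sd[["nox"]]),
    ct_nox15 = ct_true + gnoise(noise_sd[["nox"]]),
    dc45 = truth$hybrid * m + gnoise(noise_sd[["n2o"]]),
    dc46 = (1 - truth$hybrid) * m + gnoise(noise_sd[["n2o"]]),
    replicate = rows$replicate)
}

#' Generate control tracer incubations with known rates
#'
#' Triplicate bottles per station/depth/substrate at the truth's control
#' rates. Default measurement noise is set so the 3-sigma rate detection
#' limits of 0.015 nmol N L-1 d-1 (nitrification, at `f_substrate = 1`,
#' 24 h) and 0.25 pmol L-1 d-1 (N2O) correspond to 3x the sd of a blank
#' (`nox` 0.005 nmol N L-1; `n2o` 0.0373 pmol L-1 per isotopologue, since the
#' N2O rate numerator dC45 + 2*dC46 has sd sqrt(5) times the per-channel sd).
#' Noise of zero makes [compute_rates()] invert the truth exactly.
#'
#' @param truth a [synthetic_truth()].
#' @param delta_t incubation duration, hours.
#' @param noise_sd named vector: `nox` (nmol N L-1) and `n2o` (pmol L-1)
#'   Gaussian measurement sds, `>= 0`.
#' @param seed integer seed.
#' @param n_replicates bottles per condition.
#' @return an `"n2o_incubation"` table with the truth attached as
#'   `attr(, "truth")`.
#' @export
gen_incubation_series <- function(truth, delta_t = 24,
                                  noise_sd = c(nox = 0.005, n2o = 0.0373),
                                  seed = truth$seed, n_replicates = 3L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (delta_t <= 0) stop("delta_t must be > 0", call. = FALSE)
  set.seed(seed)
  rows <- merge(expand.grid(station_id = truth$stations,
                            stringsAsFactors = FALSE),
                truth$rates)
  rows$treatment <- "control"
  out <- rates_to_bottles(rows, truth, delta_t, noise_sd, n_replicates)
  attr(out, "truth") <- truth
  out
}

#' Generate a paired control/acidification experiment
#'
#' Control rates are the truth's base rates with multiplicative lognormal
#' station-level scatter; acidified rates multiply the control by
#' `1 + effect/100` with additional lognormal pair-level scatter. Because the
#' scatter is lognormal (median 1), the configured percent effects are the
#' true medians of the generated percent changes.
#'
#' @param truth a [synthetic_truth()]; `truth$effects` supplies the percent
#'   effects per metric and substrate.
#' @param n_stations number of stations, `>= 2` (labels recycled from the
#'   truth or generated).
#' @param seed integer seed.
#' @param delta_t incubation duration, hours.
#' @param sdlog_station,sdlog_effect lognormal sds of the station-level rate
#'   scatter and the pair-level effect scatter.
#' @param noise_sd per-bottle measurement noise, as in
#'   [gen_incubation_series()].
#' @param n_replicates bottles per condition.
#' @return an `"n2o_incubation"` table holding both treatments, truth
#'   attached as `attr(, "truth")`.
#' @export
gen_paired_experiment <- function(truth, n_stations = 8L, seed = truth$seed,
                                  delta_t = 24, sdlog_station = 0.3,
                                  sdlog_effect = 0.25,
                                  noise_sd = c(nox = 0.005, n2o = 0.0373),
                                  n_replicates = 3L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_stations < 2L) stop("n_stations must be >= 2", call. = FALSE)
  stations <- if (n_stations <= length(truth$stations)) {
    truth$stations[seq_len(n_stations)]
  } else sprintf("S%02d", seq_len(n_stations))
  set.seed(seed)
  ctl <- merge(expand.grid(station_id = stations, stringsAsFactors = FALSE),
               truth$rates)
  st_scatter <- stats::setNames(
    exp(stats::rnorm(length(stations), 0, sdlog_station)), stations)
  ctl$r_nitr <- ctl$r_nitr * st_scatter[ctl$station_id]
  ctl$r_n2o <- ctl$r_n2o * st_scatter[ctl$station_id]
  ctl$treatment <- "control"
  # expand to bottle level before drawing effects: each replicate pair gets
  # its own lognormal effect draw, so pooled pairs are exchangeable (which is
  # what the percentile bootstrap of the pooled median assumes)
  ctl <- ctl[rep(seq_len(nrow(ctl)), each = n_replicates), , drop = FALSE]
  ctl$replicate <- rep_len(seq_len(n_replicates), nrow(ctl))

  trt <- ctl
  trt$treatment <- "acidified"
  eff_nitr <- truth$effects$nitrification[trt$substrate]
  eff_n2o <- truth$effects$n2o_production[trt$substrate]
  if (anyNA(eff_nitr) || anyNA(eff_n2o)) {
    stop("truth$effects must name every substrate", call. = FALSE)
  }
  fac_nitr <- (1 + eff_nitr / 100) * exp(stats::rnorm(nrow(trt), 0, sdlog_effect))
  fac_n2o <- (1 + eff_n2o / 100) * exp(stats::rnorm(nrow(trt), 0, sdlog_effect))
  if (any(fac_nitr < 0) || any(fac_n2o < 0)) {
    stop("invalid effects: treated rate would be negative", call. = FALSE)
  }
  trt$r_nitr <- trt$r_nitr * fac_nitr
  trt$r_n2o <- trt$r_n2o * fac_n2o

  rows <- rbind(ctl, trt)
  out <- rates_to_bottles(rows, truth, delta_t, noise_sd, n_replicates)
  attr(out, "truth") <- truth
  out
}
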