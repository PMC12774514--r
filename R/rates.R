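# 15N tracer rate equations: substrate-specific nitrification and N2O
# production rates, hybrid fraction, N2O yield, detection-limit censoring,
# trapezoidal depth integration and substrate-contribution ratios.
#
# Rates are normalized by the 15N atom fraction of the substrate pool
# (F_substrate) and converted from the incubation duration (hours) to per-day:
#   R_nitr = (1/dT) * (C_t - C_0)/F * 24              [nmol N L-1 d-1]
#   R_N2O  = (1/dT) * (dC45 + 2*dC46)/F * 24          [pmol N L-1 d-1]
# The N2O numerator counts labeled N atoms (one per 45N2O, two per 46N2O), so
# R_N2O is on an N-atom basis.

#' Detection-limit configuration
#'
#' Defaults follow the 3-sigma enrichment criterion: 0.015 nmol N L-1 d-1 for
#' nitrification and 0.25 pmol L-1 d-1 for N2O production.
#'
#' @param lod_nitr nitrification LOD, nmol N L-1 d-1.
#' @param lod_n2o N2O production LOD, pmol L-1 d-1.
#' @return a list of class `"lod_config"`.
#' @export
lod_config <- function(lod_nitr = 0.015, lod_n2o = 0.25) {
  if (lod_nitr <= 0 || lod_n2o <= 0) stop("LODs must be > 0", call. = FALSE)
  structure(list(lod_nitr = lod_nitr, lod_n2o = lod_n2o),
            class = "lod_config")
}

check_f_substrate <- function(f) {
  if (any(!(f > 0 & f <= 1))) {
    stop("f_substrate must be in (0, 1]", call. = FALSE)
  }
}

#' Nitrification rate from a tracer incubation
#'
#' Gross substrate-specific nitrification from the accumulation of 15N in the
#' NOx- pool over the incubation, normalized by the substrate 15N atom
#' fraction and scaled to per-day.
#'
#' @param rec an `"n2o_incubation"` table (vectorized over rows).
#' @return rate(s), nmol N L-1 d-1. Negative differences (instrument noise)
#'   propagate as negative rates; they are flagged by [censor_lod()]
#'   downstream rather than clipped.
#' @export
nitrification_rate <- function(rec) {
  check_f_substrate(rec$f_substrate)
  if (any(rec$delta_t <= 0)) stop("delta_t must be > 0", call. = FALSE)
  (rec$ct_nox15 - rec$c0_nox15) / rec$f_substrate / rec$delta_t * 24
}

#' N2O production rate from a tracer incubation
#'
#' Accumulation of labeled N atoms in N2O (one per 45N2O molecule, two per
#' 46N2O), normalized by the substrate 15N atom fraction and scaled to
#' per-day. Reported on an N-atom basis, pmol N L-1 d-1.
#'
#' @param rec an `"n2o_incubation"` table (vectorized over rows).
#' @return rate(s), pmol N L-1 d-1.
#' @export
n2o_production_rate <- function(rec) {
  check_f_substrate(rec$f_substrate)
  if (any(rec$delta_t <= 0)) stop("delta_t must be > 0", call. = FALSE)
  (rec$dc45 + 2 * rec$dc46) / rec$f_substrate / rec$delta_t * 24
}

#' Hybrid fraction of labeled N2O production
#'
#' Molecule-basis fraction of labeled N2O formed as 45N2O (one labeled and one
#' unlabeled N atom — the "hybrid" pairing of a 15N-derived intermediate with
#' an unlabeled N source), `dC45 / (dC45 + dC46)`.
#'
#' @param rec an `"n2o_incubation"` table (vectorized over rows).
#' @return fraction(s) in `[0, 1]`.
#' @export
hybrid_fraction <- function(rec) {
  tot <- rec$dc45 + rec$dc46
  if (any(tot <= 0)) {
    stop("hybrid fraction undefined: dc45 + dc46 must be > 0", call. = FALSE)
  }
  rec$dc45 / tot
}

#' N2O yield of nitrification
#'
#' N2O production as a proportion of the total nitrogen conversion rate,
#' `R_N2O / (R_N2O + R_nitr)` after harmonizing both rates to nmol N L-1 d-1
#' (the pmol-N2O rate already counts N atoms, so the conversion is a factor
#' of 1e-3).
#'
#' @param r_nitr nitrification rate, nmol N L-1 d-1, `>= 0`.
#' @param r_n2o N2O production rate, pmol N L-1 d-1 (N-atom basis), `>= 0`.
#' @return yield fraction(s) in `[0, 1)`.
#' @export
n2o_yield <- function(r_nitr, r_n2o) {
  if (any(r_nitr < 0) || any(r_n2o < 0)) {
    stop("yield requires nonnegative rates", call. = FALSE)
  }
  if (any(r_nitr + r_n2o == 0)) {
    stop("yield undefined when both rates are zero", call. = FALSE)
  }
  r_n2o_nmol <- r_n2o * 1e-3
  r_n2o_nmol / (r_n2o_nmol + r_nitr)
}

#' Per-bottle rates from an incubation table
#'
#' Computes nitrification and N2O production rates, the N2O yield (NA where
#' either rate is negative or both are zero), and LOD flags for every bottle.
#'
#' @param incubations an `"n2o_incubation"` table.
#' @param lod a [lod_config()].
#' @return a `data.frame` of class `"n2o_rates"` with the bottle keys plus
#'   `r_nitr`, `r_n2o`, `yield`, `below_lod_nitr`, `below_lod_n2o`.
#' @export
compute_rates <- function(incubations, lod = lod_config()) {
  incubations <- validate_incubations(incubations)
  out <- incubations[c("station_id", "depth", "substrate", "treatment",
                       "replicate")]
  out$r_nitr <- nitrification_rate(incubations)
  out$r_n2o <- n2o_production_rate(incubations)
  ok <- out$r_nitr >= 0 & out$r_n2o >= 0 & (out$r_nitr + out$r_n2o) > 0
  out$yield <- NA_real_
  out$yield[ok] <- n2o_yield(out$r_nitr[ok], out$r_n2o[ok])
  out$below_lod_nitr <- FALSE
  out$below_lod_n2o <- FALSE
  class(out) <- c("n2o_rates", "data.frame")
  censor_lod(out, lod)
}

#' Flag rates at or below the detection limit
#'
#' Sets `below_lod_nitr` / `below_lod_n2o` for rates `<=` the configured LODs
#' (a rate exactly at the LOD is censored). Censored records are retained in
#' the table — downstream summaries exclude them, but the censoring count
#' stays auditable.
#'
#' @param rates an `"n2o_rates"` table.
#' @param lod a [lod_config()].
#' @return the table with flags set.
#' @export
censor_lod <- function(rates, lod = lod_config()) {
  stopifnot(inherits(lod, "lod_config"))
  rates$below_lod_nitr <- rates$r_nitr <= lod$lod_nitr
  rates$below_lod_n2o <- rates$r_n2o <= lod$lod_n2o
  rates
}

#' Depth-integrate a rate profile
#'
#' Trapezoidal integration of a volumetric rate profile between two depths,
#' with constant extrapolation from the shallowest and deepest measured points
#' to the integration bounds. Input order is irrelevant (depths are sorted
#' internally); duplicate depths are averaged. Since
#' 1 nmol L-1 d-1 = 1 umol m-3 d-1, integrating over metres yields
#' umol m-2 d-1.
#'
#' @param depth depths, m.
#' @param rate volumetric rates at those depths, nmol L-1 d-1.
#' @param z_top,z_bottom integration bounds, m, `z_top < z_bottom`.
#' @return areal rate, umol N m-2 d-1.
#' @export
depth_integrate <- function(depth, rate, z_top = 0, z_bottom = max(depth)) {
  if (length(depth) != length(rate)) {
    stop("depth and rate must have equal length", call. = FALSE)
  }
  ok <- is.finite(depth) & is.finite(rate)
  depth <- depth[ok]; rate <- rate[ok]
  if (length(unique(depth)) < 2L) {
    stop("insufficient profile: need rates at >= 2 distinct depths",
         call. = FALSE)
  }
  if (z_top >= z_bottom) stop("z_top must be < z_bottom", call. = FALSE)
  if (anyDuplicated(depth)) {
    agg <- stats::aggregate(rate, list(depth = depth), mean)
    depth <- agg$depth; rate <- agg$x
  }
  o <- order(depth)
  depth <- depth[o]; rate <- rate[o]
  # constant extrapolation to the bounds
  if (z_top < depth[1L]) {
    depth <- c(z_top, depth); rate <- c(rate[1L], rate)
  }
  n <- length(depth)
  if (z_bottom > depth[n]) {
    depth <- c(depth, z_bottom); rate <- c(rate, rate[n])
  }
  grid <- sort(unique(c(depth[depth > z_top & depth < z_bottom],
                        z_top, z_bottom)))
  vals <- stats::approx(depth, rate, xout = grid, rule = 2)$y
  sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Urea share of a substrate-summed rate
#'
#' Fraction of the combined (ammonium + urea) depth-integrated rate driven by
#' urea, `urea / (urea + ammonium)`.
#'
#' @param integrated_ammonium,integrated_urea depth-integrated rates,
#'   umol N m-2 d-1, `>= 0`, not both zero.
#' @return fraction in `[0, 1]`.
#' @export
substrate_contribution <- function(integrated_ammonium, integrated_urea) {
  if (any(integrated_ammonium < 0) || any(integrated_urea < 0)) {
    stop("integrated rates must be >= 0", call. = FALSE)
  }
  tot <- integrated_ammonium + integrated_urea
  if (any(tot == 0)) stop("substrate contribution undefined: zero total",
                          call. = FALSE)
  integrated_urea / tot
}

#' Station-level depth-integrated substrate contributions
#'
#' For each station and treatment, averages replicate bottles per depth,
#' excludes LOD-censored bottles, depth-integrates each substrate's profile
#' and reports the urea contribution to nitrification (`r_nitr`) or N2O
#' production (`r_n2o`).
#'
#' @param rates an `"n2o_rates"` table.
#' @param metric `"r_nitr"` or `"r_n2o"`.
#' @param z_top,z_bottom integration bounds, m.
#' @return data.frame with `station_id`, `treatment`, integrated ammonium and
#'   urea rates, and `urea_fraction`.
#' @export
integrated_contributions <- function(rates, metric = c("r_nitr", "r_n2o"),
                                     z_top = 0, z_bottom = 100) {
  metric <- match.arg(metric)
  flag <- if (metric == "r_nitr") "below_lod_nitr" else "below_lod_n2o"
  keep <- !rates[[flag]]
  rates <- rates[keep, , drop = FALSE]
  combos <- unique(rates[c("station_id", "treatment")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- rates[rates$station_id == combos$station_id[i] &
                   rates$treatment == combos$treatment[i], , drop = FALSE]
    integ <- vapply(c("ammonium", "urea"), function(s) {
      ss <- sub[sub$substrate == s, , drop = FALSE]
      prof <- stats::aggregate(ss[[metric]], list(depth = ss$depth), mean)
      if (nrow(prof) < 2L) return(NA_real_)
      depth_integrate(prof$depth, prof$x, z_top, z_bottom)
    }, numeric(1))
    data.frame(station_id = combos$station_id[i],
               treatment = combos$treatment[i],
               integrated_ammonium = integ[["ammonium"]],
               integrated_urea = integ[["urea"]],
               urea_fraction = if (anyNA(integ)) NA_real_ else
                 substrate_contribution(integ[["ammonium"]], integ[["urea"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
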