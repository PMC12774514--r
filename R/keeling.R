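# Site preference and Keeling-plot estimation of the microbial N2O isotope
# endmember under two-endmember mixing with a fixed atmospheric background.
#
# Two-pool mixing,
#   C_obs = C_atm + C_micro
#   d_obs * C_obs = d_atm * C_atm + d_micro * C_micro,
# makes d_obs exactly linear in 1/C_obs:
#   d_obs = d_micro + (d_atm - d_micro) * C_atm * (1 / C_obs),
# so the y-intercept of an OLS fit of the signal against 1/[N2O] estimates the
# microbial endmember d_micro.

#' N2O site preference
#'
#' Difference in d15N between the central (alpha) and outer (beta) nitrogen
#' atoms of the linear N2O molecule, `SP = d15N_alpha - d15N_beta`.
#'
#' @param d15n_alpha,d15n_beta per-site d15N, permil; must be finite.
#' @return site preference, permil.
#' @export
site_preference <- function(d15n_alpha, d15n_beta) {
  if (length(d15n_alpha) != length(d15n_beta)) {
    stop("d15n_alpha and d15n_beta must have the same length", call. = FALSE)
  }
  if (any(!is.finite(d15n_alpha)) || any(!is.finite(d15n_beta))) {
    stop("site_preference requires finite d15n_alpha and d15n_beta",
         call. = FALSE)
  }
  d15n_alpha - d15n_beta
}

#' Keeling regression for one isotope signal
#'
#' Ordinary least squares of an isotope signal against the inverse N2O
#' concentration within one layer. The y-intercept estimates the isotopic
#' composition of the microbially added N2O; its 95% confidence interval uses
#' the t distribution on the intercept standard error. The reported p-value is
#' the two-sided test of zero slope (equivalently of zero Pearson correlation
#' between signal and 1/[N2O]).
#'
#' @param records an `"n2o_profile"` table (see [isotopomer_profile()]).
#' @param signal `"d15n_bulk"`, `"d18o"` or `"sp"`.
#' @param layer `"surface"` or `"subsurface"`; only records in this layer are
#'   used.
#' @return a list of class `"keeling_fit"` with elements `signal`, `layer`,
#'   `n`, `slope` (permil nmol L-1), `intercept` (permil, the microbial
#'   endmember estimate), `intercept_se`, `intercept_ci95`, `pearson_r`,
#'   `p_value`.
#' @export
fit_keeling <- function(records, signal = SIGNALS, layer = c("subsurface", "surface")) {
  signal <- match.arg(signal)
  layer <- match.arg(layer)
  records <- validate_profile(records)
  sub <- records[records$layer == layer, , drop = FALSE]
  y <- sub[[signal]]
  ok <- is.finite(y) & is.finite(sub$c_n2o)
  y <- y[ok]
  x <- 1 / sub$c_n2o[ok]
  n <- length(y)
  if (n < 3L) {
    stop(sprintf("insufficient data: %d usable '%s' record(s) in layer '%s' (need >= 3)",
                 n, signal, layer), call. = FALSE)
  }
  if (stats::var(x) <= 0) {
    stop("degenerate design: no variance in 1/c_n2o", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  coefs <- sm$coefficients
  intercept <- coefs["(Intercept)", "Estimate"]
  se <- coefs["(Intercept)", "Std. Error"]
  tcrit <- stats::qt(0.975, df = n - 2L)
  r <- stats::cor(x, y)
  structure(list(signal = signal, layer = layer, n = n,
                 slope = unname(coefs["x", "Estimate"]),
                 intercept = unname(intercept),
                 intercept_se = unname(se),
                 intercept_ci95 = unname(intercept + c(-1, 1) * tcrit * se),
                 pearson_r = unname(r),
                 p_value = unname(coefs["x", "Pr(>|t|)"])),
            class = "keeling_fit")
}

#' @export
print.keeling_fit <- function(x, ...) {
  cat(sprintf("Keeling fit (%s, %s layer, n = %d)\n", x$signal, x$layer, x$n))
  cat(sprintf("  intercept (microbial endmember): %.2f permil [%.2f, %.2f]\n",
              x$intercept, x$intercept_ci95[1], x$intercept_ci95[2]))
  cat(sprintf("  slope: %.3f permil nmol L-1;  Pearson r = %.3f, p = %.3g\n",
              x$slope, x$pearson_r, x$p_value))
  invisible(x)
}

#' Classify a layer as microbially or atmospherically dominated
#'
#' A significant Keeling slope (p strictly below `alpha`) indicates that the
#' isotope signal covaries with 1/[N2O], i.e. microbial addition dominates the
#' signal; otherwise the layer is treated as atmosphere-dominated. Ties at
#' `p == alpha` classify as atmosphere-dominated (strict inequality).
#'
#' @param fit a `"keeling_fit"`.
#' @param alpha significance level, default 0.05.
#' @return `"microbial_dominated"` or `"atmosphere_dominated"`.
#' @export
keeling_significance_gate <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "keeling_fit"))
  if (fit$p_value < alpha) "microbial_dominated" else "atmosphere_dominated"
}

#' Per-sample atmospheric correction of isotope signals
#'
#' Inverts the two-pool mass balance for each record given a known atmospheric
#' endmember: `d_micro = (d_obs * C_obs - d_atm * C_atm) / (C_obs - C_atm)`.
#' Records with `C_obs <= C_atm` (no resolvable microbial excess) are dropped
#' with a message.
#'
#' @param records an `"n2o_profile"` table.
#' @param atm list with the atmospheric pool: elements `d15n_bulk`, `d18o`,
#'   `sp` (permil) and `c_n2o` (nmol L-1, the atmospheric-equilibrium
#'   concentration).
#' @return a data.frame with keys, microbial excess concentration `c_micro`,
#'   corrected signals, and propagated per-signal uncertainties (analytical
#'   sigma scaled by `C_obs / C_micro`).
#' @export
atmospheric_correction <- function(records, atm) {
  records <- validate_profile(records)
  need <- c("d15n_bulk", "d18o", "sp", "c_n2o")
  if (!all(need %in% names(atm))) {
    stop("atm must supply ", paste(need, collapse = ", "), call. = FALSE)
  }
  c_micro <- records$c_n2o - atm$c_n2o
  keep <- c_micro > 0
  if (!all(keep)) {
    message(sum(!keep), " record(s) dropped in atmospheric correction: ",
            "c_n2o does not exceed the atmospheric-equilibrium concentration")
  }
  rec <- records[keep, , drop = FALSE]
  c_micro <- c_micro[keep]
  out <- data.frame(station_id = rec$station_id, depth = rec$depth,
                    layer = rec$layer, c_micro = c_micro,
                    stringsAsFactors = FALSE)
  sigma_cols <- c(d15n_bulk = "sigma_d15n_bulk", d18o = "sigma_d18o",
                  sp = "sigma_sp")
  for (s in SIGNALS) {
    out[[s]] <- (rec[[s]] * rec$c_n2o - atm[[s]] * atm$c_n2o) / c_micro
    out[[paste0("sigma_", s)]] <- rec[[sigma_cols[[s]]]] * rec$c_n2o / c_micro
  }
  out
}
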