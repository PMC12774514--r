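# Pathway endmember tables: per-pathway, per-signal isotope endmember
# means/sds plus the net isotope effects of N2O reduction. Endmember values
# are configuration data, not code; the shipped defaults are
# literature-informed and editable.

PATHWAYS <- c("aN", "bN", "nD", "bD")

#' Build a pathway endmember table
#'
#' Holds, for each N2O production pathway and each isotope signal, the
#' endmember mean and standard deviation, plus the net isotope effect of N2O
#' reduction (`mu`, permil) per signal with its sd. The sign convention for
#' `mu` follows the closed-system Rayleigh term `mu * ln(r)`: `mu` must be
#' supplied negative (the usual negative-epsilon convention) so that partial
#' reduction (`r < 1`, `ln r < 0`) enriches the residual N2O.
#'
#' @param mean,sd numeric matrices, pathways in rows, the three signals
#'   (`d15n_bulk`, `d18o`, `sp`) in columns; `sd >= 0`.
#' @param mu,mu_sd named numeric vectors over the three signals; `mu_sd >= 0`.
#' @return a list of class `"endmember_table"`.
#' @export
endmember_table <- function(mean, sd, mu, mu_sd) {
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  if (is.null(rownames(mean)) || is.null(colnames(mean))) {
    stop("mean must have pathway rownames and signal colnames", call. = FALSE)
  }
  if (!all(SIGNALS %in% colnames(mean))) {
    stop("endmember table must cover all signals: ",
         paste(SIGNALS, collapse = ", "), call. = FALSE)
  }
  mean <- mean[, SIGNALS, drop = FALSE]
  if (!identical(dim(sd), dim(mean))) {
    stop("sd must have the same dimensions as mean", call. = FALSE)
  }
  if (is.null(dimnames(sd)) || is.null(colnames(sd))) {
    dimnames(sd) <- dimnames(mean)
  } else {
    sd <- sd[rownames(mean), SIGNALS, drop = FALSE]
  }
  if (nrow(mean) < 2L) stop("need at least two pathways", call. = FALSE)
  if (any(sd < 0)) stop("endmember sds must be >= 0", call. = FALSE)
  mu <- mu[SIGNALS]; mu_sd <- mu_sd[SIGNALS]
  if (any(is.na(mu)) || any(is.na(mu_sd)) || any(mu_sd < 0)) {
    stop("mu must be given for every signal with mu_sd >= 0", call. = FALSE)
  }
  structure(list(pathways = rownames(mean), mean = mean, sd = sd,
                 mu = mu, mu_sd = mu_sd),
            class = "endmember_table")
}

#' Literature-informed default endmember table
#'
#' Default isotope endmembers for archaeal nitrification (aN), bacterial
#' nitrification (bN), nitrifier denitrification (nD) and denitrification
#' (bD), with the reduction isotope effects in the negative-epsilon
#' convention. These are representative values assembled from the pure-culture
#' and field literature on N2O isotopocules; they are defaults to be edited
#' against the user's own compilation, not authoritative constants.
#'
#' @return an `"endmember_table"`.
#' @export
default_endmembers <- function() {
  mean <- rbind(aN = c(d15n_bulk = -47, d18o = 35, sp = 30),
                bN = c(d15n_bulk = -55, d18o = 23, sp = 33),
                nD = c(d15n_bulk = -47, d18o = 13, sp = -2),
                bD = c(d15n_bulk = -15, d18o = 43, sp = 5))
  sd <- rbind(aN = c(d15n_bulk = 6, d18o = 5, sp = 4),
              bN = c(d15n_bulk = 6, d18o = 5, sp = 4),
              nD = c(d15n_bulk = 6, d18o = 5, sp = 4),
              bD = c(d15n_bulk = 5, d18o = 5, sp = 5))
  endmember_table(mean, sd,
                  mu = c(d15n_bulk = -6, d18o = -15, sp = -5),
                  mu_sd = c(d15n_bulk = 1, d18o = 2, sp = 1))
}

#' Collapse endmember uncertainty to point values
#'
#' @param table an `"endmember_table"`.
#' @return the same table with all sds set to zero (endmembers and `mu` fixed
#'   at their means). Used by the exhaustive-grid oracle.
#' @export
collapse_endmembers <- function(table) {
  stopifnot(inherits(table, "endmember_table"))
  table$sd[] <- 0
  table$mu_sd[] <- 0
  table
}

#' Read an endmember/prior configuration file
#'
#' JSON with entries `pathways` (per-pathway lists of per-signal
#' `[mean, sd]` pairs), `mu` (per-signal `[mean, sd]`), and optional `priors`
#' (`dirichlet_alpha`, `r_min`), `mcmc` (`chains`, `iter`, `burn_frac`,
#' `seed`) and `atmosphere` (`d15n_bulk`, `d18o`, `sp`, `c_n2o`) blocks. The
#' packaged example is at
#' `system.file("extdata", "endmembers_default.json", package = "isoN2O")`.
#'
#' @param path path to the JSON configuration.
#' @return a list with elements `table` (an `"endmember_table"`), `priors`,
#'   `mcmc`, `atmosphere` (the latter three possibly NULL).
#' @export
read_endmember_config <- function(path) {
  if (!file.exists(path)) {
    stop("endmember config not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$pathways) || is.null(cfg$mu)) {
    stop("endmember config must contain 'pathways' and 'mu' blocks",
         call. = FALSE)
  }
  paths <- names(cfg$pathways)
  if (!all(PATHWAYS %in% paths)) {
    stop("endmember config must define all four pathways: ",
         paste(PATHWAYS, collapse = ", "), call. = FALSE)
  }
  grab <- function(block, i) {
    t(vapply(SIGNALS, function(s) {
      v <- block[[s]]
      if (is.null(v) || length(v) != 2L) {
        stop("config entry for signal '", s, "' must be [mean, sd]",
             call. = FALSE)
      }
      as.numeric(v)
    }, numeric(2)))[, i]
  }
  mean <- t(vapply(paths, function(p) grab(cfg$pathways[[p]], 1), numeric(3)))
  sd <- t(vapply(paths, function(p) grab(cfg$pathways[[p]], 2), numeric(3)))
  colnames(mean) <- colnames(sd) <- SIGNALS
  mu_pairs <- vapply(SIGNALS, function(s) as.numeric(cfg$mu[[s]]), numeric(2))
  table <- endmember_table(mean, sd,
                           mu = stats::setNames(mu_pairs[1, ], SIGNALS),
                           mu_sd = stats::setNames(mu_pairs[2, ], SIGNALS))
  list(table = table, priors = cfg$priors, mcmc = cfg$mcmc,
       atmosphere = cfg$atmosphere)
}
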