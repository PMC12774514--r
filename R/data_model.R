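# Typed tabular records for the pipeline: isotopocule depth profiles, 15N tracer
# incubations, and derived rate tables. Records are data.frames (one row per
# record) carrying a subclass so writers/readers can enforce schemas.

PROFILE_COLS <- c("station_id", "depth", "layer", "c_n2o",
                  "d15n_bulk", "d15n_alpha", "d15n_beta", "sp", "d18o",
                  "sigma_d15n_bulk", "sigma_d18o", "sigma_sp")
INCUBATION_COLS <- c("station_id", "depth", "substrate", "treatment",
                     "f_substrate", "delta_t", "c0_nox15", "ct_nox15",
                     "dc45", "dc46", "replicate")
RATE_COLS <- c("station_id", "depth", "substrate", "treatment", "replicate",
               "r_nitr", "r_n2o", "yield", "below_lod_nitr", "below_lod_n2o")

SIGNALS <- c("d15n_bulk", "d18o", "sp")

# analytical 1-sigma precisions (permil) for bulk d15N, d18O, SP
DEFAULT_SIGMA <- c(d15n_bulk = 0.2, d18o = 0.5, sp = 1.0)

#' Build an isotopocule profile table
#'
#' One row per sampled depth, holding the dissolved N2O concentration and its
#' isotopic signals. Site preference (`sp`) is filled in as
#' `d15n_alpha - d15n_beta` when absent; when all three are supplied they must
#' be mutually consistent. Per-signal analytical precisions default to
#' 0.2 / 0.5 / 1.0 permil for bulk d15N / d18O / SP.
#'
#' @param station_id character station labels.
#' @param depth sampling depth in metres, positive downward, `>= 0`.
#' @param layer `"surface"` or `"subsurface"`; assigned by the user (the
#'   mixed-layer split is an upstream convention, not inferred here).
#' @param c_n2o dissolved N2O, nmol L-1, strictly positive.
#' @param d15n_bulk,d15n_alpha,d15n_beta,d18o,sp isotope deltas in permil
#'   (d15N vs air-N2, d18O vs VSMOW). `d15n_alpha`, `d15n_beta` and `sp` may
#'   be `NA`.
#' @param sigma_d15n_bulk,sigma_d18o,sigma_sp analytical 1-sigma precisions,
#'   permil, strictly positive.
#' @return a `data.frame` of class `"n2o_profile"`.
#' @export
isotopomer_profile <- function(station_id, depth, layer, c_n2o,
                               d15n_bulk, d15n_alpha = NA_real_,
                               d15n_beta = NA_real_, sp = NA_real_, d18o,
                               sigma_d15n_bulk = DEFAULT_SIGMA[["d15n_bulk"]],
                               sigma_d18o = DEFAULT_SIGMA[["d18o"]],
                               sigma_sp = DEFAULT_SIGMA[["sp"]]) {
  df <- data.frame(station_id = as.character(station_id),
                   depth = as.numeric(depth), layer = as.character(layer),
                   c_n2o = as.numeric(c_n2o),
                   d15n_bulk = as.numeric(d15n_bulk),
                   d15n_alpha = as.numeric(d15n_alpha),
                   d15n_beta = as.numeric(d15n_beta),
                   sp = as.numeric(sp), d18o = as.numeric(d18o),
                   sigma_d15n_bulk = as.numeric(sigma_d15n_bulk),
                   sigma_d18o = as.numeric(sigma_d18o),
                   sigma_sp = as.numeric(sigma_sp),
                   stringsAsFactors = FALSE)
  class(df) <- c("n2o_profile", "data.frame")
  validate_profile(df)
}

#' Build a tracer incubation table
#'
#' One row per bottle. `f_substrate` is the 15N atom fraction of the substrate
#' pool (tracer + ambient, on an N-atom basis) at the start of the incubation;
#' `delta_t` is the incubation time in hours. `c0_nox15`/`ct_nox15` are 15NOx-
#' concentrations (nmol N L-1) at the start/end; `dc45`/`dc46` are the
#' accumulations of 45N2O and 46N2O (pmol L-1). Small negative tracer
#' differences from instrument noise are retained (and flagged below the
#' detection limit downstream) rather than clipped.
#'
#' @param station_id,depth,replicate bottle keys.
#' @param substrate `"ammonium"` or `"urea"`.
#' @param treatment `"control"` or `"acidified"`.
#' @param f_substrate 15N atom fraction in (0, 1].
#' @param delta_t incubation duration, hours, `> 0`.
#' @param c0_nox15,ct_nox15,dc45,dc46 concentrations as described above.
#' @return a `data.frame` of class `"n2o_incubation"`.
#' @export
incubation_records <- function(station_id, depth, substrate, treatment,
                               f_substrate, delta_t, c0_nox15, ct_nox15,
                               dc45, dc46, replicate = 1L) {
  df <- data.frame(station_id = as.character(station_id),
                   depth = as.numeric(depth),
                   substrate = as.character(substrate),
                   treatment = as.character(treatment),
                   f_substrate = as.numeric(f_substrate),
                   delta_t = as.numeric(delta_t),
                   c0_nox15 = as.numeric(c0_nox15),
                   ct_nox15 = as.numeric(ct_nox15),
                   dc45 = as.numeric(dc45), dc46 = as.numeric(dc46),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  class(df) <- c("n2o_incubation", "data.frame")
  validate_incubations(df)
}

row_errors <- function(bad, msg) {
  if (!any(bad, na.rm = TRUE)) return(character(0))
  sprintf("row %d: %s", which(bad), msg)
}

fail_validation <- function(errors, what) {
  if (length(errors) > 0L) {
    stop(sprintf("invalid %s:\n%s", what,
                 paste("  -", errors, collapse = "\n")), call. = FALSE)
  }
}

#' Validate an isotopocule profile table
#'
#' Checks every stated invariant and reports all offending rows at once:
#' positive `c_n2o`, positive precisions, a valid `layer` label, depths `>= 0`,
#' and consistency of `sp` with `d15n_alpha - d15n_beta` (1e-9 permil). Rows
#' with alpha/beta but missing `sp` have `sp` filled in.
#'
#' @param df a profile table (any data.frame with the documented columns).
#' @return the validated table, classed `"n2o_profile"`, invisibly usable.
#' @export
validate_profile <- function(df) {
  missing_cols <- setdiff(PROFILE_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("profile table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[PROFILE_COLS]
  fill <- is.na(df$sp) & !is.na(df$d15n_alpha) & !is.na(df$d15n_beta)
  df$sp[fill] <- site_preference(df$d15n_alpha[fill], df$d15n_beta[fill])

  errors <- c(
    row_errors(!(df$c_n2o > 0), "c_n2o must be > 0"),
    row_errors(df$depth < 0, "depth must be >= 0"),
    row_errors(!(df$layer %in% c("surface", "subsurface")),
               "layer must be 'surface' or 'subsurface'"),
    row_errors(!(df$sigma_d15n_bulk > 0 & df$sigma_d18o > 0 & df$sigma_sp > 0),
               "analytical precisions must be > 0"),
    row_errors(!is.na(df$sp) & !is.na(df$d15n_alpha) & !is.na(df$d15n_beta) &
                 abs(df$sp - (df$d15n_alpha - df$d15n_beta)) > 1e-9,
               "sp inconsistent with d15n_alpha - d15n_beta")
  )
  fail_validation(errors, "isotopomer profile")
  class(df) <- c("n2o_profile", "data.frame")
  df
}

#' Validate an incubation table
#'
#' @param df an incubation table with the documented columns.
#' @return the validated table, classed `"n2o_incubation"`.
#' @export
validate_incubations <- function(df) {
  missing_cols <- setdiff(INCUBATION_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("incubation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[INCUBATION_COLS]
  errors <- c(
    row_errors(!(df$f_substrate > 0 & df$f_substrate <= 1),
               "f_substrate must be in (0, 1]"),
    row_errors(!(df$delta_t > 0), "delta_t must be > 0"),
    row_errors(!(df$substrate %in% c("ammonium", "urea")),
               "substrate must be 'ammonium' or 'urea'"),
    row_errors(!(df$treatment %in% c("control", "acidified")),
               "treatment must be 'control' or 'acidified'")
  )
  fail_validation(errors, "incubation records")
  class(df) <- c("n2o_incubation", "data.frame")
  df
}

read_typed_csv <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(required, names(raw))
  # optional derivables are filled by the validator, not required on disk
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  errors <- character(0)
  for (col in intersect(numeric_cols, names(raw))) {
    v <- trimws(raw[[col]])
    v[v == "" | toupper(v) == "NA"] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    errors <- c(errors,
                sprintf("row %d: non-numeric value '%s' in column '%s'",
                        which(bad), v[bad], col))
    raw[[col]] <- num
  }
  fail_validation(errors, what)
  raw
}

#' Read an isotopocule profile CSV
#'
#' Expects the documented `profiles.csv` schema (UTF-8, comma-separated, `.`
#' decimal, one header row). The `d15n_alpha`, `d15n_beta` and `sp` columns are
#' optional on disk (`sp` is derived when alpha/beta are present); sigma
#' columns default to the analytical precisions when absent. All rows are
#' validated and every violation is reported with its row number.
#'
#' @param path path to a CSV file.
#' @return a validated `"n2o_profile"` data.frame.
#' @export
read_profile_csv <- function(path) {
  required <- c("station_id", "depth", "layer", "c_n2o", "d15n_bulk", "d18o")
  numeric_cols <- setdiff(PROFILE_COLS, c("station_id", "layer"))
  raw <- read_typed_csv(path, required, numeric_cols, "profile CSV")
  defaults <- c(d15n_alpha = NA_real_, d15n_beta = NA_real_, sp = NA_real_,
                sigma_d15n_bulk = DEFAULT_SIGMA[["d15n_bulk"]],
                sigma_d18o = DEFAULT_SIGMA[["d18o"]],
                sigma_sp = DEFAULT_SIGMA[["sp"]])
  for (col in names(defaults)) {
    if (is.null(raw[[col]])) raw[[col]] <- defaults[[col]]
  }
  validate_profile(raw)
}

#' Read a tracer incubation CSV
#'
#' @param path path to a CSV file with the documented `incubations.csv` schema.
#' @return a validated `"n2o_incubation"` data.frame.
#' @export
read_incubation_csv <- function(path) {
  raw <- read_typed_csv(path, INCUBATION_COLS,
                        setdiff(INCUBATION_COLS,
                                c("station_id", "substrate", "treatment")),
                        "incubation CSV")
  raw$replicate <- as.integer(raw$replicate)
  validate_incubations(raw)
}

#' Write a record table to CSV
#'
#' Numeric fields are serialized with 15 significant digits so that a
#' write/read round trip is lossless to at least 12 significant digits. A list
#' of record tables is accepted only when all elements share the same record
#' class (they are row-bound); mixing record types is an error.
#'
#' @param records a record data.frame (`"n2o_profile"`, `"n2o_incubation"`,
#'   `"n2o_rates"`) or a list of tables of one such class.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  if (is.list(records) && !is.data.frame(records)) {
    classes <- vapply(records, function(x) class(x)[1L], character(1))
    if (length(unique(classes)) != 1L) {
      stop("cannot write a mixed list of record types: ",
           paste(unique(classes), collapse = ", "), call. = FALSE)
    }
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  out <- as.data.frame(records)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 15,
                                                scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
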