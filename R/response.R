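# Paired control-vs-acidified response statistics: percent change, median/IQR
# summaries, percentile bootstrap CIs for the median, and leave-one-station-
# out robustness checks.

#' Percent change of a treated rate relative to its control
#'
#' `100 * (treated - control) / control`; negative values mean inhibition
#' under treatment, positive values enhancement.
#'
#' @param control control rate(s), `> 0`.
#' @param treated treated rate(s).
#' @return percent change(s).
#' @export
percent_change <- function(control, treated) {
  if (any(control <= 0)) {
    stop("percent change undefined for control <= 0", call. = FALSE)
  }
  100 * (treated - control) / control
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics (type 7, the
#' R default); the convention is fixed here because IQR endpoints are
#' convention-sensitive.
#'
#' @param values numeric vector, `>= 1` value (NAs dropped).
#' @return named vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("median_iqr needs >= 1 value", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Percentile bootstrap CI for the median
#'
#' @param values numeric vector, `>= 2` values.
#' @param n_resamples bootstrap resamples, `>= 100` (default 10 000).
#' @param level confidence level, default 0.95.
#' @param seed integer seed; the interval is reproducible given the seed.
#' @return named vector `c(lower, upper)`; endpoints always lie within the
#'   sample range.
#' @export
bootstrap_median_ci <- function(values, n_resamples = 10000L, level = 0.95,
                                seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("bootstrap needs >= 2 values", call. = FALSE)
  }
  if (n_resamples < 100L) {
    stop("n_resamples must be >= 100", call. = FALSE)
  }
  set.seed(seed)
  n <- length(values)
  resamples <- matrix(sample(values, n * n_resamples, replace = TRUE),
                      nrow = n_resamples)
  meds <- row_medians(resamples)
  ci <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  c(lower = ci[1], upper = ci[2])
}

# Fast per-row medians via partial sort; equals stats::median row-wise.
row_medians <- function(m) {
  n <- ncol(m)
  k <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    vapply(seq_len(nrow(m)), function(i) {
      sort.int(m[i, ], partial = k)[k]
    }, numeric(1))
  } else {
    vapply(seq_len(nrow(m)), function(i) {
      x <- sort.int(m[i, ], partial = c(k, k + 1L))
      (x[k] + x[k + 1L]) / 2
    }, numeric(1))
  }
}

#' Pair control and acidified bottles
#'
#' Joins control and acidified rate records on (station, depth, substrate,
#' replicate) and computes the percent change for each requested metric.
#' Pairs in which either member is LOD-censored (or the control is
#' nonpositive) are excluded; unpaired records are dropped. Both exclusion
#' counts are reported via attributes and a message.
#'
#' @param rates an `"n2o_rates"` table holding both treatments.
#' @param metric `"nitrification"`, `"n2o_production"` or `"yield"`.
#' @return data.frame of class `"paired_response"` with keys,
#'   `control_value`, `treated_value`, `pct_change`; attributes
#'   `n_unpaired`, `n_censored`.
#' @export
paired_responses <- function(rates,
                             metric = c("nitrification", "n2o_production",
                                        "yield")) {
  metric <- match.arg(metric)
  col <- switch(metric, nitrification = "r_nitr",
                n2o_production = "r_n2o", yield = "yield")
  flag <- switch(metric, nitrification = "below_lod_nitr",
                 n2o_production = "below_lod_n2o", yield = NULL)
  keys <- c("station_id", "depth", "substrate", "replicate")
  ctl <- rates[rates$treatment == "control", , drop = FALSE]
  trt <- rates[rates$treatment == "acidified", , drop = FALSE]
  merged <- merge(ctl[c(keys, col, if (!is.null(flag)) flag)],
                  trt[c(keys, col, if (!is.null(flag)) flag)],
                  by = keys, suffixes = c("_control", "_treated"))
  n_unpaired <- nrow(ctl) + nrow(trt) - 2L * nrow(merged)
  if (is.null(flag)) {
    censored <- is.na(merged[[paste0(col, "_control")]]) |
      is.na(merged[[paste0(col, "_treated")]])
  } else {
    censored <- merged[[paste0(flag, "_control")]] |
      merged[[paste0(flag, "_treated")]]
  }
  usable <- merged[!censored & merged[[paste0(col, "_control")]] > 0, ,
                   drop = FALSE]
  out <- data.frame(usable[keys], metric = metric,
                    control_value = usable[[paste0(col, "_control")]],
                    treated_value = usable[[paste0(col, "_treated")]],
                    stringsAsFactors = FALSE)
  out$pct_change <- percent_change(out$control_value, out$treated_value)
  if (n_unpaired > 0L || any(censored)) {
    message(sprintf("paired_responses (%s): dropped %d unpaired record(s), %d censored/invalid pair(s)",
                    metric, n_unpaired, sum(censored)))
  }
  structure(out, n_unpaired = n_unpaired, n_censored = sum(censored),
            class = c("paired_response", "data.frame"))
}

#' Leave-one-station-out medians
#'
#' Recomputes the median percent change with each station excluded in turn;
#' the spread (min/max) across leave-outs summarizes how much any single
#' station drives the overall median.
#'
#' @param responses a `"paired_response"` table (or any data.frame with
#'   `station_id` and `pct_change`), `>= 2` distinct stations.
#' @return list with `medians` (data.frame of left-out station and resulting
#'   median), `spread` (`c(min, max)`), `overall` (all-station median).
#' @export
leave_one_station_out <- function(responses) {
  stations <- unique(responses$station_id)
  if (length(stations) < 2L) {
    stop("leave-one-station-out needs >= 2 distinct stations", call. = FALSE)
  }
  meds <- vapply(stations, function(st) {
    stats::median(responses$pct_change[responses$station_id != st])
  }, numeric(1))
  list(medians = data.frame(left_out = stations, median = unname(meds),
                            stringsAsFactors = FALSE),
       spread = c(min = min(meds), max = max(meds)),
       overall = stats::median(responses$pct_change))
}

#' Summarize paired responses
#'
#' Median and IQR of the percent changes (optionally pooling all pairs or
#' taking station medians first), with a percentile bootstrap CI for the
#' median and the leave-one-station-out spread.
#'
#' @param responses a `"paired_response"` table.
#' @param n_resamples,level,seed passed to [bootstrap_median_ci()].
#' @param by `"pooled"` (default: all pairs pooled) or `"station"` (pairs
#'   reduced to station medians first).
#' @return list with `n`, `median`, `q1`, `q3`, `ci95`, `loso` (NULL when
#'   fewer than 2 stations).
#' @export
summarize_response <- function(responses, n_resamples = 10000L, level = 0.95,
                               seed = 1L, by = c("pooled", "station")) {
  by <- match.arg(by)
  x <- responses$pct_change
  if (by == "station") {
    x <- vapply(split(x, responses$station_id), stats::median, numeric(1))
  }
  mi <- median_iqr(x)
  ci <- if (length(x) >= 2L) {
    bootstrap_median_ci(x, n_resamples, level, seed)
  } else c(lower = NA_real_, upper = NA_real_)
  loso <- if (length(unique(responses$station_id)) >= 2L) {
    leave_one_station_out(responses)
  }
  list(n = length(x), median = unname(mi["median"]), q1 = unname(mi["q1"]),
       q3 = unname(mi["q3"]), ci95 = ci, loso = loso)
}
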