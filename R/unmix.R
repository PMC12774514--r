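# Bayesian apportionment of N2O among production pathways with a
# closed-system Rayleigh reduction term, jointly fitting bulk d15N, d18O and
# site preference:
#
#   F_s = sum_i f_i * E_{i,s} + mu_s * ln(r)
#
# with f on the simplex, residual unreduced fraction r in (0, 1], and latent
# endmembers E (and optionally mu) given Gaussian priors from the endmember
# table. Sampling is random-walk Metropolis on a stick-breaking transform of
# f and a scaled-logit transform of r, with non-centred latent endmembers.

#' Forward isotope mixing/fractionation model
#'
#' Computes the expected isotope signature of the N2O pool produced by a
#' mixture of pathways and partially reduced to residual fraction `r`:
#' `F_s = sum_i f_i E_{i,s} + mu_s ln(r)` per signal.
#'
#' @param f source fractions, one per pathway of the table, on the simplex
#'   (checked to 1e-9).
#' @param r residual unreduced N2O fraction, in (0, 1].
#' @param table an `"endmember_table"`; its means are used. Alternatively
#'   supply explicit values via `E` and `mu`.
#' @param E optional pathway-by-signal matrix overriding the table means.
#' @param mu optional per-signal reduction isotope effects overriding the
#'   table's `mu`.
#' @return named numeric vector over the signals (permil).
#' @export
forward_model <- function(f, r, table, E = NULL, mu = NULL) {
  if (is.null(E)) E <- table$mean
  if (is.null(mu)) mu <- table$mu
  if (length(f) != nrow(E)) {
    stop("f must have one fraction per pathway", call. = FALSE)
  }
  if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-9) {
    stop("f must lie on the simplex (nonnegative, summing to 1 within 1e-9)",
         call. = FALSE)
  }
  if (r <= 0 || r > 1) stop("r must be in (0, 1]", call. = FALSE)
  drop(crossprod(E, f)) + mu * log(r)
}

#' Mixing-model prior configuration
#'
#' @param dirichlet_alpha Dirichlet concentration for the source fractions;
#'   recycled to the number of pathways. Default flat (all 1).
#' @param r_min lower bound of the uniform prior on the residual fraction
#'   `r ~ Uniform(r_min, 1]`; default 0.1.
#' @param sample_mu if `TRUE` (default), `mu` is sampled with the table's sd
#'   wherever that sd is positive; otherwise fixed at the table mean.
#' @return a list of class `"prior_config"`.
#' @export
prior_config <- function(dirichlet_alpha = 1, r_min = 0.1, sample_mu = TRUE) {
  if (r_min <= 0 || r_min >= 1) stop("r_min must be in (0, 1)", call. = FALSE)
  if (any(dirichlet_alpha <= 0)) {
    stop("dirichlet_alpha must be > 0", call. = FALSE)
  }
  structure(list(dirichlet_alpha = dirichlet_alpha, r_min = r_min,
                 sample_mu = isTRUE(sample_mu)),
            class = "prior_config")
}

#' MCMC sampler configuration
#'
#' Defaults: 4 chains of 20 000 random-walk Metropolis iterations, first half
#' discarded as burn-in, split-chain convergence flagged above 1.05.
#'
#' @param chains,iter,burn_frac chain count, iterations per chain, burn-in
#'   fraction.
#' @param seed integer RNG seed; the sampler is a deterministic function of
#'   (inputs, seed).
#' @param step_f,step_r,step_z proposal scales for the simplex coordinates,
#'   the r transform, and the latent endmember z-scores.
#' @param rhat_threshold split-chain statistic above which a convergence
#'   warning is flagged in the output.
#' @return a list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4L, iter = 20000L, burn_frac = 0.5,
                        seed = 1L, step_f = 0.25, step_r = 0.4,
                        step_z = 0.25, rhat_threshold = 1.05) {
  stopifnot(chains >= 1L, iter >= 100L, burn_frac > 0, burn_frac < 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn_frac = burn_frac, seed = as.integer(seed),
                 step_f = step_f, step_r = step_r, step_z = step_z,
                 rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

#' A single corrected observation for unmixing
#'
#' @param values named vector of atmosphere-corrected isotope values over
#'   `d15n_bulk`, `d18o`, `sp` (permil).
#' @param sigma named vector of per-signal uncertainties, `> 0` (permil).
#' @return a list of class `"mixing_observation"`.
#' @export
mixing_observation <- function(values, sigma = DEFAULT_SIGMA) {
  values <- values[SIGNALS]; sigma <- sigma[SIGNALS]
  if (any(is.na(values))) stop("values must cover all signals", call. = FALSE)
  if (any(is.na(sigma)) || any(sigma <= 0)) {
    stop("sigma must be > 0 for all signals", call. = FALSE)
  }
  structure(list(values = values, sigma = sigma), class = "mixing_observation")
}

## ---- transforms -----------------------------------------------------------

# Stick-breaking simplex transform (Stan convention) with log-Jacobian.
simplex_from_unconstrained <- function(y) {
  k <- length(y) + 1L
  f <- numeric(k)
  rest <- 1
  logj <- 0
  for (i in seq_along(y)) {
    z <- stats::plogis(y[i] + log(1 / (k - i)))
    f[i] <- rest * z
    logj <- logj + log(rest) + log(z) + log1p(-z)
    rest <- rest - f[i]
  }
  f[k] <- rest
  list(f = f, logj = logj)
}

unconstrained_from_simplex <- function(f) {
  k <- length(f)
  y <- numeric(k - 1L)
  rest <- 1
  for (i in seq_len(k - 1L)) {
    z <- f[i] / rest
    y[i] <- stats::qlogis(z) - log(1 / (k - i))
    rest <- rest - f[i]
  }
  y
}

# r = r_min + (1 - r_min) * plogis(t); returns r and log-Jacobian
r_from_unconstrained <- function(t, r_min) {
  z <- stats::plogis(t)
  list(r = r_min + (1 - r_min) * z,
       logj = log(1 - r_min) + log(z) + log1p(-z))
}

ldirichlet <- function(f, alpha) {
  # pmax guards 0 * log(0) at simplex-boundary nodes under a flat prior
  sum((alpha - 1) * log(pmax(f, 1e-300))) +
    lgamma(sum(alpha)) - sum(lgamma(alpha))
}

## ---- posterior ------------------------------------------------------------

#' Log posterior density of the mixing model
#'
#' Gaussian likelihood of each observed signal around the forward model,
#' Dirichlet prior on the source fractions, uniform prior on the residual
#' fraction, and standard-normal priors on the non-centred latent endmember
#' z-scores (`E = mean + sd * z`, likewise `mu`). Returns `-Inf` outside the
#' support.
#'
#' @param params list with elements `f` (simplex), `r`, and optionally `zE`
#'   (pathway-by-signal z-score matrix) and `zmu` (per-signal z-scores);
#'   omitted z-scores are taken as 0 (endmembers at their means).
#' @param obs a [mixing_observation()].
#' @param table an `"endmember_table"`.
#' @param priors a [prior_config()].
#' @return log-density (unnormalized).
#' @export
log_posterior <- function(params, obs, table, priors = prior_config()) {
  f <- params$f; r <- params$r
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) return(-Inf)
  if (r <= priors$r_min || r > 1) return(-Inf)
  zE <- params$zE
  if (is.null(zE)) zE <- array(0, dim(table$mean))
  zmu <- params$zmu
  if (is.null(zmu)) zmu <- numeric(length(table$mu))
  E <- table$mean + table$sd * zE
  mu <- table$mu + table$mu_sd * zmu
  pred <- drop(crossprod(E, f)) + mu * log(r)
  alpha <- rep_len(priors$dirichlet_alpha, length(f))
  sum(stats::dnorm(obs$values, pred, obs$sigma, log = TRUE)) +
    ldirichlet(f, alpha) - log(1 - priors$r_min) +
    sum(stats::dnorm(zE, log = TRUE)) + sum(stats::dnorm(zmu, log = TRUE))
}

# Marginal log posterior over (f, r): the latent endmembers (and mu) are
# Gaussian and enter the forward model linearly, so they integrate out in
# closed form — each signal's predictive is Gaussian with variance
#   sigma_s^2 + sum_i f_i^2 sdE_{i,s}^2 + (ln r)^2 sdmu_s^2.
# The (f, r) posterior is identical to that of the full joint in
# log_posterior(); sampling the 4-dimensional marginal just mixes far better.
log_marginal_posterior <- function(f, r, obs, table, priors) {
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) return(-Inf)
  if (r <= priors$r_min || r > 1) return(-Inf)
  lr <- log(r)
  pred <- drop(crossprod(table$mean, f)) + table$mu * lr
  var_extra <- drop(crossprod(table$sd^2, f^2))
  if (priors$sample_mu) var_extra <- var_extra + table$mu_sd^2 * lr^2
  alpha <- rep_len(priors$dirichlet_alpha, length(f))
  sum(stats::dnorm(obs$values, pred, sqrt(obs$sigma^2 + var_extra),
                   log = TRUE)) +
    ldirichlet(f, alpha) - log(1 - priors$r_min)
}

## ---- sampler --------------------------------------------------------------

split_rhat <- function(draws_by_chain) {
  halves <- do.call(cbind, lapply(draws_by_chain, function(x) {
    n <- floor(length(x) / 2) * 2
    x <- x[seq_len(n)]
    matrix(x, ncol = 2)
  }))
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Sample the mixing-model posterior
#'
#' Random-walk Metropolis in unconstrained coordinates: stick-breaking for the
#' source fractions and a scaled logit for the residual fraction. The latent
#' endmembers (and `mu`, when `priors$sample_mu`) are Gaussian and enter the
#' forward model linearly, so they are integrated out analytically — each
#' signal's predictive variance is inflated by `sum_i f_i^2 sd_{i,s}^2`
#' (+ `(ln r)^2 mu_sd_s^2`) — leaving a 4-dimensional walk whose (f, r)
#' posterior is exactly that of the full joint in [log_posterior()]. The
#' proposal scale is adapted during burn-in only, then frozen.
#' Deterministic given `config$seed`. Convergence is
#' summarized by the split-chain statistic on every retained parameter; values
#' above `config$rhat_threshold` set `converged = FALSE` (flagged, never
#' silent).
#'
#' @param obs a [mixing_observation()].
#' @param table an `"endmember_table"`.
#' @param config an [mcmc_config()].
#' @param priors a [prior_config()].
#' @return a list of class `"mixing_posterior"`: `draws` (matrix with one
#'   column per source fraction, prefixed `f_`, plus `r`), `summary`
#'   (per-parameter mean, sd, 2.5/97.5% quantiles, rhat), `acceptance_rate`,
#'   `converged`, `config`.
#' @export
sample_posterior <- function(obs, table, config = mcmc_config(),
                             priors = prior_config()) {
  stopifnot(inherits(obs, "mixing_observation"),
            inherits(table, "endmember_table"))
  npath <- length(table$pathways)
  dim_theta <- npath  # npath - 1 simplex coordinates + 1 for r
  steps <- c(rep(config$step_f, npath - 1L), config$step_r)

  unpack <- function(theta) {
    sb <- simplex_from_unconstrained(theta[seq_len(npath - 1L)])
    rt <- r_from_unconstrained(theta[npath], priors$r_min)
    list(f = sb$f, r = rt$r, logj = sb$logj + rt$logj)
  }
  logdens <- function(theta) {
    p <- unpack(theta)
    log_marginal_posterior(p$f, p$r, obs, table, priors) + p$logj
  }

  burn <- floor(config$iter * config$burn_frac)
  keep <- config$iter - burn
  chains_f <- vector("list", config$chains)
  chains_r <- vector("list", config$chains)
  accepted <- 0L
  set.seed(config$seed)
  for (ch in seq_len(config$chains)) {
    theta <- stats::rnorm(dim_theta, 0, 0.5)
    ld <- logdens(theta)
    while (!is.finite(ld)) {
      theta <- stats::rnorm(dim_theta, 0, 0.5)
      ld <- logdens(theta)
    }
    fdraws <- matrix(NA_real_, keep, npath)
    rdraws <- numeric(keep)
    # global proposal scale, Robbins-Monro-adapted towards ~30% acceptance
    # during burn-in only, then frozen (retained draws stay Markovian)
    scale <- 1
    window_acc <- 0L
    for (it in seq_len(config$iter)) {
      prop <- theta + stats::rnorm(dim_theta, 0, scale * steps)
      ldp <- logdens(prop)
      if (is.finite(ldp) && log(stats::runif(1)) < ldp - ld) {
        theta <- prop; ld <- ldp
        if (it > burn) accepted <- accepted + 1L else window_acc <- window_acc + 1L
      }
      if (it <= burn && it %% 50L == 0L) {
        scale <- scale * exp((window_acc / 50 - 0.3) / sqrt(it / 50))
        window_acc <- 0L
      }
      if (it > burn) {
        p <- unpack(theta)
        fdraws[it - burn, ] <- p$f / sum(p$f)  # enforce exact closure
        rdraws[it - burn] <- p$r
      }
    }
    chains_f[[ch]] <- fdraws
    chains_r[[ch]] <- rdraws
  }
  draws <- cbind(do.call(rbind, chains_f), unlist(chains_r))
  colnames(draws) <- c(paste0("f_", table$pathways), "r")

  rhat <- vapply(seq_len(ncol(draws)), function(j) {
    split_rhat(lapply(seq_len(config$chains), function(ch) {
      if (j <= npath) chains_f[[ch]][, j] else chains_r[[ch]]
    }))
  }, numeric(1))
  summary <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q97.5 = apply(draws, 2, stats::quantile, 0.975),
    rhat = rhat, row.names = NULL, stringsAsFactors = FALSE)
  converged <- all(rhat < config$rhat_threshold)
  if (!converged) {
    warning("split-chain statistic above ", config$rhat_threshold,
            " for: ", paste(summary$parameter[rhat >= config$rhat_threshold],
                            collapse = ", "), call. = FALSE)
  }
  structure(list(draws = draws, summary = summary,
                 acceptance_rate = accepted / (config$chains * keep),
                 converged = converged, config = config),
            class = "mixing_posterior")
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat(sprintf("Mixing posterior: %d draws (%d chains), acceptance %.2f, %s\n",
              nrow(x$draws), x$config$chains, x$acceptance_rate,
              if (x$converged) "converged" else "NOT converged"))
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

## ---- exhaustive-grid oracle ------------------------------------------------

#' Brute-force grid posterior (verification oracle)
#'
#' Normalizes the posterior over an exhaustive simplex grid for the source
#' fractions crossed with a uniform grid on the residual fraction, with
#' endmember uncertainty collapsed to the table means. Intended as an
#' independent check on the MCMC sampler, not for production use.
#'
#' @param obs a [mixing_observation()].
#' @param table an `"endmember_table"`; sds are ignored (collapsed).
#' @param grid_step simplex grid resolution, must be `<= 0.05`.
#' @param priors a [prior_config()].
#' @param r_points number of r grid points over `(r_min, 1]`; set `r_fixed`
#'   to bypass.
#' @param r_fixed optional fixed value of r (no marginalization over r).
#' @return list with `means` (posterior mean of each fraction and of r) and
#'   the grid log-normalizing constant `log_z`.
#' @export
grid_posterior_oracle <- function(obs, table, grid_step = 0.02,
                                  priors = prior_config(), r_points = 25L,
                                  r_fixed = NULL) {
  if (grid_step > 0.05) {
    stop("grid too coarse: grid_step must be <= 0.05", call. = FALSE)
  }
  table <- collapse_endmembers(table)
  npath <- length(table$pathways)
  n <- round(1 / grid_step)
  counts <- compositions(n, npath)
  fgrid <- counts / n
  if (is.null(r_fixed)) {
    rgrid <- priors$r_min + (seq_len(r_points) - 0.5) / r_points *
      (1 - priors$r_min)
  } else {
    rgrid <- r_fixed
  }
  alpha <- rep_len(priors$dirichlet_alpha, npath)
  pred_mix <- fgrid %*% table$mean              # nodes x signals
  lprior <- apply(fgrid, 1, ldirichlet, alpha = alpha)
  ll <- matrix(0, nrow(fgrid), length(rgrid))
  for (j in seq_along(rgrid)) {
    shift <- table$mu * log(rgrid[j])
    ll[, j] <- lprior +
      rowSums(vapply(seq_along(SIGNALS), function(s) {
        stats::dnorm(obs$values[s], pred_mix[, s] + shift[s], obs$sigma[s],
                     log = TRUE)
      }, numeric(nrow(fgrid))))
  }
  m <- max(ll)
  w <- exp(ll - m)
  z <- sum(w)
  wf <- rowSums(w) / z
  wr <- colSums(w) / z
  means <- c(drop(crossprod(fgrid, wf)), sum(rgrid * wr))
  names(means) <- c(paste0("f_", table$pathways), "r")
  list(means = means, log_z = m + log(z))
}

# all nonnegative integer k-tuples summing to n (rows)
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1L))
  })
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

## ---- dataset-level apportionment -------------------------------------------

#' Apportion N2O sources for a set of corrected observations
#'
#' Runs [sample_posterior()] for every row of a corrected-observation table
#' (as produced by [atmospheric_correction()], or any table with the three
#' signal columns and their `sigma_*` companions) and returns tidy summaries,
#' together with the across-sample mean and sd of each pathway's posterior-
#' mean fraction (the dataset-level aggregation used to headline the archaeal
#' share).
#'
#' @param records data.frame with columns `d15n_bulk`, `d18o`, `sp` and
#'   `sigma_d15n_bulk`, `sigma_d18o`, `sigma_sp` (plus optional key columns
#'   `station_id`, `depth` carried through).
#' @param table an `"endmember_table"`.
#' @param config an [mcmc_config()]; each row uses `seed + row - 1`.
#' @param priors a [prior_config()].
#' @return a list of class `"n2o_apportionment"`: `samples` (long tidy
#'   data.frame of per-sample parameter summaries), `overall` (per-parameter
#'   mean and sd of the posterior means across samples), `converged`.
#' @export
apportion_dataset <- function(records, table, config = mcmc_config(),
                              priors = prior_config()) {
  records <- as.data.frame(records)
  if (nrow(records) < 1L) stop("no records to apportion", call. = FALSE)
  keys <- intersect(c("station_id", "depth"), names(records))
  res <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    obs <- mixing_observation(
      values = unlist(records[i, SIGNALS]),
      sigma = stats::setNames(unlist(records[i, paste0("sigma_", SIGNALS)]),
                              SIGNALS))
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    post <- sample_posterior(obs, table, cfg, priors)
    s <- post$summary
    s$sample <- i
    s$converged <- post$converged
    for (k in keys) s[[k]] <- records[[k]][i]
    res[[i]] <- s
  }
  samples <- do.call(rbind, res)
  means_wide <- do.call(rbind, lapply(res, function(s) {
    stats::setNames(s$mean, s$parameter)
  }))
  overall <- data.frame(parameter = colnames(means_wide),
                        mean = colMeans(means_wide),
                        sd = apply(means_wide, 2, stats::sd),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(samples = samples, overall = overall,
                 converged = all(samples$converged)),
            class = "n2o_apportionment")
}
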