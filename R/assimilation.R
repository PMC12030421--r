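#' Build a fast likelihood closure over the crop model
#'
#' Precomputes all weather-derived arrays once and returns a function
#' `theta -> log-likelihood` that simulates the crop, reads LAI and PNA off
#' the trajectory at the observation dates, and scores them against the
#' observation set.  Candidate sowing dates that postdate an observation get
#' `-Inf` (the model cannot explain a canopy before sowing).
#'
#' @param obs An [observation_set()].
#' @param weather Weather `data.frame`.
#' @param constants Model constants.
#' @param gaussian_half Apply the Gaussian 1/2 factor in the likelihood.
#' @return Function taking a named vector `c(sowing_doy, seeding_rate,
#'   n_amount)` and returning the log-likelihood; it carries the
#'   precomputation in its environment.
#' @export
make_likelihood <- function(obs, weather,
                            constants = default_model_constants(),
                            gaussian_half = FALSE) {
  stopifnot(inherits(obs, "observation_set"))
  pre <- precompute_weather(weather, constants)
  obs_doy <- obs$doy
  function(theta) {
    sowing <- theta[["sowing_doy"]]
    pos <- obs_doy - floor(sowing)   # index into the post-sowing day grid
    if (any(pos < 1L)) return(-Inf)
    sim <- simulate_core(sowing, theta[["seeding_rate"]],
                         theta[["n_amount"]], pre, constants)
    if (any(pos > length(sim$lai))) return(-Inf)
    log_likelihood(list(lai = sim$lai[pos], pna = sim$pna[pos]), obs,
                   gaussian_half = gaussian_half)
  }
}

#' Assimilate observations into the crop model
#'
#' The end-to-end recalibration pipeline: initialize the three management
#' parameters uniformly within their bounds, run a random-walk
#' Metropolis-Hastings chain against the NDVI-derived LAI/PNA observations,
#' summarize the posterior after burn-in, and compute posterior-predictive
#' LAI/PNA trajectories and yield by re-running the crop model at thinned
#' retained samples.  Predictive spread is reported as RMSD (root-mean-square
#' dispersion of the ensemble) per stage and variable, and for yield.
#'
#' @param obs An [observation_set()].
#' @param weather Weather `data.frame` covering the candidate sowing window
#'   through maturity.
#' @param space A [parameter_space()] over `sowing_doy`, `seeding_rate`,
#'   `n_amount` (default [default_parameter_space()]).
#' @param constants Model constants.
#' @param n_iter Chain length (default 10000).
#' @param burn_in Burn-in iterations discarded (default 2000).
#' @param seed Integer RNG seed.
#' @param thin Posterior-predictive thinning stride over retained samples
#'   (default 20: 8000 retained samples give a 400-member ensemble).
#' @param literal Use the one-sided audit proposal.
#' @param gaussian_half Apply the Gaussian 1/2 factor in the likelihood.
#' @return An `assimilation_fit`: list with `posterior` (an `mh_posterior`),
#'   `chain`, `theta_hat` (recalibrated [management_params()], the posterior
#'   means), `predictive` (ensemble matrices plus per-stage means and RMSD,
#'   yield mean and RMSD), `obs`, `seed` and the chain settings.
#' @export
run_assimilation <- function(obs, weather,
                             space = default_parameter_space(),
                             constants = default_model_constants(),
                             n_iter = 10000L, burn_in = 2000L, seed = 1L,
                             thin = 20L, literal = FALSE,
                             gaussian_half = FALSE) {
  if (burn_in >= n_iter) {
    stop("burn_in (", burn_in, ") must be smaller than n_iter (", n_iter,
         ")", call. = FALSE)
  }
  loglik <- make_likelihood(obs, weather, constants,
                            gaussian_half = gaussian_half)
  chain <- run_chain(loglik, space, n_iter = n_iter, seed = seed,
                     literal = literal)
  posterior <- summarize_chain(chain, burn_in = burn_in)
  m <- posterior$summary$mean
  names(m) <- posterior$summary$parameter
  theta_hat <- management_params(m[["sowing_doy"]], m[["seeding_rate"]],
                                 m[["n_amount"]],
                                 n_split = constants$nitrogen$n_split)
  predictive <- posterior_predictive(posterior, obs, weather, constants,
                                     thin = thin)
  structure(list(posterior = posterior, chain = chain, theta_hat = theta_hat,
                 predictive = predictive, obs = obs, seed = seed,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, D = space$D,
                                 literal = literal,
                                 gaussian_half = gaussian_half),
                 space = space),
            class = "assimilation_fit")
}

# Posterior-predictive ensemble: crop model re-run at thinned retained
# samples; stage-level LAI/PNA and yield collected across the ensemble.
posterior_predictive <- function(posterior, obs, weather, constants,
                                 thin = 20L) {
  pre <- precompute_weather(weather, constants)
  rows <- posterior$retained[seq(1L, posterior$n_retained, by = thin), ,
                             drop = FALSE]
  K <- nrow(rows)
  nT <- length(obs$doy)
  lai <- matrix(NA_real_, K, nT)
  pna <- matrix(NA_real_, K, nT)
  yield <- numeric(K)
  for (k in seq_len(K)) {
    th <- rows[k, ]
    sim <- simulate_core(th[["sowing_doy"]], th[["seeding_rate"]],
                         th[["n_amount"]], pre, constants)
    pos <- obs$doy - floor(th[["sowing_doy"]])
    lai[k, ] <- sim$lai[pos]
    pna[k, ] <- sim$pna[pos]
    yield[k] <- sim$yield
  }
  colnames(lai) <- colnames(pna) <- obs$stage
  list(lai = lai, pna = pna, yield = yield,
       lai_mean = colMeans(lai), pna_mean = colMeans(pna),
       lai_rmsd = apply(lai, 2L, rmsd), pna_rmsd = apply(pna, 2L, rmsd),
       yield_mean = mean(yield), yield_rmsd = rmsd(yield),
       ensemble_size = K)
}

#' @export
print.assimilation_fit <- function(x, ...) {
  cat("assimilation_fit\n")
  cat(sprintf("  chain: %d iterations, burn-in %d, acceptance rate %.2f, seed %d\n",
              x$settings$n_iter, x$settings$burn_in,
              x$posterior$acceptance_rate, x$seed))
  cat("  recalibrated parameters (posterior means):\n")
  cat(sprintf("    sowing doy %.2f, seeding rate %.2f kg/ha, N amount %.1f kg/ha\n",
              x$theta_hat$sowing_doy, x$theta_hat$seeding_rate,
              x$theta_hat$n_amount))
  cat(sprintf("  predicted yield %.0f kg/ha (RMSD %.0f, ensemble of %d)\n",
              x$predictive$yield_mean, x$predictive$yield_rmsd,
              x$predictive$ensemble_size))
  invisible(x)
}

#' Assimilate every treatment of a synthetic experiment
#'
#' Convenience wrapper running [run_assimilation()] once per treatment-level
#' observation set of a [make_experiment()] bundle, with per-treatment seeds
#' derived from `seed`.
#'
#' @param experiment A `synthetic_experiment`.
#' @param treatments Treatment names to assimilate (default: all).
#' @param seed Base seed; treatment i uses `seed + i`.
#' @param ... Passed on to [run_assimilation()] (chain settings, space, ...).
#' @return Named list of `assimilation_fit` objects.
#' @export
assimilate_experiment <- function(experiment, treatments = NULL, seed = 1L,
                                  ...) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (is.null(treatments)) treatments <- names(experiment$observations)
  sp <- default_parameter_space(
    nominal_sowing_doy = experiment$design$nominal_sowing_doy)
  fits <- lapply(seq_along(treatments), function(i) {
    run_assimilation(experiment$observations[[treatments[i]]],
                     experiment$weather, space = sp,
                     seed = seed + i, ...)
  })
  names(fits) <- treatments
  fits
}
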