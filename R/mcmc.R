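#' Bounded parameter space for the sampler
#'
#' Box constraints for the sampled parameters together with the
#' proposal-scale divisor `D`: the random-walk proposal steps each component
#' by `r * (max - min) / D`.
#'
#' @param min,max Named numeric vectors of lower/upper bounds (same names,
#'   same length).
#' @param D Proposal-scale divisor (default 5).
#' @return A `parameter_space` object.
#' @export
#' @examples
#' parameter_space(c(x = 0), c(x = 1))
parameter_space <- function(min, max, D = 5) {
  if (is.null(names(min))) names(min) <- paste0("theta", seq_along(min))
  if (is.null(names(max))) names(max) <- names(min)
  stopifnot(length(min) == length(max), all(names(min) == names(max)))
  if (any(max < min)) stop("max must be >= min for every parameter",
                           call. = FALSE)
  if (!is.finite(D) || D <= 0) stop("D must be positive", call. = FALSE)
  structure(list(min = min, max = max, D = D, names = names(min)),
            class = "parameter_space")
}

#' Default management-parameter bounds
#'
#' Sowing date nominal +/- 15 days, seeding rate 30-90 kg/ha around the
#' nominal 60, nitrogen 0-350 kg/ha (covering the 0-280 kg/ha treatment
#' range with headroom).  All overridable by constructing a
#' [parameter_space()] directly.
#'
#' @param nominal_sowing_doy Nominal sowing day-of-year (default 148,
#'   a late-May sowing).
#' @param D Proposal-scale divisor.
#' @return A `parameter_space` over `sowing_doy`, `seeding_rate`, `n_amount`.
#' @export
default_parameter_space <- function(nominal_sowing_doy = 148, D = 5) {
  parameter_space(
    min = c(sowing_doy = nominal_sowing_doy - 15, seeding_rate = 30,
            n_amount = 0),
    max = c(sowing_doy = nominal_sowing_doy + 15, seeding_rate = 90,
            n_amount = 350),
    D = D)
}

#' Per-stage observation set for the likelihood
#'
#' The assimilation's data: NDVI-derived LAI (`o1`) and PNA (`o2`) estimates
#' at each observed stage, with scalar measurement standard deviations
#' `sigma1` (LAI) and `sigma2` (PNA, kg/ha) pooled across replicates.
#'
#' @param stage Character vector of stage labels.
#' @param doy Integer day-of-year of each observation.
#' @param o1,o2 Observed/estimated LAI and PNA per stage.
#' @param sigma1,sigma2 Positive scalar standard deviations.
#' @return An `observation_set` object.
#' @export
observation_set <- function(stage, doy, o1, o2, sigma1, sigma2) {
  n <- length(stage)
  stopifnot(n >= 1L, length(doy) == n, length(o1) == n, length(o2) == n)
  if (!is.finite(sigma1) || !is.finite(sigma2) || sigma1 <= 0 || sigma2 <= 0) {
    stop("sigma1 and sigma2 must be positive scalars", call. = FALSE)
  }
  structure(list(stage = as.character(stage), doy = as.integer(doy),
                 o1 = as.numeric(o1), o2 = as.numeric(o2),
                 sigma1 = sigma1, sigma2 = sigma2),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("observation_set: %d stages (%s), sigma1 = %.3g, sigma2 = %.3g\n",
              length(x$stage), paste(x$stage, collapse = ", "),
              x$sigma1, x$sigma2))
  invisible(x)
}

#' Draw an initial parameter vector uniformly within bounds
#'
#' @param space A [parameter_space()].
#' @return Named numeric vector, each component uniform on `[min, max]`.
#'   Uses the current RNG state; seed control belongs to the caller (see
#'   [run_chain()]).
#' @export
init_theta <- function(space) {
  stopifnot(inherits(space, "parameter_space"))
  setNames(runif(length(space$min), space$min, space$max), space$names)
}

#' Propose a candidate parameter vector
#'
#' Random-walk step: each component moves by `r * (max - min) / D` with `r`
#' uniform on `[-1, 1]`, then is reflected at the bounds so the candidate
#' stays inside the space.  The kernel is symmetric, so the proposal-density
#' ratio in the acceptance probability is exactly 1.  `literal = TRUE`
#' switches to a one-sided audit variant with `r` uniform on `[0, 1]`
#' (strictly non-negative steps); it is not symmetric and is provided for
#' comparison only.
#'
#' @param theta Current named parameter vector, inside `space`.
#' @param space A [parameter_space()].
#' @param literal Use the one-sided step variant (default `FALSE`).
#' @return Proposed parameter vector, guaranteed inside the bounds.
#' @export
propose_theta <- function(theta, space, literal = FALSE) {
  r <- if (literal) runif(length(theta), 0, 1) else runif(length(theta), -1, 1)
  cand <- theta + r * (space$max - space$min) / space$D
  reflect_into(cand, space$min, space$max)
}

# reflect a vector into [min, max] (repeatedly, though one bounce suffices
# for any D >= 2 on a non-degenerate box)
reflect_into <- function(x, lo, hi) {
  rng <- hi - lo
  fixed <- rng == 0
  x[fixed] <- lo[fixed]
  i <- which(!fixed & (x < lo | x > hi))
  while (length(i)) {
    x[i] <- ifelse(x[i] < lo[i], 2 * lo[i] - x[i], 2 * hi[i] - x[i])
    i <- i[x[i] < lo[i] | x[i] > hi[i]]
  }
  x
}

#' Log-likelihood of simulated state against observations
#'
#' `log pi_p(theta) = -(1/sigma1^2) * sum_t (O1(t) - S1(t))^2
#'                    -(1/sigma2^2) * sum_t (O2(t) - S2(t))^2`,
#' summed over all observation times, up to an additive constant.  Note the
#' exponent carries no Gaussian 1/2 factor; `gaussian_half = TRUE` restores
#' it (halving the exponent), which widens the posterior.
#'
#' @param sim List or data.frame with `lai` and `pna` aligned with `obs`
#'   (same stages, same order).
#' @param obs An [observation_set()].
#' @param gaussian_half Apply the 1/2 factor of a Gaussian log-density.
#' @return Scalar log-likelihood (0 is the maximum, attained at `sim == obs`).
#' @export
log_likelihood <- function(sim, obs, gaussian_half = FALSE) {
  stopifnot(inherits(obs, "observation_set"))
  if (length(sim$lai) != length(obs$o1) || length(sim$pna) != length(obs$o2)) {
    stop("stage mismatch: simulated and observed series have different ",
         "lengths", call. = FALSE)
  }
  ll <- -sum((obs$o1 - sim$lai)^2) / obs$sigma1^2 -
    sum((obs$o2 - sim$pna)^2) / obs$sigma2^2
  if (gaussian_half) ll <- ll / 2
  ll
}

#' Metropolis acceptance probability
#'
#' `a_p = min(1, exp(loglik_new - loglik_old))`; under the symmetric
#' proposal the Hastings proposal-density correction is exactly 1.
#'
#' @param loglik_new,loglik_old Finite log-likelihoods.
#' @return Acceptance probability in `(0, 1]`.
#' @export
acceptance_ratio <- function(loglik_new, loglik_old) {
  if (is.nan(loglik_new) || is.nan(loglik_old)) {
    stop("NaN log-likelihood in acceptance ratio", call. = FALSE)
  }
  if (loglik_new == -Inf) return(0)  # impossible candidate, never accepted
  min(1, exp(loglik_new - loglik_old))
}

#' Metropolis-Hastings accept/reject decision
#'
#' Accepts when `a_p >= u` (ties accept), with `u` uniform on `[0, 1]`.
#' Split out from [mh_step()] so the decision rule is testable with forced
#' `u` values.
#'
#' @param a_p Acceptance probability.
#' @param u Uniform random number in `[0, 1]`.
#' @return Logical: accept the candidate.
#' @export
mh_accept <- function(a_p, u) a_p >= u

#' One Metropolis-Hastings transition
#'
#' Proposes a candidate, evaluates its log-likelihood, and accepts or
#' retains the current state by the M-H criterion.
#'
#' @param state List with `theta` (named vector) and `loglik`.
#' @param loglik_fun Function `theta -> log-likelihood`.
#' @param space A [parameter_space()].
#' @param literal Use the one-sided audit proposal.
#' @return Updated state list with an `accepted` flag.
#' @export
mh_step <- function(state, loglik_fun, space, literal = FALSE) {
  cand <- propose_theta(state$theta, space, literal = literal)
  ll_new <- tryCatch(loglik_fun(cand), error = function(e) {
    stop("model failure at theta = (",
         paste(signif(cand, 6), collapse = ", "), "): ",
         conditionMessage(e), call. = FALSE)
  })
  a_p <- acceptance_ratio(ll_new, state$loglik)
  u <- runif(1)
  if (mh_accept(a_p, u)) {
    list(theta = cand, loglik = ll_new, accepted = TRUE)
  } else {
    list(theta = state$theta, loglik = state$loglik, accepted = FALSE)
  }
}

#' Run a Metropolis-Hastings chain
#'
#' Initializes uniformly within the bounds (or at `init`), then iterates
#' [mh_step()] to a chain of length `n_iter` (the initial state is sample
#' 1).  The whole chain is driven by a single seeded RNG stream, so
#' identical seeds give bit-identical chains.
#'
#' @param loglik_fun Function `theta -> log-likelihood`.
#' @param space A [parameter_space()].
#' @param n_iter Chain length `N` (default 10000).
#' @param seed Integer RNG seed.
#' @param init Optional named starting vector (default: uniform draw).
#' @param literal Use the one-sided audit proposal.
#' @return An `mh_chain`: list with `samples` (N x p matrix), `loglik`,
#'   `accepted`, `acceptance_rate`, `n_iter`, `seed`, `space`.
#' @export
#' @examples
#' sp <- parameter_space(c(x = 0), c(x = 1))
#' ch <- run_chain(function(th) 0, sp, n_iter = 100, seed = 1)
#' ch$acceptance_rate
run_chain <- function(loglik_fun, space, n_iter = 10000L, seed = 1L,
                      init = NULL, literal = FALSE) {
  stopifnot(n_iter >= 1L)
  set.seed(seed)
  p <- length(space$min)
  samples <- matrix(NA_real_, nrow = n_iter, ncol = p,
                    dimnames = list(NULL, space$names))
  loglik <- numeric(n_iter)
  accepted <- logical(n_iter)
  theta <- if (is.null(init)) init_theta(space) else {
    stopifnot(all(init >= space$min - 1e-9), all(init <= space$max + 1e-9))
    setNames(as.numeric(init), space$names)
  }
  state <- list(theta = theta, loglik = loglik_fun(theta), accepted = TRUE)
  samples[1L, ] <- state$theta
  loglik[1L] <- state$loglik
  accepted[1L] <- TRUE
  if (n_iter > 1L) {
    for (k in 2:n_iter) {
      state <- mh_step(state, loglik_fun, space, literal = literal)
      samples[k, ] <- state$theta
      loglik[k] <- state$loglik
      accepted[k] <- state$accepted
    }
  }
  structure(list(samples = samples, loglik = loglik, accepted = accepted,
                 acceptance_rate = mean(accepted[-1L]),
                 n_iter = n_iter, seed = seed, space = space),
            class = "mh_chain")
}

#' @export
print.mh_chain <- function(x, ...) {
  cat(sprintf("mh_chain: %d iterations, %d parameter(s), acceptance rate %.2f (seed %d)\n",
              x$n_iter, ncol(x$samples), x$acceptance_rate, x$seed))
  invisible(x)
}

#' Summarize a chain into a posterior
#'
#' Discards the first `burn_in` iterations and reports per-parameter
#' posterior mean, variance, SD and central credible interval from the
#' retained samples (`N - burn_in` of them; the defaults 10000/2000 retain
#' 8000).
#'
#' @param chain An `mh_chain`.
#' @param burn_in Iterations to discard (default 2000); must be `< N`.
#' @param level Credible-interval coverage (default 0.95).
#' @return An `mh_posterior`: list with `summary` (data.frame of mean, var,
#'   sd, lower, upper per parameter), `retained` (matrix), `burn_in`,
#'   `n_retained`, `level`, `acceptance_rate`, `seed`.
#' @export
summarize_chain <- function(chain, burn_in = 2000L, level = 0.95) {
  stopifnot(inherits(chain, "mh_chain"))
  if (burn_in >= chain$n_iter) {
    stop("burn_in (", burn_in, ") must be smaller than the chain length (",
         chain$n_iter, ")", call. = FALSE)
  }
  keep <- chain$samples[seq.int(burn_in + 1L, chain$n_iter), , drop = FALSE]
  alpha <- (1 - level) / 2
  qs <- apply(keep, 2L, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  summ <- data.frame(parameter = colnames(keep),
                     mean = colMeans(keep),
                     var = apply(keep, 2L, var),
                     sd = apply(keep, 2L, sd),
                     lower = qs[1L, ], upper = qs[2L, ],
                     row.names = NULL)
  structure(list(summary = summ, retained = keep,
                 burn_in = as.integer(burn_in), n_retained = nrow(keep),
                 level = level, acceptance_rate = chain$acceptance_rate,
                 seed = chain$seed),
            class = "mh_posterior")
}

#' @export
print.mh_posterior <- function(x, ...) {
  cat(sprintf("mh_posterior: %d retained samples (burn-in %d), %.0f%% credible intervals\n",
              x$n_retained, x$burn_in, 100 * x$level))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Effective sample size of an autocorrelated draw sequence
#'
#' Initial-positive-sequence estimator: sums autocorrelations over lags while
#' consecutive pairs stay positive.  Used to form Monte-Carlo standard errors
#' for chain summaries.
#'
#' @param x Numeric vector of (autocorrelated) samples.
#' @return Effective sample size, between 1 and `length(x)`.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  max_lag <- min(n - 2L, 1000L)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  ess <- n / (1 + 2 * s)
  max(1, min(n, ess))
}
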