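#' Export a chain to delimited text
#'
#' One row per iteration: `k,<parameters...>,loglik,accepted`.
#'
#' @param chain An `mh_chain`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "mh_chain"))
  d <- data.frame(k = seq_len(chain$n_iter), chain$samples,
                  loglik = chain$loglik,
                  accepted = as.integer(chain$accepted))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chain exported by [write_chain()]
#' @param path CSV path.
#' @return A `data.frame` with `k`, parameter columns, `loglik`, `accepted`.
#' @export
read_chain <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Small stable FNV-1a hash of a config list (via its canonical JSON form),
# so every report can carry a fingerprint of the settings that produced it.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  # polynomial rolling hash kept in double precision (31^5 * 2^32 < 2^53)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a posterior report as structured JSON
#'
#' Means, variances, credible intervals, acceptance rate, seed, chain
#' settings, posterior-predictive summaries and a config hash.
#'
#' @param fit An `assimilation_fit` from [run_assimilation()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_posterior_report <- function(fit, path) {
  stopifnot(inherits(fit, "assimilation_fit"))
  post <- fit$posterior
  params <- setNames(lapply(seq_len(nrow(post$summary)), function(i) {
    r <- post$summary[i, ]
    list(mean = r$mean, var = r$var, sd = r$sd,
         ci = c(r$lower, r$upper))
  }), post$summary$parameter)
  cfg <- list(n_iter = fit$settings$n_iter, burn_in = fit$settings$burn_in,
              D = fit$settings$D, thin = fit$settings$thin,
              literal = fit$settings$literal,
              gaussian_half = fit$settings$gaussian_half,
              seed = fit$seed,
              bounds = list(min = as.list(fit$space$min),
                            max = as.list(fit$space$max)))
  report <- list(
    parameters = params,
    acceptance_rate = post$acceptance_rate,
    n_retained = post$n_retained,
    credible_level = post$level,
    predictive = list(
      stages = fit$obs$stage,
      lai_mean = unname(fit$predictive$lai_mean),
      pna_mean = unname(fit$predictive$pna_mean),
      lai_rmsd = unname(fit$predictive$lai_rmsd),
      pna_rmsd = unname(fit$predictive$pna_rmsd),
      yield_mean = fit$predictive$yield_mean,
      yield_rmsd = fit$predictive$yield_rmsd,
      ensemble_size = fit$predictive$ensemble_size),
    seed = fit$seed,
    settings = cfg,
    config_hash = config_hash(cfg))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
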