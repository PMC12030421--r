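#' Default surrogate crop model constants
#'
#' Reads the versioned defaults shipped with the package
#' (`inst/extdata/model_constants.yaml`) and validates its schema.  The
#' constants parameterize the surrogate rice model: phenology thresholds in
#' growing degree-days (GDD), the logistic canopy expansion, the
#' Michaelis-Menten nitrogen ceiling, pool-limited N uptake, and the
#' radiation-use-efficiency yield component.  They are design choices of this
#' package, not estimates of any cultivar.
#'
#' @param path Optional path to an alternative YAML constants file with the
#'   same schema, allowing full override of the defaults.
#' @return A nested list with elements `phenology`, `canopy`, `nitrogen`,
#'   `assimilate` and a `version` tag.
#' @export
#' @examples
#' cc <- default_model_constants()
#' cc$phenology$base_temp
default_model_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_constants.yaml",
                        package = "riceAssim", mustWork = TRUE)
  }
  cc <- yaml::read_yaml(path)
  validate_model_constants(cc)
  cc
}

validate_model_constants <- function(cc) {
  need <- c("phenology", "canopy", "nitrogen", "assimilate")
  missing <- setdiff(need, names(cc))
  if (length(missing)) {
    stop("model constants file is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  thr <- unlist(cc$phenology$gdd_at_stage)
  stages <- c("tilling", "jointing", "booting", "flowering", "maturity")
  if (!all(stages %in% names(thr))) {
    stop("phenology$gdd_at_stage must name all of: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  if (any(diff(thr[stages]) <= 0)) {
    stop("phenology thresholds must be strictly increasing along ",
         "tilling < jointing < booting < flowering < maturity", call. = FALSE)
  }
  ns <- cc$nitrogen$n_split
  if (length(ns) != 2L || abs(sum(ns) - 1) > 1e-8 || any(ns < 0)) {
    stop("nitrogen$n_split must be two non-negative fractions summing to 1",
         call. = FALSE)
  }
  pos <- c(cc$canopy$lai_pot, cc$canopy$k_seed, cc$canopy$k_n,
           cc$canopy$r_growth, cc$canopy$lai_init_per_seed,
           cc$nitrogen$soil_n, cc$nitrogen$uptake_max,
           cc$nitrogen$k_uptake, cc$assimilate$rue, cc$assimilate$k_ext,
           cc$assimilate$harvest_index, cc$assimilate$k_yield_n)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all canopy/nitrogen/assimilate scale constants must be positive",
         call. = FALSE)
  }
  invisible(cc)
}

#' Phenology thresholds of the surrogate model
#'
#' @param constants Model constants list, see [default_model_constants()].
#' @return A list with `base_temp` (deg C) and `gdd_at_stage`, a named numeric
#'   vector of cumulative GDD thresholds ordered
#'   tilling < jointing < booting < flowering < maturity.
#' @export
phenology_thresholds <- function(constants = default_model_constants()) {
  list(base_temp = constants$phenology$base_temp,
       gdd_at_stage = unlist(constants$phenology$gdd_at_stage))
}

#' Stage names used throughout the package
#' @return Character vector of growth stages in temporal order.
#' @export
crop_stages <- function() {
  c("sown", "tilling", "jointing", "booting", "flowering", "maturity")
}

#' Observation stages (the canopy measurement times)
#' @return The four stages at which LAI and PNA are observed.
#' @export
observation_stages <- function() {
  c("tilling", "jointing", "booting", "flowering")
}
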