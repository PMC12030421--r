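#' Observation noise and forward-NDVI model
#'
#' Parameters of the synthetic observation process: the saturating forward
#' NDVI response to canopy state and the replicate measurement noise.
#' Defaults place NDVI saturation onset near LAI 6-7 and PNA 90 kg/ha and
#' use plausible replicate noise magnitudes (LAI CV 8%, PNA CV 10%, NDVI
#' additive SD 0.02); none are calibrated to any field campaign.
#'
#' @param ndvi_sd Additive Gaussian SD on each NDVI reading.
#' @param lai_cv,pna_cv Replicate coefficients of variation of the true
#'   plot-level state.
#' @param ndvi_max NDVI asymptote of a fully closed canopy (`<= 1`).
#' @param k_lai,k_pna Log-slope of the forward model (state units per
#'   e-fold of NDVI): the `b` exponent of the matching exponential
#'   regression.
#' @param lai_sat,pna_sat Saturation onsets: the state values at which the
#'   forward NDVI reaches `ndvi_max` and flattens.
#' @param sigma1_floor,sigma2_floor Lower bounds for the pooled measurement
#'   SDs (used verbatim when only one replicate exists).
#' @return A `noise_model` list.
#' @export
noise_model <- function(ndvi_sd = 0.02, lai_cv = 0.08, pna_cv = 0.10,
                        ndvi_max = 0.92, k_lai = 3.8, k_pna = 4.7,
                        lai_sat = 6.5, pna_sat = 90,
                        sigma1_floor = 0.2, sigma2_floor = 5) {
  vals <- c(ndvi_sd, lai_cv, pna_cv, ndvi_max, k_lai, k_pna,
            lai_sat, pna_sat, sigma1_floor, sigma2_floor)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all noise model parameters must be positive", call. = FALSE)
  }
  if (ndvi_max > 1) stop("ndvi_max must be <= 1", call. = FALSE)
  structure(list(ndvi_sd = ndvi_sd, lai_cv = lai_cv, pna_cv = pna_cv,
                 ndvi_max = ndvi_max, k_lai = k_lai, k_pna = k_pna,
                 lai_sat = lai_sat, pna_sat = pna_sat,
                 sigma1_floor = sigma1_floor, sigma2_floor = sigma2_floor),
            class = "noise_model")
}

#' Forward NDVI response to canopy state
#'
#' Log-linear in the state below the saturation onset -
#' `ndvi = ndvi_max + log(state / sat) / k`, the exact inverse of the
#' exponential regression `state = a * exp(b * ndvi)` with `b = k` and
#' `a = sat * exp(-k * ndvi_max)` - and flat at `ndvi_max` above the onset,
#' clipped to `[0, ndvi_max]`.  NDVI therefore resolves the canopy exactly
#' on the unsaturated range and loses all sensitivity at dense canopies
#' (high LAI) and high nitrogen loads, the mechanism that biases direct
#' spectral inversion.
#'
#' @param state_value Non-negative LAI or PNA value(s).
#' @param target `"LAI"` or `"PNA"` (selects slope and onset).
#' @param noise A [noise_model()].
#' @return Noise-free NDVI value(s) in `[0, ndvi_max]`.
#' @export
#' @examples
#' forward_ndvi(2, "LAI")
forward_ndvi <- function(state_value, target = c("LAI", "PNA"),
                         noise = noise_model()) {
  target <- match.arg(target)
  if (any(state_value < 0)) stop("state_value must be >= 0", call. = FALSE)
  k <- if (target == "LAI") noise$k_lai else noise$k_pna
  sat <- if (target == "LAI") noise$lai_sat else noise$pna_sat
  raw <- ifelse(state_value == 0, -Inf,
                noise$ndvi_max + log(state_value / sat) / k)
  pmin(pmax(raw, 0), noise$ndvi_max)
}

#' Generate replicated NDVI-derived observations from a trajectory
#'
#' Emulates the field observation process: at each stage date the true
#' plot-level state is perturbed per replicate (biological CV), passed
#' through the saturating forward NDVI model with additive sensor noise, and
#' inverted through the fitted exponential regressions back to LAIe / PNAe.
#' Replicate means become `O1`, `O2`; the measurement SDs `sigma1`, `sigma2`
#' are pooled across stages (root mean square of per-stage replicate SDs),
#' with a configured floor (used verbatim when `reps = 1`).
#'
#' @param traj A `crop_trajectory` (the truth).
#' @param calibration List with `lai` and `pna` `exp_regression` fits.
#' @param stages Stages to observe (default the four canopy stages).
#' @param noise A [noise_model()].
#' @param reps Number of replicate plots.
#' @param seed Integer RNG seed.
#' @return An [observation_set()] with attribute `replicates` (the full
#'   replicate-level table).
#' @export
generate_observations <- function(traj, calibration,
                                  stages = observation_stages(),
                                  noise = noise_model(), reps = 3L,
                                  seed = 1L) {
  set.seed(seed)
  truth <- extract_at_stages(traj, stages)
  nT <- nrow(truth)
  lai_rep <- matrix(NA_real_, nT, reps)
  pna_rep <- matrix(NA_real_, nT, reps)
  for (t in seq_len(nT)) {
    for (r in seq_len(reps)) {
      s1 <- truth$lai[t] * (1 + rnorm(1, 0, noise$lai_cv))
      s2 <- truth$pna[t] * (1 + rnorm(1, 0, noise$pna_cv))
      nd1 <- clip01(forward_ndvi(max(s1, 0), "LAI", noise) +
                      rnorm(1, 0, noise$ndvi_sd), noise$ndvi_max)
      nd2 <- clip01(forward_ndvi(max(s2, 0), "PNA", noise) +
                      rnorm(1, 0, noise$ndvi_sd), noise$ndvi_max)
      lai_rep[t, r] <- invert_quiet(calibration$lai, nd1)
      pna_rep[t, r] <- invert_quiet(calibration$pna, nd2)
    }
  }
  o1 <- rowMeans(lai_rep)
  o2 <- rowMeans(pna_rep)
  if (reps > 1L) {
    sigma1 <- max(sqrt(mean(apply(lai_rep, 1L, sd)^2)), noise$sigma1_floor)
    sigma2 <- max(sqrt(mean(apply(pna_rep, 1L, sd)^2)), noise$sigma2_floor)
  } else {
    sigma1 <- noise$sigma1_floor
    sigma2 <- noise$sigma2_floor
  }
  obs <- observation_set(stage = truth$stage, doy = truth$doy,
                         o1 = o1, o2 = o2, sigma1 = sigma1, sigma2 = sigma2)
  attr(obs, "replicates") <- data.frame(
    stage = rep(truth$stage, reps), rep = rep(seq_len(reps), each = nT),
    lai_e = as.vector(lai_rep), pna_e = as.vector(pna_rep))
  obs
}

clip01 <- function(x, hi) pmin(pmax(x, 0), hi)

invert_quiet <- function(model, ndvi) {
  suppressWarnings(invert_spectral(model, ndvi))
}

#' Default synthetic experiment design
#'
#' The multi-rate nitrogen trial emulated by the generator: five N rates
#' (0/70/140/210/280 kg/ha) in three replicates, nominal seeding 60 kg/ha,
#' late-May sowing, with small treatment-level jitter on the true sowing
#' date (+/- 3 d) and seeding rate (+/- 8%).
#'
#' @return A design list.
#' @export
default_design <- function() {
  list(n_rates = c(0, 70, 140, 210, 280), reps = 3L,
       nominal_sowing_doy = 148, nominal_seeding = 60,
       sowing_jitter_days = 3, seeding_jitter_frac = 0.08,
       n_days = 220, weather_start_doy = 120,
       calibration_interval_days = 5)
}

#' Generate a complete synthetic assimilation experiment
#'
#' Builds, from one seed: a weather season; per-treatment true management
#' parameters (N rates exact, sowing date and seeding rate jittered around
#' their nominals); true crop trajectories; a spectral calibration data set
#' and fitted NDVI-to-LAI / NDVI-to-PNA exponential regressions; and
#' replicated NDVI-derived observation sets per treatment.  Regenerating
#' with the same seed reproduces the bundle exactly.
#'
#' @param design Design list, see [default_design()].
#' @param noise A [noise_model()].
#' @param constants Model constants.
#' @param seed Integer RNG seed.
#' @return A `synthetic_experiment`: list with `design`, `truth`
#'   (per-plot data.frame), `weather`, `trajectories`, `calibration`,
#'   `observations` (one [observation_set()] per treatment), `noise`,
#'   `seed`.
#' @export
#' @examples
#' ex <- make_experiment(seed = 7)
#' names(ex$observations)
make_experiment <- function(design = default_design(),
                            noise = noise_model(),
                            constants = default_model_constants(),
                            seed = 1L) {
  set.seed(seed)
  weather <- generate_weather(design$n_days, seed = seed,
                              start_doy = design$weather_start_doy)
  set.seed(seed + 1L)
  nt <- length(design$n_rates)
  sow <- design$nominal_sowing_doy +
    runif(nt, -design$sowing_jitter_days, design$sowing_jitter_days)
  seedr <- design$nominal_seeding *
    (1 + runif(nt, -design$seeding_jitter_frac, design$seeding_jitter_frac))
  trt <- paste0("N", seq_len(nt) - 1L)
  truth_trt <- data.frame(treatment = trt, n_rate = design$n_rates,
                          sowing_doy = sow, seeding_rate = seedr)
  trajectories <- lapply(seq_len(nt), function(i) {
    run_crop_model(management_params(sow[i], seedr[i], design$n_rates[i]),
                   weather, constants)
  })
  names(trajectories) <- trt

  calibration <- fit_experiment_calibration(trajectories, design, noise,
                                            seed = seed + 2L)
  observations <- lapply(seq_len(nt), function(i) {
    generate_observations(trajectories[[i]], calibration,
                          noise = noise, reps = design$reps,
                          seed = seed + 10L + i)
  })
  names(observations) <- trt

  truth_plot <- truth_trt[rep(seq_len(nt), each = design$reps), ]
  truth_plot$plot <- paste0(truth_plot$treatment, "R",
                            rep(seq_len(design$reps), times = nt))
  rownames(truth_plot) <- NULL
  structure(list(design = design, truth = truth_plot,
                 truth_treatment = truth_trt, weather = weather,
                 trajectories = trajectories, calibration = calibration,
                 observations = observations, noise = noise, seed = seed),
            class = "synthetic_experiment")
}

# Calibration sweep emulating the relation-building trials: canopy states
# sampled along every trajectory between early tillering and flowering,
# observed through the noisy forward NDVI model, then regressed.
fit_experiment_calibration <- function(trajectories, design, noise, seed) {
  set.seed(seed)
  lai <- numeric(0); pna <- numeric(0)
  for (tr in trajectories) {
    sd_ <- attr(tr, "stage_days")
    days <- seq(15, sd_[["flowering"]], by = design$calibration_interval_days)
    rows <- match(round(days), round(tr$day))
    rows <- rows[!is.na(rows)]
    lai <- c(lai, tr$lai[rows])
    pna <- c(pna, tr$pna[rows])
  }
  keep <- lai > 0.05 & pna > 0.5
  lai <- lai[keep]; pna <- pna[keep]
  nd_lai <- clip01(forward_ndvi(lai, "LAI", noise) +
                     rnorm(length(lai), 0, noise$ndvi_sd), noise$ndvi_max)
  nd_pna <- clip01(forward_ndvi(pna, "PNA", noise) +
                     rnorm(length(pna), 0, noise$ndvi_sd), noise$ndvi_max)
  list(lai = fit_exponential(nd_lai, lai, "LAI"),
       pna = fit_exponential(nd_pna, pna, "PNA"))
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic_experiment (seed %d): %d N treatments x %d reps, %d weather days\n",
              x$seed, nrow(x$truth_treatment), x$design$reps,
              nrow(x$weather)))
  print(x$truth_treatment, digits = 4)
  invisible(x)
}

#' Write a synthetic experiment to a directory
#'
#' Writes `weather.csv`, `truth.csv`, `observations.csv` (treatment-pooled
#' LAIe/PNAe schema: `plot,stage,doy,lai_e,pna_e,sigma1,sigma2`) and
#' `config.yaml` (design, noise, calibration coefficients, seed).
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_weather(experiment$weather, file.path(dir, "weather.csv"))
  tt <- experiment$truth
  tt$sowing_doy <- round(tt$sowing_doy, 4)
  tt$seeding_rate <- round(tt$seeding_rate, 4)
  write.csv(tt[, c("plot", "treatment", "n_rate", "sowing_doy",
                   "seeding_rate")],
            file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  obs_rows <- do.call(rbind, lapply(names(experiment$observations), function(nm) {
    o <- experiment$observations[[nm]]
    data.frame(plot = nm, stage = o$stage, doy = o$doy,
               lai_e = round(o$o1, 6), pna_e = round(o$o2, 6),
               sigma1 = round(o$sigma1, 6), sigma2 = round(o$sigma2, 6))
  }))
  write.csv(obs_rows, file.path(dir, "observations.csv"),
            row.names = FALSE, quote = FALSE)
  cal <- experiment$calibration
  yaml::write_yaml(list(
    seed = experiment$seed,
    design = experiment$design,
    noise = unclass(experiment$noise),
    calibration = list(
      lai = list(a = cal$lai$a, b = cal$lai$b, r2 = cal$lai$r2),
      pna = list(a = cal$pna$a, b = cal$pna$b, r2 = cal$pna$r2))),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read an observation table (LAIe/PNAe schema) into observation sets
#'
#' Reads `plot,stage,doy,lai_e,pna_e,sigma1,sigma2` delimited text (as
#' written by [write_experiment()]) and returns one [observation_set()] per
#' plot/treatment identifier.
#'
#' @param path CSV path.
#' @return Named list of `observation_set` objects.
#' @export
read_observations <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "stage", "doy", "lai_e", "pna_e", "sigma1", "sigma2")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("observation file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(d, d$plot), function(g) {
    observation_set(g$stage, g$doy, g$lai_e, g$pna_e,
                    g$sigma1[1L], g$sigma2[1L])
  })
  out[unique(d$plot)]
}

#' Read raw NDVI readings, optionally averaging replicates
#'
#' Reads the `plot,stage,doy,ndvi[,rep]` schema.  When `aggregate = TRUE`
#' and a `rep` column exists, replicate readings are averaged to a single
#' observation per plot and stage (the canopy-sensor convention of taking
#' several readings per plot and using their mean).
#'
#' @param path CSV path.
#' @param aggregate Average over the `rep` column if present.
#' @return A `data.frame` with `plot`, `stage`, `doy`, `ndvi`.
#' @export
read_ndvi_readings <- function(path, aggregate = TRUE) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "stage", "doy", "ndvi")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("NDVI file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (aggregate && "rep" %in% names(d)) {
    agg <- stats::aggregate(ndvi ~ plot + stage + doy, data = d, FUN = mean)
    return(agg[order(agg$plot, agg$doy), ])
  }
  d[, need]
}
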