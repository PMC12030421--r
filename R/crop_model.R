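#' Management parameter set
#'
#' The three recalibrated crop-management parameters the assimilation walks
#' over, plus the fertilizer split schedule.
#'
#' @param sowing_doy Sowing date as day-of-year (may be fractional inside the
#'   sampler; trajectories are reported on whole days).
#' @param seeding_rate Seed mass sown per area, kg/ha (plant-density proxy).
#' @param n_amount Total fertilizer nitrogen, kg/ha.
#' @param n_split Ordered fractions of `n_amount` applied at pre-planting and
#'   at jointing; must sum to 1.  Default 50/50.
#' @return An object of class `management_params` (named list).
#' @export
#' @examples
#' management_params(148, 60, 210)
management_params <- function(sowing_doy, seeding_rate, n_amount,
                              n_split = c(0.5, 0.5)) {
  if (!is.finite(sowing_doy) || !is.finite(seeding_rate) ||
      !is.finite(n_amount)) {
    stop("management parameters must be finite numbers", call. = FALSE)
  }
  if (seeding_rate < 0 || n_amount < 0) {
    stop("seeding_rate and n_amount must be non-negative", call. = FALSE)
  }
  if (length(n_split) != 2L || abs(sum(n_split) - 1) > 1e-8) {
    stop("n_split must be two fractions summing to 1", call. = FALSE)
  }
  structure(list(sowing_doy = sowing_doy, seeding_rate = seeding_rate,
                 n_amount = n_amount, n_split = n_split),
            class = "management_params")
}

#' @export
print.management_params <- function(x, ...) {
  cat(sprintf("management_params: sowing doy %.1f, seeding %.1f kg/ha, N %.1f kg/ha (split %s)\n",
              x$sowing_doy, x$seeding_rate, x$n_amount,
              paste(x$n_split, collapse = "/")))
  invisible(x)
}

#' Cumulative growing degree-days from sowing
#'
#' Thermal time driver of the surrogate model.  The daily increment is
#' `max(0, (tmin + tmax)/2 - base_temp)`; accumulation starts at zero on the
#' sowing day, so day *d* after sowing carries the sum of the increments of
#' days 1..d.
#'
#' @param weather Weather `data.frame` (see [generate_weather()]).
#' @param sowing_doy Integer day-of-year of sowing; must fall inside the
#'   weather series.
#' @param base_temp Base temperature, deg C (default from the model
#'   constants, 10).
#' @return A `data.frame` with `day` (days after sowing, day 0 = sowing day),
#'   `doy`, and cumulative `gdd` (deg C d).
#' @export
#' @examples
#' w <- data.frame(date = NA, doy = 100:110, tmin = 15, tmax = 25, srad = 15)
#' compute_gdd(w, 100)$gdd # 0, 10, 20, ...
compute_gdd <- function(weather, sowing_doy,
                        base_temp = default_model_constants()$phenology$base_temp) {
  if (sowing_doy < min(weather$doy) || sowing_doy >= max(weather$doy)) {
    stop("insufficient weather coverage: sowing doy ", sowing_doy,
         " not inside weather span [", min(weather$doy), ", ",
         max(weather$doy), ")", call. = FALSE)
  }
  idx <- which(weather$doy >= sowing_doy)
  inc <- pmax(0, (weather$tmin[idx] + weather$tmax[idx]) / 2 - base_temp)
  # day 0 = sowing day carries gdd 0; day d accumulates days 1..d after sowing
  gdd <- cumsum(c(0, inc[-1L]))
  data.frame(day = seq_along(idx) - 1L, doy = weather$doy[idx], gdd = gdd)
}

#' Date phenological stages from a cumulative GDD series
#'
#' Each stage is dated at the first day its GDD threshold is reached; stages
#' whose threshold is never reached are returned as `NA`.
#'
#' @param gdd Either the `data.frame` returned by [compute_gdd()] or a plain
#'   non-decreasing numeric vector whose first element is day 0.
#' @param thresholds List with `gdd_at_stage`, see [phenology_thresholds()].
#' @return Named integer vector of stage days (days after sowing).
#' @export
advance_phenology <- function(gdd, thresholds = phenology_thresholds()) {
  g <- if (is.data.frame(gdd)) gdd$gdd else as.numeric(gdd)
  if (any(diff(g) < 0)) {
    stop("invariant violation: gdd series must be non-decreasing",
         call. = FALSE)
  }
  thr <- thresholds$gdd_at_stage
  vapply(thr, function(th) {
    i <- which(g >= th)
    if (length(i)) i[1L] - 1L else NA_integer_
  }, integer(1))
}

# Precompute weather-derived arrays shared by every model evaluation of a
# chain.  Centralizing this keeps run_crop_model and the MCMC fast path on a
# single code path.
precompute_weather <- function(weather, constants) {
  base <- constants$phenology$base_temp
  inc <- pmax(0, (weather$tmin + weather$tmax) / 2 - base)
  list(doy = weather$doy, inc = inc, cuminc = cumsum(inc),
       srad = weather$srad, doy0 = weather$doy[1L], n = nrow(weather))
}

# Deterministic daily simulation core.  sowing may be fractional: thermal
# time is measured from the (linearly interpolated) cumulative heat at the
# sowing instant, which keeps the likelihood surface continuous in theta.
simulate_core <- function(sowing, seeding, n_amount, pre, constants,
                          n_split = constants$nitrogen$n_split) {
  if (seeding < 0 || n_amount < 0) {
    stop("negative parameters: seeding_rate and n_amount must be >= 0",
         call. = FALSE)
  }
  if (sowing < pre$doy0 || sowing >= pre$doy[pre$n]) {
    stop("insufficient weather coverage: sowing doy ", sowing,
         " outside weather span", call. = FALSE)
  }
  cp <- constants$canopy; np <- constants$nitrogen; ap <- constants$assimilate
  # cumulative heat at the sowing instant (interpolated between whole days)
  i0 <- floor(sowing) - pre$doy0 + 1L
  frac <- sowing - floor(sowing)
  c_sow <- pre$cuminc[i0] + frac * if (i0 < pre$n) pre$inc[i0 + 1L] else 0
  first <- i0 + 1L                       # first whole day after sowing
  if (first > pre$n) stop("insufficient weather coverage", call. = FALSE)
  idx <- first:pre$n
  gdd <- pmax(0, pre$cuminc[idx] - c_sow)

  thr <- unlist(constants$phenology$gdd_at_stage)
  stage_pos <- vapply(thr, function(th) {
    i <- which(gdd >= th)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))

  n_supply <- np$soil_n + n_amount
  lai_max <- cp$lai_pot * seeding / (seeding + cp$k_seed) *
    n_supply / (n_supply + cp$k_n)
  # logistic growth ODE solution: initial canopy proportional to plant
  # density, ceiling set by N supply and (weakly) density
  lai0 <- min(cp$lai_init_per_seed * seeding, lai_max)
  sen <- rep(1, length(gdd))
  over <- gdd > thr[["flowering"]]
  sen[over] <- exp(-cp$senescence_rate * (gdd[over] - thr[["flowering"]]))
  x <- lai0 * exp(cp$r_growth * gdd)
  lai <- lai_max * x / (lai_max + x - lai0) * sen

  # pool-limited N uptake; fertilizer released at pre-planting and jointing
  nd <- length(gdd)
  avail <- np$soil_n + n_split[1L] * n_amount
  jpos <- stage_pos[["jointing"]]
  pna <- numeric(nd)
  acc <- 0
  umax <- np$uptake_max; kup <- np$k_uptake
  for (t in seq_len(nd)) {
    if (!is.na(jpos) && t == jpos) avail <- avail + n_split[2L] * n_amount
    up <- umax * lai[t] * avail / (avail + kup)
    acc <- acc + up
    avail <- avail - up
    pna[t] <- acc
  }

  mpos <- stage_pos[["maturity"]]
  grow <- seq_len(if (is.na(mpos)) nd else mpos)
  biomass <- sum(ap$rue * pre$srad[idx][grow] * (1 - exp(-ap$k_ext * lai[grow])))
  yield <- ap$harvest_index * biomass * ap$biomass_to_kg_ha *
    (1 - exp(-n_supply / ap$k_yield_n))

  list(doy = pre$doy[idx], day = seq_len(nd) + (floor(sowing) - sowing),
       gdd = gdd, lai = lai, pna = pna, stage_pos = stage_pos, yield = yield,
       lai_max = lai_max)
}

#' Run the surrogate rice growth model
#'
#' Deterministic daily-timestep simulation of canopy development (LAI),
#' plant nitrogen accumulation (PNA) and final yield from sowing to the end
#' of the weather series.  Canopy expansion is logistic in thermal time with
#' a ceiling that saturates in nitrogen supply (Michaelis-Menten) and plant
#' density, and senesces exponentially after flowering; N uptake is
#' proportional to LAI and limited by the remaining soil + fertilizer pool
#' (fertilizer released at pre-planting and jointing per the split); yield is
#' harvest-index times radiation-driven assimilate with a saturating N
#' response that plateaus above roughly 210 kg/ha applied N.
#'
#' @param params A [management_params()] object.
#' @param weather Weather `data.frame` covering sowing through maturity.
#' @param constants Model constants, see [default_model_constants()].
#' @return A `crop_trajectory`: `data.frame` with `day` (days after sowing,
#'   day 0 = sowing day), `doy`, `gdd`, `lai`, `pna`, `stage`, and attributes
#'   `yield` (kg/ha), `stage_days` (named, days after sowing), `stage_doys`
#'   and `params`.
#' @export
#' @examples
#' w <- generate_weather(250, seed = 1)
#' tr <- run_crop_model(management_params(148, 60, 210), w)
#' attr(tr, "yield")
run_crop_model <- function(params, weather,
                           constants = default_model_constants()) {
  stopifnot(inherits(params, "management_params"))
  pre <- precompute_weather(weather, constants)
  sim <- simulate_core(params$sowing_doy, params$seeding_rate,
                       params$n_amount, pre, constants,
                       n_split = params$n_split)
  stages <- crop_stages()
  stage_day <- rep(NA_integer_, length(sim$gdd))
  lab <- rep("sown", length(sim$gdd))
  for (s in names(sim$stage_pos)) {
    p <- sim$stage_pos[[s]]
    if (!is.na(p)) lab[p:length(lab)] <- s
  }
  # prepend the sowing day itself when sowing falls on a whole day
  traj <- data.frame(day = round(sim$day, 6), doy = sim$doy, gdd = sim$gdd,
                     lai = sim$lai, pna = sim$pna,
                     stage = factor(lab, levels = stages))
  if (abs(params$sowing_doy - round(params$sowing_doy)) < 1e-9) {
    cp <- constants$canopy
    sow_row <- data.frame(day = 0, doy = round(params$sowing_doy), gdd = 0,
                          lai = min(cp$lai_init_per_seed * params$seeding_rate,
                                    sim$lai_max),
                          pna = 0,
                          stage = factor("sown", levels = stages))
    traj <- rbind(sow_row, traj)
  }
  stage_days <- vapply(sim$stage_pos, function(p) {
    if (is.na(p)) NA_real_ else round(sim$day[p], 6)
  }, numeric(1))
  stage_doys <- vapply(sim$stage_pos, function(p) {
    if (is.na(p)) NA_real_ else as.numeric(sim$doy[p])
  }, numeric(1))
  structure(traj, yield = sim$yield, stage_days = stage_days,
            stage_doys = stage_doys, params = params,
            class = c("crop_trajectory", "data.frame"))
}

#' Extract simulated state at phenological stages
#'
#' Returns the simulated LAI and PNA pairs at the dates the requested stages
#' were reached, preserving the requested order.
#'
#' @param traj A `crop_trajectory` from [run_crop_model()].
#' @param stages Character vector of stage names (subset of
#'   [crop_stages()]); an empty vector returns a zero-row frame.
#' @return `data.frame` with `stage`, `day`, `doy`, `lai`, `pna`.
#' @export
extract_at_stages <- function(traj, stages = observation_stages()) {
  stage_days <- attr(traj, "stage_days")
  if (length(stages) == 0L) {
    return(data.frame(stage = character(), day = numeric(), doy = numeric(),
                      lai = numeric(), pna = numeric()))
  }
  bad <- setdiff(stages, names(stage_days))
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  miss <- stages[is.na(stage_days[stages])]
  if (length(miss)) {
    stop("stage not reached: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- match(stage_days[stages], traj$day)
  data.frame(stage = stages, day = traj$day[rows], doy = traj$doy[rows],
             lai = traj$lai[rows], pna = traj$pna[rows])
}

#' @export
print.crop_trajectory <- function(x, ...) {
  sd <- attr(x, "stage_days")
  cat(sprintf("crop_trajectory: %d days, peak LAI %.2f, final PNA %.1f kg/ha, yield %.0f kg/ha\n",
              nrow(x), max(x$lai, na.rm = TRUE), max(x$pna, na.rm = TRUE),
              attr(x, "yield")))
  cat("stage days after sowing:",
      paste(names(sd), ifelse(is.na(sd), "-", sd), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
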