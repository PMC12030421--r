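test_that("synthetic weather follows the configured climatology", {
  clim <- default_climate()
  clim$temp_noise_sd_c <- 1e-12
  clim$srad_noise_sd <- 1e-12
  w <- generate_weather(365, climate = clim, seed = 1)
  doy <- w$doy
  expect_equal((w$tmin + w$tmax) / 2,
               clim$temp_mean_c +
                 clim$temp_amp_c * cos(2 * pi * (doy - clim$temp_peak_doy) / 365),
               tolerance = 0.01)  # rounding to 2 decimals in the writer path

  expect_identical(generate_weather(100, seed = 5),
                   generate_weather(100, seed = 5))
  w2 <- generate_weather(400, seed = 6)
  expect_true(all(w2$tmax >= w2$tmin))
  expect_true(all(diff(w2$doy) == 1))

  # multi-year sample: July mean temperature near the configured peak
  wl <- generate_weather(3650, seed = 2)
  july <- (wl$doy - 1) %% 365 + 1
  sel <- july >= 186 & july <= 216
  tm <- (wl$tmin[sel] + wl$tmax[sel]) / 2
  clim0 <- default_climate()
  expected <- mean(clim0$temp_mean_c +
                     clim0$temp_amp_c * cos(2 * pi * ((186:216) - clim0$temp_peak_doy) / 365))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - expected), 3 * se)
})

test_that("forward NDVI is monotone, saturating and inverse-compatible", {
  nm <- noise_model()
  expect_equal(forward_ndvi(0, "LAI", nm), 0)
  expect_equal(forward_ndvi(1e9, "LAI", nm), nm$ndvi_max)
  v <- forward_ndvi(seq(0, 12, by = 0.1), "LAI", nm)
  expect_true(all(diff(v) >= 0))

  # slope collapse in the saturated regime: dNDVI/dLAI at 8 vs at 2
  h <- 1e-5
  s2 <- (forward_ndvi(2 + h, "LAI", nm) - forward_ndvi(2 - h, "LAI", nm)) / (2 * h)
  s8 <- (forward_ndvi(8 + h, "LAI", nm) - forward_ndvi(8 - h, "LAI", nm)) / (2 * h)
  expect_lt(s8 / s2, 0.05)

  # below the onset the map is the exact inverse of the exponential form
  st <- c(0.5, 2, 4, 6)
  nd <- forward_ndvi(st, "LAI", nm)
  a <- nm$lai_sat * exp(-nm$k_lai * nm$ndvi_max)
  expect_equal(a * exp(nm$k_lai * nd), st, tolerance = 1e-10)
})

test_that("replicated observations reduce to inverted truth without noise", {
  w <- season_weather(1)
  tr <- run_crop_model(management_params(148, 60, 140), w)
  nm0 <- noise_model(ndvi_sd = 1e-12, lai_cv = 1e-12, pna_cv = 1e-12,
                     sigma1_floor = 0.2, sigma2_floor = 5)
  # calibration fitted on noiseless forward data: near-exact coefficients
  st <- seq(0.3, 6.4, length.out = 40)
  cal <- list(lai = fit_exponential(forward_ndvi(st, "LAI", nm0), st, "LAI"),
              pna = fit_exponential(forward_ndvi(seq(2, 88, length.out = 40),
                                                 "PNA", nm0),
                                    seq(2, 88, length.out = 40), "PNA"))
  obs <- generate_observations(tr, cal, noise = nm0, reps = 3, seed = 1)
  truth <- extract_at_stages(tr)
  unsat <- truth$lai < nm0$lai_sat
  expect_equal(obs$o1[unsat], truth$lai[unsat], tolerance = 1e-4)
  unsat2 <- truth$pna < nm0$pna_sat
  expect_equal(obs$o2[unsat2], truth$pna[unsat2], tolerance = 1e-3)

  # single replicate: SDs fall back to the configured floors
  obs1 <- generate_observations(tr, cal, noise = nm0, reps = 1, seed = 2)
  expect_equal(obs1$sigma1, nm0$sigma1_floor)
  expect_equal(obs1$sigma2, nm0$sigma2_floor)

  # many replicates: empirical replicate SD tracks the configured CV
  nm <- noise_model(ndvi_sd = 1e-12)
  obs_many <- generate_observations(tr, cal, noise = nm, reps = 1000,
                                    seed = 3)
  reps <- attr(obs_many, "replicates")
  jnt <- reps$lai_e[reps$stage == "jointing"]
  truth_jnt <- truth$lai[truth$stage == "jointing"]
  expect_lt(abs(sd(jnt) / truth_jnt - nm$lai_cv) / nm$lai_cv, 0.10)
})

test_that("experiment bundles are seeded, complete and within bounds", {
  ex1 <- make_experiment(seed = 5)
  ex2 <- make_experiment(seed = 5)
  expect_identical(ex1$truth, ex2$truth)
  expect_identical(ex1$observations, ex2$observations)
  expect_identical(ex1$weather, ex2$weather)

  expect_equal(nrow(ex1$truth), 15L)  # 5 N levels x 3 replicates
  expect_setequal(unique(ex1$truth$n_rate), c(0, 70, 140, 210, 280))

  sp <- default_parameter_space()
  for (s in 1:25) {
    tt <- make_experiment(seed = s)$truth_treatment
    expect_true(all(tt$sowing_doy >= sp$min[["sowing_doy"]] &
                      tt$sowing_doy <= sp$max[["sowing_doy"]]))
    expect_true(all(tt$seeding_rate >= sp$min[["seeding_rate"]] &
                      tt$seeding_rate <= sp$max[["seeding_rate"]]))
    expect_true(all(tt$n_rate >= sp$min[["n_amount"]] &
                      tt$n_rate <= sp$max[["n_amount"]]))
  }

  stages <- unique(unlist(lapply(ex1$observations, function(o) o$stage)))
  expect_true(all(stages %in% observation_stages()))
})

test_that("spectral inversion underestimates peak LAI beyond the saturation onset", {
  errs <- numeric(0)
  for (s in 1:8) {
    ex <- make_experiment(seed = 200 + s)
    for (trt in names(ex$trajectories)) {
      tr <- ex$trajectories[[trt]]
      truth <- extract_at_stages(tr)
      if (max(truth$lai) <= ex$noise$lai_sat) next
      o <- ex$observations[[trt]]
      peak_stage <- which.max(truth$lai)
      errs <- c(errs, o$o1[peak_stage] - truth$lai[peak_stage])
    }
  }
  expect_gt(length(errs), 10)
  expect_lt(mean(errs), 0)
})
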