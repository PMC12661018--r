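# Still-segment fixture: constant unit orientations observed through a
# known gain/offset distortion (observed = true * gain + offset).
stills_rec <- function(gain = c(1, 1, 1), offset = c(0, 0, 0), fs = 25,
                       secs = 10) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0.6, 0.64, 0.48))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  seg <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(i) {
    matrix(rep(dirs[i, ] * gain + offset, each = fs * secs), ncol = 3)
  }))
  triaxial_recording(seg, fs, wide_dev(fs))
}

test_that("autocalibration recovers gains and offsets from stills", {
  cal0 <- autocalibrate_device(stills_rec())
  expect_lt(max(abs(cal0$gain - 1)), 1e-4)
  expect_lt(max(abs(cal0$offset)), 1e-4)

  g <- c(1.05, 0.97, 1.02)
  o <- c(0.02, -0.03, 0.01)
  cal <- autocalibrate_device(stills_rec(g, o))
  expect_lt(max(abs(cal$gain - g)), 1e-3)
  expect_lt(max(abs(cal$offset - o)), 1e-3)
  expect_lt(cal$residual, 1e-3)

  # applying the estimate back to its own stills lands on the unit sphere
  corr <- apply_calibration(stills_rec(g, o), cal)
  fe <- extract_features(corr, device = wide_dev())
  still <- fe[fe$sd_raw < 0.013, ]
  vm <- sqrt(still$mean_u^2 + still$mean_v^2 + still$mean_w^2)
  expect_lt(stats::median(abs(vm - 1)), 1e-3)
})

test_that("underdetermined sphere fits fall back to the identity", {
  one <- const_rec(c(1, 0, 0), n = 25 * 30)
  expect_warning(cal <- autocalibrate_device(one), "underdetermined")
  expect_true(cal$warning_flag)
  expect_equal(cal$gain, c(1, 1, 1))
  expect_equal(cal$rotation, diag(3))
})

test_that("individual calibration recovers mounting rotations", {
  sim <- simulate_recording(behaviour_script(c("stand", "walk"), c(60, 180)),
                            fs_hz = 25, seed = 5)

  # perfect mounting: rotation within 0.5 degrees of the identity
  ic0 <- individual_calibration(extract_features(sim$recording))
  ang0 <- acos(actithigh:::clamp((sum(diag(ic0$rotation)) - 1) / 2, -1, 1)) *
    180 / pi
  expect_lt(ang0, 0.5)

  # sensor rotated 15 degrees about V: recovered within 1 degree of inverse
  th <- 15 / 180 * pi
  Rv <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  obs <- triaxial_recording(t(Rv %*% t(sim$recording$samples)), 25,
                            sim$recording$device)
  ic <- individual_calibration(extract_features(obs))
  mismatch <- ic$rotation %*% Rv          # should be ~identity
  ang <- acos(actithigh:::clamp((sum(diag(mismatch)) - 1) / 2, -1, 1)) *
    180 / pi
  expect_lt(ang, 1)

  # upside-down mounting is detected and flipped back
  ud <- triaxial_recording(sim$recording$samples %*% diag(c(-1, -1, 1)),
                           25, sim$recording$device)
  icud <- individual_calibration(extract_features(ud))
  fixed <- extract_features(apply_calibration(ud, icud))
  stand_epochs <- 1:50
  expect_lt(stats::median(fixed$inclination[stand_epochs]), 15)

  # too little locomotion: identity with a warning flag
  still <- simulate_recording(behaviour_script("sedentary", 120),
                              fs_hz = 25, seed = 6)
  expect_warning(
    icf <- individual_calibration(extract_features(still$recording)),
    "too few"
  )
  expect_true(icf$warning_flag)
})

test_that("apply_calibration composes and preserves the time base", {
  sim <- simulate_recording(behaviour_script("walk", 30), fs_hz = 25,
                            seed = 7)
  rec <- sim$recording
  expect_equal(apply_calibration(rec, calibration_params())$samples,
               rec$samples)

  th <- 10 / 180 * pi
  R1 <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  c1 <- calibration_params(rotation = R1)
  c2 <- calibration_params(rotation = R2)
  seq_ <- apply_calibration(apply_calibration(rec, c1), c2)
  onc <- apply_calibration(rec, calibration_params(rotation = R2 %*% R1))
  expect_equal(seq_$samples, onc$samples, tolerance = 1e-9)
  expect_equal(nrow(seq_$samples), nrow(rec$samples))
  expect_equal(seq_$start_time, rec$start_time)
})

test_that("full two-step calibration bounds static inclination error", {
  # distorted device worn slightly rotated; stills + locomotion available
  g <- c(1.04, 0.96, 1.01)
  o <- c(0.03, -0.02, 0.02)
  th <- 8 / 180 * pi
  Rv <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  sim <- simulate_recording(
    behaviour_script(c("stand", "walk", "sedentary"), c(60, 180, 60)),
    params = behaviour_params(
      stand = list(noise_sd_g = 0.005, inclination_jitter_deg = 0.5),
      sedentary = list(noise_sd_g = 0.005, inclination_jitter_deg = 0.5)
    ),
    fs_hz = 25, seed = 8
  )
  distorted <- sweep(sweep(t(Rv %*% t(sim$recording$samples)), 2, g, "*"),
                     2, o, "+")
  obs <- triaxial_recording(distorted, 25, wide_dev())
  still_cal <- autocalibrate_device(stills_rec(g, o))
  step1 <- apply_calibration(obs, still_cal)
  ic <- individual_calibration(extract_features(step1))
  fixed <- extract_features(apply_calibration(step1, ic))
  expect_lt(abs(stats::median(fixed$inclination[1:55]) - 10), 2)
  expect_lt(abs(stats::median(fixed$inclination[245:295]) - 75), 2)
})

test_that("calibration parameter sanity bounds are enforced", {
  expect_error(calibration_params(gain = c(3, 1, 1)), "gain")
  expect_error(calibration_params(offset = c(0.6, 0, 0)), "offset")
  expect_error(calibration_params(rotation = diag(c(1, 1, 2))),
               "orthonormal")
})
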