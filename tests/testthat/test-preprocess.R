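test_that("zero-phase low-pass has exact DC gain and the expected rolloff", {
  cst <- const_rec(c(0.7, 0.7, 0.7), n = 2500)
  f <- lowpass_filter(cst, 5)
  expect_lt(max(abs(f$samples - 0.7)), 1e-9)

  # at the cutoff the forward-backward response is the squared -3 dB
  # point: amplitude ratio 1/2 (amplitude via RMS * sqrt(2))
  tone <- sine_rec(5, 1, dur_s = 100)
  ft <- lowpass_filter(tone, 5)
  mid <- 500:2000
  expect_equal(stats::sd(ft$samples[mid, 1]) * sqrt(2), 0.5,
               tolerance = 0.02)

  # a tone a decade above the cutoff is attenuated by >= 70 dB
  hi <- sine_rec(5, 1, dur_s = 100)
  fh <- lowpass_filter(hi, 0.5)
  att_db <- 20 * log10(stats::sd(fh$samples[mid, 1]) /
                         stats::sd(hi$samples[mid, 1]))
  expect_lt(att_db, -70)

  expect_error(lowpass_filter(cst, 13), "Nyquist")
})

test_that("epoch grid and orientation features match the analytic model", {
  sim <- simulate_recording(behaviour_script("stand", 60), fs_hz = 25,
                            seed = 1)
  fe <- extract_features(sim$recording)
  expect_equal(nrow(fe), 59)
  expect_equal(fe$t_center, 1:59)

  # noise- and wander-free standing: inclination exact, no intensity
  p <- behaviour_params(stand = list(noise_sd_g = 0,
                                     inclination_jitter_deg = 0))
  clean <- simulate_recording(behaviour_script("stand", 30), params = p,
                              fs_hz = 25, seed = 2)
  fc <- extract_features(clean$recording)
  expect_lt(max(abs(fc$inclination - 10)), 0.5)
  expect_lt(max(fc$sd_raw), 1e-6)

  # walking cadence recovered from the spectral peak
  walk <- simulate_recording(behaviour_script("walk", 120), fs_hz = 25,
                             seed = 3)
  fw <- extract_features(walk$recording)
  expect_lt(abs(stats::median(fw$cadence) - 1.8), 0.15)

  expect_error(extract_features(const_rec(c(1, 0, 0), n = 30)), "2 s")
})

test_that("inclination is invariant to overall gain", {
  sim <- simulate_recording(behaviour_script(c("stand", "sedentary"),
                                             c(30, 30)), fs_hz = 25, seed = 4)
  fe <- extract_features(sim$recording)
  scaled <- triaxial_recording(sim$recording$samples * 1.7, 25, wide_dev())
  fs <- extract_features(scaled, device = wide_dev())
  expect_equal(fs$inclination, fe$inclination, tolerance = 1e-6)
})

test_that("chunked feature extraction equals whole-recording extraction", {
  sim <- simulate_recording(behaviour_script(c("walk", "stand", "cycle"),
                                             c(40, 20, 40)),
                            fs_hz = 25, seed = 5)
  whole <- extract_features(sim$recording)
  chunked <- actithigh:::extract_features_chunked(sim$recording, 5, 30)
  expect_equal(chunked$sd_raw, whole$sd_raw, tolerance = 1e-8)
  expect_equal(chunked$inclination, whole$inclination, tolerance = 1e-6)
  expect_equal(chunked$cadence, whole$cadence, tolerance = 1e-6)
})

test_that("SD polynomial correction evaluates and fits exactly", {
  expect_equal(correct_sd(0.37, narrow_dev()), 0.37)
  dev2 <- device_model("d", 4, 25, sd_correction = c(0.1, 1, 0))
  expect_equal(correct_sd(0.5, dev2), 0.525)

  # monotone non-decreasing over the dynamic range for the default set
  grid <- seq(0, 4, by = 0.01)
  expect_true(all(diff(correct_sd(grid, dev2)) >= 0))

  # exact recovery of identity and of a noiseless quadratic
  x <- seq(0.05, 1.5, length.out = 40)
  cf1 <- calibrate_sd_polynomial(list(sd_clipped = x, sd_reference = x))
  expect_equal(unname(cf1[]), c(0, 1, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  y <- 0.05 * x^2 + 1.1 * x
  cf2 <- calibrate_sd_polynomial(list(sd_clipped = x, sd_reference = y))
  expect_equal(unname(cf2[]), c(0.05, 1.1, 0), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(calibrate_sd_polynomial(list(sd_clipped = x[1:5],
                                            sd_reference = x[1:5])),
               "at least 10")
  same <- rep(0.4, 12)
  expect_error(calibrate_sd_polynomial(list(sd_clipped = same,
                                            sd_reference = same)),
               "degenerate")
})

test_that("saturation deflates SD and the fitted polynomial restores it", {
  wide <- wide_dev()
  narrow <- narrow_dev(2)
  amps <- seq(0.3, 1.6, by = 0.1)
  pairs <- do.call(rbind, lapply(seq_along(amps), function(i) {
    p <- behaviour_params(run = list(periodic_amplitude_g = amps[i],
                                     noise_sd_g = 0))
    sim <- simulate_recording(behaviour_script("run", 30), params = p,
                              fs_hz = 25, device = wide, seed = 100 + i)
    clip <- apply_device_model(sim$recording, narrow)
    fw <- extract_features(sim$recording, device = wide)
    fc <- extract_features(clip, device = wide)
    data.frame(sd_clipped = fc$sd_raw, sd_reference = fw$sd_raw)
  }))
  # the saturation property the correction targets
  high <- pairs$sd_reference > 0.9
  expect_true(all(pairs$sd_clipped[high] < pairs$sd_reference[high]))

  cf <- calibrate_sd_polynomial(pairs)
  expect_lt(attr(cf, "rms"), 0.05)
  devc <- device_model("narrow", 2, 25, sd_correction = cf)
  corrected <- correct_sd(pairs$sd_clipped, devc)
  rel <- abs(corrected - pairs$sd_reference) / pmax(pairs$sd_reference, 0.1)
  expect_lt(max(rel), 0.10)
})
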