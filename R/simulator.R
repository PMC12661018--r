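# Synthetic thigh-accelerometer signal generator: the test substrate for
# every other module. Behaviour signals are minimal gravity-projection +
# sinusoid constructions (not biomechanical gait models): the classifier
# consumes only SD / inclination / cadence, so this suffices to exercise
# every decision branch.

#' Behaviour script
#'
#' Ordered segments of behaviours with durations, describing a (laboratory
#' or free-living) session.
#'
#' @param behaviour character vector of behaviour labels
#'   (see [behaviour_levels()]).
#' @param duration_s positive durations in seconds (integer seconds keep
#'   the per-second ground truth exact).
#' @return A `data.frame` of class `behaviour_script`.
#' @export
behaviour_script <- function(behaviour, duration_s) {
  stopifnot(length(behaviour) == length(duration_s), all(duration_s > 0))
  unknown <- setdiff(behaviour, behaviour_levels())
  if (length(unknown)) stop("unknown behaviour: ", paste(unknown, collapse = ", "))
  structure(
    data.frame(behaviour = behaviour, duration_s = as.numeric(duration_s)),
    class = c("behaviour_script", "data.frame")
  )
}

#' Standard laboratory protocol script
#'
#' Six behaviours of one minute each separated by 15-second standing
#' breaks (roughly a 7.5-minute session), emulating a structured
#' laboratory validation protocol.
#'
#' @param behaviours behaviours to cycle through.
#' @param behaviour_s seconds per behaviour bout.
#' @param break_s seconds of standing between bouts.
#' @return A [behaviour_script()].
#' @export
lab_protocol_script <- function(behaviours = c("sedentary", "stand", "walk",
                                               "stairs", "run", "cycle"),
                                behaviour_s = 60, break_s = 15) {
  beh <- as.vector(rbind(behaviours, "stand"))
  dur <- as.vector(rbind(rep(behaviour_s, length(behaviours)),
                         rep(break_s, length(behaviours))))
  behaviour_script(beh[-length(beh)], dur[-length(dur)])
}

#' Default behaviour signal parameters
#'
#' Per-behaviour mean thigh inclination (degrees from gravity), slow
#' inclination wander (degrees), dominant periodic frequency (Hz; 0 for
#' static postures), periodic amplitude (g), white sensor noise SD (g) and
#' whether the posture leans forward. The values are package choices
#' consistent with qualitative descriptions of thigh-worn signals: daily
#' movement rarely exceeds 5-6 Hz, sitting puts the thigh near horizontal,
#' stair climbing lifts the thigh higher than level walking, and cycling
#' holds a strongly forward-leaning thigh at pedalling cadence. "move" is
#' brief irregular activity (shifting, a few steps) modelled as
#' slow-cadence bursts with short quiet gaps.
#'
#' @param ... named per-behaviour overrides, each a list with any of
#'   `inclination_deg`, `inclination_jitter_deg`, `cadence_hz`,
#'   `periodic_amplitude_g`, `noise_sd_g`, `forward_lean`, `burst_s`,
#'   `gap_s`.
#' @return Named list of per-behaviour parameter lists.
#' @export
behaviour_params <- function(...) {
  bp <- function(incl, jit, cad, amp, noise, fwd, burst = Inf, gap = 0) {
    list(inclination_deg = incl, inclination_jitter_deg = jit,
         cadence_hz = cad, periodic_amplitude_g = amp, noise_sd_g = noise,
         forward_lean = fwd, burst_s = burst, gap_s = gap)
  }
  p <- list(
    sedentary = bp(75, 2, 0.0, 0.00, 0.02, TRUE),
    stand     = bp(10, 2, 0.0, 0.00, 0.02, TRUE),
    move      = bp(15, 3, 0.5, 0.20, 0.03, TRUE, burst = 4, gap = 0.5),
    walk      = bp(20, 2, 1.8, 0.35, 0.03, TRUE),
    run       = bp(25, 2, 2.8, 1.20, 0.05, TRUE),
    stairs    = bp(35, 2, 1.6, 0.40, 0.03, TRUE),
    cycle     = bp(55, 3, 1.1, 0.30, 0.03, TRUE)
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% names(p)) stop("unknown behaviour: ", nm)
    p[[nm]][names(mods[[nm]])] <- mods[[nm]]
  }
  p
}

# smooth slow wander in [-1, 1]-ish units: per-second normals linearly
# interpolated to the sample grid, then lightly smoothed
slow_wander <- function(n, fs) {
  nsec <- max(2, ceiling(n / fs) + 1)
  knots <- stats::rnorm(nsec)
  y <- stats::approx(seq_len(nsec) - 1, knots,
                     xout = (seq_len(n) - 1) / fs, rule = 2)$y
  stats::filter(y, rep(1 / 5, 5), sides = 2, circular = TRUE)
}

# one behaviour segment of n samples (unclipped, in g)
segment_signal <- function(b, n, fs, par) {
  t <- (seq_len(n) - 1) / fs
  th <- (par$inclination_deg +
           par$inclination_jitter_deg * slow_wander(n, fs)) / DEG
  sgn <- if (isTRUE(par$forward_lean)) 1 else sample(c(-1, 1), 1)
  vtilt <- (par$inclination_jitter_deg / DEG) * 0.5 * slow_wander(n, fs)
  # exact unit gravity direction
  d <- cbind(cos(th), vtilt, sin(th) * sgn)
  d <- d / sqrt(rowSums(d^2))
  if (par$cadence_hz > 0 && par$periodic_amplitude_g > 0) {
    env <- rep(1, n)
    if (is.finite(par$burst_s) && par$gap_s > 0) {
      cyc <- par$burst_s + par$gap_s
      phase_off <- stats::runif(1, 0, cyc)
      env <- as.numeric(((t + phase_off) %% cyc) < par$burst_s)
    }
    ph <- stats::runif(1, 0, 2 * pi)
    osc_u <- par$periodic_amplitude_g * sin(2 * pi * par$cadence_hz * t + ph)
    # in phase with U: the acceleration magnitude then oscillates with the
    # periodic amplitude (so intensity grows with effort, and range
    # clipping visibly deflates the SD feature)
    osc_w <- par$periodic_amplitude_g * sin(2 * pi * par$cadence_hz * t + ph)
    d[, 1] <- d[, 1] + env * osc_u
    d[, 3] <- d[, 3] + env * osc_w
  }
  if (par$noise_sd_g > 0) {
    d <- d + matrix(stats::rnorm(3 * n, sd = par$noise_sd_g), n, 3)
  }
  d
}

#' Simulate a labelled thigh recording
#'
#' Generates, per script segment, a gravity projection of the behaviour's
#' thigh posture plus a cadence sinusoid on the U and W axes, slow
#' inclination wander, and white sensor noise; then clips through the
#' device model (saturation). Deterministic given `seed`.
#'
#' @param script a [behaviour_script()].
#' @param params per-behaviour parameters from [behaviour_params()].
#' @param fs_hz generator sampling frequency; must satisfy Nyquist for the
#'   fastest cadence in `params` (the point of a device under test is to
#'   violate it downstream, via [downsample()]).
#' @param device [device_model()] the signal is observed through.
#' @param seed integer seed.
#' @return List with `recording` (a [triaxial_recording()]) and `truth`
#'   (per-second ground-truth [epoch_labels()]).
#' @export
simulate_recording <- function(script, params = behaviour_params(),
                               fs_hz = 25,
                               device = device_model("narrow-range", 4, fs_hz),
                               seed = 1) {
  stopifnot(inherits(script, "behaviour_script"))
  cad_max <- max(vapply(script$behaviour,
                        function(b) params[[b]]$cadence_hz, numeric(1)))
  if (fs_hz < 2 * cad_max) {
    stop("fs ", fs_hz, " Hz below Nyquist for cadence ", cad_max, " Hz")
  }
  with_seed(seed, {
    segs <- vector("list", nrow(script))
    truth <- character(0)
    for (k in seq_len(nrow(script))) {
      b <- script$behaviour[k]
      dsec <- script$duration_s[k]
      n <- round(dsec * fs_hz)
      segs[[k]] <- segment_signal(b, n, fs_hz, params[[b]])
      truth <- c(truth, rep(b, round(dsec)))
    }
    ideal <- do.call(rbind, segs)
    wide <- device_model("ideal-wide", 1e6, fs_hz)
    rec <- apply_device_model(
      triaxial_recording(ideal, fs_hz, wide, start_time = 0), device
    )
    list(recording = rec, truth = epoch_labels(truth, t0_s = 0))
  })
}

#' Superimpose heel-drop synchronisation spikes
#'
#' At each anchor time, adds `n_drops` short biphasic spikes 250 ms apart
#' on the U axis (nominal 40 ms width; realised at nearest-sample
#' resolution so the spike is visible on any supported grid), then
#' re-applies device clipping.
#'
#' @param rec a [triaxial_recording()].
#' @param times_s anchor times in the recording's own clock.
#' @param n_drops spikes per anchor (protocol default 3).
#' @param amplitude_g spike amplitude in g; may exceed the device range
#'   (it will clip).
#' @return The [triaxial_recording()] with spikes.
#' @export
inject_heel_drops <- function(rec, times_s, n_drops = 3, amplitude_g = 3) {
  if (!length(times_s)) return(rec)
  tt <- rec_times(rec)
  if (any(times_s < tt[1] | times_s > tt[length(tt)])) {
    stop("anchor time outside recording span")
  }
  s <- rec$samples
  n <- nrow(s)
  for (t0 in times_s) {
    for (j in seq_len(n_drops) - 1) {
      i <- which.min(abs(tt - (t0 + 0.25 * j)))
      s[i, 1] <- s[i, 1] + amplitude_g
      if (i + 1 <= n) s[i + 1, 1] <- s[i + 1, 1] + 0.9 * amplitude_g
      if (i + 2 <= n) s[i + 2, 1] <- s[i + 2, 1] - 0.7 * amplitude_g
    }
  }
  wide <- device_model("ideal-wide", 1e6, rec$fs_hz)
  apply_device_model(
    triaxial_recording(s, rec$fs_hz, wide, start_time = rec$start_time),
    rec$device
  )
}

#' Observe a recording through a drifted clock
#'
#' Returns the same physical signal as seen by a device whose clock
#' satisfies `t_observed = t_true * (1 + drift_ppm * 1e-6) + offset_s`.
#' The copy keeps the original nominal time grid; each nominal sample time
#' is mapped back through the clock model and the physical signal is
#' linearly interpolated there (held at the edges), with independent
#' sensor noise added. A pure offset therefore appears as an array-level
#' cross-correlation lag of `offset_s`.
#'
#' @param rec a [triaxial_recording()].
#' @param offset_s clock offset in seconds.
#' @param drift_ppm clock drift in parts per million (|drift| < 1000).
#' @param seed integer seed for the added noise.
#' @param noise_sd_g independent sensor noise SD in g (0 for none).
#' @return The drifted-copy [triaxial_recording()].
#' @export
derive_drifted_copy <- function(rec, offset_s, drift_ppm, seed = 1,
                                noise_sd_g = 0.005) {
  stopifnot(abs(drift_ppm) < 1000)
  tt <- rec_times(rec)
  t_true <- (tt - offset_s) / (1 + drift_ppm * 1e-6)
  out <- vapply(1:3, function(k) {
    stats::approx(tt, rec$samples[, k], xout = t_true, rule = 2)$y
  }, numeric(length(tt)))
  if (noise_sd_g > 0) {
    out <- out + with_seed(seed, matrix(stats::rnorm(length(out),
                                                     sd = noise_sd_g),
                                        nrow(out), 3))
  }
  wide <- device_model("ideal-wide", 1e6, rec$fs_hz)
  apply_device_model(
    triaxial_recording(out, rec$fs_hz, wide, start_time = rec$start_time),
    rec$device
  )
}

#' Simulate a rater's annotation track
#'
#' Corrupts a ground-truth label series the way a human video annotator
#' would: each epoch is independently relabelled to a random other
#' behaviour with probability `confusion_rate` or marked "uncertain" with
#' probability `uncertain_rate`; the resulting interval boundaries are
#' then jittered by `N(0, boundary_jitter_s)` (kept strictly increasing).
#' Deterministic given `seed`.
#'
#' @param truth per-second [epoch_labels()].
#' @param boundary_jitter_s SD of boundary perturbation in seconds.
#' @param confusion_rate per-epoch relabelling probability in [0, 1).
#' @param uncertain_rate per-epoch "uncertain" probability in [0, 1).
#' @param seed integer seed.
#' @param rater rater identifier.
#' @return An [annotation_track()].
#' @export
simulate_annotations <- function(truth, boundary_jitter_s = 0,
                                 confusion_rate = 0, uncertain_rate = 0,
                                 seed = 1, rater = "R1") {
  stopifnot(confusion_rate >= 0, confusion_rate < 1,
            uncertain_rate >= 0, uncertain_rate < 1)
  lab <- as.character(truth)
  t0 <- attr(truth, "t0_s") %||% 0
  with_seed(seed, {
    n <- length(lab)
    flip <- stats::runif(n) < confusion_rate
    for (i in which(flip)) {
      lab[i] <- sample(setdiff(behaviour_levels(), lab[i]), 1)
    }
    lab[stats::runif(n) < uncertain_rate] <- "uncertain"
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    bounds <- c(0, ends)
    if (boundary_jitter_s > 0 && length(bounds) > 2) {
      interior <- 2:(length(bounds) - 1)
      bounds[interior] <- bounds[interior] +
        stats::rnorm(length(interior), sd = boundary_jitter_s)
      bounds <- clamp(bounds, 0, n)
      bounds <- cummax(bounds)
    }
    keep <- diff(bounds) > 1e-9
    annotation_track(
      start_s = t0 + bounds[-length(bounds)][keep],
      end_s = t0 + bounds[-1][keep],
      label = r$values[keep],
      rater = rater
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
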