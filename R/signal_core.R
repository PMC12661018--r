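# Data model for raw triaxial recordings, CSV I/O, resampling and device
# emulation.
#
# Axis convention (fixed throughout the package):
#   U = longitudinal thigh axis, positive toward the knee; aligned with
#       gravity when standing upright,
#   V = mediolateral,
#   W = anteroposterior, positive forward.
# All accelerations are in g (1 g = 9.80665 m/s^2).

#' Accelerometer device model
#'
#' Describes a device's dynamic range (half-range in g, so 4 means +/- 4 g),
#' nominal sampling frequency, and the second-order polynomial correction
#' `(c2, c1, c0)` applied to the standard-deviation feature to compensate
#' for saturation of narrow-range sensors. The identity correction is
#' `(0, 1, 0)`.
#'
#' @param name device name.
#' @param dynamic_range_g positive half-range in g.
#' @param fs_nominal_hz positive nominal sampling frequency in Hz.
#' @param sd_correction numeric length-3 vector `(c2, c1, c0)`.
#' @return An object of class `device_model`.
#' @examples
#' device_model("narrow", dynamic_range_g = 4, fs_nominal_hz = 25)
#' @export
device_model <- function(name, dynamic_range_g, fs_nominal_hz,
                         sd_correction = c(0, 1, 0)) {
  stopifnot(
    is.character(name), length(name) == 1,
    is.numeric(dynamic_range_g), dynamic_range_g > 0,
    is.numeric(fs_nominal_hz), fs_nominal_hz > 0,
    is.numeric(sd_correction), length(sd_correction) == 3,
    all(is.finite(sd_correction))
  )
  structure(
    list(
      name = name,
      dynamic_range_g = as.numeric(dynamic_range_g),
      fs_nominal_hz = as.numeric(fs_nominal_hz),
      sd_correction = as.numeric(sd_correction)
    ),
    class = "device_model"
  )
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf(
    "<device_model> %s: +/-%g g, %g Hz, sd correction (%g, %g, %g)\n",
    x$name, x$dynamic_range_g, x$fs_nominal_hz,
    x$sd_correction[1], x$sd_correction[2], x$sd_correction[3]
  ))
  invisible(x)
}

#' Triaxial thigh recording
#'
#' A uniform-grid triaxial acceleration series in g on axes (U, V, W).
#' Implied timestamps are `start_time + (i - 1) / fs_hz` for sample `i`;
#' per-sample timestamps are never stored (clock error is modelled
#' explicitly by the sync module). Samples are clipped to the device's
#' dynamic range on construction.
#'
#' @param samples N x 3 numeric matrix (columns U, V, W) in g.
#' @param fs_hz positive sampling frequency in Hz.
#' @param device a [device_model()].
#' @param start_time recording start, seconds (UTC or session-relative).
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(samples, fs_hz, device, start_time = 0) {
  samples <- as.matrix(samples)
  stopifnot(
    ncol(samples) == 3, nrow(samples) >= 1,
    all(is.finite(samples)),
    is.numeric(fs_hz), fs_hz > 0,
    inherits(device, "device_model")
  )
  r <- device$dynamic_range_g
  samples <- clamp(samples, -r, r)
  dimnames(samples) <- list(NULL, c("u", "v", "w"))
  structure(
    list(
      samples = samples,
      fs_hz = as.numeric(fs_hz),
      start_time = as.numeric(start_time),
      device = device
    ),
    class = "triaxial_recording"
  )
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf(
    "<triaxial_recording> %d samples @ %g Hz (%.1f s) on %s, start %g s\n",
    nrow(x$samples), x$fs_hz, rec_duration(x), x$device$name, x$start_time
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [triaxial_recording()].
#' @return Duration `N / fs` in seconds.
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs_hz

# implied sample times (seconds, in the recording's own clock)
rec_times <- function(rec) {
  rec$start_time + (seq_len(nrow(rec$samples)) - 1) / rec$fs_hz
}

#' Read a recording from CSV
#'
#' Expects the header `time,u,v,w`; `time` as float seconds (or ISO-8601,
#' converted to epoch seconds) and strictly increasing; accelerations in g.
#' The sampling frequency is estimated as `(N - 1) / (t_last - t_first)`;
#' gaps larger than two nominal sample periods raise a non-uniform
#' sampling error.
#'
#' @param path CSV file path.
#' @param device a [device_model()] attached to the result.
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, device) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty recording file: ", path)
  need <- c("time", "u", "v", "w")
  if (!all(need %in% names(d))) {
    stop("recording CSV must have header 'time,u,v,w': ", path)
  }
  tm <- d$time
  if (is.character(tm)) {
    tm <- suppressWarnings(as.numeric(tm))
    if (anyNA(tm)) tm <- as.numeric(as.POSIXct(d$time, tz = "UTC"))
  }
  for (k in c("u", "v", "w")) {
    if (!is.numeric(d[[k]])) d[[k]] <- suppressWarnings(as.numeric(d[[k]]))
  }
  bad <- which(!is.finite(tm) | !is.finite(d$u) | !is.finite(d$v) |
                 !is.finite(d$w))
  if (length(bad)) {
    stop("malformed row ", bad[1] + 1L, " in ", path)
  }
  if (nrow(d) < 2) stop("recording needs at least 2 samples: ", path)
  if (any(diff(tm) <= 0)) stop("time must be strictly increasing: ", path)
  fs <- (nrow(d) - 1) / (tm[nrow(d)] - tm[1])
  if (max(diff(tm)) > 2 / fs) {
    stop("non-uniform sampling: gap of ", signif(max(diff(tm)), 4),
         " s exceeds 2/fs = ", signif(2 / fs, 4), " s")
  }
  triaxial_recording(cbind(d$u, d$v, d$w), fs_hz = fs, device = device,
                     start_time = tm[1])
}

#' Write a recording to CSV
#'
#' Emits the `time,u,v,w` dialect read by [read_recording()], with float
#' seconds at full precision so a read/write round trip preserves samples
#' to better than 1e-9 g.
#'
#' @param rec a [triaxial_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  d <- data.frame(
    time = sprintf("%.9f", rec_times(rec)),
    u = sprintf("%.10f", rec$samples[, 1]),
    v = sprintf("%.10f", rec$samples[, 2]),
    w = sprintf("%.10f", rec$samples[, 3])
  )
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase Butterworth at 0.8 of the target
#' Nyquist) followed by linear-interpolation resampling onto the target
#' uniform grid. The source/target ratio need not be an integer; output
#' length is `floor((N - 1) * fs_target / fs_src) + 1`. Downsampling at
#' the source rate is the identity.
#'
#' @param rec a [triaxial_recording()].
#' @param fs_target_hz target rate, must not exceed `rec$fs_hz`.
#' @return The downsampled [triaxial_recording()].
#' @export
downsample <- function(rec, fs_target_hz) {
  stopifnot(is.numeric(fs_target_hz), fs_target_hz > 0)
  fs <- rec$fs_hz
  if (fs_target_hz > fs * (1 + 1e-12)) {
    stop("no upsampling: target ", fs_target_hz, " Hz > source ", fs, " Hz")
  }
  if (abs(fs_target_hz - fs) < 1e-12) return(rec)
  n <- nrow(rec$samples)
  cutoff <- 0.8 * (fs_target_hz / 2)
  bt <- signal::butter(4, cutoff / (fs / 2), type = "low")
  filtered <- apply(rec$samples, 2, function(x) filtfilt_zp(bt$b, bt$a, x))
  t_src <- (seq_len(n) - 1) / fs
  n_out <- floor((n - 1) * fs_target_hz / fs) + 1
  t_out <- (seq_len(n_out) - 1) / fs_target_hz
  out <- vapply(1:3, function(k) {
    stats::approx(t_src, filtered[, k], xout = t_out, rule = 2)$y
  }, numeric(n_out))
  triaxial_recording(out, fs_hz = fs_target_hz, device = rec$device,
                     start_time = rec$start_time)
}

#' Emulate a device's dynamic range
#'
#' Clips an ideal signal to the device's measurement limits (saturation)
#' and attaches the device metadata. Idempotent (a projection).
#'
#' @param ideal a [triaxial_recording()] whose samples may exceed the range.
#' @param device the [device_model()] to emulate.
#' @return A [triaxial_recording()] with clipped samples.
#' @export
apply_device_model <- function(ideal, device) {
  r <- device$dynamic_range_g
  triaxial_recording(clamp(ideal$samples, -r, r), fs_hz = ideal$fs_hz,
                     device = device, start_time = ideal$start_time)
}
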