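# Low-pass filtering, 2-s windowed feature extraction on the 1-s epoch
# grid, and the polynomial saturation correction of the SD feature.

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase) per axis.
#' Zero-phase filtering keeps features time-aligned with annotations; the
#' effective magnitude response is the squared single-pass response, so the
#' gain at the cutoff is 1/2 rather than the single-pass -3 dB.
#'
#' @param rec a [triaxial_recording()].
#' @param cutoff_hz cutoff in Hz, strictly below Nyquist.
#' @return The filtered [triaxial_recording()].
#' @export
lowpass_filter <- function(rec, cutoff_hz = 5) {
  nyq <- rec$fs_hz / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) {
    stop("cutoff ", cutoff_hz, " Hz must lie in (0, Nyquist = ", nyq, " Hz)")
  }
  bt <- signal::butter(4, cutoff_hz / nyq, type = "low")
  out <- apply(rec$samples, 2, function(x) filtfilt_zp(bt$b, bt$a, x))
  res <- rec
  res$samples <- clamp(out, -rec$device$dynamic_range_g,
                       rec$device$dynamic_range_g)
  colnames(res$samples) <- c("u", "v", "w")
  res
}

# sample indices (1-based) covering window [a, b) seconds of a recording
window_idx <- function(a, b, fs, n) {
  j0 <- max(1L, as.integer(ceiling(a * fs - 1e-9)) + 1L)
  j1 <- min(n, as.integer(ceiling(b * fs - 1e-9)))
  if (j1 < j0) integer(0) else j0:j1
}

#' Extract per-second epoch features
#'
#' Windows are 2 s long with 1-s overlap, anchored at integer seconds from
#' the recording start: epoch `i` (0-based) covers `[i, i + 2)` s and is
#' reported at centre `i + 1` s, giving `floor(T) - 1` epochs for a
#' duration-`T` recording. Per epoch:
#' * `mean_u/v/w` - mean of the low-pass filtered axes,
#' * `sd_raw` - standard deviation of the filtered vector magnitude
#'   (movement intensity),
#' * `sd_corr` - `sd_raw` through the device's polynomial correction,
#' * `inclination` - angle (degrees) between the mean vector and +U,
#' * `forward_lean` - signed angle (degrees) of the mean vector in the U-W
#'   plane, positive forward,
#' * `cadence` - dominant frequency (Hz) of the detrended U axis over a
#'   centred 4-s context window, restricted to 0.3-4 Hz; 0 when no
#'   spectral peak reaches 3x the band's median power.
#'
#' @param rec a [triaxial_recording()] of duration >= 2 s.
#' @param cutoff_hz low-pass cutoff (default 5 Hz, inside the 12.5-Hz
#'   Nyquist limit and covering the dominant band of daily movement).
#' @param device device whose polynomial corrects the SD feature
#'   (default: the recording's device).
#' @return A `data.frame` of class `epoch_features`, one row per epoch.
#' @export
extract_features <- function(rec, cutoff_hz = 5, device = rec$device) {
  n <- nrow(rec$samples)
  fs <- rec$fs_hz
  dur <- n / fs
  if (dur < 2) stop("recording shorter than 2 s (", signif(dur, 3), " s)")
  filt <- lowpass_filter(rec, cutoff_hz)
  x <- filt$samples
  n_ep <- as.integer(floor(dur + 1e-9)) - 1L
  ep <- seq_len(n_ep) - 1L
  out <- data.frame(
    epoch = ep, t_center = ep + 1,
    mean_u = NA_real_, mean_v = NA_real_, mean_w = NA_real_,
    sd_raw = NA_real_, sd_corr = NA_real_,
    inclination = NA_real_, forward_lean = NA_real_, cadence = NA_real_,
    degenerate = FALSE
  )
  for (k in seq_len(n_ep)) {
    i <- ep[k]
    idx <- window_idx(i, i + 2, fs, n)
    win <- x[idx, , drop = FALSE]
    m <- colMeans(win)
    vm <- sqrt(rowSums(win^2))
    sdr <- if (length(vm) > 1) stats::sd(vm) else 0
    nrm <- sqrt(sum(m^2))
    if (nrm < 1e-9) {
      out$degenerate[k] <- TRUE
      incl <- 0
      lean <- 0
    } else {
      incl <- acos(clamp(m[1] / nrm, -1, 1)) * DEG
      lean <- atan2(m[3], m[1]) * DEG
    }
    cidx <- window_idx(i - 1, i + 3, fs, n)
    cad <- dominant_frequency(x[cidx, 1], fs)
    out$mean_u[k] <- m[1]; out$mean_v[k] <- m[2]; out$mean_w[k] <- m[3]
    out$sd_raw[k] <- sdr
    out$sd_corr[k] <- correct_sd(sdr, device)
    out$inclination[k] <- incl
    out$forward_lean[k] <- lean
    out$cadence[k] <- cad
  }
  class(out) <- c("epoch_features", "data.frame")
  attr(out, "fs_hz") <- fs
  attr(out, "t0_s") <- rec$start_time
  out
}

#' Apply the device's SD saturation correction
#'
#' Narrow-range sensors clip high-intensity signals, deflating the SD
#' feature; a second-order polynomial re-aligns it with wide-range
#' reference sensors: `max(0, c2 * sd^2 + c1 * sd + c0)`.
#'
#' @param sd_raw_g non-negative raw SD in g (vectorised).
#' @param device a [device_model()] carrying `(c2, c1, c0)`.
#' @return Corrected SD in g, floored at 0.
#' @export
correct_sd <- function(sd_raw_g, device) {
  cf <- device$sd_correction
  pmax(0, cf[1] * sd_raw_g^2 + cf[2] * sd_raw_g + cf[3])
}

#' Fit the SD correction polynomial
#'
#' Least-squares quadratic fit of reference (wide-range) SD on clipped
#' (narrow-range) SD over paired epochs spanning the intensity range.
#'
#' @param paired data.frame or list with components `sd_clipped` and
#'   `sd_reference` (>= 10 pairs).
#' @return Numeric `(c2, c1, c0)` for [correct_sd()], with the residual
#'   RMS in attribute `"rms"`.
#' @export
calibrate_sd_polynomial <- function(paired) {
  x <- paired$sd_clipped
  y <- paired$sd_reference
  if (is.null(x) || is.null(y) || length(x) != length(y)) {
    stop("paired must provide equal-length sd_clipped and sd_reference")
  }
  if (length(x) < 10) stop("need at least 10 pairs, got ", length(x))
  X <- cbind(x^2, x, 1)
  qx <- qr(X)
  if (qx$rank < 3) stop("degenerate design: SD pairs do not span a quadratic")
  cf <- qr.coef(qx, y)
  rms <- sqrt(mean((y - X %*% cf)^2))
  structure(as.numeric(cf), names = c("c2", "c1", "c0"), rms = rms)
}
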