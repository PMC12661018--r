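# Clock alignment between devices: heel-drop anchor detection, linear
# clock-model fitting, cross-correlation drift refinement, and
# resampling onto the reference clock.

#' Linear clock synchronisation model
#'
#' Device and reference clocks are related by
#' `t_dev = t_ref * (1 + drift_ppm * 1e-6) + offset_s`; the inverse map
#' `t_ref = (t_dev - offset_s) / (1 + drift_ppm * 1e-6)` is strictly
#' increasing.
#'
#' @param offset_s clock offset in seconds.
#' @param drift_ppm clock drift in parts per million.
#' @param anchors_used number of anchors behind the fit.
#' @param residual_s maximum absolute fit residual in seconds.
#' @return An object of class `sync_model`.
#' @export
sync_model <- function(offset_s = 0, drift_ppm = 0, anchors_used = 0L,
                       residual_s = 0) {
  stopifnot(1 + drift_ppm * 1e-6 > 0)
  structure(
    list(offset_s = as.numeric(offset_s), drift_ppm = as.numeric(drift_ppm),
         anchors_used = as.integer(anchors_used),
         residual_s = as.numeric(residual_s)),
    class = "sync_model"
  )
}

#' @export
print.sync_model <- function(x, ...) {
  cat(sprintf(
    "<sync_model> offset %.4f s, drift %.1f ppm (%d anchors, residual %.4g s)\n",
    x$offset_s, x$drift_ppm, x$anchors_used, x$residual_s
  ))
  invisible(x)
}

#' Detect heel-drop anchors
#'
#' Heel-drops produce distinct high-amplitude spikes on the longitudinal
#' axis. Samples with |U| above the threshold are clustered
#' (exceedances within `group_window_s` of each other belong to one
#' cluster); clusters containing at least three distinct peaks (the
#' protocol's three heel-drops, local maxima separated by > 0.1 s) are
#' kept and reported by the time of their first peak, in the recording's
#' own clock.
#'
#' @param rec a [triaxial_recording()].
#' @param amplitude_threshold_g detection threshold (default 2.5 g, above
#'   typical activity peaks).
#' @param group_window_s clustering window in seconds.
#' @param min_peaks minimum distinct peaks per cluster.
#' @return Sorted numeric vector of anchor times (possibly empty).
#' @export
detect_heel_drops <- function(rec, amplitude_threshold_g = 2.5,
                              group_window_s = 2, min_peaks = 3) {
  u <- abs(rec$samples[, 1])
  tt <- rec_times(rec)
  exc <- which(u > amplitude_threshold_g)
  if (!length(exc)) return(numeric(0))
  grp <- cumsum(c(1, diff(tt[exc]) > group_window_s))
  anchors <- numeric(0)
  for (g in unique(grp)) {
    idx <- exc[grp == g]
    n <- nrow(rec$samples)
    is_peak <- vapply(idx, function(i) {
      (i == 1 || u[i] >= u[i - 1]) && (i == n || u[i] >= u[i + 1])
    }, logical(1))
    pk <- idx[is_peak]
    if (!length(pk)) next
    # merge peaks closer than 0.1 s, keeping the larger
    keep <- pk[1]
    for (i in pk[-1]) {
      if (tt[i] - tt[keep[length(keep)]] > 0.1) {
        keep <- c(keep, i)
      } else if (u[i] > u[keep[length(keep)]]) {
        keep[length(keep)] <- i
      }
    }
    if (length(keep) >= min_peaks) anchors <- c(anchors, tt[keep[1]])
  }
  sort(anchors)
}

#' Fit the linear clock model from matched anchors
#'
#' Least-squares line through `(t_ref, t_dev)` pairs (matched by order,
#' as the protocol places drops before/during/after the session); exact
#' with two anchors.
#'
#' @param anchors_dev anchor times on the device clock.
#' @param anchors_ref anchor times on the reference clock (equal count).
#' @return A [sync_model()].
#' @export
fit_sync_model <- function(anchors_dev, anchors_ref) {
  if (length(anchors_dev) != length(anchors_ref)) {
    stop("mismatched anchor counts: ", length(anchors_dev), " vs ",
         length(anchors_ref))
  }
  if (length(anchors_dev) < 2) {
    stop("insufficient anchors: need >= 2, got ", length(anchors_dev))
  }
  cf <- stats::lm.fit(cbind(1, anchors_ref), anchors_dev)
  fitted <- cbind(1, anchors_ref) %*% cf$coefficients
  sync_model(
    offset_s = cf$coefficients[1],
    drift_ppm = (cf$coefficients[2] - 1) * 1e6,
    anchors_used = length(anchors_dev),
    residual_s = max(abs(fitted - anchors_dev))
  )
}

# median absolute residual cross-correlation lag (s) of dev vs ref after
# aligning dev with `model`; helper shared by refine_by_xcorr
xcorr_lags <- function(rec_dev, rec_ref, model, window_s, band, max_lag_s,
                       min_corr) {
  dev <- apply_sync(rec_dev, model)
  fs <- rec_ref$fs_hz
  t_ref <- rec_times(rec_ref)
  t_dev <- rec_times(dev)
  lo <- max(t_ref[1], t_dev[1])
  hi <- min(t_ref[length(t_ref)], t_dev[length(t_dev)])
  if (hi - lo < 3 * window_s) {
    stop("overlap ", signif(hi - lo, 4), " s shorter than 3 windows")
  }
  grid <- seq(lo, hi, by = 1 / fs)
  x <- stats::approx(t_ref, rec_ref$samples[, 1], xout = grid, rule = 2)$y
  y <- stats::approx(t_dev, dev$samples[, 1], xout = grid, rule = 2)$y
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- filtfilt_zp(bp$b, bp$a, x)
  y <- filtfilt_zp(bp$b, bp$a, y)
  wlen <- round(window_s * fs)
  lmax <- round(max_lag_s * fs)
  n_win <- floor(length(grid) / wlen)
  centres <- lags <- numeric(0)
  for (k in seq_len(n_win)) {
    i0 <- (k - 1) * wlen + 1
    xs <- x[i0:(i0 + wlen - 1)]
    ys <- y[i0:(i0 + wlen - 1)]
    if (stats::sd(xs) < 1e-9 || stats::sd(ys) < 1e-9) next
    cc <- stats::ccf(xs, ys, lag.max = lmax, plot = FALSE,
                     demean = TRUE)
    i <- which.max(cc$acf)
    if (cc$acf[i] < min_corr) next
    k_lag <- cc$lag[i]
    centres <- c(centres, grid[i0] + (wlen / 2) / fs - lo)
    # dev(t) ~ ref(t - delta): ccf peaks at k = -delta * fs
    lags <- c(lags, -k_lag / fs)
  }
  list(centres = centres, lags = lags, span = hi - lo, t0 = lo)
}

#' Refine a clock model by cross-correlation
#'
#' After coarse (anchor-based) alignment, the residual misalignment is
#' measured as the lag maximising the normalised cross-correlation of
#' the band-passed longitudinal axes (gait periodicity is the shared
#' signal between co-located devices) in evenly spaced windows; a linear
#' clock correction is re-fitted to the (window centre, lag) pairs and
#' composed with the coarse model. The refined model replaces the coarse
#' one only when it reduces the median absolute window lag; windows with
#' flat signal or an insignificant correlation peak are skipped, and if
#' all are skipped the coarse model is returned with a warning.
#'
#' @param rec_dev device [triaxial_recording()].
#' @param rec_ref reference [triaxial_recording()].
#' @param coarse the anchor-based [sync_model()].
#' @param window_s correlation window length in seconds.
#' @param band band-pass limits in Hz.
#' @param max_lag_s lag search half-range in seconds.
#' @param min_corr minimum normalised correlation peak for a window to
#'   count.
#' @return A [sync_model()] (refined or the retained coarse model).
#' @export
refine_by_xcorr <- function(rec_dev, rec_ref, coarse, window_s = 120,
                            band = c(0.5, 3), max_lag_s = 2,
                            min_corr = 0.2) {
  w0 <- xcorr_lags(rec_dev, rec_ref, coarse, window_s, band, max_lag_s,
                   min_corr)
  if (length(w0$lags) < 3) {
    warning("no usable cross-correlation windows; coarse model retained")
    return(coarse)
  }
  cf <- stats::lm.fit(cbind(1, w0$centres), w0$lags)$coefficients
  o2 <- cf[1]
  d2 <- cf[2]                       # residual lag per second of ref time
  # compose: t_ref_new = (t_ref_coarse - o2') / (1 + d2), with the lag
  # line referenced to absolute ref time t0 + centre
  o2_abs <- o2 - d2 * w0$t0
  s1 <- 1 + coarse$drift_ppm * 1e-6
  s2 <- 1 + d2
  refined <- sync_model(
    offset_s = coarse$offset_s + o2_abs * s1,
    drift_ppm = (s1 * s2 - 1) * 1e6,
    anchors_used = coarse$anchors_used,
    residual_s = max(abs(w0$lags - cbind(1, w0$centres) %*% cf))
  )
  w1 <- tryCatch(
    xcorr_lags(rec_dev, rec_ref, refined, window_s, band, max_lag_s,
               min_corr),
    error = function(e) NULL
  )
  if (is.null(w1) || length(w1$lags) < 3) return(coarse)
  if (stats::median(abs(w1$lags)) < stats::median(abs(w0$lags))) {
    refined
  } else {
    coarse
  }
}

#' Resample a recording onto the reference clock
#'
#' Maps the device's uniform grid through the clock model and linearly
#' interpolates onto a uniform grid in reference time (same sampling
#' frequency).
#'
#' @param rec device [triaxial_recording()].
#' @param model a [sync_model()].
#' @return The synchronised [triaxial_recording()] on the reference
#'   clock.
#' @export
apply_sync <- function(rec, model) {
  s <- 1 + model$drift_ppm * 1e-6
  if (model$offset_s == 0 && model$drift_ppm == 0) return(rec)
  t_dev <- rec_times(rec)
  tau <- (t_dev - model$offset_s) / s       # device samples in ref time
  tau0 <- tau[1]
  fs <- rec$fs_hz
  n_out <- floor((tau[length(tau)] - tau0) * fs) + 1
  tau_grid <- tau0 + (seq_len(n_out) - 1) / fs
  out <- vapply(1:3, function(k) {
    stats::approx(tau, rec$samples[, k], xout = tau_grid, rule = 2)$y
  }, numeric(n_out))
  triaxial_recording(out, fs, rec$device, start_time = tau0)
}

#' Invert a clock model
#' @param model a [sync_model()].
#' @return The [sync_model()] mapping the other way.
#' @export
invert_sync_model <- function(model) {
  s <- 1 + model$drift_ppm * 1e-6
  sync_model(offset_s = -model$offset_s / s, drift_ppm = (1 / s - 1) * 1e6,
             anchors_used = model$anchors_used,
             residual_s = model$residual_s)
}

#' Serialise a sync model to JSON
#' @param model a [sync_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
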