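# Two-step calibration: device autocalibration (per-axis gain/offset to
# the unit gravity sphere, estimated from still periods) and
# individual-specific orientation calibration (rotation aligning the
# observed locomotion direction with its expected posture).

#' Calibration parameters
#'
#' Applied to a recording as `sample' = rotation %*% ((sample - offset) /
#' gain)` per sample (elementwise gain).
#'
#' @param gain positive per-axis gains (sanity bounds [0.5, 2]).
#' @param offset per-axis offsets in g (|offset| <= 0.5 g).
#' @param rotation 3x3 rotation matrix (det = 1).
#' @param warning_flag logical; TRUE when an estimation step fell back to
#'   the identity.
#' @param residual achieved fit residual of the estimation step, if any.
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(gain = c(1, 1, 1), offset = c(0, 0, 0),
                               rotation = diag(3), warning_flag = FALSE,
                               residual = NA_real_) {
  stopifnot(length(gain) == 3, length(offset) == 3,
            all(dim(rotation) == c(3, 3)))
  if (any(gain < 0.5 | gain > 2)) {
    stop("gain outside sanity bounds [0.5, 2]: ",
         paste(signif(gain, 4), collapse = ", "))
  }
  if (any(abs(offset) > 0.5)) {
    stop("offset outside sanity bounds +/-0.5 g: ",
         paste(signif(offset, 4), collapse = ", "))
  }
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be orthonormal with det 1")
  }
  structure(
    list(gain = as.numeric(gain), offset = as.numeric(offset),
         rotation = rotation, warning_flag = isTRUE(warning_flag),
         residual = residual),
    class = "calibration_params"
  )
}

#' @export
print.calibration_params <- function(x, ...) {
  ang <- acos(clamp((sum(diag(x$rotation)) - 1) / 2, -1, 1)) * DEG
  cat(sprintf(
    "<calibration_params> gain (%s), offset (%s) g, rotation %.2f deg%s\n",
    paste(signif(x$gain, 4), collapse = ", "),
    paste(signif(x$offset, 4), collapse = ", "),
    ang, if (x$warning_flag) " [fallback]" else ""
  ))
  invisible(x)
}

# greedy count of mutually distinct orientations (pairwise angle > min_deg)
count_orientations <- function(units, min_deg = 15) {
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    if (!nrow(kept) ||
        all(acos(clamp(kept %*% u, -1, 1)) * DEG > min_deg)) {
      kept <- rbind(kept, u)
    }
  }
  nrow(kept)
}

#' Device autocalibration from still periods
#'
#' During still periods an ideal accelerometer measures exactly 1 g, so
#' per-axis gain and offset are estimated by iteratively regressing each
#' axis of the still-epoch mean vectors onto its closest point on the
#' unit sphere, until the parameters change by less than `tol` (or
#' `max_iter` iterations). Needs still epochs spanning at least three
#' distinct orientations (pairwise angle > 15 degrees); otherwise the
#' sphere fit is underdetermined and the identity is returned with
#' `warning_flag = TRUE`.
#'
#' @param rec a [triaxial_recording()].
#' @param still_sd_threshold_g epoch SD below which an epoch is still.
#' @param max_iter,tol iteration controls.
#' @return A [calibration_params()] with identity rotation; `residual` is
#'   the RMS deviation of calibrated still magnitudes from 1 g.
#' @export
autocalibrate_device <- function(rec, still_sd_threshold_g = 0.013,
                                 max_iter = 100, tol = 1e-6) {
  fe <- extract_features(rec, cutoff_hz = min(5, 0.8 * rec$fs_hz / 2))
  still <- fe[fe$sd_raw < still_sd_threshold_g & !fe$degenerate, ]
  M <- as.matrix(still[, c("mean_u", "mean_v", "mean_w")])
  if (nrow(M) >= 3) {
    units <- M / sqrt(rowSums(M^2))
    n_orient <- count_orientations(units)
  } else {
    n_orient <- 0
  }
  if (n_orient < 3) {
    warning("sphere fit underdetermined: ", n_orient,
            " distinct still orientations (need >= 3); calibration skipped")
    return(calibration_params(warning_flag = TRUE))
  }
  g <- c(1, 1, 1)
  o <- c(0, 0, 0)
  for (it in seq_len(max_iter)) {
    W <- sweep(sweep(M, 2, o, "-"), 2, g, "/")
    tgt <- W / sqrt(rowSums(W^2))
    change <- 0
    for (k in 1:3) {
      cf <- stats::lm.fit(cbind(1, W[, k]), tgt[, k])$coefficients
      new_g <- g[k] / cf[2]
      new_o <- o[k] - cf[1] * new_g
      change <- max(change, abs(new_g - g[k]), abs(new_o - o[k]))
      g[k] <- new_g
      o[k] <- new_o
    }
    if (change < tol) break
  }
  # polish: direct least squares on the sphere residual (the per-axis
  # regression converges linearly and can stall short of the optimum)
  obj <- function(p) {
    W <- sweep(sweep(M, 2, p[4:6], "-"), 2, p[1:3], "/")
    sum((sqrt(rowSums(W^2)) - 1)^2)
  }
  opt <- stats::optim(c(g, o), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  g <- clamp(opt$par[1:3], 0.5, 2)
  o <- clamp(opt$par[4:6], -0.5, 0.5)
  W <- sweep(sweep(M, 2, o, "-"), 2, g, "/")
  resid <- sqrt(mean((sqrt(rowSums(W^2)) - 1)^2))
  calibration_params(gain = g, offset = o, residual = resid)
}

#' Individual orientation calibration
#'
#' Estimates the small mounting rotation of the sensor on the thigh. A
#' pre-pass with default thresholds (and the population stairs fallback)
#' provisionally classifies epochs; over epochs labelled as upright
#' locomotion (walk/run/stairs) the componentwise-median mean vector is
#' taken as the observed thigh direction. Upside-down/inside-out mounting
#' (median U < 0) is corrected by a 180-degree flip about W; the returned
#' rotation then maps the observed direction onto the expected locomotion
#' posture `(cos(ref), 0, sin(ref))` with `ref = reference_lean_deg`, so
#' a perfectly mounted sensor yields the identity.
#'
#' @param features an `epoch_features` data.frame.
#' @param config a [classifier_config()].
#' @param reference_lean_deg expected mean forward lean of the thigh
#'   during level locomotion (degrees).
#' @param min_epochs minimum locomotion epochs required; below this the
#'   identity is returned with `warning_flag = TRUE`.
#' @return A [calibration_params()] with unit gain and zero offset.
#' @export
individual_calibration <- function(features, config = classifier_config(),
                                   reference_lean_deg = 20,
                                   min_epochs =
                                     config$min_epochs_for_individual_threshold) {
  # inside-out/upside-down mounting first: with U inverted the pre-pass
  # would mistake gait for cycling (forward lean wraps past 90 degrees),
  # so inversion is detected from the active epochs' longitudinal sign
  feats <- features
  flip <- diag(3)
  active <- feats$sd_corr >= config$sigma_stationary_g
  if (any(active) && stats::median(feats$mean_u[active]) < 0) {
    flip <- diag(c(-1, -1, 1))     # 180-degree flip about W
    feats$mean_u <- -feats$mean_u
    feats$mean_v <- -feats$mean_v
    nrm <- sqrt(feats$mean_u^2 + feats$mean_v^2 + feats$mean_w^2)
    ok <- nrm > 1e-9
    feats$inclination[ok] <- acos(clamp(feats$mean_u[ok] / nrm[ok],
                                        -1, 1)) * DEG
    feats$forward_lean[ok] <- atan2(feats$mean_w[ok], feats$mean_u[ok]) * DEG
  }
  pre <- classify_epochs_(feats, config$theta_stairs_fallback_deg, config)
  loco <- pre %in% c("walk", "run", "stairs")
  if (sum(loco) < min_epochs) {
    warning("too few locomotion epochs (", sum(loco), " < ", min_epochs,
            "); identity rotation returned")
    return(calibration_params(warning_flag = TRUE))
  }
  M <- as.matrix(feats[loco, c("mean_u", "mean_v", "mean_w")])
  med <- apply(M, 2, stats::median)
  ref <- reference_lean_deg / DEG
  R <- rotation_between(med, c(cos(ref), 0, sin(ref)))
  calibration_params(rotation = R %*% flip)
}

#' Apply calibration to a recording
#'
#' @param rec a [triaxial_recording()].
#' @param cal a [calibration_params()].
#' @return The calibrated [triaxial_recording()] (same epoch count and
#'   time base).
#' @export
apply_calibration <- function(rec, cal) {
  s <- sweep(sweep(rec$samples, 2, cal$offset, "-"), 2, cal$gain, "/")
  s <- s %*% t(cal$rotation)
  wide <- device_model(rec$device$name, 1e6, rec$fs_hz,
                       rec$device$sd_correction)
  out <- triaxial_recording(s, rec$fs_hz, wide, start_time = rec$start_time)
  out$device <- rec$device
  out
}

#' Serialise calibration parameters to JSON
#' @param cal a [calibration_params()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(
    list(gain = cal$gain, offset = cal$offset,
         rotation = as.vector(cal$rotation),
         warning_flag = cal$warning_flag, residual = cal$residual),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read calibration parameters from JSON
#' @param path JSON path written by [write_calibration()].
#' @return A [calibration_params()].
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(gain = x$gain, offset = x$offset,
                     rotation = matrix(x$rotation, 3, 3),
                     warning_flag = isTRUE(x$warning_flag),
                     residual = x$residual %||% NA_real_)
}
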