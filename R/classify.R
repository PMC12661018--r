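# Fixed decision tree over epoch features, individually estimated
# walk-vs-stairs forward-lean threshold, label smoothing, and
# time-in-behaviour aggregation.

#' Per-second behaviour label series
#'
#' @param labels character vector of per-epoch labels over the behaviours
#'   plus `"excluded"`.
#' @param t0_s time of the first epoch, seconds.
#' @return Character vector of class `epoch_labels` with attribute `t0_s`.
#' @export
epoch_labels <- function(labels, t0_s = 0) {
  labels <- as.character(labels)
  ok <- c(behaviour_levels(), .excluded_label)
  bad <- setdiff(unique(labels), ok)
  if (length(bad)) stop("unknown label: ", paste(bad, collapse = ", "))
  structure(labels, t0_s = as.numeric(t0_s), class = "epoch_labels")
}

#' @export
print.epoch_labels <- function(x, ...) {
  cat(sprintf("<epoch_labels> %d epochs from t0 = %g s\n",
              length(x), attr(x, "t0_s")))
  print(table(as.character(x)))
  invisible(x)
}

#' Classifier configuration
#'
#' All decision-tree thresholds and smoothing settings. The tree follows
#' the Acti4-lineage structure (stationary vs active on movement
#' intensity, postures on inclination, activities on cadence and forward
#' lean); the exact constants are package defaults, exposed here because
#' the lineage's published descriptions do not fix them.
#'
#' @param sigma_stationary_g SD (g) below which an epoch is stationary.
#' @param theta_sit_deg inclination (deg) separating sitting from standing.
#' @param sigma_run_g SD (g) at or above which an active epoch is running.
#' @param f_run_hz cadence (Hz) at or above which an active epoch is running.
#' @param walk_band_hz cadence band (Hz) of gait (walking/stairs).
#' @param theta_cycle_deg forward lean (deg) at or above which a
#'   cadenced epoch is cycling.
#' @param cycle_band_hz cadence band (Hz) of pedalling.
#' @param stairs_quantile quantile of walking forward lean defining the
#'   individual stairs threshold.
#' @param stairs_offset_deg margin (deg) added above that quantile.
#' @param theta_stairs_fallback_deg population fallback threshold (deg)
#'   when too little walking data is available.
#' @param min_epochs_for_individual_threshold minimum qualifying epochs
#'   before the individual threshold is trusted.
#' @param median_filter_epochs odd length of the modal label filter.
#' @param min_bout_s named minimum bout durations (s) per behaviour;
#'   shorter bouts are absorbed by their longer neighbour.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(sigma_stationary_g = 0.1,
                              theta_sit_deg = 45,
                              sigma_run_g = 0.72,
                              f_run_hz = 2.5,
                              walk_band_hz = c(0.6, 2.5),
                              theta_cycle_deg = 40,
                              cycle_band_hz = c(0.3, 2.0),
                              stairs_quantile = 0.95,
                              stairs_offset_deg = 2,
                              theta_stairs_fallback_deg = 25,
                              min_epochs_for_individual_threshold = 60,
                              median_filter_epochs = 5,
                              min_bout_s = c(run = 2, cycle = 15, stairs = 4)) {
  stopifnot(
    sigma_stationary_g > 0, theta_sit_deg > 0, sigma_run_g > 0,
    f_run_hz > 0, walk_band_hz[1] < walk_band_hz[2],
    cycle_band_hz[1] < cycle_band_hz[2], theta_cycle_deg > 0,
    stairs_quantile > 0, stairs_quantile < 1,
    theta_stairs_fallback_deg > 0,
    median_filter_epochs %% 2 == 1
  )
  mb <- stats::setNames(rep(2, length(behaviour_levels())), behaviour_levels())
  mb[names(min_bout_s)] <- min_bout_s
  structure(
    list(
      sigma_stationary_g = sigma_stationary_g,
      theta_sit_deg = theta_sit_deg,
      sigma_run_g = sigma_run_g,
      f_run_hz = f_run_hz,
      walk_band_hz = walk_band_hz,
      theta_cycle_deg = theta_cycle_deg,
      cycle_band_hz = cycle_band_hz,
      stairs_quantile = stairs_quantile,
      stairs_offset_deg = stairs_offset_deg,
      theta_stairs_fallback_deg = theta_stairs_fallback_deg,
      min_epochs_for_individual_threshold =
        min_epochs_for_individual_threshold,
      median_filter_epochs = median_filter_epochs,
      min_bout_s = mb
    ),
    class = "classifier_config"
  )
}

#' Individual walk-vs-stairs forward-lean threshold
#'
#' Walking and stair climbing differ mainly in how high the thigh is
#' lifted, so the stairs threshold is estimated per participant: over
#' epochs that are active, within the gait cadence band, and provisionally
#' walking-like (forward lean below both the cycling threshold and the
#' population fallback), the threshold is the configured quantile of
#' forward lean plus a margin. With fewer qualifying epochs than
#' `min_epochs_for_individual_threshold` (short recordings make the
#' estimate unreliable) the population fallback is returned and flagged.
#'
#' @param features an `epoch_features` data.frame.
#' @param config a [classifier_config()].
#' @return Threshold in degrees, with logical attribute `"fallback"`.
#' @export
estimate_stairs_threshold <- function(features, config = classifier_config()) {
  if (!nrow(features)) stop("empty feature list")
  qual <- features$sd_corr >= config$sigma_stationary_g &
    features$cadence >= config$walk_band_hz[1] &
    features$cadence <= config$walk_band_hz[2] &
    features$forward_lean < config$theta_cycle_deg &
    features$forward_lean < config$theta_stairs_fallback_deg
  if (sum(qual) < config$min_epochs_for_individual_threshold) {
    return(structure(config$theta_stairs_fallback_deg, fallback = TRUE))
  }
  th <- stats::quantile(features$forward_lean[qual], config$stairs_quantile,
                        names = FALSE) + config$stairs_offset_deg
  structure(th, fallback = FALSE)
}

# vectorised decision tree over feature rows
classify_epochs_ <- function(features, theta_stairs, config) {
  sdc <- features$sd_corr
  incl <- features$inclination
  lean <- features$forward_lean
  cad <- features$cadence
  lab <- rep("move", nrow(features))
  stationary <- sdc < config$sigma_stationary_g
  lab[stationary & incl >= config$theta_sit_deg] <- "sedentary"
  lab[stationary & incl < config$theta_sit_deg] <- "stand"
  act <- !stationary
  in_cycle_band <- cad >= config$cycle_band_hz[1] &
    cad <= config$cycle_band_hz[2]
  in_walk_band <- cad >= config$walk_band_hz[1] &
    cad <= config$walk_band_hz[2]
  cyc <- act & lean >= config$theta_cycle_deg & in_cycle_band
  lab[cyc] <- "cycle"
  rn <- act & !cyc & (cad >= config$f_run_hz | sdc >= config$sigma_run_g)
  lab[rn] <- "run"
  st <- act & !cyc & !rn & lean >= theta_stairs & in_walk_band
  lab[st] <- "stairs"
  wk <- act & !cyc & !rn & !st & in_walk_band
  lab[wk] <- "walk"
  lab
}

#' Classify a single feature epoch
#'
#' Evaluates the decision tree in order: (1) stationary epochs
#' (`sd < sigma_stationary`) split into sedentary vs stand on
#' inclination; (2) strongly forward-leaning epochs at pedalling cadence
#' are cycling (checked before running so intense pedalling is not
#' swallowed by the SD rule); (3) high cadence or high SD is running;
#' (4) gait-band cadence with forward lean at or above the individual
#' threshold is stair climbing; (5) remaining gait-band cadence is
#' walking; (6) everything else active is "move".
#'
#' @param f one-row `epoch_features` data.frame.
#' @param theta_stairs individual stairs threshold (degrees), e.g. from
#'   [estimate_stairs_threshold()].
#' @param config a [classifier_config()].
#' @return A single behaviour label.
#' @export
classify_epoch <- function(f, theta_stairs, config = classifier_config()) {
  classify_epochs_(f[1, , drop = FALSE], theta_stairs, config)
}

#' Smooth a label series
#'
#' Odd-length modal (majority) filter, then bouts shorter than their
#' class's minimum duration are absorbed into the longer neighbouring
#' bout (earlier neighbour on ties). Series shorter than the filter
#' window are returned unchanged.
#'
#' @param raw an [epoch_labels()] series.
#' @param config a [classifier_config()].
#' @return The smoothed [epoch_labels()].
#' @export
smooth_labels <- function(raw, config = classifier_config()) {
  lab <- as.character(raw)
  w <- config$median_filter_epochs
  n <- length(lab)
  if (n < w) return(raw)
  h <- (w - 1) %/% 2
  out <- lab
  for (i in seq_len(n)) {
    win <- lab[max(1, i - h):min(n, i + h)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (lab[i] %in% top) lab[i] else win[win %in% top][1]
  }
  # absorb implausibly short bouts
  repeat {
    r <- rle(out)
    if (length(r$lengths) <= 1) break
    minlen <- config$min_bout_s[r$values]
    minlen[is.na(minlen)] <- 2
    bad <- which(r$lengths < minlen)
    if (!length(bad)) break
    k <- bad[which.min(r$lengths[bad])]
    left <- if (k > 1) r$lengths[k - 1] else -Inf
    right <- if (k < length(r$lengths)) r$lengths[k + 1] else -Inf
    r$values[k] <- if (left >= right) r$values[k - 1] else r$values[k + 1]
    out <- inverse.rle(r)
  }
  epoch_labels(out, t0_s = attr(raw, "t0_s"))
}

#' Classify a full recording
#'
#' Pipeline: optional calibration, low-pass filtering, epoch feature
#' extraction with polynomial SD correction, individual stairs-threshold
#' estimation (once, globally), the per-epoch decision tree, and label
#' smoothing. With `chunk_s` set, features are computed in chunks with a
#' generous context margin on each side; the global threshold, tree and
#' smoothing are unchanged, so chunked and whole-recording processing
#' yield identical labels.
#'
#' @param rec a [triaxial_recording()] of duration >= 2 s.
#' @param config a [classifier_config()].
#' @param cal optional [calibration_params()] applied first.
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param chunk_s optional chunk length (s) for chunked feature
#'   extraction.
#' @return An [epoch_labels()] series with attributes `theta_stairs` and
#'   `features`.
#' @export
classify_recording <- function(rec, config = classifier_config(), cal = NULL,
                               cutoff_hz = 5, chunk_s = NULL) {
  if (!is.null(cal)) rec <- apply_calibration(rec, cal)
  feats <- if (is.null(chunk_s)) {
    extract_features(rec, cutoff_hz)
  } else {
    extract_features_chunked(rec, cutoff_hz, chunk_s)
  }
  th <- estimate_stairs_threshold(feats, config)
  raw <- epoch_labels(classify_epochs_(feats, th, config),
                      t0_s = rec$start_time)
  out <- smooth_labels(raw, config)
  attr(out, "theta_stairs") <- th
  attr(out, "features") <- feats
  out
}

# chunked feature extraction with context margins; epoch grid stays
# anchored at integer seconds of the whole recording
extract_features_chunked <- function(rec, cutoff_hz, chunk_s, context_s = 8) {
  n <- nrow(rec$samples)
  fs <- rec$fs_hz
  dur <- n / fs
  n_ep <- as.integer(floor(dur + 1e-9)) - 1L
  chunk_s <- max(4, round(chunk_s))
  starts <- seq(0, n_ep - 1, by = chunk_s)
  pieces <- lapply(starts, function(a) {
    b <- min(a + chunk_s, n_ep)          # epochs [a, b)
    lo <- max(0, a - context_s)
    hi <- min(dur, b + 1 + context_s)
    idx <- window_idx(lo, hi, fs, n)
    sub <- triaxial_recording(rec$samples[idx, , drop = FALSE], fs,
                              rec$device, start_time = lo)
    fe <- extract_features(sub, cutoff_hz)
    fe$epoch <- fe$epoch + as.integer(lo)
    fe$t_center <- fe$t_center + lo
    fe[fe$epoch >= a & fe$epoch < b, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("epoch_features", "data.frame")
  attr(out, "fs_hz") <- fs
  attr(out, "t0_s") <- rec$start_time
  out
}

#' Daily time-in-behaviour summary
#'
#' Minutes per behaviour per consecutive 24-h window from the series
#' start, plus the mean across complete windows (the free-living
#' convention); a partial trailing day is reported but excluded from the
#' mean.
#'
#' @param labels an [epoch_labels()] series (1-s epochs).
#' @return List with `per_day` (data.frame: day, behaviour columns, in
#'   minutes), `mean` (named minutes per behaviour across complete days,
#'   or NULL when no complete day exists) and `n_complete_days`.
#' @export
aggregate_daily <- function(labels) {
  lab <- as.character(labels)
  if (!length(lab)) stop("empty label series")
  day_len <- 86400L
  day <- (seq_along(lab) - 1L) %/% day_len
  lvls <- c(behaviour_levels(), .excluded_label)
  per_day <- do.call(rbind, lapply(split(lab, day), function(x) {
    cnt <- table(factor(x, levels = lvls))
    as.numeric(cnt) / 60
  }))
  per_day <- as.data.frame(per_day)
  names(per_day) <- lvls
  per_day <- cbind(day = sort(unique(day)), per_day,
                   complete = as.numeric(table(day)) == day_len)
  complete <- per_day$complete
  mean_min <- if (any(complete)) {
    colMeans(per_day[complete, lvls, drop = FALSE])
  } else {
    NULL
  }
  list(per_day = per_day, mean = mean_min,
       n_complete_days = sum(complete))
}
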