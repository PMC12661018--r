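# Shared fixture builders and independent oracles.

wide_dev <- function(fs = 25) device_model("wide", 16, fs)
narrow_dev <- function(range = 4, fs = 25) device_model("narrow", range, fs)

const_rec <- function(vals, n = 250, fs = 25, device = wide_dev(fs)) {
  triaxial_recording(matrix(rep(vals, each = n), ncol = 3), fs, device)
}

sine_rec <- function(freq, amp, dur_s = 60, fs = 25, device = wide_dev(fs)) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  triaxial_recording(cbind(amp * sin(2 * pi * freq * t), 0 * t, 0 * t),
                     fs, device)
}

# write a recording CSV by hand (independent of write_recording)
hand_csv <- function(path, time, u, v = 0 * u, w = 0 * u) {
  writeLines(c("time,u,v,w",
               sprintf("%.6f,%.6f,%.6f,%.6f", time, u, v, w)), path)
}

# feature row for direct decision-tree tests
feat_row <- function(sd_corr, inclination = 10, forward_lean = inclination,
                     cadence = 0) {
  data.frame(epoch = 0, t_center = 1, mean_u = cos(inclination / 180 * pi),
             mean_v = 0, mean_w = sin(inclination / 180 * pi),
             sd_raw = sd_corr, sd_corr = sd_corr,
             inclination = inclination, forward_lean = forward_lean,
             cadence = cadence, degenerate = FALSE)
}

# brute-force one-vs-all metrics from raw label pairs (no confusion matrix)
brute_metrics <- function(true, pred, cls) {
  keep <- true != "excluded" & pred != "excluded"
  true <- true[keep]
  pred <- pred[keep]
  tp <- sum(true == cls & pred == cls)
  fn <- sum(true == cls & pred != cls)
  fp <- sum(true != cls & pred == cls)
  tn <- sum(true != cls & pred != cls)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- tp / (tp + fn)
  s <- tn / (tn + fp)
  c(precision = p, recall = r, specificity = s,
    f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
    balanced_accuracy = (r + s) / 2)
}

# brute-force modal filter matching the documented tie rule (keep the
# centre label when tied, else the first tied label in window order)
modal_oracle <- function(lab, w) {
  n <- length(lab)
  if (n < w) return(lab)
  h <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    win <- lab[max(1, i - h):min(n, i + h)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    if (lab[i] %in% top) lab[i] else win[win %in% top][1]
  }, character(1))
}

# truth aligned to the classifier's epoch grid (one label per epoch start)
truth_for <- function(truth, labels) {
  epoch_labels(as.character(truth)[seq_along(labels)])
}
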