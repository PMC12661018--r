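# Annotation alignment and exclusion rules, classification metrics,
# confusion matrices, inter-rater agreement, and Bland-Altman agreement.

#' Annotation track
#'
#' Intervals of rater-assigned labels; a rater's intervals must not
#' overlap. Labels are the behaviours plus the annotator categories
#' "other", "invisible" and "uncertain" (excluded from all metrics).
#'
#' @param start_s,end_s interval bounds in seconds (`start < end`).
#' @param label interval labels.
#' @param rater rater identifier(s).
#' @return A `data.frame` of class `annotation_track`.
#' @export
annotation_track <- function(start_s, end_s, label, rater = "R1") {
  stopifnot(length(start_s) == length(end_s),
            length(label) == length(start_s))
  if (any(end_s <= start_s)) stop("intervals must satisfy start < end")
  ok <- c(behaviour_levels(), .annotation_extras)
  bad <- setdiff(unique(label), ok)
  if (length(bad)) stop("unknown annotation label: ",
                        paste(bad, collapse = ", "))
  d <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                  label = as.character(label),
                  rater = rep_len(as.character(rater), length(label)))
  for (r in unique(d$rater)) {
    di <- d[d$rater == r, ]
    di <- di[order(di$start_s), ]
    if (nrow(di) > 1 &&
        any(di$start_s[-1] < di$end_s[-nrow(di)] - 1e-9)) {
      stop("overlapping intervals for rater ", r)
    }
  }
  structure(d, class = c("annotation_track", "data.frame"))
}

#' Read an annotation track from CSV
#' @param path CSV with header `start_s,end_s,label,rater`.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  annotation_track(d$start_s, d$end_s, d$label,
                   if ("rater" %in% names(d)) d$rater else "R1")
}

#' Write an annotation track to CSV
#' @param track an [annotation_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Epoch-align an annotation track
#'
#' Each 1-s epoch takes the label covering the majority of the epoch;
#' epochs whose majority label is "other"/"invisible"/"uncertain", or
#' with no coverage, become `"excluded"` (and are dropped from all
#' downstream metrics). Transitions inherit the majority behaviour.
#'
#' @param track a single-rater [annotation_track()] (or pass `rater`).
#' @param t0_s epoch-grid origin in seconds.
#' @param n_epochs number of 1-s epochs.
#' @param rater optional rater to select from a multi-rater track.
#' @return An [epoch_labels()] series of length `n_epochs`.
#' @export
annotations_to_epochs <- function(track, t0_s, n_epochs, rater = NULL) {
  d <- as.data.frame(track)
  if (!is.null(rater)) d <- d[d$rater == rater, ]
  if (length(unique(d$rater)) > 1) {
    stop("track has multiple raters; pass `rater`")
  }
  out <- rep(.excluded_label, n_epochs)
  for (i in seq_len(n_epochs)) {
    a <- t0_s + i - 1
    b <- a + 1
    cover <- pmin(d$end_s, b) - pmax(d$start_s, a)
    cover[cover < 0] <- 0
    if (sum(cover) <= 1e-9) next
    by_lab <- tapply(cover, d$label, sum)
    top <- names(by_lab)[which.max(by_lab)]
    out[i] <- if (top %in% .annotation_extras) .excluded_label else top
  }
  epoch_labels(out, t0_s = t0_s)
}

#' Confusion matrix of behaviour labels
#'
#' Rows are true behaviours, columns predicted; epochs excluded in either
#' series are dropped pairwise. Class order is fixed as sedentary, stand,
#' walk, run, stairs, cycle, move (restricted to classes that occur).
#' Matrices from several participants can be pooled with `+`.
#'
#' @param true,pred equal-length [epoch_labels()] series.
#' @param classes class order (default: canonical order of occurring
#'   classes).
#' @return Integer matrix of class `behaviour_confusion`.
#' @export
confusion <- function(true, pred, classes = NULL) {
  a <- as.character(true)
  b <- as.character(pred)
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  keep <- a != .excluded_label & b != .excluded_label
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) stop("no comparable epochs after exclusions")
  if (is.null(classes)) {
    classes <- intersect(behaviour_levels(), unique(c(a, b)))
  }
  m <- table(factor(a, levels = classes), factor(b, levels = classes))
  m <- unclass(as.matrix(m))
  structure(m, class = c("behaviour_confusion", class(m)))
}

#' Row-percentage form of a confusion matrix
#' @param cm a [confusion()] matrix.
#' @return Matrix of row percentages (rows sum to 100).
#' @export
confusion_percent <- function(cm) {
  rs <- rowSums(cm)
  sweep(unclass(cm), 1, ifelse(rs > 0, rs, 1), "/") * 100
}

#' @export
print.behaviour_confusion <- function(x, ...) {
  cat("<behaviour_confusion> rows = true, cols = predicted\n")
  print(unclass(x))
  cat(sprintf("overall accuracy %.3f\n", sum(diag(x)) / sum(x)))
  invisible(x)
}

#' F1 score from precision and recall
#' @param precision,recall values in [0, 1].
#' @return `2 * p * r / (p + r)` (0 where `p + r = 0`).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Balanced accuracy from recall and specificity
#' @param recall,specificity values in [0, 1].
#' @return `(recall + specificity) / 2`.
#' @export
balanced_accuracy <- function(recall, specificity) {
  (recall + specificity) / 2
}

#' Default overall-F1 prevalence weights
#'
#' Free-living 24-h time-use proportions (% of the day) per behaviour,
#' used to weight per-class F1 scores into an overall score so that the
#' summary reflects behaviours as they occur in daily life.
#'
#' @return Named numeric vector of percentages.
#' @export
freeliving_weights <- function() {
  c(sedentary = 75.7, stand = 11.2, move = 4.2, walk = 5.3,
    run = 0.4, stairs = 0.5, cycle = 2.0)
}

#' Classification metrics from a confusion matrix
#'
#' One-versus-all precision, recall, specificity, F1 and balanced
#' accuracy per class; overall balanced accuracy as the unweighted mean
#' of per-class recalls; overall F1 as the prevalence-weighted mean of
#' per-class F1 scores. Classes with zero true instances are reported
#' absent (dropped), not zero.
#'
#' @param cm a [confusion()] matrix.
#' @param weights named prevalence weights for the overall F1
#'   (renormalised over the classes present).
#' @return List of class `metrics_report` with `per_class` (data.frame)
#'   and `overall` (named numeric: `weighted_f1`,
#'   `overall_balanced_accuracy`, `accuracy`).
#' @export
class_metrics <- function(cm, weights = freeliving_weights()) {
  m <- unclass(cm)
  if (sum(m) == 0) stop("empty confusion matrix")
  present <- rownames(m)[rowSums(m) > 0]
  total <- sum(m)
  per <- do.call(rbind, lapply(present, function(k) {
    tp <- m[k, k]
    fn <- sum(m[k, ]) - tp
    fp <- sum(m[, k]) - tp
    tn <- total - tp - fn - fp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    s <- if (tn + fp > 0) tn / (tn + fp) else 0
    data.frame(class = k, precision = p, recall = r, specificity = s,
               f1 = f1_score(p, r), balanced_accuracy = balanced_accuracy(r, s))
  }))
  rownames(per) <- NULL
  w <- weights[per$class]
  if (any(is.na(w))) w[is.na(w)] <- 0
  wf1 <- if (sum(w) > 0) sum(w * per$f1) / sum(w) else mean(per$f1)
  structure(
    list(
      per_class = per,
      overall = c(weighted_f1 = wf1,
                  overall_balanced_accuracy = mean(per$recall),
                  accuracy = sum(diag(m)) / total),
      weights = w
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  p <- x$per_class
  p[-1] <- lapply(p[-1], round_half_up, 2)
  print(p, row.names = FALSE)
  cat(sprintf(
    "overall: weighted F1 %.2f, balanced accuracy %.2f, accuracy %.2f\n",
    round_half_up(x$overall["weighted_f1"], 2),
    round_half_up(x$overall["overall_balanced_accuracy"], 2),
    round_half_up(x$overall["accuracy"], 2)
  ))
  invisible(x)
}

#' Inter-rater agreement
#'
#' Epoch-aligns two raters' tracks on a shared grid, drops epochs
#' excluded by either, and reports percent agreement and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal label distributions.
#'
#' @param track_a,track_b single-rater [annotation_track()]s over the
#'   same span.
#' @param t0_s epoch-grid origin.
#' @param n_epochs number of epochs.
#' @return List with `percent_agreement`, `kappa` and `n_compared`.
#' @export
interrater <- function(track_a, track_b, t0_s, n_epochs) {
  a <- as.character(annotations_to_epochs(track_a, t0_s, n_epochs))
  b <- as.character(annotations_to_epochs(track_b, t0_s, n_epochs))
  keep <- a != .excluded_label & b != .excluded_label
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) stop("no comparable epochs after exclusions")
  po <- mean(a == b)
  lv <- union(unique(a), unique(b))
  pe <- sum(table(factor(a, lv)) / length(a) *
              table(factor(b, lv)) / length(b))
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  list(percent_agreement = po, kappa = kappa, n_compared = length(a))
}

#' Bland-Altman agreement
#'
#' Paired-difference agreement between a test and a reference method:
#' mean bias, sample SD of the differences, limits of agreement at
#' bias +/- 1.96 SD, and the relative bias as a percentage of the
#' reference mean (reported rounded to integer percent for display).
#'
#' @param values_test,values_ref paired per-participant values (n >= 2).
#' @return List of class `bland_altman`.
#' @export
bland_altman <- function(values_test, values_ref) {
  stopifnot(length(values_test) == length(values_ref))
  n <- length(values_test)
  if (n < 2) stop("need at least 2 pairs, got ", n)
  d <- values_test - values_ref
  bias <- mean(d)
  s <- stats::sd(d)
  mref <- mean(values_ref)
  rel <- if (abs(mref) > 1e-12) 100 * bias / mref else NA_real_
  structure(
    list(mean_bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         relative_bias_pct = rel,
         relative_bias_display = if (is.na(rel)) NA_real_
           else round_half_up(rel, 0),
         n_pairs = n),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.2f (%s%%), LoA [%.2f, %.2f], n = %d\n",
    x$mean_bias,
    if (is.na(x$relative_bias_display)) "NA"
    else sprintf("%d", as.integer(x$relative_bias_display)),
    x$loa_low, x$loa_high, x$n_pairs
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Minimal base-graphics plot of differences against pair means with the
#' bias and limits of agreement; a convenience for data inspection.
#'
#' @param x a [bland_altman()] result.
#' @param values_test,values_ref the paired values the result came from.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_bland_altman <- function(x, values_test, values_ref, ...) {
  m <- (values_test + values_ref) / 2
  d <- values_test - values_ref
  graphics::plot(m, d, xlab = "pair mean", ylab = "difference", ...)
  graphics::abline(h = c(x$mean_bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}
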