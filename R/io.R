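# Plain-text serialisation of label series and feature tables.

#' Write a label series to CSV (`t_s,label`)
#' @param labels an [epoch_labels()] series.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  t0 <- attr(labels, "t0_s") %||% 0
  utils::write.csv(
    data.frame(t_s = t0 + seq_along(labels) - 1, label = as.character(labels)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a label series from CSV (`t_s,label`)
#' @param path CSV path written by [write_labels()].
#' @return An [epoch_labels()] series.
#' @export
read_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  epoch_labels(d$label, t0_s = if (nrow(d)) d$t_s[1] else 0)
}

#' Write an epoch feature table to CSV
#' @param features an `epoch_features` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  d <- as.data.frame(features)
  names(d)[names(d) == "inclination"] <- "inclination"
  utils::write.csv(
    d[, c("epoch", "t_center", "mean_u", "mean_v", "mean_w", "sd_raw",
          "sd_corr", "inclination", "forward_lean", "cadence")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
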