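# Reliability diagrams, average calibration error (ACE), AUC, and Dice.
# All metrics operate on a vector of scores in [0, 1] and binary labels
# (anomaly = 1), or on a probability_map plus a label array.

as_scores <- function(x) {
  if (inherits(x, "probability_map")) as.vector(x$values) else as.vector(x)
}

as_binary_labels <- function(y) {
  if (inherits(y, "labeled_volume")) y <- anomaly_mask(y)
  y <- as.integer(as.vector(y))
  if (!all(y %in% c(0L, 1L))) stopf("labels must be binary 0/1 (use anomaly_mask())")
  y
}

#' Reliability bins
#'
#' Assigns each score to the half-open equal-width bin
#' `B_m = ((m-1)/n_bins, m/n_bins]` (a score of exactly `m/n_bins` falls in
#' bin `m`; zeros fall in bin 1) and computes per-bin count, mean confidence
#' (mean score) and empirical accuracy. Two accuracy modes are provided:
#' * `argmax_accuracy` (default): fraction of voxels whose thresholded
#'   prediction `1[score >= 0.5]` equals the label — the literal bin-accuracy
#'   formula;
#' * `positive_frequency`: fraction of positive labels in the bin — the
#'   diagonal-over-`[0,1]` reading of a binary reliability diagram.
#'
#' @param scores numeric scores in `[0, 1]` (or a [probability_map()]).
#' @param labels binary labels (or a [labeled_volume()], reduced via
#'   [anomaly_mask()]).
#' @param n_bins number of bins (>= 2, default 10).
#' @param mode `"argmax_accuracy"` or `"positive_frequency"`.
#' @param threshold decision threshold for the argmax mode.
#' @return An object of class `reliability_bins`: data frame with columns
#'   `bin`, `lower`, `upper`, `count`, `confidence`, `accuracy`, plus
#'   attributes `mode` and `n_bins`.
#' @export
reliability_bins <- function(scores, labels, n_bins = 10,
                             mode = c("argmax_accuracy", "positive_frequency"),
                             threshold = 0.5) {
  mode <- match.arg(mode)
  s <- as_scores(scores); y <- as_binary_labels(labels)
  if (length(s) != length(y)) stopf("scores and labels differ in length")
  if (n_bins < 2) stopf("need at least 2 bins")
  if (min(s) < 0 || max(s) > 1) stopf("scores outside [0, 1]")
  bin <- pmax(ceiling(s * n_bins), 1L)
  correct <- if (mode == "argmax_accuracy") as.integer((s >= threshold) == y) else y
  cnt <- tabulate(bin, nbins = n_bins)
  conf <- acc <- rep(NA_real_, n_bins)
  nz <- cnt > 0
  conf[nz] <- vapply(which(nz), function(m) mean(s[bin == m]), 0)
  acc[nz] <- vapply(which(nz), function(m) mean(correct[bin == m]), 0)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = (seq_len(n_bins) - 1) / n_bins,
                    upper = seq_len(n_bins) / n_bins,
                    count = cnt, confidence = conf, accuracy = acc)
  structure(out, mode = mode, n_bins = n_bins, threshold = threshold,
            class = c("reliability_bins", "data.frame"))
}

#' Average calibration error
#'
#' Unweighted mean over bins of `|accuracy - confidence|`. By default empty
#' bins are excluded (mean over nonempty bins); `strict = TRUE` divides by
#' the total bin count with empty bins contributing zero.
#'
#' @param bins a [reliability_bins()] object.
#' @param strict divide by all bins instead of nonempty ones.
#' @return ACE in `[0, 1]`.
#' @export
compute_ace <- function(bins, strict = FALSE) {
  stopifnot(inherits(bins, "reliability_bins"))
  nz <- bins$count > 0
  if (!any(nz)) stopf("all bins are empty")
  gaps <- abs(bins$accuracy[nz] - bins$confidence[nz])
  if (strict) sum(gaps) / nrow(bins) else mean(gaps)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half; computed from midranks, so it is exactly invariant
#' under strictly increasing score transforms.
#'
#' @inheritParams reliability_bins
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  s <- as_scores(scores); y <- as_binary_labels(labels)
  n1 <- as.numeric(sum(y == 1L)); n0 <- as.numeric(sum(y == 0L))
  if (n1 == 0 || n0 == 0) stopf("AUC requires both classes")
  r <- rank(s)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for the thresholded prediction mask
#' `A = {score >= threshold}` and ground-truth mask `B = {label = 1}`.
#' Defined as 1 when both masks are empty (and 0 when exactly one is).
#'
#' @inheritParams reliability_bins
#' @param threshold decision threshold (default 0.5).
#' @return DSC in `[0, 1]`.
#' @export
compute_dsc <- function(scores, labels, threshold = 0.5) {
  s <- as_scores(scores); y <- as_binary_labels(labels)
  a <- s >= threshold
  na <- sum(a); nb <- sum(y == 1L)
  if (na + nb == 0L) return(1)
  2 * sum(a & y == 1L) / (na + nb)
}

#' Bundle calibration and classification metrics for one map
#'
#' Computes the reliability bins, ACE, AUC, and DSC of a scored map against
#' binary labels, optionally writing the per-bin diagram data to CSV and
#' drawing the reliability diagram.
#'
#' @inheritParams reliability_bins
#' @param threshold DSC decision threshold.
#' @param csv optional path; per-bin table written via [utils::write.csv()].
#' @param plot draw a base-graphics reliability diagram on the current
#'   device.
#' @return An object of class `metrics_report`: list with `ace`, `auc`,
#'   `dsc`, `n_voxels`, `threshold`, `mode`, `n_bins`, `bins`, and
#'   `provenance` (taken from the map when available).
#' @export
reliability_report <- function(scores, labels, n_bins = 10,
                               mode = c("argmax_accuracy", "positive_frequency"),
                               threshold = 0.5, csv = NULL, plot = FALSE) {
  mode <- match.arg(mode)
  prov <- if (inherits(scores, "probability_map"))
    c(list(semantics = scores$semantics), scores$provenance) else list()
  bins <- reliability_bins(scores, labels, n_bins = n_bins, mode = mode,
                           threshold = threshold)
  rep <- structure(list(ace = compute_ace(bins),
                        auc = compute_auc(scores, labels),
                        dsc = compute_dsc(scores, labels, threshold),
                        n_voxels = length(as_scores(scores)),
                        threshold = threshold, mode = mode, n_bins = n_bins,
                        bins = bins, provenance = prov),
                   class = "metrics_report")
  if (!is.null(csv)) {
    tab <- as.data.frame(bins)
    tab$gap <- abs(tab$accuracy - tab$confidence)
    write.csv(tab, csv, row.names = FALSE)
  }
  if (isTRUE(plot)) plot(rep)
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ACE %.4f | AUC %.4f | DSC %.4f (n = %d, %d bins, %s)\n",
              x$ace, x$auc, x$dsc, x$n_voxels, x$n_bins, x$mode))
  invisible(x)
}

#' @export
plot.metrics_report <- function(x, ...) {
  b <- x$bins[x$bins$count > 0, ]
  mid <- (b$lower + b$upper) / 2
  graphics::barplot(b$accuracy, names.arg = sprintf("%.1f", mid),
                    ylim = c(0, 1), col = "orange",
                    xlab = "confidence bin", ylab = "empirical accuracy",
                    main = sprintf("Reliability diagram (ACE %.3f)", x$ace), ...)
  graphics::abline(0, 1 / (nrow(b) * 1.2), lty = 2)
  invisible(x)
}

# Flat single-row data.frame used by sweep tables and report CSVs.
report_row <- function(rep, ...) {
  data.frame(..., ace = rep$ace, auc = rep$auc, dsc = rep$dsc,
             n_voxels = rep$n_voxels, stringsAsFactors = FALSE)
}
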