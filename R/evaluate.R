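#' Frame/clip-level classification metrics
#'
#' Accuracy, sensitivity, specificity (at the given threshold with the
#' `z <= T -> 0` boundary rule) and AUC, pooled over all evaluated units.
#' The AUC is the Mann-Whitney rank statistic with midranks for ties.
#'
#' @param probs numeric vector of adenoma probabilities (or, for vote-only
#'   combiners, binary 0/1 values).
#' @param labels 0/1 ground-truth labels aligned with `probs`.
#' @param T decision threshold.
#' @return A `metrics_report` list: `accuracy`, `sensitivity`, `specificity`,
#'   `auc` (`NA` when only one class is present), `n_units`, `threshold`.
#' @export
frame_metrics <- function(probs, labels, T = 0.5) {
  stopifnot(length(probs) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  pred <- apply_threshold(probs, T)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n_pos <- tp + fn
  n_neg <- tn + fp
  auc <- if (n_pos == 0L || n_neg == 0L) NA_real_ else {
    r <- rank(probs) # midranks for ties
    (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (as.double(n_pos) * n_neg)
  }
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = if (n_pos) tp / n_pos else NA_real_,
                 specificity = if (n_neg) tn / n_neg else NA_real_,
                 auc = auc, n_units = length(labels), threshold = T),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d, T=%.2f\n",
                     "  accuracy %.4f | sensitivity %s | specificity %s | auc %s\n"),
              x$n_units, x$threshold, x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity)),
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Per-polyp accuracy with a 95% confidence interval
#'
#' The fraction of correctly predicted units is computed for each lesion and
#' averaged unweighted across lesions — a consistency metric: it is high only
#' when most lesions have most of their frames right. The 95% CI is the
#' normal approximation `mean +/- 1.96 * sd / sqrt(n_lesions)`.
#'
#' @param preds data.frame with columns `lesion_id`, `label` and either a
#'   binary `y` or a continuous `probability`/`z` column (thresholded at `T`).
#' @param T threshold for continuous predictions.
#' @return A `polyp_accuracy_report`: `per_lesion` (named vector), `mean`,
#'   `ci_low`, `ci_high`, `n_lesions`.
#' @export
polyp_accuracy <- function(preds, T = 0.5) {
  if (!nrow(preds)) stopf("polyp_accuracy() needs at least one prediction")
  y <- if ("y" %in% names(preds) && !all(is.na(preds$y))) {
    as.integer(preds$y)
  } else if ("probability" %in% names(preds)) {
    apply_threshold(preds$probability, T)
  } else if ("z" %in% names(preds)) {
    apply_threshold(preds$z, T)
  } else stopf("preds must carry `y`, `probability` or `z`")
  correct <- as.integer(y == preds$label)
  per <- c(tapply(correct, preds$lesion_id, mean)) # c() drops the 1d-array dim
  per <- per[order(names(per))]
  n <- length(per)
  m <- mean(per)
  s <- if (n > 1L) stats::sd(per) else 0
  half <- 1.96 * s / sqrt(n)
  structure(list(per_lesion = per, mean = m,
                 ci_low = m - half, ci_high = m + half, n_lesions = n),
            class = "polyp_accuracy_report")
}

#' @export
print.polyp_accuracy_report <- function(x, ...) {
  cat(sprintf("<polyp_accuracy_report> %d lesions\n  mean %.4f [95%% CI %.4f, %.4f]\n",
              x$n_lesions, x$mean, x$ci_low, x$ci_high))
  invisible(x)
}

#' Normalised cross-correlation between two images
#'
#' Energy-normalised inner product at zero displacement over the full frame:
#' `R = sum(a * b) / sqrt(sum(a^2) * sum(b^2))`. No mean centering is applied,
#' so for non-negative images `R` lies in `[0, 1]` and `R(I, I) = 1`: high
#' values indicate small appearance change.
#'
#' @param a,b numeric arrays of identical dimensions, non-negative.
#' @return `R` in `[0, 1]`.
#' @export
ncc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("ncc() needs images of identical dimensions")
  ea <- sum(a * a)
  eb <- sum(b * b)
  if (ea == 0 || eb == 0) stopf("ncc() is undefined for an all-zero image")
  sum(a * b) / sqrt(ea * eb)
}

#' Mean consecutive-frame similarity of a clip
#'
#' NCC is computed between each of the `k - 1` consecutive frame pairs and
#' averaged across the clip.
#'
#' @param images ordered list of `k >= 2` same-shaped arrays.
#' @return Mean NCC.
#' @export
clip_similarity <- function(images) {
  k <- length(images)
  if (k < 2L) stopf("clip_similarity() needs at least 2 frames")
  mean(vapply(seq_len(k - 1L),
              function(i) ncc(images[[i]], images[[i + 1L]]), numeric(1L)))
}

#' Relate clip similarity to classification performance
#'
#' Pearson correlation (two-sided, alpha = 0.05) between per-clip similarity
#' and the per-clip correctness indicator, plus binned accuracy curves with
#' normal-approximation 95% CI bands for plotting/reporting.
#'
#' @param similarity numeric vector, one mean-NCC value per clip.
#' @param correct logical/0-1 vector, whether each clip was classified
#'   correctly.
#' @param n_bins number of equal-width similarity bins for the curve.
#' @return A `similarity_analysis`: `pearson_r`, `pearson_p`, `alpha`,
#'   `significant`, `bins` (data.frame with bin centres, n, accuracy, CI).
#' @export
similarity_performance_analysis <- function(similarity, correct, n_bins = 5L) {
  stopifnot(length(similarity) == length(correct))
  if (length(similarity) < 3L) stopf("need at least 3 clips")
  correct <- as.numeric(correct)
  if (stats::sd(similarity) == 0) {
    r <- NA_real_; p <- NA_real_
  } else if (stats::sd(correct) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(similarity, correct, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  breaks <- seq(min(similarity), max(similarity), length.out = n_bins + 1L)
  breaks[1L] <- breaks[1L] - 1e-9
  bin <- cut(similarity, breaks, labels = FALSE)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    acc <- if (length(idx)) mean(correct[idx]) else NA_real_
    se <- if (length(idx) > 1L) stats::sd(correct[idx]) / sqrt(length(idx)) else NA_real_
    data.frame(bin_center = (breaks[b] + breaks[b + 1L]) / 2,
               n = length(idx), accuracy = acc,
               ci_low = acc - 1.96 * se, ci_high = acc + 1.96 * se)
  }))
  structure(list(pearson_r = r, pearson_p = p, alpha = 0.05,
                 significant = isTRUE(p < 0.05), bins = bins,
                 n_clips = length(similarity)),
            class = "similarity_analysis")
}

#' @export
print.similarity_analysis <- function(x, ...) {
  cat(sprintf("<similarity_analysis> %d clips: r = %s, p = %s (alpha = %.2f)%s\n",
              x$n_clips,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
              ifelse(is.na(x$pearson_p), "NA", sprintf("%.3g", x$pearson_p)),
              x$alpha,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
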