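#' Randomly perturb a box to a prescribed IoU with the original
#'
#' Draws integer candidate boxes by jittering each edge of the input box
#' (jitter magnitude scaled to the requested IoU) and accepts the first
#' candidate whose IoU with the original lies within `target_iou +/- tol`
#' and which fits inside the image. Seed-deterministic rejection sampling.
#'
#' @param box the original (expert) [bounding_box()].
#' @param target_iou requested IoU, strictly inside `(0, 1)`.
#' @param tol acceptance tolerance (default 0.01).
#' @param image_width,image_height image bounds in pixels.
#' @param seed integer seed.
#' @param max_attempts candidates to try before giving up.
#' @return A `bounding_box` whose IoU with `box` is within tolerance.
#' @export
perturb_box_to_iou <- function(box, target_iou, tol = 0.01,
                               image_width, image_height, seed = 1L,
                               max_attempts = 20000L) {
  if (target_iou <= 0 || target_iou >= 1) {
    stopf("target_iou must lie strictly inside (0, 1)")
  }
  w <- box[["x_max"]] - box[["x_min"]]
  h <- box[["y_max"]] - box[["y_min"]]
  spread <- (1 - target_iou) / target_iou
  shift_x <- min(as.integer(image_width),
                 max(2L, as.integer(ceiling(w * spread * 1.5))))
  shift_y <- min(as.integer(image_height),
                 max(2L, as.integer(ceiling(h * spread * 1.5))))
  with_seed(seed, {
    batch <- 200L
    tried <- 0L
    while (tried < max_attempts) {
      n <- min(batch, max_attempts - tried)
      tried <- tried + n
      d <- matrix(as.integer(round(stats::runif(4L * n, -0.5, 0.5) *
                                   rep(c(shift_x, shift_y, shift_x, shift_y),
                                       each = n) * 2)), ncol = 4L)
      x0 <- clamp(box[["x_min"]] + d[, 1L], 0L, image_width - 1L)
      y0 <- clamp(box[["y_min"]] + d[, 2L], 0L, image_height - 1L)
      x1 <- clamp(box[["x_max"]] + d[, 3L], 1L, image_width)
      y1 <- clamp(box[["y_max"]] + d[, 4L], 1L, image_height)
      ok <- x0 < x1 & y0 < y1
      for (i in which(ok)) {
        cand <- bounding_box(x0[i], y0[i], x1[i], y1[i])
        # small epsilon so exact-boundary candidates are not lost to rounding
        if (abs(iou(box, cand) - target_iou) <= tol + 1e-9) return(cand)
      }
    }
  })
  stopf("could not reach IoU %.2f +/- %.3f within %d attempts (box %dx%d in %dx%d image)",
        target_iou, tol, max_attempts, w, h, image_width, image_height)
}

#' Classification robustness as a function of box quality
#'
#' Implements the box-perturbation protocol: at each IoU level every eligible
#' frame is re-cropped with a randomly perturbed box achieving that IoU with
#' the expert annotation, the classifier is re-run, and the frame-level
#' metrics, each requested temporal combination, and the per-polyp accuracy
#' are recomputed. The default grid is the 9 levels 0.1..0.9; an extended
#' grid adds the 0.05 and 0.95 endpoints.
#'
#' @param classifier a trained `frame_net`, or any function mapping a list of
#'   preprocessed image arrays to adenoma probabilities.
#' @param m a `polyp_manifest` of evaluation frames with expert boxes.
#' @param levels IoU levels, each in `(0, 1)`, sorted ascending.
#' @param k clip length for the temporal combinations.
#' @param methods temporal combination methods to evaluate alongside the
#'   frame baseline.
#' @param out_size preprocessing output size.
#' @param tol IoU acceptance tolerance.
#' @param seed integer seed; each (level, frame) pair gets its own derived
#'   stream, so the curve is reproducible bit-exactly.
#' @return A `robustness_curve`: data.frame with one row per (level, method)
#'   holding accuracy, sensitivity, specificity, auc and polyp accuracy.
#' @export
iou_robustness_curve <- function(classifier, m, levels = seq(0.1, 0.9, by = 0.1),
                                 k = 15L, methods = "soft_average",
                                 out_size = 64L, tol = 0.01, seed = 1L) {
  if (any(levels <= 0 | levels >= 1)) stopf("levels must lie in (0, 1)")
  levels <- sort(levels)
  prob_fun <- as_prob_fun(classifier)
  df <- as.data.frame(m)
  df <- df[nzchar(df$boxes), , drop = FALSE]
  if (!nrow(df)) stopf("no frames with boxes to evaluate")
  rows <- list()
  for (li in seq_along(levels)) {
    level <- levels[li]
    probs <- numeric(nrow(df))
    for (i in seq_len(nrow(df))) {
      img <- read_image(df$image_path[i])
      b <- parse_boxes(df$boxes[i])[[1L]]
      pb <- perturb_box_to_iou(b, level, tol = tol,
                               image_width = dim(img)[2L],
                               image_height = dim(img)[1L],
                               seed = child_seed(seed, li * 100000L + i))
      probs[i] <- prob_fun(list(preprocess_frame(img, pb, out_size = out_size)))
    }
    fm <- frame_metrics(probs, df$label)
    pa <- polyp_accuracy(data.frame(lesion_id = df$lesion_id, label = df$label,
                                    probability = probs))
    rows[[length(rows) + 1L]] <-
      data.frame(iou_level = level, method = "frame", accuracy = fm$accuracy,
                 sensitivity = fm$sensitivity, specificity = fm$specificity,
                 auc = fm$auc, polyp_accuracy = pa$mean,
                 stringsAsFactors = FALSE)
    stream <- data.frame(lesion_id = df$lesion_id, frame_index = df$frame_index,
                         probability = probs, label = df$label,
                         stringsAsFactors = FALSE)
    for (meth in methods) {
      agg <- stream_aggregate(stream, k = k, method = meth)
      if (!nrow(agg)) next
      zz <- if (meth == "plurality") agg$y else agg$z
      cm <- frame_metrics(zz, agg$label)
      cpa <- polyp_accuracy(agg)
      rows[[length(rows) + 1L]] <-
        data.frame(iou_level = level, method = meth, accuracy = cm$accuracy,
                   sensitivity = cm$sensitivity, specificity = cm$specificity,
                   auc = cm$auc, polyp_accuracy = cpa$mean,
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("robustness_curve", "data.frame"))
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("<robustness_curve> %d IoU levels x %d method(s)\n",
              length(unique(x$iou_level)), length(unique(x$method))))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
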