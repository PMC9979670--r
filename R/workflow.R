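#' Reduce detector output for one frame to a single crop box
#'
#' Applies the pipeline's box rules: (i) frames whose annotation contains
#' multiple polyps are discarded; (ii) a single detected region is
#' circumscribed by its rectangular bounding box; (iii) multiple detected
#' regions (false positives) are enclosed together in one minimal rectangle;
#' (iv) with no detection the frame is discarded since no box can crop the
#' image. Discards are signals, not errors.
#'
#' @param regions list of `bounding_box` regions detected in the frame.
#' @param annotated_polyp_count number of expert-annotated polyps in the
#'   frame (rule (i) keys on the annotation, not the detector output).
#' @return List with `box` (a `bounding_box` or `NULL`) and `discard`
#'   (`NA`, `"multi_polyp"` or `"no_detection"`).
#' @export
detections_to_box <- function(regions, annotated_polyp_count = 1L) {
  if (annotated_polyp_count > 1L) {
    return(list(box = NULL, discard = "multi_polyp"))
  }
  if (length(regions) == 0L) {
    return(list(box = NULL, discard = "no_detection"))
  }
  list(box = box_union(regions), discard = NA_character_)
}

#' Expert-annotation detections
#'
#' Wraps the manifest's expert boxes in the detection format, for the
#' expert-box pathway and for identity checks against simulated detectors.
#'
#' @param m a `polyp_manifest`.
#' @return data.frame with `lesion_id`, `frame_index`, `regions` (box string)
#'   and `source`.
#' @export
expert_detections <- function(m) {
  df <- as.data.frame(m)
  data.frame(lesion_id = df$lesion_id, frame_index = df$frame_index,
             regions = df$boxes, source = "expert", stringsAsFactors = FALSE)
}

#' Simulate a polyp detector
#'
#' Stands in for a trained segmentation detector so the full
#' detection-then-classification pipeline is testable: per frame the ground
#' truth box is dropped with probability `miss_rate`, jittered otherwise,
#' and a spurious region is added with probability `fp_rate`.
#'
#' @param m a `polyp_manifest` carrying expert boxes.
#' @param miss_rate probability of a false negative (no detection).
#' @param fp_rate probability of an extra false-positive region.
#' @param jitter maximum box translation/resize as a fraction of box size.
#' @param seed integer seed; output is a pure function of `(m, rates, seed)`.
#' @return Detection data.frame (`lesion_id`, `frame_index`, `regions`,
#'   `source = "simulated"`).
#' @export
simulate_detector <- function(m, miss_rate = 0, fp_rate = 0, jitter = 0,
                              seed = 1L) {
  if (any(c(miss_rate, fp_rate) < 0 | c(miss_rate, fp_rate) > 1)) {
    stopf("rates must lie in [0, 1]")
  }
  df <- as.data.frame(m)
  with_seed(seed, {
    regions <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      gt <- parse_boxes(df$boxes[i])
      if (!length(gt)) { regions[i] <- ""; next }
      if (stats::runif(1) < miss_rate) { regions[i] <- ""; next }
      add_fp <- stats::runif(1) < fp_rate
      # image dimensions are only needed when boxes actually move or appear
      img_dim <- if (jitter > 0 || add_fp) guess_image_dim(df$image_path[i])
      out <- lapply(gt, function(b) jitter_box(b, jitter, img_dim))
      if (add_fp) out <- c(out, list(random_box(img_dim)))
      regions[i] <- format_boxes(out)
    }
    data.frame(lesion_id = df$lesion_id, frame_index = df$frame_index,
               regions = regions, source = "simulated",
               stringsAsFactors = FALSE)
  })
}

guess_image_dim <- function(path) {
  img <- read_image(path)
  c(height = dim(img)[1L], width = dim(img)[2L])
}

jitter_box <- function(b, jitter, img_dim) {
  if (jitter <= 0) return(b)
  w <- b[["x_max"]] - b[["x_min"]]
  h <- b[["y_max"]] - b[["y_min"]]
  d <- round(stats::runif(4L, -jitter, jitter) * c(w, h, w, h))
  bounding_box(clamp(b[["x_min"]] + d[1L], 0L, img_dim[["width"]] - 2L),
               clamp(b[["y_min"]] + d[2L], 0L, img_dim[["height"]] - 2L),
               clamp(b[["x_max"]] + d[3L], b[["x_min"]] + d[1L] + 1L, img_dim[["width"]]),
               clamp(b[["y_max"]] + d[4L], b[["y_min"]] + d[2L] + 1L, img_dim[["height"]]))
}

random_box <- function(img_dim) {
  w <- img_dim[["width"]]; h <- img_dim[["height"]]
  x0 <- sample.int(w - 8L, 1L) - 1L
  y0 <- sample.int(h - 8L, 1L) - 1L
  bounding_box(x0, y0, min(w, x0 + sample(4:max(5L, w %/% 4L), 1L)),
               min(h, y0 + sample(4:max(5L, h %/% 4L), 1L)))
}

#' Run the detection-then-classification pipeline
#'
#' Boxes derived from the detections via [detections_to_box()] replace the
#' expert boxes for cropping; discarded frames lose their box and therefore
#' break clip continuity exactly like non-annotated frames. Clips are
#' extracted from the surviving frames, every unique clip frame is
#' classified, per-frame predictions are combined per clip, and the usual
#' reports are computed on what survives.
#'
#' @param m a `polyp_manifest` (expert annotations; rule (i) uses its box
#'   counts).
#' @param detections detection data.frame (see [simulate_detector()]), or
#'   `NULL` for the expert-box pathway.
#' @param classifier a trained `frame_net` or probability function.
#' @param config a [clip_config()].
#' @param method temporal combination method.
#' @param out_size preprocessing output side.
#' @param T decision threshold.
#' @return A `pipeline_result`: `frame_report`, `clip_report`,
#'   `polyp_frame`, `polyp_clip`, `discards` (counts by reason),
#'   `frame_preds`, `clip_preds`, `n_clips`.
#' @export
run_pipeline <- function(m, detections = NULL, classifier, config = clip_config(),
                         method = "soft_average", out_size = 64L, T = 0.5) {
  df <- as.data.frame(m)
  discards <- c(multi_polyp = 0L, no_detection = 0L)
  if (!is.null(detections)) {
    key <- frame_key(detections$lesion_id, detections$frame_index)
    lut <- stats::setNames(detections$regions, key)
    new_boxes <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      n_annot <- length(parse_boxes(df$boxes[i]))
      if (n_annot == 0L) { new_boxes[i] <- ""; next }
      regions <- parse_boxes(lut[[frame_key(df$lesion_id[i], df$frame_index[i])]] %||% "")
      res <- detections_to_box(regions, n_annot)
      if (is.null(res$box)) {
        discards[res$discard] <- discards[res$discard] + 1L
        new_boxes[i] <- ""
      } else {
        new_boxes[i] <- format_boxes(list(res$box))
      }
    }
    df$boxes <- new_boxes
  }
  m2 <- manifest(df, consecutive_frames = attr(m, "consecutive_frames"),
                 frame_rate = attr(m, "frame_rate"), check_images = FALSE)
  clips <- extract_clips_manifest(m2, config)
  if (!length(clips)) {
    warning("no clips survive the pipeline; returning an empty report")
    return(structure(list(frame_report = NULL, clip_report = NULL,
                          polyp_frame = NULL, polyp_clip = NULL,
                          discards = discards, frame_preds = NULL,
                          clip_preds = NULL, n_clips = 0L),
                     class = "pipeline_result"))
  }
  prob_fun <- as_prob_fun(classifier)
  frames <- unique(do.call(rbind, lapply(clips, `[[`, "frames")))
  keys <- frame_key(frames$lesion_id, frames$frame_index)
  keep <- !duplicated(keys)
  frames <- frames[keep, , drop = FALSE]; keys <- keys[keep]
  x <- lapply(seq_len(nrow(frames)), function(i) {
    preprocess_frame(frames$image_path[i], parse_boxes(frames$boxes[i])[[1L]],
                     out_size = out_size)
  })
  probs <- prob_fun(x)
  frame_preds <- data.frame(lesion_id = frames$lesion_id,
                            frame_index = frames$frame_index,
                            probability = probs, label = frames$label,
                            stringsAsFactors = FALSE)
  plut <- stats::setNames(probs, keys)
  clip_preds <- do.call(rbind, lapply(clips, function(cl) {
    p <- unname(plut[frame_key(cl$frames$lesion_id, cl$frames$frame_index)])
    if (method == "soft_average") {
      z <- soft_average(p); y <- apply_threshold(z, T)
    } else if (method == "extreme") {
      z <- extreme_vote(p); y <- apply_threshold(z, T)
    } else if (method == "plurality") {
      z <- NA_real_; y <- plurality_vote(p, T)
    } else stopf("unknown method '%s'", method)
    data.frame(lesion_id = cl$lesion_id, start_index = cl$frame_index[1L],
               z = z, y = y, label = cl$frames$label[1L],
               stringsAsFactors = FALSE)
  }))
  frame_report <- frame_metrics(frame_preds$probability, frame_preds$label, T)
  clip_report <- frame_metrics(if (method == "plurality") clip_preds$y else clip_preds$z,
                               clip_preds$label, T)
  structure(list(frame_report = frame_report, clip_report = clip_report,
                 polyp_frame = polyp_accuracy(frame_preds, T),
                 polyp_clip = polyp_accuracy(clip_preds, T),
                 discards = discards, frame_preds = frame_preds,
                 clip_preds = clip_preds, n_clips = length(clips)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d clips; discards: multi_polyp=%d, no_detection=%d\n",
              x$n_clips, x$discards[["multi_polyp"]], x$discards[["no_detection"]]))
  if (!is.null(x$frame_report)) {
    cat("frame level: "); print(x$frame_report)
    cat("clip level:  "); print(x$clip_report)
  }
  invisible(x)
}

# per-patient balance statistics entering the fold cost (all count-valued so
# fold shares are comparable): NBI polyp frames, lesions, polyp pixels,
# adenoma lesions (histology mix), high-quality frames
patient_balance_stats <- function(m) {
  df <- as.data.frame(m)
  df$has_box <- nzchar(df$boxes)
  df$nbi <- df$modality %in% c("NBI", "NBI_NEAR_FOCUS")
  df$box_pixels <- vapply(df$boxes, function(s) {
    sum(vapply(parse_boxes(s), box_area, numeric(1L)))
  }, numeric(1L), USE.NAMES = FALSE)
  les <- unique(df[c("patient_id", "lesion_id", "label")])
  stats <- lapply(split(df, df$patient_id), function(g) {
    c(nbi_polyp_frames = sum(g$nbi & g$has_box),
      lesions = length(unique(g$lesion_id)),
      polyp_pixels = sum(g$box_pixels),
      adenoma_lesions = sum(tapply(g$label, g$lesion_id, `[`, 1L)),
      hq_frames = sum(g$high_quality))
  })
  do.call(rbind, stats)
}

fold_balance_cost <- function(stats, assignment, n_folds) {
  cost <- 0
  for (c_idx in seq_len(ncol(stats))) {
    tot <- sum(stats[, c_idx])
    if (tot == 0) next
    fold_tot <- vapply(seq_len(n_folds), function(f) {
      sum(stats[assignment == f, c_idx])
    }, numeric(1L))
    cost <- cost + sum(abs(fold_tot / tot - 1 / n_folds))
  }
  cost
}

#' Patient-level cross-validation folds with balance optimisation
#'
#' Patients are partitioned into `n_folds` disjoint folds (each fold's test
#' set holds ~1/`n_folds` of the patients, giving the 80/20 train/test split
#' at 5 folds). Among `n_candidates` random near-equal-size partitions the
#' one minimising the summed per-fold deviation of five balance criteria
#' (NBI polyp frame count, lesion count, polyp pixel size, histology mix,
#' image quality) from the global distribution is returned. No patient ever
#' appears in two folds.
#'
#' @param m a `polyp_manifest`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @param n_candidates random partitions scored.
#' @return A `fold_assignment`: `assignment` (data.frame patient_id/fold),
#'   `cost`, `balance` (per-fold criterion totals), `n_folds`.
#' @export
patient_folds <- function(m, n_folds = 5L, seed = 1L, n_candidates = 200L) {
  stats <- patient_balance_stats(m)
  patients <- rownames(stats)
  if (length(patients) < n_folds) {
    stopf("need at least %d patients for %d folds", n_folds, n_folds)
  }
  base_sizes <- rep(length(patients) %/% n_folds, n_folds) +
    (seq_len(n_folds) <= length(patients) %% n_folds)
  best <- NULL
  best_cost <- Inf
  with_seed(seed, {
    for (cand in seq_len(n_candidates)) {
      perm <- sample(patients)
      assignment <- rep(seq_len(n_folds), times = base_sizes)
      names(assignment) <- perm
      assignment <- assignment[patients]
      cost <- fold_balance_cost(stats, assignment, n_folds)
      if (cost < best_cost) {
        best_cost <- cost
        best <- assignment
      }
    }
  })
  balance <- do.call(rbind, lapply(seq_len(n_folds), function(f) {
    colSums(stats[best == f, , drop = FALSE])
  }))
  rownames(balance) <- paste0("fold", seq_len(n_folds))
  structure(list(assignment = data.frame(patient_id = patients,
                                         fold = unname(best),
                                         stringsAsFactors = FALSE),
                 cost = best_cost, balance = balance, n_folds = n_folds),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d folds over %d patients, balance cost %.4f\n",
              x$n_folds, nrow(x$assignment), x$cost))
  print(x$balance)
  invisible(x)
}

#' Patient-level cross-validation of the clip diagnosis workflow
#'
#' For each fold a classifier is trained on the training patients and every
#' test lesion is predicted; all test predictions are pooled before any
#' metric is computed, so each lesion is predicted exactly once and the
#' pooled metrics equal metrics over the concatenated prediction set.
#'
#' @param m a `polyp_manifest`.
#' @param n_folds number of folds.
#' @param config a [clip_config()].
#' @param out_size preprocessing output side.
#' @param method temporal combination method for the clip-level report.
#' @param train_fun `function(train_manifest, fold_seed)` returning a
#'   classifier (`frame_net` or probability function). The default trains a
#'   small-encoder frame classifier with `enc_spec`/`control`.
#' @param enc_spec,control specs for the default `train_fun`.
#' @param seed integer seed.
#' @param n_candidates candidate partitions for [patient_folds()].
#' @return A `crossval_result`: `folds`, per-fold `models`, pooled
#'   `frame_preds`/`clip_preds`, `frame_report`, `clip_report`,
#'   `polyp_frame`, `polyp_clip`.
#' @export
run_crossval <- function(m, n_folds = 5L, config = clip_config(),
                         out_size = 64L, method = "soft_average",
                         train_fun = NULL, enc_spec = encoder_spec("small"),
                         control = train_spec(), seed = 1L,
                         n_candidates = 100L) {
  folds <- patient_folds(m, n_folds = n_folds, seed = seed,
                         n_candidates = n_candidates)
  fa <- stats::setNames(folds$assignment$fold, folds$assignment$patient_id)
  df <- as.data.frame(m)
  if (is.null(train_fun)) {
    train_fun <- function(train_m, fold_seed) {
      ds <- build_frame_dataset(train_m, config, out_size)
      ctl <- control
      ctl$seed <- fold_seed
      train_frame_classifier(ds$x, ds$y, spec = enc_spec, control = ctl)
    }
  }
  models <- vector("list", n_folds)
  fp <- list(); cp <- list()
  for (f in seq_len(n_folds)) {
    test_patients <- names(fa)[fa == f]
    train_df <- df[!(df$patient_id %in% test_patients), , drop = FALSE]
    test_df <- df[df$patient_id %in% test_patients, , drop = FALSE]
    stopifnot(length(intersect(train_df$patient_id, test_df$patient_id)) == 0L)
    train_m <- manifest(train_df, check_images = FALSE)
    test_m <- manifest(test_df, check_images = FALSE)
    models[[f]] <- train_fun(train_m, child_seed(seed, 100L + f))
    res <- run_pipeline(test_m, detections = NULL, classifier = models[[f]],
                        config = config, method = method, out_size = out_size)
    if (!is.null(res$frame_preds)) {
      res$frame_preds$fold <- f
      res$clip_preds$fold <- f
      fp[[length(fp) + 1L]] <- res$frame_preds
      cp[[length(cp) + 1L]] <- res$clip_preds
    }
  }
  frame_preds <- do.call(rbind, fp)
  clip_preds <- do.call(rbind, cp)
  structure(list(folds = folds, models = models,
                 frame_preds = frame_preds, clip_preds = clip_preds,
                 frame_report = frame_metrics(frame_preds$probability,
                                              frame_preds$label),
                 clip_report = frame_metrics(
                   if (method == "plurality") clip_preds$y else clip_preds$z,
                   clip_preds$label),
                 polyp_frame = polyp_accuracy(frame_preds),
                 polyp_clip = polyp_accuracy(clip_preds),
                 method = method),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds, %d pooled frame predictions, method %s\n",
              x$folds$n_folds, nrow(x$frame_preds), x$method))
  cat("frame level: "); print(x$frame_report)
  cat("clip level:  "); print(x$clip_report)
  cat("polyp accuracy (frame): "); print(x$polyp_frame)
  invisible(x)
}
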