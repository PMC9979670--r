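#' Configuration for the synthetic polyp-video generator
#'
#' The generator emulates the statistical structure that the clip-based
#' diagnosis method assumes: two visually separable lesion texture classes
#' inside a bounded elliptical region (adenoma: high-frequency tubular
#' striping; non-adenoma: low-contrast smooth dotting), smooth per-frame
#' camera motion, variable image quality (blur on low-quality frames), frozen
#' segments that repeat the previous frame verbatim, class imbalance, and
#' multiple lesions per patient.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient integer range `c(min, max)` of lesions drawn per
#'   patient.
#' @param frames_per_lesion integer range `c(min, max)` of frames per lesion.
#' @param image_size square frame side in pixels.
#' @param class_balance fraction of lesions labelled adenoma (default 0.76,
#'   the adenoma/non-adenoma box balance the clinical setting exhibits).
#' @param low_quality_rate per-frame probability of a low-quality (blurred)
#'   frame.
#' @param frozen_segment_rate per-frame probability that a short frozen run
#'   (verbatim repeats of the previous frame) starts.
#' @param motion_scale list with per-frame `translate` (pixels), `rotate`
#'   (degrees) and `scale` (relative) drift magnitudes.
#' @param texture_params list with `stripe_period` (px), `stripe_contrast`,
#'   `dot_contrast` and `hardness` in `[0,1]`; hardness scales both contrasts
#'   down by `1 - hardness` so per-frame errors can be induced for
#'   aggregation studies.
#' @param seed integer; together with the config it fully determines output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 10L,
                         lesions_per_patient = c(1L, 2L),
                         frames_per_lesion = c(20L, 40L),
                         image_size = 64L,
                         class_balance = 0.76,
                         low_quality_rate = 0.1,
                         frozen_segment_rate = 0.03,
                         motion_scale = list(translate = 1.5, rotate = 3, scale = 0.02),
                         texture_params = list(stripe_period = 4, stripe_contrast = 0.45,
                                               dot_contrast = 0.12, hardness = 0),
                         seed = 1L) {
  rates <- c(class_balance, low_quality_rate, frozen_segment_rate)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0, 1]")
  if (image_size < 16L) stopf("image_size must be >= 16")
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 frames_per_lesion = as.integer(frames_per_lesion),
                 image_size = as.integer(image_size),
                 class_balance = class_balance,
                 low_quality_rate = low_quality_rate,
                 frozen_segment_rate = frozen_segment_rate,
                 motion_scale = motion_scale,
                 texture_params = texture_params,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Render one frame: background mucosa + elliptical lesion with class texture.
# state: cx, cy, a, b, theta (ellipse), phase (texture), dots (matrix of blob
# centres in unit ellipse coords, non-adenoma only).
render_frame <- function(state, label, size, tp) {
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), nrow = size) # columns
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), nrow = size) # rows
  dx <- xs - state$cx
  dy <- ys - state$cy
  ct <- cos(state$theta); st <- sin(state$theta)
  u <- (dx * ct + dy * st) / state$a
  v <- (-dx * st + dy * ct) / state$b
  inside <- (u * u + v * v) <= 1
  soft <- 1 - clamp((sqrt(u * u + v * v) - 0.85) / 0.15, 0, 1) # rim feather

  hard <- 1 - (tp$hardness %||% 0)
  if (label == 1L) {
    # tubular striping: oriented high-frequency grating following the ellipse
    tex <- sin(2 * pi * (u * state$a) / tp$stripe_period + state$phase) *
      0.5 * tp$stripe_contrast * hard
  } else {
    # smooth dotting: a few gentle blobs
    tex <- matrix(0, size, size)
    for (i in seq_len(nrow(state$dots))) {
      du <- u - state$dots[i, 1L]
      dv <- v - state$dots[i, 2L]
      tex <- tex + exp(-(du * du + dv * dv) / (2 * 0.12^2))
    }
    tex <- (tex / max(1, nrow(state$dots) / 3) - 0.3) * tp$dot_contrast * hard
  }

  bg_r <- 0.72 + 0.05 * sin(2 * pi * ys / size + state$phase / 3)
  bg_g <- 0.50 + 0.04 * cos(2 * pi * xs / size)
  bg_b <- 0.48 + 0.03 * sin(2 * pi * (xs + ys) / (2 * size))
  les_r <- 0.62 + tex
  les_g <- 0.40 + 0.8 * tex
  les_b <- 0.34 + 0.6 * tex
  w <- inside * soft
  img <- array(0, c(size, size, 3L))
  img[, , 1L] <- bg_r * (1 - w) + les_r * w
  img[, , 2L] <- bg_g * (1 - w) + les_g * w
  img[, , 3L] <- bg_b * (1 - w) + les_b * w
  clamp(img, 0, 1)
}

tight_box <- function(state, size) {
  # analytic tight bounds of the rotated ellipse, clamped to the image
  hx <- sqrt((state$a * cos(state$theta))^2 + (state$b * sin(state$theta))^2)
  hy <- sqrt((state$a * sin(state$theta))^2 + (state$b * cos(state$theta))^2)
  bounding_box(max(0L, floor(state$cx - hx)), max(0L, floor(state$cy - hy)),
               min(size, ceiling(state$cx + hx)), min(size, ceiling(state$cy + hy)))
}

box_blur <- function(img) {
  for (ch in 1:3) {
    m <- img[, , ch]
    p <- rbind(m[1L, ], m, m[nrow(m), ])
    p <- cbind(p[, 1L], p, p[, ncol(p)])
    n <- nrow(m); k <- ncol(m)
    img[, , ch] <- (p[1:n, 1:k] + p[1:n, 2:(k + 1)] + p[1:n, 3:(k + 2)] +
                    p[2:(n + 1), 1:k] + p[2:(n + 1), 2:(k + 1)] + p[2:(n + 1), 3:(k + 2)] +
                    p[3:(n + 2), 1:k] + p[3:(n + 2), 2:(k + 1)] + p[3:(n + 2), 3:(k + 2)]) / 9
  }
  img
}

#' Generate one lesion's video
#'
#' Renders an ordered run of frames showing a single drifting elliptical
#' lesion whose texture encodes the histology label, writes them as PNGs and
#' returns the corresponding manifest rows. Identical `(config, seed)` give
#' bit-identical output.
#'
#' @param config a [synth_config()].
#' @param lesion_label 0 (non-adenoma) or 1 (adenoma).
#' @param seed integer seed for this lesion.
#' @param out_dir directory for the PNG frames (created if needed).
#' @param patient_id,lesion_id,sequence_id identifiers for the manifest rows.
#' @param n_frames optional frame count; drawn from the config range if `NULL`.
#' @return data.frame of manifest rows for this lesion.
#' @export
generate_lesion_video <- function(config, lesion_label, seed, out_dir,
                                  patient_id = "p1", lesion_id = "p1_l1",
                                  sequence_id = "s1", n_frames = NULL) {
  stopifnot(inherits(config, "synth_config"), lesion_label %in% c(0L, 1L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  size <- config$image_size
  ms <- config$motion_scale
  tp <- config$texture_params
  with_seed(seed, {
    if (is.null(n_frames)) {
      n_frames <- sample_range(config$frames_per_lesion[1L],
                               config$frames_per_lesion[2L])
    }
    base_a <- runif(1, 0.16, 0.26) * size
    base_b <- runif(1, 0.14, 0.22) * size
    state <- list(cx = runif(1, 0.4, 0.6) * size, cy = runif(1, 0.4, 0.6) * size,
                  a = base_a, b = base_b, theta = runif(1, 0, pi),
                  phase = runif(1, 0, 2 * pi),
                  dots = cbind(runif(8, -0.7, 0.7), runif(8, -0.7, 0.7)))
    rows <- vector("list", n_frames)
    prev_img <- NULL; prev_box <- NULL; prev_hq <- TRUE
    frozen_left <- 0L
    for (t in seq_len(n_frames)) {
      frozen <- FALSE
      if (frozen_left > 0L && !is.null(prev_img)) {
        # a frozen frame repeats the previous frame verbatim, quality included
        img <- prev_img; box <- prev_box; frozen <- TRUE
        frozen_left <- frozen_left - 1L
      } else {
        if (t > 1L) {
          if (runif(1) < config$frozen_segment_rate) frozen_left <- sample(1:3, 1L)
          state$cx <- clamp(state$cx + runif(1, -ms$translate, ms$translate),
                            0.3 * size, 0.7 * size)
          state$cy <- clamp(state$cy + runif(1, -ms$translate, ms$translate),
                            0.3 * size, 0.7 * size)
          state$theta <- state$theta + runif(1, -ms$rotate, ms$rotate) * pi / 180
          sc <- 1 + runif(1, -ms$scale, ms$scale)
          state$a <- clamp(state$a * sc, max(4, 0.10 * size), 0.30 * size)
          state$b <- clamp(state$b * sc, max(4, 0.10 * size), 0.30 * size)
        }
        img <- render_frame(state, lesion_label, size, tp)
        box <- tight_box(state, size)
      }
      high_quality <- if (frozen) prev_hq else runif(1) >= config$low_quality_rate
      out_img <- if (high_quality) img else box_blur(box_blur(img))
      path <- file.path(out_dir, sprintf("%s_f%04d.png", lesion_id, t - 1L))
      png::writePNG(out_img, path)
      prev_img <- img; prev_box <- box; prev_hq <- high_quality
      rows[[t]] <- data.frame(patient_id = patient_id, lesion_id = lesion_id,
                              sequence_id = sequence_id, frame_index = t - 1L,
                              image_path = path, modality = "NBI",
                              high_quality = high_quality, frozen = frozen,
                              boxes = format_boxes(list(box)),
                              label = as.integer(lesion_label),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic dataset
#'
#' Draws lesions nested under patients, labels them adenoma with probability
#' `class_balance`, renders every lesion video and writes `manifest.csv` plus
#' an image tree under `out_dir`.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @return The validated `polyp_manifest` (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- with_seed(config$seed, {
    lesions <- list()
    idx <- 0L
    for (p in seq_len(config$n_patients)) {
      n_les <- sample_range(config$lesions_per_patient[1L],
                            config$lesions_per_patient[2L])
      for (l in seq_len(n_les)) {
        idx <- idx + 1L
        lesions[[idx]] <- list(patient_id = sprintf("p%03d", p),
                               lesion_id = sprintf("p%03d_l%d", p, l),
                               label = as.integer(runif(1) < config$class_balance),
                               seed = child_seed(config$seed, idx))
      }
    }
    lesions
  })
  rows <- lapply(plan, function(les) {
    generate_lesion_video(config, les$label, les$seed,
                          out_dir = file.path(out_dir, les$patient_id),
                          patient_id = les$patient_id, lesion_id = les$lesion_id,
                          sequence_id = paste0(les$lesion_id, "_s1"))
  })
  m <- manifest(do.call(rbind, rows), consecutive_frames = TRUE)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}
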