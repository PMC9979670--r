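# Per-channel normalisation constants; the ImageNet statistics are the
# conventional default for encoders initialised in that regime.
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Read an image file as an H x W x 3 array in [0, 1]
#'
#' @param path PNG or JPEG file.
#' @return Numeric array, height x width x 3.
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    as.array(EBImage::imageData(EBImage::readImage(path)))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

# bilinear resize via EBImage; array is H x W x C, EBImage images are
# W x H x C, hence the transposes
resize_bilinear <- function(img, out_h, out_w) {
  x <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
  y <- EBImage::resize(x, w = out_w, h = out_h, filter = "bilinear")
  aperm(as.array(EBImage::imageData(y)), c(2L, 1L, 3L))
}

#' Crop a polyp box and prepare it for the classifier
#'
#' Crops the half-open pixel box out of the frame (only the polyp area enters
#' the model), optionally expands it by a margin, resizes the crop to
#' `out_size` x `out_size` with bilinear interpolation and standardises each
#' channel as `(x - mean) / sd`.
#'
#' @param image H x W x 3 array in `[0, 1]`, or a file path.
#' @param box a [bounding_box()] within the image.
#' @param out_size output side in pixels (224 for the reference encoder,
#'   smaller for desk-scale encoders).
#' @param margin fractional box expansion on every side (default 0: the
#'   annotated box is used exactly).
#' @param normalize apply the per-channel standardisation.
#' @param mean,sd per-channel normalisation constants.
#' @return `out_size` x `out_size` x 3 numeric array.
#' @export
preprocess_frame <- function(image, box, out_size = 224L, margin = 0,
                             normalize = TRUE,
                             mean = IMAGENET_MEAN, sd = IMAGENET_SD) {
  if (is.character(image)) image <- read_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (margin > 0) {
    mw <- round(margin * (box[["x_max"]] - box[["x_min"]]))
    mh <- round(margin * (box[["y_max"]] - box[["y_min"]]))
    box <- bounding_box(box[["x_min"]] - mw, box[["y_min"]] - mh,
                        box[["x_max"]] + mw, box[["y_max"]] + mh)
  }
  box <- box_clamp(box, w, h) # errors if degenerate after clamping
  crop <- image[(box[["y_min"]] + 1L):box[["y_max"]],
                (box[["x_min"]] + 1L):box[["x_max"]], , drop = FALSE]
  out <- resize_bilinear(crop, out_size, out_size)
  if (normalize) {
    for (ch in 1:3) out[, , ch] <- (out[, , ch] - mean[ch]) / sd[ch]
  }
  out
}

#' Augmentation configuration
#'
#' One parameter vector is drawn per clip and applied identically to every
#' frame in the clip, so augmentation never introduces artificial intra-clip
#' variation. Zeroing all ranges yields the identity transform.
#'
#' @param rotation max absolute rotation in degrees.
#' @param translation max absolute translation as a fraction of image side.
#' @param scale multiplicative scale range `c(lo, hi)`.
#' @param brightness max absolute additive brightness shift.
#' @param contrast max absolute relative contrast change.
#' @param saturation max absolute relative saturation change.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation = 10, translation = 0.05,
                           scale = c(0.9, 1.1), brightness = 0.15,
                           contrast = 0.15, saturation = 0.15) {
  stopifnot(all(is.finite(c(rotation, translation, scale, brightness,
                            contrast, saturation))))
  structure(list(rotation = rotation, translation = translation, scale = scale,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation),
            class = "augment_config")
}

draw_augment_params <- function(config, seed) {
  with_seed(seed, list(
    angle = stats::runif(1, -config$rotation, config$rotation) * pi / 180,
    tx = stats::runif(1, -config$translation, config$translation),
    ty = stats::runif(1, -config$translation, config$translation),
    s = stats::runif(1, config$scale[1L], config$scale[2L]),
    brightness = stats::runif(1, -config$brightness, config$brightness),
    contrast = 1 + stats::runif(1, -config$contrast, config$contrast),
    saturation = 1 + stats::runif(1, -config$saturation, config$saturation)))
}

apply_augment <- function(img, par) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  affine_needed <- par$angle != 0 || par$tx != 0 || par$ty != 0 || par$s != 1
  if (affine_needed) {
    # forward map in EBImage row-vector convention: p' = p A^T + b
    a11 <- par$s * cos(par$angle); a12 <- -par$s * sin(par$angle)
    a21 <- par$s * sin(par$angle); a22 <- par$s * cos(par$angle)
    cx <- w / 2; cy <- h / 2
    bx <- cx + par$tx * w - (a11 * cx + a12 * cy)
    by <- cy + par$ty * h - (a21 * cx + a22 * cy)
    m <- rbind(c(a11, a21), c(a12, a22), c(bx, by))
    x <- EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
    y <- EBImage::affine(x, m, filter = "bilinear", bg.col = "black")
    img <- aperm(as.array(EBImage::imageData(y)), c(2L, 1L, 3L))
  }
  gray <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  for (ch in 1:3) {
    v <- gray + par$saturation * (img[, , ch] - gray)   # saturation
    v <- (v - 0.5) * par$contrast + 0.5                 # contrast
    img[, , ch] <- clamp(v + par$brightness, 0, 1)      # brightness
  }
  img
}

#' Augment a clip with identical per-frame transforms
#'
#' Draws a single affine + colour parameter vector from `(config, seed)` and
#' applies it to every image of the clip; the output is bit-reproducible for
#' a fixed `(clip, config, seed)`.
#'
#' @param images list of same-shaped H x W x 3 arrays in `[0, 1]`.
#' @param config an [augment_config()].
#' @param seed integer seed for the parameter draw.
#' @return List of transformed arrays.
#' @export
augment_clip <- function(images, config, seed) {
  stopifnot(inherits(config, "augment_config"), length(images) >= 1L)
  par <- draw_augment_params(config, seed)
  lapply(images, apply_augment, par = par)
}
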