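#' Create a bounding box
#'
#' Boxes use 0-based, half-open pixel coordinates: the box covers columns
#' `[x_min, x_max)` and rows `[y_min, y_max)`, so the width is exactly
#' `x_max - x_min` pixels. This is the convention of image arrays and makes
#' areas and intersections integer-exact.
#'
#' @param x_min,y_min,x_max,y_max integer pixel coordinates, `x_min < x_max`,
#'   `y_min < y_max`.
#' @return An object of class `bounding_box`: a named integer vector.
#' @examples
#' b <- bounding_box(10, 30, 20, 50)
#' box_area(b) # 10 * 20 = 200
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.integer(x_min), y_min = as.integer(y_min),
         x_max = as.integer(x_max), y_max = as.integer(y_max))
  if (anyNA(b)) stopf("bounding box coordinates must be integers")
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"]) {
    stopf("degenerate bounding box: [%d,%d) x [%d,%d)",
          b["x_min"], b["x_max"], b["y_min"], b["y_max"])
  }
  if (any(b[c("x_min", "y_min")] < 0L)) stopf("bounding box coordinates must be >= 0")
  structure(b, class = "bounding_box")
}

#' @rdname bounding_box
#' @param box a `bounding_box`.
#' @export
box_area <- function(box) {
  unname((box[["x_max"]] - box[["x_min"]]) * (box[["y_max"]] - box[["y_min"]]))
}

#' Clamp a box to image bounds
#'
#' @param box a `bounding_box`.
#' @param width,height image dimensions in pixels.
#' @return The clamped `bounding_box`; errors if the box degenerates.
#' @export
box_clamp <- function(box, width, height) {
  bounding_box(max(0L, box[["x_min"]]), max(0L, box[["y_min"]]),
               min(as.integer(width), box[["x_max"]]),
               min(as.integer(height), box[["y_max"]]))
}

#' Minimal axis-aligned rectangle enclosing several boxes
#'
#' @param boxes list of `bounding_box` objects (non-empty).
#' @return A `bounding_box`.
#' @export
box_union <- function(boxes) {
  if (length(boxes) == 0L) stopf("box_union() needs at least one box")
  m <- do.call(rbind, lapply(boxes, unclass))
  bounding_box(min(m[, "x_min"]), min(m[, "y_min"]),
               max(m[, "x_max"]), max(m[, "y_max"]))
}

#' Intersection over union of two boxes
#'
#' Areas are half-open pixel counts, so `iou()` agrees exactly with counting
#' pixels in the rasterised intersection and union.
#'
#' @param a,b `bounding_box` objects.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ix <- max(0L, min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]]))
  iy <- max(0L, min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]]))
  inter <- as.double(ix) * as.double(iy)
  uni <- as.double(box_area(a)) + as.double(box_area(b)) - inter
  inter / uni
}

# "x_min:y_min:x_max:y_max;..." <-> list of boxes; "" is the empty list.
format_boxes <- function(boxes) {
  if (length(boxes) == 0L) return("")
  paste(vapply(boxes, function(b) paste(unclass(b), collapse = ":"), ""),
        collapse = ";")
}

parse_boxes <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  lapply(parts, function(p) {
    v <- suppressWarnings(as.integer(strsplit(p, ":", fixed = TRUE)[[1L]]))
    if (length(v) != 4L || anyNA(v)) stopf("malformed box string '%s'", p)
    bounding_box(v[1L], v[2L], v[3L], v[4L])
  })
}
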