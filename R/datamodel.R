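MANIFEST_COLUMNS <- c("patient_id", "lesion_id", "sequence_id", "frame_index",
                      "image_path", "modality", "high_quality", "frozen",
                      "boxes", "label")
MODALITIES <- c("NBI", "NBI_NEAR_FOCUS", "WL")

#' Construct a frame manifest
#'
#' A manifest holds one row per annotated video frame: its patient, lesion and
#' sequence identity, position in the video, image file, imaging modality,
#' quality and frozen flags, zero or more polyp bounding boxes (encoded
#' `"x_min:y_min:x_max:y_max"` and separated by `";"` for multi-box frames)
#' and the lesion-level histology label (0 = non-adenoma, 1 = adenoma).
#'
#' @param df data.frame with the columns listed above.
#' @param consecutive_frames logical; `TRUE` when frames within a sequence are
#'   consecutive video frames (internal-style data), `FALSE` for datasets
#'   sampled at intervals.
#' @param frame_rate optional frames/second, metadata only.
#' @param check_images verify that every `image_path` exists.
#' @return A validated `polyp_manifest` (a data.frame).
#' @export
manifest <- function(df, consecutive_frames = TRUE, frame_rate = NA_real_,
                     check_images = TRUE) {
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols)) {
    stopf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[MANIFEST_COLUMNS]
  df$patient_id <- as.character(df$patient_id)
  df$lesion_id <- as.character(df$lesion_id)
  df$sequence_id <- as.character(df$sequence_id)
  df$frame_index <- as.integer(df$frame_index)
  df$image_path <- as.character(df$image_path)
  df$modality <- as.character(df$modality)
  df$high_quality <- as.logical(df$high_quality)
  df$frozen <- as.logical(df$frozen)
  df$boxes <- as.character(df$boxes)
  df$boxes[is.na(df$boxes)] <- ""
  df$label <- as.integer(df$label)
  out <- structure(df,
                   class = c("polyp_manifest", "data.frame"),
                   consecutive_frames = isTRUE(consecutive_frames),
                   frame_rate = as.numeric(frame_rate))
  validate_manifest(out, check_images = check_images)
  out
}

#' Validate manifest invariants
#'
#' Checks column presence and types, per-row field validity (frame_index >= 0,
#' known modality, parseable boxes, binary label), one histology label and one
#' patient per lesion, strictly increasing frame indices within each
#' (lesion, sequence) run, and (optionally) that every image file exists.
#' Violations raise an error naming the offending row or lesion; nothing is
#' silently repaired.
#'
#' @param m a `polyp_manifest`.
#' @param check_images verify image paths on disk.
#' @return `m`, invisibly.
#' @export
validate_manifest <- function(m, check_images = TRUE) {
  df <- as.data.frame(m)
  if (nrow(df) == 0L) return(invisible(m))
  bad <- which(is.na(df$frame_index) | df$frame_index < 0L)
  if (length(bad)) stopf("row %d: frame_index must be a non-negative integer", bad[1L])
  bad <- which(!(df$modality %in% MODALITIES))
  if (length(bad)) stopf("row %d: unknown modality '%s'", bad[1L], df$modality[bad[1L]])
  bad <- which(is.na(df$high_quality) | is.na(df$frozen))
  if (length(bad)) stopf("row %d: high_quality/frozen must be true or false", bad[1L])
  bad <- which(!(df$label %in% c(0L, 1L)))
  if (length(bad)) stopf("row %d: label must be 0 (non-adenoma) or 1 (adenoma)", bad[1L])
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_boxes(df$boxes[i]),
             error = function(e) stopf("row %d: %s", i, conditionMessage(e)))
  }
  by_lesion <- split(df, df$lesion_id)
  for (lid in names(by_lesion)) {
    g <- by_lesion[[lid]]
    if (length(unique(g$label)) != 1L) {
      stopf("lesion '%s' carries conflicting labels (%s)", lid,
            paste(sort(unique(g$label)), collapse = ", "))
    }
    if (length(unique(g$patient_id)) != 1L) {
      stopf("lesion '%s' is assigned to more than one patient", lid)
    }
    for (sid in unique(g$sequence_id)) {
      idx <- g$frame_index[g$sequence_id == sid]
      if (any(diff(sort(idx)) == 0L)) {
        stopf("lesion '%s', sequence '%s': duplicated frame_index", lid, sid)
      }
    }
  }
  if (check_images) {
    missing <- !file.exists(df$image_path)
    if (any(missing)) {
      stopf("row %d: image_path '%s' does not exist",
            which(missing)[1L], df$image_path[which(missing)[1L]])
    }
  }
  invisible(m)
}

#' Read a manifest CSV
#'
#' The file is a plain CSV with the ten manifest columns; dataset-level flags
#' are carried in leading comment lines of the form
#' `#consecutive_frames=true` and `#frame_rate=23`.
#'
#' @param path CSV file path.
#' @param check_images verify image paths (paths are resolved relative to the
#'   manifest's directory when not absolute).
#' @return A validated `polyp_manifest`.
#' @export
read_manifest <- function(path, check_images = TRUE) {
  if (!file.exists(path)) stopf("manifest file '%s' does not exist", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  consecutive <- TRUE
  frame_rate <- NA_real_
  for (ln in meta) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      if (kv[1L] == "consecutive_frames") consecutive <- identical(kv[2L], "true")
      if (kv[1L] == "frame_rate" && nzchar(kv[2L])) frame_rate <- as.numeric(kv[2L])
    }
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                                     collapse = "\n"),
                        colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols)) {
    stopf("manifest '%s' is missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df)) {
    df$high_quality <- df$high_quality == "true"
    df$frozen <- df$frozen == "true"
  } else {
    df$high_quality <- logical(0)
    df$frozen <- logical(0)
  }
  # paths stay verbatim so write o read is the identity; relative paths are
  # resolved against the manifest's directory for the existence check only
  m <- manifest(df, consecutive_frames = consecutive, frame_rate = frame_rate,
                check_images = FALSE)
  if (check_images && nrow(df)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$image_path)
    resolved <- df$image_path
    resolved[rel] <- file.path(dirname(path), df$image_path[rel])
    missing <- !file.exists(resolved)
    if (any(missing)) {
      stopf("row %d: image_path '%s' does not exist",
            which(missing)[1L], df$image_path[which(missing)[1L]])
    }
  }
  m
}

#' Write a manifest CSV
#'
#' Output is deterministic: fixed column order, rows sorted by
#' (patient_id, lesion_id, frame_index), booleans serialised as
#' `true`/`false`, flags in leading comment lines. `read_manifest()` composed
#' with `write_manifest()` is the identity on valid manifests.
#'
#' @param m a `polyp_manifest`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  validate_manifest(m, check_images = FALSE)
  df <- as.data.frame(m)
  if (nrow(df)) {
    df <- df[order(df$patient_id, df$lesion_id, df$frame_index), MANIFEST_COLUMNS]
  }
  fmt_bool <- function(x) ifelse(x, "true", "false")
  fr <- attr(m, "frame_rate")
  hdr <- c(sprintf("#consecutive_frames=%s", fmt_bool(attr(m, "consecutive_frames"))),
           sprintf("#frame_rate=%s", if (is.na(fr)) "" else format(fr)))
  body <- paste(MANIFEST_COLUMNS, collapse = ",")
  if (nrow(df)) {
    rows <- apply(cbind(df$patient_id, df$lesion_id, df$sequence_id,
                        df$frame_index, df$image_path, df$modality,
                        fmt_bool(df$high_quality), fmt_bool(df$frozen),
                        df$boxes, df$label),
                  1L, paste, collapse = ",")
    body <- c(body, rows)
  }
  con <- file(path, "wb") # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Group manifest frames by lesion
#'
#' Partitions the manifest into per-lesion data.frames ordered by
#' `frame_index`; every row appears in exactly one group.
#'
#' @param m a `polyp_manifest`.
#' @return Named list of data.frames, one per `lesion_id`.
#' @export
group_by_lesion <- function(m) {
  df <- as.data.frame(m)
  groups <- split(df, df$lesion_id)
  lapply(groups, function(g) g[order(g$frame_index), , drop = FALSE])
}

#' @export
print.polyp_manifest <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<polyp_manifest> %d frames, %d lesions, %d patients\n",
              nrow(df), length(unique(df$lesion_id)),
              length(unique(df$patient_id))))
  if (nrow(df)) {
    lab <- tapply(df$label, df$lesion_id, function(v) v[1L])
    cat(sprintf("  adenoma lesions: %d / %d; consecutive_frames=%s\n",
                sum(lab == 1L), length(lab), attr(x, "consecutive_frames")))
  }
  invisible(x)
}
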