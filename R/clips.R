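#' Clip extraction configuration
#'
#' A clip is an ordered window of `k` frames from one lesion, the unit of
#' temporal classification. Defaults mirror the consecutive-video protocol:
#' windows of 15 frames at stride 1, frozen frames excluded, a box required
#' on every frame, and a window kept only when at least half of its frames
#' are labelled high-quality. For datasets of non-consecutive sampled frames
#' use `sampled_clip_config()`, which drops the consecutiveness requirement
#' and disables quality filtering.
#'
#' @param k clip length in frames.
#' @param stride window stride over eligible runs.
#' @param quality_threshold minimum fraction of high-quality frames in a kept
#'   window (inclusive `>=` comparison); `0` disables quality filtering.
#' @param exclude_frozen drop frozen frames (they break run continuity).
#' @param require_consecutive require successive frame indices to differ by 1
#'   within a clip.
#' @param require_box_every_frame frames without a box are ineligible.
#' @param allowed_modalities modalities admitted to clips; white-light frames
#'   are excluded by default.
#' @return A `clip_config` list.
#' @export
clip_config <- function(k = 15L, stride = 1L, quality_threshold = 0.5,
                        exclude_frozen = TRUE, require_consecutive = TRUE,
                        require_box_every_frame = TRUE,
                        allowed_modalities = c("NBI", "NBI_NEAR_FOCUS")) {
  if (k < 1L) stopf("k must be >= 1")
  if (stride < 1L) stopf("stride must be >= 1")
  if (quality_threshold < 0 || quality_threshold > 1) {
    stopf("quality_threshold must lie in [0, 1]")
  }
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 quality_threshold = quality_threshold,
                 exclude_frozen = isTRUE(exclude_frozen),
                 require_consecutive = isTRUE(require_consecutive),
                 require_box_every_frame = isTRUE(require_box_every_frame),
                 allowed_modalities = allowed_modalities),
            class = "clip_config")
}

#' @rdname clip_config
#' @param ... overrides passed on to [clip_config()].
#' @export
sampled_clip_config <- function(k = 15L, ...) {
  clip_config(k = k, require_consecutive = FALSE, quality_threshold = 0,
              exclude_frozen = FALSE, ...)
}

#' Frame eligibility for clip membership
#'
#' @param frame one manifest row (data.frame of one row or list).
#' @param config a [clip_config()].
#' @return List with `eligible` (logical) and `reason` (`"ok"`, `"no_box"`,
#'   `"frozen"` or `"wrong_modality"`).
#' @export
frame_eligibility <- function(frame, config) {
  if (!(frame$modality %in% config$allowed_modalities)) {
    return(list(eligible = FALSE, reason = "wrong_modality"))
  }
  if (config$require_box_every_frame && !nzchar(frame$boxes %||% "")) {
    return(list(eligible = FALSE, reason = "no_box"))
  }
  if (config$exclude_frozen && isTRUE(frame$frozen)) {
    return(list(eligible = FALSE, reason = "frozen"))
  }
  list(eligible = TRUE, reason = "ok")
}

eligibility_vector <- function(frames, config) {
  vapply(seq_len(nrow(frames)), function(i) {
    frame_eligibility(frames[i, , drop = FALSE], config)$eligible
  }, logical(1L))
}

#' Extract clips from one lesion's frame sequence
#'
#' Windows of `k` frames are taken at the configured stride over maximal runs
#' of eligible frames (a frame is eligible when it has a box, is not frozen,
#' and is of an admitted modality; a gap in `frame_index` breaks a run when
#' consecutiveness is required). A window survives only if the fraction of
#' its frames labelled high-quality is at least `quality_threshold`. For a
#' clean run of `n` eligible frames at stride 1 exactly `max(0, n - k + 1)`
#' clips result: the last `k - 1` frames start no clip.
#'
#' @param frames data.frame of manifest rows for a single lesion, ordered by
#'   `frame_index`.
#' @param config a [clip_config()].
#' @return List of `clip` objects; each has `lesion_id`, `frames` (the k-row
#'   data.frame), `frame_index` (integer vector) and `consecutive`. Lesions
#'   with fewer than `k` eligible frames yield an empty list.
#' @export
extract_clips <- function(frames, config) {
  stopifnot(inherits(config, "clip_config"))
  if (nrow(frames) == 0L) return(list())
  if (length(unique(frames$lesion_id)) != 1L) {
    stopf("extract_clips() expects frames from a single lesion")
  }
  frames <- frames[order(frames$frame_index), , drop = FALSE]
  elig <- eligibility_vector(frames, config)
  # split eligible frames into maximal runs; index gaps break runs when
  # consecutiveness is required
  run_id <- integer(nrow(frames))
  current <- 0L
  prev_idx <- NA_integer_
  for (i in seq_len(nrow(frames))) {
    if (!elig[i]) {
      run_id[i] <- NA_integer_
      prev_idx <- NA_integer_
      next
    }
    new_run <- is.na(prev_idx) ||
      (config$require_consecutive && frames$frame_index[i] != prev_idx + 1L)
    if (new_run) current <- current + 1L
    run_id[i] <- current
    prev_idx <- frames$frame_index[i]
  }
  clips <- list()
  k <- config$k
  for (r in unique(run_id[!is.na(run_id)])) {
    rows <- which(!is.na(run_id) & run_id == r)
    n <- length(rows)
    if (n < k) next
    for (start in seq(1L, n - k + 1L, by = config$stride)) {
      idx <- rows[start:(start + k - 1L)]
      if (config$quality_threshold > 0 &&
          mean(frames$high_quality[idx]) < config$quality_threshold) next
      clips[[length(clips) + 1L]] <-
        structure(list(lesion_id = frames$lesion_id[1L],
                       frames = frames[idx, , drop = FALSE],
                       frame_index = frames$frame_index[idx],
                       consecutive = config$require_consecutive),
                  class = "clip")
    }
  }
  clips
}

#' Extract clips for every lesion of a manifest
#'
#' @param m a `polyp_manifest`.
#' @param config a [clip_config()].
#' @return Flat list of `clip` objects across lesions.
#' @export
extract_clips_manifest <- function(m, config) {
  groups <- group_by_lesion(m)
  do.call(c, lapply(groups, extract_clips, config = config))
}

#' @export
print.clip <- function(x, ...) {
  cat(sprintf("<clip> lesion %s, %d frames [%d..%d]%s\n", x$lesion_id,
              length(x$frame_index), min(x$frame_index), max(x$frame_index),
              if (x$consecutive) ", consecutive" else ""))
  invisible(x)
}
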