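frame_key <- function(lesion_id, frame_index) paste(lesion_id, frame_index, sep = "#")

#' Build a preprocessed frame dataset from a manifest
#'
#' Extracts clips with the given configuration and preprocesses every unique
#' frame that appears in at least one clip (the frame classifier trains on
#' exactly the frames the clip model sees). The first annotated box of each
#' frame is used for cropping.
#'
#' @param m a `polyp_manifest`.
#' @param config a [clip_config()].
#' @param out_size preprocessing output side in pixels.
#' @return List with `x` (list of arrays), `y` (0/1), `lesion_id`,
#'   `patient_id`, `key` (lesion#frame identifiers) and `clips` (the clip
#'   list the frames came from).
#' @export
build_frame_dataset <- function(m, config = clip_config(), out_size = 64L) {
  clips <- extract_clips_manifest(m, config)
  if (!length(clips)) {
    return(list(x = list(), y = integer(0), lesion_id = character(0),
                patient_id = character(0), key = character(0), clips = clips))
  }
  frames <- unique(do.call(rbind, lapply(clips, `[[`, "frames")))
  keys <- frame_key(frames$lesion_id, frames$frame_index)
  keep <- !duplicated(keys)
  frames <- frames[keep, , drop = FALSE]
  keys <- keys[keep]
  x <- lapply(seq_len(nrow(frames)), function(i) {
    preprocess_frame(frames$image_path[i], parse_boxes(frames$boxes[i])[[1L]],
                     out_size = out_size)
  })
  list(x = x, y = frames$label, lesion_id = frames$lesion_id,
       patient_id = frames$patient_id, key = keys, clips = clips)
}

#' Assemble per-clip feature matrices from a frame dataset
#'
#' Encodes every unique frame once with the (frozen) encoder and gathers the
#' `k x feature_dim` matrix of each clip.
#'
#' @param clips list of `clip` objects.
#' @param frame_ds a [build_frame_dataset()] result covering the clips.
#' @param model a trained `frame_net` (its encoder is used).
#' @return List with `features` (list of matrices), `y`, `lesion_id`.
#' @export
build_clip_features <- function(clips, frame_ds, model) {
  feats <- predict(model, frame_ds$x, type = "feature")
  rownames(feats) <- frame_ds$key
  features <- lapply(clips, function(cl) {
    feats[frame_key(cl$frames$lesion_id, cl$frames$frame_index), , drop = FALSE]
  })
  list(features = features,
       y = vapply(clips, function(cl) cl$frames$label[1L], integer(1L)),
       lesion_id = vapply(clips, `[[`, "", "lesion_id"))
}
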