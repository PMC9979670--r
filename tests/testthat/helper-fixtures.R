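# Shared fixtures. Rendered datasets are cached per test run so several test
# files can reuse one image tree.

.fixture_cache <- new.env(parent = emptyenv())

# A mid-sized rendered dataset: 10 patients, 1-2 lesions each, short videos.
test_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    dir <- file.path(tempdir(), "polypclip-fixture-ds")
    cfg <- synth_config(n_patients = 10L, lesions_per_patient = c(1L, 2L),
                        frames_per_lesion = c(16L, 20L),
                        low_quality_rate = 0.05, frozen_segment_rate = 0.02,
                        seed = 123L)
    .fixture_cache$ds <- list(manifest = generate_dataset(cfg, dir), config = cfg)
  }
  .fixture_cache$ds
}

# In-memory manifest rows (no images on disk); check_images = FALSE users only.
fake_frames <- function(lesion_id, n, patient_id = sub("_l\\d+$", "", lesion_id),
                        label = 1L, frame_index = seq_len(n) - 1L,
                        high_quality = TRUE, frozen = FALSE, modality = "NBI",
                        boxes = "4:4:28:28") {
  n <- length(frame_index)
  data.frame(patient_id = rep_len(patient_id, n),
             lesion_id = rep_len(lesion_id, n),
             sequence_id = rep_len(paste0(lesion_id, "_s1"), n),
             frame_index = frame_index,
             image_path = sprintf("%s_f%03d.png", rep_len(lesion_id, n), frame_index),
             modality = rep_len(modality, n),
             high_quality = rep_len(high_quality, n),
             frozen = rep_len(frozen, n),
             boxes = rep_len(boxes, n), label = rep_len(label, n),
             stringsAsFactors = FALSE)
}

fake_manifest <- function(..., consecutive_frames = TRUE) {
  manifest(rbind(...), consecutive_frames = consecutive_frames,
           check_images = FALSE)
}

# Deterministic image-statistic classifier: separates the two synthetic
# textures by high-frequency energy, with the decision point calibrated on a
# labelled dataset. Cheap stand-in where a trained network is not the point.
energy_score <- function(img) {
  g <- img[, , 2L]
  mean(diff(g)^2) + mean(t(diff(t(g)))^2)
}

make_energy_classifier <- function(x, y) {
  e <- vapply(x, energy_score, numeric(1L))
  thr <- (mean(e[y == 1L]) + mean(e[y == 0L])) / 2
  scale <- 4 / stats::sd(e)
  function(images) {
    stats::plogis(scale * (vapply(images, energy_score, numeric(1L)) - thr))
  }
}

test_energy_classifier <- function() {
  if (is.null(.fixture_cache$clf)) {
    ds <- test_dataset()
    fd <- build_frame_dataset(ds$manifest, clip_config(k = 15L), out_size = 32L)
    .fixture_cache$clf <- list(fun = make_energy_classifier(fd$x, fd$y),
                               frame_ds = fd, out_size = 32L)
  }
  .fixture_cache$clf
}
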