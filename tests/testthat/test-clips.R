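# brute-force clip oracle: test every start row directly against the window
# rules, independent of the run-splitting implementation
oracle_starts <- function(frames, config) {
  frames <- frames[order(frames$frame_index), ]
  elig <- vapply(seq_len(nrow(frames)), function(i) {
    frame_eligibility(frames[i, , drop = FALSE], config)$eligible
  }, logical(1L))
  k <- config$k
  keep <- c()
  for (s in seq_len(max(0L, nrow(frames) - k + 1L))) {
    idx <- s:(s + k - 1L)
    if (!all(elig[idx])) next
    if (config$require_consecutive &&
        any(diff(frames$frame_index[idx]) != 1L)) next
    if (config$quality_threshold > 0 &&
        mean(frames$high_quality[idx]) < config$quality_threshold) next
    keep <- c(keep, frames$frame_index[s])
  }
  keep
}

test_that("a 20-frame clean run with k=15 yields 6 clips; the last 14 frames start none", {
  frames <- fake_frames("p001_l1", 20)
  clips <- extract_clips(frames, clip_config(k = 15L))
  expect_length(clips, 6L)
  expect_equal(vapply(clips, function(cl) cl$frame_index[1L], integer(1L)), 0:5)
  # no clip starts within the last k-1 = 14 frames
  expect_true(all(vapply(clips, function(cl) cl$frame_index[1L], integer(1L)) < 6L))
})

test_that("the >=50% quality rule is inclusive and counts window fractions", {
  frames <- fake_frames("p001_l1", 15, high_quality = rep(c(FALSE, TRUE), c(8, 7)))
  expect_length(extract_clips(frames, clip_config(k = 15L)), 0L) # 7/15 < 0.5
  frames2 <- fake_frames("p001_l1", 16, high_quality = rep(c(FALSE, TRUE), each = 8))
  clips2 <- extract_clips(frames2, clip_config(k = 16L))
  expect_length(clips2, 1L) # 8/16 = 0.5 kept: comparison is inclusive
})

test_that("frame eligibility returns machine-readable reasons", {
  cfg <- clip_config()
  f <- fake_frames("p001_l1", 1)
  expect_identical(frame_eligibility(f, cfg),
                   list(eligible = TRUE, reason = "ok"))
  expect_identical(frame_eligibility(fake_frames("p1_l1", 1, frozen = TRUE), cfg)$reason,
                   "frozen")
  expect_identical(frame_eligibility(fake_frames("p1_l1", 1, boxes = ""), cfg)$reason,
                   "no_box")
  expect_identical(frame_eligibility(fake_frames("p1_l1", 1, modality = "WL"), cfg)$reason,
                   "wrong_modality")
})

test_that("extraction matches the brute-force window oracle on random eligibility patterns", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    frames <- fake_frames("p001_l1", n,
                          high_quality = runif(n) > 0.3,
                          frozen = runif(n) < 0.15,
                          boxes = ifelse(runif(n) < 0.1, "", "4:4:28:28"))
    # occasionally knock out frame indices to create gaps
    if (runif(1) < 0.5) {
      drop <- sample(n, size = sample(0:3, 1))
      if (length(drop)) frames <- frames[-drop, ]
    }
    cfg <- clip_config(k = sample(3:8, 1),
                       quality_threshold = sample(c(0, 0.5, 0.8), 1),
                       require_consecutive = sample(c(TRUE, FALSE), 1))
    clips <- extract_clips(frames, cfg)
    got <- vapply(clips, function(cl) cl$frame_index[1L], integer(1L))
    expect_equal(as.integer(got), as.integer(oracle_starts(frames, cfg)))
  }
})

test_that("the clip-count law holds for clean runs at any stride", {
  for (n in c(10L, 23L)) for (k in c(3L, 7L)) for (stride in 1:3) {
    frames <- fake_frames("p001_l1", n)
    clips <- extract_clips(frames, clip_config(k = k, stride = stride))
    expect_length(clips, max(0L, (n - k) %/% stride + 1L))
  }
  # fewer than k eligible frames: lesion excluded entirely
  expect_length(extract_clips(fake_frames("p001_l1", 4), clip_config(k = 15L)), 0L)
})

test_that("clips never span frozen frames or index gaps", {
  frames <- fake_frames("p001_l1", 12, frozen = seq_len(12) == 6L)
  clips <- extract_clips(frames, clip_config(k = 4L))
  for (cl in clips) {
    expect_false(any(cl$frames$frozen))
    expect_true(all(diff(cl$frame_index) == 1L))
  }
  # sampled-dataset preset tolerates gaps and ignores quality
  sampled <- fake_frames("p001_l1", 10, frame_index = c(0:3, 10:15),
                         high_quality = FALSE)
  clips_s <- extract_clips(sampled, sampled_clip_config(k = 5L))
  expect_length(clips_s, 6L)
})

naive_bilinear <- function(img, oh, ow) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  out <- array(0, c(oh, ow, dim(img)[3L]))
  for (ch in seq_len(dim(img)[3L])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sy <- min(max((i - 0.5) * h / oh - 0.5, 0), h - 1)
    sx <- min(max((j - 0.5) * w / ow - 0.5, 0), w - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
    out[i, j, ch] <- (1 - fy) * (1 - fx) * img[y0 + 1, x0 + 1, ch] +
      (1 - fy) * fx * img[y0 + 1, x1 + 1, ch] +
      fy * (1 - fx) * img[y1 + 1, x0 + 1, ch] +
      fy * fx * img[y1 + 1, x1 + 1, ch]
  }
  out
}

test_that("preprocessing crops, resizes and normalises as specified", {
  set.seed(5)
  img <- array(runif(40 * 32 * 3), c(40, 32, 3))
  # full-image box: a pure resize
  full <- preprocess_frame(img, bounding_box(0, 0, 32, 40), out_size = 16L,
                           normalize = FALSE)
  expect_equal(full, naive_bilinear(img, 16L, 16L), tolerance = 1e-12)
  # constant crop stays constant, and the normalisation is exact
  cimg <- array(0.5, c(24, 24, 3))
  out <- preprocess_frame(cimg, bounding_box(2, 2, 20, 20), out_size = 8L)
  for (ch in 1:3) {
    expect_equal(unique(round(as.vector(out[, , ch]), 10)),
                 round((0.5 - polypclip:::IMAGENET_MEAN[ch]) /
                         polypclip:::IMAGENET_SD[ch], 10))
  }
  # crop-then-resize agrees with the independent double-loop resampler
  for (rep in 1:3) {
    b <- bounding_box(sample(0:5, 1), sample(0:5, 1),
                      sample(20:30, 1), sample(25:38, 1))
    got <- preprocess_frame(img, b, out_size = 12L, normalize = FALSE)
    crop <- img[(b[["y_min"]] + 1):b[["y_max"]], (b[["x_min"]] + 1):b[["x_max"]], ,
                drop = FALSE]
    expect_equal(got, naive_bilinear(crop, 12L, 12L), tolerance = 1e-12)
  }
  expect_error(preprocess_frame(img, bounding_box(50, 50, 60, 60), out_size = 8L),
               "degenerate")
})

test_that("augmentation applies one identical transform to every frame of a clip", {
  set.seed(6)
  imgs <- replicate(3, array(runif(24 * 24 * 3), c(24, 24, 3)), simplify = FALSE)
  id_cfg <- augment_config(rotation = 0, translation = 0, scale = c(1, 1),
                           brightness = 0, contrast = 0, saturation = 0)
  expect_identical(augment_clip(imgs, id_cfg, seed = 3L), imgs)

  cfg <- augment_config()
  same <- augment_clip(list(imgs[[1L]], imgs[[1L]]), cfg, seed = 4L)
  expect_identical(same[[1L]], same[[2L]]) # identical frames stay identical
  a <- augment_clip(imgs, cfg, seed = 9L)
  b <- augment_clip(imgs, cfg, seed = 9L)
  expect_identical(a, b) # seed-deterministic
  expect_false(identical(a, augment_clip(imgs, cfg, seed = 10L)))
})
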