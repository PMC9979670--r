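# O(n^2) AUC oracle: fraction of (positive, negative) pairs correctly ranked,
# ties counted half
auc_pairs <- function(probs, labels) {
  pos <- probs[labels == 1L]; neg <- probs[labels == 0L]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("frame metrics match direct counting and the pairwise AUC oracle", {
  # perfect predictions
  fm <- frame_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(fm$accuracy, 1); expect_equal(fm$sensitivity, 1)
  expect_equal(fm$specificity, 1); expect_equal(fm$auc, 1)

  # all probabilities at the boundary: everything predicted 0
  fm2 <- frame_metrics(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(fm2$accuracy, 0.5)
  expect_equal(fm2$sensitivity, 0)
  expect_equal(fm2$specificity, 1)

  set.seed(11)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.6)
    if (length(unique(labels)) < 2) next
    probs <- round(plogis(rnorm(n, mean = labels)), 2) # rounded: forces ties
    fm <- frame_metrics(probs, labels)
    pred <- as.integer(probs > 0.5)
    expect_equal(fm$accuracy, mean(pred == labels))
    expect_equal(fm$sensitivity, sum(pred == 1 & labels == 1) / sum(labels == 1))
    expect_equal(fm$specificity, sum(pred == 0 & labels == 0) / sum(labels == 0))
    expect_equal(fm$auc, auc_pairs(probs, labels), tolerance = 1e-12)
  }
  # single-class labels: AUC undefined, reported as NA
  expect_true(is.na(frame_metrics(runif(5), rep(1, 5))$auc))
})

test_that("rank-statistic AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- rbinom(150, 1, 0.5)
  probs <- round(plogis(rnorm(150, labels)), 2)
  ours <- frame_metrics(probs, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("polyp accuracy averages per-lesion fractions unweighted with a normal CI", {
  preds <- data.frame(lesion_id = rep(c("A", "B"), c(4, 2)),
                      y = c(1, 1, 1, 0, 1, 0),
                      label = c(1, 1, 1, 1, 1, 1))
  pa <- polyp_accuracy(preds)
  expect_equal(unname(pa$per_lesion), c(0.75, 0.5))
  expect_equal(pa$mean, 0.625)

  # all lesions perfect: degenerate CI
  perfect <- data.frame(lesion_id = rep(c("A", "B"), each = 3),
                        y = 1, label = 1)
  pp <- polyp_accuracy(perfect)
  expect_equal(c(pp$mean, pp$ci_low, pp$ci_high), c(1, 1, 1))

  # 50 simulated lesions against direct recomputation, plus order invariance
  set.seed(13)
  sim <- data.frame(lesion_id = rep(sprintf("L%02d", 1:50), each = 8),
                    probability = runif(400), label = rep(rbinom(50, 1, 0.5), each = 8))
  pa1 <- polyp_accuracy(sim)
  direct <- tapply(as.integer((sim$probability > 0.5) == sim$label),
                   sim$lesion_id, mean)
  expect_equal(pa1$mean, mean(direct))
  expect_equal(pa1$ci_low, mean(direct) - 1.96 * sd(direct) / sqrt(50))
  pa2 <- polyp_accuracy(sim[sample(nrow(sim)), ])
  expect_equal(pa1$per_lesion, pa2$per_lesion)
})

test_that("NCC satisfies self-similarity, disjoint support, scale invariance and the naive oracle", {
  set.seed(14)
  a <- array(runif(32 * 32), c(32, 32))
  expect_equal(ncc(a, a), 1)

  ind1 <- matrix(0, 8, 8); ind1[1:4, ] <- 1
  ind2 <- matrix(0, 8, 8); ind2[5:8, ] <- 1
  expect_equal(ncc(ind1, ind2), 0)

  b <- array(runif(32 * 32), c(32, 32))
  expect_equal(ncc(3.7 * a, b), ncc(a, b), tolerance = 1e-12)
  expect_equal(ncc(a, b), ncc(b, a))
  expect_lte(ncc(a, b), 1) # Cauchy-Schwarz

  naive_ncc <- function(x, y) {
    num <- 0; ex <- 0; ey <- 0
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
      num <- num + x[i, j] * y[i, j]
      ex <- ex + x[i, j]^2; ey <- ey + y[i, j]^2
    }
    num / sqrt(ex * ey)
  }
  for (rep in 1:5) {
    x <- matrix(runif(32 * 32), 32); y <- matrix(runif(32 * 32), 32)
    expect_equal(ncc(x, y), naive_ncc(x, y), tolerance = 1e-10)
  }
  expect_error(ncc(a, matrix(0, 32, 32)), "all-zero")
  expect_error(ncc(a, matrix(1, 8, 8)), "identical dimensions")
})

test_that("clip similarity is the mean over consecutive pairs", {
  set.seed(15)
  imgs <- replicate(5, matrix(runif(64), 8), simplify = FALSE)
  expect_equal(clip_similarity(imgs),
               mean(c(ncc(imgs[[1]], imgs[[2]]), ncc(imgs[[2]], imgs[[3]]),
                      ncc(imgs[[3]], imgs[[4]]), ncc(imgs[[4]], imgs[[5]]))))
  expect_equal(clip_similarity(imgs[1:2]), ncc(imgs[[1]], imgs[[2]]))
  expect_equal(clip_similarity(list(imgs[[1]], imgs[[1]], imgs[[1]])), 1)
  expect_error(clip_similarity(imgs[1]), "at least 2")
})

test_that("similarity-performance analysis recovers null and alternative structure", {
  # independence: |r| small, not significant (fixed seed, n = 1000)
  set.seed(16)
  sim <- runif(1000)
  correct <- rbinom(1000, 1, 0.8)
  null_res <- similarity_performance_analysis(sim, correct)
  expect_lt(abs(null_res$pearson_r), 0.08)
  expect_gt(null_res$pearson_p, 0.05)

  # deterministic decrease: strongly negative and significant
  sim2 <- seq(0, 1, length.out = 200)
  correct2 <- as.integer(sim2 < 0.5)
  alt_res <- similarity_performance_analysis(sim2, correct2)
  expect_lt(alt_res$pearson_r, 0)
  expect_lt(alt_res$pearson_p, 0.05)
  expect_true(alt_res$significant)

  # textbook Pearson on a 10-point fixture
  s <- c(0.11, 0.25, 0.32, 0.41, 0.48, 0.55, 0.63, 0.74, 0.86, 0.95)
  y <- c(1, 1, 0, 1, 1, 0, 1, 0, 0, 0)
  res <- similarity_performance_analysis(s, y, n_bins = 2L)
  r_hand <- sum((s - mean(s)) * (y - mean(y))) /
    sqrt(sum((s - mean(s))^2) * sum((y - mean(y))^2))
  t_stat <- r_hand * sqrt(8 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_stat), df = 8)
  expect_equal(res$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(res$pearson_p, p_hand, tolerance = 1e-12)
  expect_equal(sum(res$bins$n), 10L)
})

test_that("IoU matches pixel rasterisation counting on random box pairs", {
  expect_equal(iou(bounding_box(2, 2, 10, 10), bounding_box(2, 2, 10, 10)), 1)
  expect_equal(iou(bounding_box(0, 0, 4, 4), bounding_box(10, 10, 14, 14)), 0)
  raster_iou <- function(a, b, n = 64L) {
    g1 <- matrix(FALSE, n, n); g2 <- matrix(FALSE, n, n)
    g1[(a[["y_min"]] + 1):a[["y_max"]], (a[["x_min"]] + 1):a[["x_max"]]] <- TRUE
    g2[(b[["y_min"]] + 1):b[["y_max"]], (b[["x_min"]] + 1):b[["x_max"]]] <- TRUE
    sum(g1 & g2) / sum(g1 | g2)
  }
  set.seed(17)
  for (rep in 1:50) {
    a <- bounding_box(sample(0:40, 1), sample(0:40, 1),
                      sample(41:64, 1), sample(41:64, 1))
    b <- bounding_box(sample(0:40, 1), sample(0:40, 1),
                      sample(41:64, 1), sample(41:64, 1))
    expect_equal(iou(a, b), raster_iou(a, b), tolerance = 1e-12)
    expect_equal(iou(a, b), iou(b, a))
  }
})

test_that("box perturbation hits the requested IoU and respects image bounds", {
  b <- bounding_box(30, 25, 70, 75)
  for (target in c(0.2, 0.5, 0.8, 0.95)) {
    pb <- perturb_box_to_iou(b, target, image_width = 128, image_height = 128,
                             seed = 21L)
    expect_lte(abs(iou(b, pb) - target), 0.01)
    expect_gte(pb[["x_min"]], 0L); expect_lte(pb[["x_max"]], 128L)
    expect_gte(pb[["y_min"]], 0L); expect_lte(pb[["y_max"]], 128L)
  }
  expect_error(perturb_box_to_iou(b, 1.0, image_width = 128, image_height = 128),
               "strictly inside")
  # determinism
  p1 <- perturb_box_to_iou(b, 0.5, image_width = 128, image_height = 128, seed = 8L)
  p2 <- perturb_box_to_iou(b, 0.5, image_width = 128, image_height = 128, seed = 8L)
  expect_identical(p1, p2)
})

test_that("the IoU robustness curve improves with box quality and is reproducible", {
  clf <- test_energy_classifier()
  ds <- test_dataset()
  df <- as.data.frame(ds$manifest)
  sub <- manifest(df[df$frame_index < 6L, ], check_images = FALSE)
  # the highest level stays below the lattice limit of the fixture's box
  # sizes: with integer pixel boxes of ~20 px, IoU values near 1 are spaced
  # too coarsely to hit arbitrarily
  levels <- c(0.2, 0.5, 0.85)
  curve <- iou_robustness_curve(clf$fun, sub, levels = levels, k = 3L,
                                out_size = clf$out_size, seed = 31L)
  frame_rows <- curve[curve$method == "frame", ]
  expect_equal(frame_rows$iou_level, levels)
  # monotone trend: accuracy increases with IoU
  expect_gt(cor(frame_rows$iou_level, frame_rows$accuracy, method = "spearman"), 0)
  # high-IoU limit approaches expert-box performance
  expert_probs <- clf$fun(lapply(seq_len(nrow(sub)), function(i) {
    preprocess_frame(sub$image_path[i], polypclip:::parse_boxes(sub$boxes[i])[[1L]],
                     out_size = clf$out_size)
  }))
  expert_acc <- frame_metrics(expert_probs, sub$label)$accuracy
  expect_lt(abs(frame_rows$accuracy[frame_rows$iou_level == 0.85] - expert_acc), 0.15)
  # bit-exact reproducibility
  curve2 <- iou_robustness_curve(clf$fun, sub, levels = levels, k = 3L,
                                 out_size = clf$out_size, seed = 31L)
  expect_identical(curve, curve2)
})
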