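test_that("encoders emit the contracted feature length deterministically", {
  enc <- init_encoder(encoder_spec("small", feature_dim = 64L), seed = 1L)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f1 <- encode_frame(x, enc)
  expect_length(f1, 64L)
  expect_identical(f1, encode_frame(x, enc))

  enc8 <- init_encoder(encoder_spec("small", feature_dim = 8L), seed = 1L)
  expect_length(encode_frame(array(0.5, c(64, 64, 3)), enc8), 8L)

  expect_error(encode_frame(array(0, c(32, 32, 3)), enc), "expects a 64 x 64")
  expect_error(encoder_spec("small", feature_dim = 63L), "even")
})

test_that("the reference encoder maps a 224x224x3 frame to 2048 features", {
  enc <- init_encoder(encoder_spec("reference"), seed = 2L)
  f <- encode_frame(array(runif(224 * 224 * 3), c(224, 224, 3)), enc)
  expect_length(f, 2048L)
  expect_true(all(is.finite(f)))
})

test_that("frame probabilities are softmax-normalised and batch-invariant", {
  set.seed(21)
  ds_x <- replicate(6, array(runif(64 * 64 * 3), c(64, 64, 3)), simplify = FALSE)
  net <- train_frame_classifier(ds_x, c(0, 1, 0, 1, 0, 1),
                                spec = encoder_spec("small", feature_dim = 16L),
                                control = train_spec(learning_rate = 0.01,
                                                     max_epochs = 1L, seed = 3L))
  # zeroed final layer: exact (0.5, 0.5)
  net0 <- net
  net0$head$W[] <- 0; net0$head$b[] <- 0
  expect_equal(predict(net0, ds_x[[1L]]), 0.5)
  # batch predictions equal one-at-a-time predictions
  batch <- predict(net, ds_x)
  single <- vapply(ds_x, function(img) predict(net, img), numeric(1L))
  expect_equal(batch, single, tolerance = 1e-12)
  expect_true(all(batch >= 0 & batch <= 1))
})

test_that("class weights are inverse-frequency, averaged to one", {
  w <- compute_class_weights(c(rep(1, 76), rep(0, 24)))
  expect_equal(mean(w), 1)
  expect_equal(w[2] / w[1], (1 / 0.76) / (1 / 0.24), tolerance = 1e-12)
  expect_equal(compute_class_weights(c(0, 0, 1, 1)), c(1, 1))
  expect_error(compute_class_weights(c(1, 1, 1)), "both classes")
  set.seed(22)
  for (rep in 1:20) {
    y <- rbinom(sample(10:200, 1), 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    w <- compute_class_weights(y)
    f0 <- mean(y == 0); f1 <- mean(y == 1)
    raw <- c(1 / f0, 1 / f1)
    expect_equal(w, raw / mean(raw), tolerance = 1e-12)
  }
  # proportionality law: doubling the majority class halves its weight ratio
  w1 <- compute_class_weights(c(rep(0, 10), rep(1, 10)))
  w2 <- compute_class_weights(c(rep(0, 10), rep(1, 20)))
  expect_equal((w2[2] / w2[1]) / (w1[2] / w1[1]), 0.5, tolerance = 1e-12)
})

test_that("frame-classifier training reduces the loss on a learnable fixture", {
  set.seed(23)
  # two blob patterns distinguishable by intensity statistics
  make_img <- function(label) {
    base <- array(runif(32 * 32 * 3, 0.3, 0.5), c(32, 32, 3))
    if (label == 1L) {
      stripes <- 0.4 * sin(outer(1:17, 1:17, "+"))
      for (ch in 1:3) base[8:24, 8:24, ch] <- base[8:24, 8:24, ch] + stripes
    }
    base
  }
  y <- rep(c(0L, 1L), each = 15)
  x <- lapply(y, make_img)
  net <- train_frame_classifier(x, y,
                                spec = encoder_spec("small", feature_dim = 16L,
                                                    input_size = 32L),
                                control = train_spec(learning_rate = 0.05,
                                                     max_epochs = 8L,
                                                     batch_size = 8L, seed = 4L))
  expect_lt(tail(net$history$loss, 1), net$history$loss[1L])
  expect_gt(tail(net$history$accuracy, 1), 0.8)
  # epoch subsampling clamps to the dataset size without error
  net2 <- train_frame_classifier(x, y,
                                 spec = encoder_spec("small", feature_dim = 16L,
                                                     input_size = 32L),
                                 control = train_spec(learning_rate = 0.05,
                                                      max_epochs = 1L,
                                                      epoch_subsample = 10000L,
                                                      seed = 4L))
  expect_equal(nrow(net2$history), 1L)
  # determinism: same seed, same training curve
  net3 <- train_frame_classifier(x, y,
                                 spec = encoder_spec("small", feature_dim = 16L,
                                                     input_size = 32L),
                                 control = train_spec(learning_rate = 0.05,
                                                      max_epochs = 8L,
                                                      batch_size = 8L, seed = 4L))
  expect_identical(net$history, net3$history)
})

test_that("the LSTM clip model is order sensitive and learns order-defined classes", {
  # class is encoded ONLY in temporal direction: rising vs falling ramps over
  # otherwise identical feature sets
  set.seed(24)
  k <- 6L; D <- 8L
  make_clip <- function(label) {
    v <- abs(rnorm(D))
    ramp <- seq(0.1, 1, length.out = k)
    if (label == 0L) ramp <- rev(ramp)
    outer(ramp, v) + matrix(rnorm(k * D, sd = 0.02), k, D)
  }
  y <- rep(c(0L, 1L), each = 60)
  feats <- lapply(y, make_clip)
  net <- train_lrcn(feats, y, spec = lrcn_spec(hidden_units = 16L),
                    control = train_spec(learning_rate = 0.1, max_epochs = 25L,
                                         batch_size = 16L, val_fraction = 0,
                                         seed = 5L))
  test_y <- rep(c(0L, 1L), each = 20)
  test_f <- lapply(test_y, make_clip)
  acc <- mean(apply_threshold(predict(net, test_f)) == test_y)
  expect_gt(acc, 0.9)
  # reversing the frame order changes the prediction materially
  clip <- test_f[[1L]]
  p_fwd <- predict(net, clip)
  p_rev <- predict(net, clip[k:1, , drop = FALSE])
  expect_gt(abs(p_fwd - p_rev), 0.2)
  # a k=1 clip is a defined boundary case with a normalised output
  p1 <- predict(net, clip[1L, , drop = FALSE])
  expect_true(p1 >= 0 && p1 <= 1)
})

test_that("the plateau schedule reduces the rate by 0.1 after 4 flat epochs", {
  losses <- c(1.0, 0.9, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8)
  lr <- plateau_schedule(losses, lr = 0.01, factor = 0.1, patience = 4L)
  expect_equal(lr, c(rep(0.01, 7), 0.001, 0.001))
  # improving losses never reduce
  expect_equal(plateau_schedule(seq(1, 0.1, by = -0.1), 0.05),
               rep(0.05, 10))
})

test_that("LRCN training freezes the encoder and follows its own plateau schedule", {
  set.seed(25)
  xs <- replicate(8, array(runif(64 * 64 * 3), c(64, 64, 3)), simplify = FALSE)
  net <- train_frame_classifier(xs, rep(c(0L, 1L), 4),
                                spec = encoder_spec("small", feature_dim = 16L),
                                control = train_spec(learning_rate = 0.01,
                                                     max_epochs = 1L, seed = 6L))
  before <- serialize(net$encoder$weights, NULL)
  feats <- lapply(1:20, function(i) matrix(rnorm(5 * 16), 5, 16))
  y <- rep(c(0L, 1L), 10)
  lnet <- train_lrcn(feats, y, spec = lrcn_spec(hidden_units = 8L),
                     control = train_spec(learning_rate = 0.05, max_epochs = 12L,
                                          val_fraction = 0, seed = 7L),
                     encoder = net)
  expect_identical(serialize(lnet$encoder$encoder$weights, NULL), before)
  # recorded learning rates equal the plateau schedule applied to the
  # monitored loss sequence
  expect_equal(lnet$history$lr,
               plateau_schedule(lnet$history$val_loss, 0.05,
                                factor = 0.1, patience = 4L))
})
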