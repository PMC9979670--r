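#' Encoder specification
#'
#' Two variants of the per-frame convolutional encoder are provided. The
#' `"small"` variant is a compact stack of strided convolution blocks sized
#' for desk-scale experiments (64 px inputs, configurable feature length) so
#' the full clip-classification path trains on a CPU in minutes. The
#' `"reference"` variant preserves the contract of the full-scale backbone
#' setting: 224 x 224 x 3 inputs and a 2048-element feature vector after the
#' final fully connected layer is removed. Both end in a global mean+max
#' pooling readout, so `feature_dim` is twice the last block's channels.
#'
#' @param variant `"small"` or `"reference"`.
#' @param feature_dim feature vector length (must be even; fixed at 2048 for
#'   the reference variant).
#' @param input_size expected square input side (64 small, 224 reference).
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(variant = c("small", "reference"),
                         feature_dim = if (match.arg(variant) == "reference") 2048L else 64L,
                         input_size = if (match.arg(variant) == "reference") 224L else 64L) {
  variant <- match.arg(variant)
  feature_dim <- as.integer(feature_dim)
  if (feature_dim <= 0L || feature_dim %% 2L != 0L) {
    stopf("feature_dim must be a positive even integer")
  }
  if (variant == "reference" && feature_dim != 2048L) {
    stopf("the reference encoder emits 2048 features")
  }
  arch <- if (variant == "reference") {
    list(list(kernel = 7L, stride = 4L, out = 64L),
         list(kernel = 3L, stride = 2L, out = 128L),
         list(kernel = 3L, stride = 2L, out = 256L),
         list(kernel = 3L, stride = 2L, out = 512L),
         list(kernel = 3L, stride = 2L, out = 1024L))
  } else {
    list(list(kernel = 5L, stride = 2L, out = max(8L, feature_dim %/% 4L)),
         list(kernel = 3L, stride = 2L, out = feature_dim %/% 2L))
  }
  structure(list(variant = variant, feature_dim = feature_dim,
                 input_size = as.integer(input_size), arch = arch),
            class = "encoder_spec")
}

#' Initialise an encoder from its specification
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed for the (He-normal) weight draw.
#' @return An `encoder` object holding architecture, geometry and weights.
#' @export
init_encoder <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "encoder_spec"))
  geom <- build_encoder_geom(spec$arch, spec$input_size)
  if (geom$feature_dim != spec$feature_dim) {
    stopf("architecture emits %d features, spec says %d",
          geom$feature_dim, spec$feature_dim)
  }
  structure(list(spec = spec, arch = spec$arch, geom = geom,
                 weights = init_encoder_weights(spec$arch, seed)),
            class = "encoder")
}

#' Encode one frame into a feature vector
#'
#' @param image preprocessed array matching the encoder's input size.
#' @param encoder an `encoder` (or a trained `frame_net`, whose encoder is
#'   used).
#' @return Numeric feature vector of length `feature_dim`.
#' @export
encode_frame <- function(image, encoder) {
  if (inherits(encoder, "frame_net")) encoder <- encoder$encoder
  stopifnot(inherits(encoder, "encoder"))
  d <- dim(image)
  if (length(d) != 3L || d[1L] != encoder$spec$input_size ||
      d[2L] != encoder$spec$input_size || d[3L] != 3L) {
    stopf("encoder expects a %d x %d x 3 input, got %s",
          encoder$spec$input_size, encoder$spec$input_size,
          paste(d, collapse = " x "))
  }
  encoder_forward(image, encoder)
}

#' Inverse-frequency class weights
#'
#' `w_c` is proportional to `1 / freq_c` and normalised so the two class
#' weights average to 1.
#'
#' @param labels vector of 0/1 labels containing both classes.
#' @return Numeric vector `c(w0, w1)`.
#' @export
compute_class_weights <- function(labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) stopf("both classes must be present")
  raw <- c(1 / (n0 / length(labels)), 1 / (n1 / length(labels)))
  raw / mean(raw)
}

#' Training specification
#'
#' Defaults follow the training protocol of the full-scale setting: SGD at
#' learning rate 1e-4 for at most 20 epochs, inverse-frequency class weights
#' recomputed from the training split, a fresh random subsample of 5000
#' frames per epoch for the frame classifier, and for the clip model a
#' frozen encoder plus a reduce-on-plateau schedule (factor 0.1, patience 4)
#' on the validation loss. Desk-scale encoders train well with a larger
#' learning rate (see the package vignette).
#'
#' @param learning_rate SGD learning rate (> 0).
#' @param max_epochs epoch cap.
#' @param batch_size minibatch size.
#' @param class_weighting use inverse-frequency class weights.
#' @param epoch_subsample frames drawn per epoch for the frame classifier;
#'   clamped to the dataset size.
#' @param plateau_factor,plateau_patience reduce-on-plateau parameters
#'   (clip-model training only).
#' @param freeze_encoder keep encoder weights fixed while training the clip
#'   model.
#' @param val_fraction fraction of training lesions held out to monitor the
#'   plateau schedule.
#' @param seed integer seed governing initialisation and sampling.
#' @return A `train_spec` list.
#' @export
train_spec <- function(learning_rate = 1e-4, max_epochs = 20L, batch_size = 32L,
                       class_weighting = TRUE, epoch_subsample = 5000L,
                       plateau_factor = 0.1, plateau_patience = 4L,
                       freeze_encoder = TRUE, val_fraction = 0.1, seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 class_weighting = isTRUE(class_weighting),
                 epoch_subsample = as.integer(epoch_subsample),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 freeze_encoder = isTRUE(freeze_encoder),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Train the frame-level classifier
#'
#' Fits the convolutional encoder plus softmax head by SGD on class-weighted
#' cross-entropy. Each epoch draws a fresh random subsample of at most
#' `epoch_subsample` frames. Training diverging to a non-finite loss aborts
#' with diagnostics.
#'
#' @param x list of preprocessed image arrays (encoder input size).
#' @param y 0/1 labels (both classes present).
#' @param spec an [encoder_spec()].
#' @param control a [train_spec()].
#' @return A `frame_net` with components `encoder`, `head`, `history`
#'   (per-epoch loss and accuracy) and `classes`.
#' @export
train_frame_classifier <- function(x, y, spec = encoder_spec("small"),
                                   control = train_spec()) {
  stopifnot(length(x) == length(y))
  y <- as.integer(y)
  n <- length(x)
  cw <- if (control$class_weighting) compute_class_weights(y) else c(1, 1)
  enc <- init_encoder(spec, seed = child_seed(control$seed, 1L))
  D <- spec$feature_dim
  head <- with_seed(child_seed(control$seed, 2L),
                    list(W = matrix(stats::rnorm(D * 2L, sd = 0.01), D, 2L),
                         b = numeric(2L)))
  lr <- control$learning_rate
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0), lr = numeric(0))
  with_seed(child_seed(control$seed, 3L), {
    for (epoch in seq_len(control$max_epochs)) {
      take <- sample.int(n, min(control$epoch_subsample, n))
      ep_loss <- 0; ep_correct <- 0L
      batches <- split(take, ceiling(seq_along(take) / control$batch_size))
      for (bt in batches) {
        g_enc <- NULL
        g_W <- 0 * head$W; g_b <- numeric(2L)
        for (i in bt) {
          fw <- encoder_forward(x[[i]], enc, keep_cache = TRUE)
          logits <- drop(fw$feat %*% head$W) + head$b
          p <- softmax2(logits)
          ls <- wce_loss(p, y[i], cw)
          ep_loss <- ep_loss + ls$loss
          ep_correct <- ep_correct + as.integer(which.max(p) - 1L == y[i])
          g_W <- g_W + outer(fw$feat, ls$dlogits)
          g_b <- g_b + ls$dlogits
          dfeat <- drop(head$W %*% ls$dlogits)
          gb <- encoder_backward(dfeat, enc, fw)
          if (is.null(g_enc)) g_enc <- gb else {
            for (l in seq_along(gb)) {
              g_enc[[l]]$W <- g_enc[[l]]$W + gb[[l]]$W
              g_enc[[l]]$b <- g_enc[[l]]$b + gb[[l]]$b
            }
          }
        }
        bsz <- length(bt)
        for (l in seq_along(enc$weights)) {
          enc$weights[[l]]$W <- enc$weights[[l]]$W - lr * g_enc[[l]]$W / bsz
          enc$weights[[l]]$b <- enc$weights[[l]]$b - lr * g_enc[[l]]$b / bsz
        }
        head$W <- head$W - lr * g_W / bsz
        head$b <- head$b - lr * g_b / bsz
      }
      ep_loss <- ep_loss / length(take)
      if (!is.finite(ep_loss)) {
        stopf("frame classifier diverged at epoch %d (loss = %s); lower the learning rate",
              epoch, format(ep_loss))
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                           accuracy = ep_correct / length(take),
                                           lr = lr))
    }
  })
  structure(list(encoder = enc, head = head, spec = spec, control = control,
                 class_weights = cw, history = history, classes = c(0L, 1L)),
            class = "frame_net")
}

#' @export
predict.frame_net <- function(object, newdata,
                              type = c("prob", "class", "feature"), ...) {
  type <- match.arg(type)
  if (is.array(newdata)) newdata <- list(newdata)
  feats <- t(vapply(newdata, encoder_forward, numeric(object$spec$feature_dim),
                    enc = object$encoder))
  if (type == "feature") return(feats)
  logits <- sweep(feats %*% object$head$W, 2L, object$head$b, "+")
  probs <- t(apply(logits, 1L, softmax2))
  if (type == "class") return(apply_threshold(probs[, 2L])) else probs[, 2L]
}

#' @export
print.frame_net <- function(x, ...) {
  cat(sprintf("<frame_net> %s encoder, %d features, %d conv blocks\n",
              x$spec$variant, x$spec$feature_dim, length(x$spec$arch)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, train accuracy %.3f\n",
                last$epoch, last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
summary.frame_net <- function(object, ...) {
  print(object)
  cat("  class weights:", sprintf("%.3f", object$class_weights), "\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' Clip-model (LRCN head) specification
#'
#' A single-layer LSTM over the per-frame feature vectors with a
#' many-to-one readout: only the hidden state after the last frame, which
#' carries temporal information from all previous frames, is passed through
#' a fully connected layer to the two classes.
#'
#' @param hidden_units LSTM hidden size (default 100).
#' @param lstm_layers number of LSTM layers (only 1 supported).
#' @param n_classes number of output classes (2).
#' @return An `lrcn_spec` list.
#' @export
lrcn_spec <- function(hidden_units = 100L, lstm_layers = 1L, n_classes = 2L) {
  if (lstm_layers != 1L) stopf("only a single LSTM layer is supported")
  if (n_classes != 2L) stopf("binary classification only")
  structure(list(hidden_units = as.integer(hidden_units),
                 lstm_layers = 1L, n_classes = 2L),
            class = "lrcn_spec")
}

#' Train the clip classifier (LSTM over frozen encoder features)
#'
#' The encoder is pretrained on the available frames and its weights stay
#' frozen here: clip features are computed once up front and only the LSTM
#' and readout parameters are updated (the returned model carries the
#' encoder object untouched). A reduce-on-plateau schedule (factor
#' `plateau_factor`, patience `plateau_patience`) acts on the validation
#' loss, monitored on a lesion-level holdout of `val_fraction` of the
#' training lesions (or on the training loss when too few lesions exist).
#'
#' @param features list of `k x feature_dim` matrices, one per clip.
#' @param labels 0/1 clip labels.
#' @param lesion_ids lesion of each clip (used for the validation split).
#' @param spec an [lrcn_spec()].
#' @param control a [train_spec()].
#' @param encoder optional trained `encoder`/`frame_net` stored (frozen) with
#'   the model so that `predict()` can consume raw images.
#' @return An `lrcn_net` with `params`, `history` (loss, val loss, lr per
#'   epoch) and the frozen `encoder`, if given.
#' @export
train_lrcn <- function(features, labels, lesion_ids = NULL,
                       spec = lrcn_spec(), control = train_spec(),
                       encoder = NULL) {
  stopifnot(length(features) == length(labels))
  labels <- as.integer(labels)
  n <- length(features)
  D <- ncol(features[[1L]])
  H <- spec$hidden_units
  cw <- if (control$class_weighting && length(unique(labels)) == 2L) {
    compute_class_weights(labels)
  } else c(1, 1)
  enc_checksum <- if (!is.null(encoder)) encoder_checksum(encoder) else NULL

  # lesion-level validation holdout for the plateau monitor
  if (is.null(lesion_ids)) lesion_ids <- sprintf("clip%06d", seq_len(n))
  lesions <- unique(lesion_ids)
  val_idx <- integer(0)
  if (control$val_fraction > 0 && length(lesions) >= 5L) {
    n_val <- max(1L, round(control$val_fraction * length(lesions)))
    val_lesions <- with_seed(child_seed(control$seed, 11L),
                             sample(lesions, n_val))
    val_idx <- which(lesion_ids %in% val_lesions)
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!length(train_idx)) stopf("no training clips left after validation split")

  par <- init_lstm_weights(D, H, child_seed(control$seed, 12L))
  lr <- control$learning_rate
  best <- Inf; wait <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))

  batch_loss <- function(idx, par) {
    xs <- stack_clips(features[idx])
    fw <- lstm_forward(xs, par)
    p <- t(apply(fw$logits, 1L, softmax2))
    yv <- labels[idx]
    mean(-cw[yv + 1L] * log(pmax(p[cbind(seq_along(idx), yv + 1L)], 1e-12)))
  }

  with_seed(child_seed(control$seed, 13L), {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        xs <- stack_clips(features[bt])
        fw <- lstm_forward(xs, par, keep_cache = TRUE)
        p <- t(apply(fw$logits, 1L, softmax2))
        yv <- labels[bt]
        wv <- cw[yv + 1L]
        ep_loss <- ep_loss + sum(-wv * log(pmax(p[cbind(seq_along(bt), yv + 1L)], 1e-12)))
        dlog <- p
        dlog[cbind(seq_along(bt), yv + 1L)] <- dlog[cbind(seq_along(bt), yv + 1L)] - 1
        dlog <- dlog * wv / length(bt)
        g <- lstm_backward(dlog, xs, par, fw)
        for (nm in names(par)) par[[nm]] <- par[[nm]] - lr * g[[nm]]
      }
      ep_loss <- ep_loss / length(ord)
      if (!is.finite(ep_loss)) {
        stopf("clip model diverged at epoch %d; lower the learning rate", epoch)
      }
      monitored <- if (length(val_idx)) batch_loss(val_idx, par) else ep_loss
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                           val_loss = monitored, lr = lr))
      if (monitored < best - 1e-10) {
        best <- monitored; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$plateau_patience) {
          lr <- lr * control$plateau_factor
          wait <- 0L
        }
      }
    }
  })
  if (!is.null(enc_checksum) && control$freeze_encoder &&
      !identical(enc_checksum, encoder_checksum(encoder))) {
    stopf("encoder weights changed during clip training despite freeze_encoder = TRUE")
  }
  structure(list(params = par, spec = spec, control = control,
                 class_weights = cw, history = history, encoder = encoder,
                 feature_dim = D, classes = c(0L, 1L)),
            class = "lrcn_net")
}

stack_clips <- function(feats) {
  k <- nrow(feats[[1L]])
  lapply(seq_len(k), function(t) {
    do.call(rbind, lapply(feats, function(f) f[t, , drop = FALSE]))
  })
}

encoder_checksum <- function(encoder) {
  if (inherits(encoder, "frame_net")) encoder <- encoder$encoder
  sum(vapply(encoder$weights, function(w) sum(w$W) + sum(w$b), numeric(1L)))
}

#' Forward a clip through the trained LRCN
#'
#' @param object an `lrcn_net`.
#' @param newdata one `k x feature_dim` matrix, a list of such matrices, or
#'   (when the model carries an encoder) a list of clips given as lists of
#'   preprocessed image arrays.
#' @param type `"prob"` for adenoma probabilities, `"class"` for thresholded
#'   labels.
#' @param ... unused.
#' @return Numeric vector of adenoma probabilities (softmax class 1) or
#'   binary labels.
#' @export
predict.lrcn_net <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) && is.list(newdata[[1L]]) &&
      is.array(newdata[[1L]][[1L]])) {
    if (is.null(object$encoder)) stopf("model has no encoder; supply feature matrices")
    newdata <- lapply(newdata, function(clip) {
      t(vapply(clip, encode_frame, numeric(object$feature_dim),
               encoder = object$encoder))
    })
  }
  xs <- stack_clips(newdata)
  fw <- lstm_forward(xs, object$params)
  probs <- t(apply(fw$logits, 1L, softmax2))[, 2L]
  if (type == "class") apply_threshold(probs) else probs
}

#' @export
print.lrcn_net <- function(x, ...) {
  cat(sprintf("<lrcn_net> LSTM(%d hidden) over %d-dim frame features, many-to-one readout\n",
              x$spec$hidden_units, x$feature_dim))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f (val %.4f), lr %.2g\n",
                last$epoch, last$loss, last$val_loss, last$lr))
  }
  invisible(x)
}

#' Turn a classifier into a probability function over image lists
#'
#' @param classifier a `frame_net` or a function mapping a list of
#'   preprocessed arrays to adenoma probabilities.
#' @return A `function(images) -> numeric`.
#' @keywords internal
as_prob_fun <- function(classifier) {
  if (inherits(classifier, "frame_net")) {
    function(images) predict(classifier, images, type = "prob")
  } else if (is.function(classifier)) {
    classifier
  } else {
    stopf("classifier must be a frame_net or a function")
  }
}
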