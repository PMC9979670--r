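# Minimal CNN/LSTM machinery: strided convolutions via im2col, ReLU, a
# global mean+max pooling readout, a softmax head, and an LSTM with BPTT.
# Everything is plain matrix algebra so the full training path runs on CPU.

# geometry of one conv layer: output dims plus the im2col index matrix
conv_geom <- function(h, w, c, kh, kw, stride) {
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  if (oh < 1L || ow < 1L) stopf("conv kernel %dx%d does not fit a %dx%d input", kh, kw, h, w)
  ti <- rep(seq(1L, by = stride, length.out = oh), times = ow)
  tj <- rep(seq(1L, by = stride, length.out = ow), each = oh)
  base <- ti + (tj - 1L) * h
  dy <- rep(0:(kh - 1L), times = kw * c)
  dx <- rep(rep(0:(kw - 1L), each = kh), times = c)
  dc <- rep(0:(c - 1L), each = kh * kw)
  offs <- dy + dx * h + dc * h * w
  list(oh = oh, ow = ow, idx = outer(base, offs, "+"),
       plen = kh * kw * c, n_patches = oh * ow)
}

# architecture: list of conv layers (kernel, stride, out), applied with ReLU,
# closed by global mean+max pooling (feature_dim = 2 * last out)
build_encoder_geom <- function(arch, input_size) {
  h <- input_size; w <- input_size; c <- 3L
  geoms <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    ly <- arch[[i]]
    geoms[[i]] <- conv_geom(h, w, c, ly$kernel, ly$kernel, ly$stride)
    h <- geoms[[i]]$oh; w <- geoms[[i]]$ow; c <- ly$out
  }
  list(geoms = geoms, out_channels = c, feature_dim = 2L * c)
}

init_encoder_weights <- function(arch, seed) {
  with_seed(seed, {
    c_in <- 3L
    lapply(arch, function(ly) {
      plen <- ly$kernel^2 * c_in
      w <- matrix(stats::rnorm(plen * ly$out, sd = sqrt(2 / plen)), plen, ly$out)
      c_in <<- ly$out
      list(W = w, b = numeric(ly$out))
    })
  })
}

encoder_forward <- function(x, enc, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(enc$arch)) else NULL
  for (i in seq_along(enc$arch)) {
    g <- enc$geom$geoms[[i]]
    xcol <- x[g$idx]
    dim(xcol) <- dim(g$idx)
    z <- xcol %*% enc$weights[[i]]$W
    z <- sweep(z, 2L, enc$weights[[i]]$b, "+")
    a <- z * (z > 0) # ReLU
    if (keep_cache) cache[[i]] <- list(xcol = xcol, mask = z > 0, in_dim = dim(x))
    x <- array(a, c(g$oh, g$ow, enc$arch[[i]]$out))
  }
  n_sp <- prod(dim(x)[1:2])
  fm <- matrix(x, n_sp, dim(x)[3L])
  amax <- max.col(t(fm), ties.method = "first")
  feat <- c(colMeans(fm), fm[cbind(amax, seq_len(ncol(fm)))])
  if (keep_cache) {
    list(feat = feat, cache = cache, pool = list(n_sp = n_sp, amax = amax,
                                                 dims = dim(x)))
  } else feat
}

encoder_backward <- function(dfeat, enc, fw) {
  p <- fw$pool
  f <- p$dims[3L]
  dfm <- matrix(rep(dfeat[1:f] / p$n_sp, each = p$n_sp), p$n_sp, f)
  dfm[cbind(p$amax, seq_len(f))] <- dfm[cbind(p$amax, seq_len(f))] + dfeat[(f + 1L):(2L * f)]
  dx <- array(dfm, p$dims)
  grads <- vector("list", length(enc$arch))
  for (i in rev(seq_along(enc$arch))) {
    g <- enc$geom$geoms[[i]]
    cc <- fw$cache[[i]]
    dz <- matrix(dx, g$n_patches, enc$arch[[i]]$out) * cc$mask
    grads[[i]] <- list(W = crossprod(cc$xcol, dz), b = colSums(dz))
    if (i > 1L) {
      dxcol <- dz %*% t(enc$weights[[i]]$W)
      dvec <- numeric(prod(cc$in_dim))
      for (q in seq_len(ncol(g$idx))) {
        dvec[g$idx[, q]] <- dvec[g$idx[, q]] + dxcol[, q]
      }
      dx <- array(dvec, cc$in_dim)
    }
  }
  grads
}

softmax2 <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}

# weighted cross-entropy for one sample; returns loss and dlogits
wce_loss <- function(p, y, w) {
  loss <- -w[y + 1L] * log(max(p[y + 1L], 1e-12))
  d <- p
  d[y + 1L] <- d[y + 1L] - 1
  list(loss = loss, dlogits = d * w[y + 1L])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_weights <- function(input_dim, hidden, seed) {
  with_seed(seed, {
    s <- 1 / sqrt(hidden)
    W <- list(Wx = matrix(stats::runif(input_dim * 4L * hidden, -s, s), input_dim, 4L * hidden),
              Wh = matrix(stats::runif(hidden * 4L * hidden, -s, s), hidden, 4L * hidden),
              b = numeric(4L * hidden),
              Wy = matrix(stats::runif(hidden * 2L, -s, s), hidden, 2L),
              by = numeric(2L))
    W$b[(hidden + 1L):(2L * hidden)] <- 1 # forget-gate bias
    W
  })
}

# forward a batch of clips: xs is a list of k matrices (B x D each)
lstm_forward <- function(xs, par, keep_cache = FALSE) {
  k <- length(xs)
  B <- nrow(xs[[1L]])
  H <- ncol(par$Wh) / 4L
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", k) else NULL
  idx_i <- 1:H; idx_f <- (H + 1L):(2L * H)
  idx_g <- (2L * H + 1L):(3L * H); idx_o <- (3L * H + 1L):(4L * H)
  for (t in seq_len(k)) {
    G <- xs[[t]] %*% par$Wx + h %*% par$Wh
    G <- sweep(G, 2L, par$b, "+")
    gi <- sigmoid(G[, idx_i, drop = FALSE])
    gf <- sigmoid(G[, idx_f, drop = FALSE])
    gg <- tanh(G[, idx_g, drop = FALSE])
    go <- sigmoid(G[, idx_o, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    if (keep_cache) {
      cache[[t]] <- list(gi = gi, gf = gf, gg = gg, go = go,
                         c_prev = cc, h_prev = h, tc = tc)
    }
    cc <- c_new
    h <- go * tc
  }
  logits <- sweep(h %*% par$Wy, 2L, par$by, "+")
  list(logits = logits, h_last = h, cache = cache)
}

lstm_backward <- function(dlogits, xs, par, fw) {
  k <- length(xs)
  B <- nrow(xs[[1L]])
  H <- ncol(par$Wh) / 4L
  grads <- list(Wx = 0 * par$Wx, Wh = 0 * par$Wh, b = 0 * par$b,
                Wy = crossprod(fw$h_last, dlogits), by = colSums(dlogits))
  dh <- dlogits %*% t(par$Wy)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(k))) {
    cs <- fw$cache[[t]]
    dct <- dc + dh * cs$go * (1 - cs$tc^2)
    dgo <- dh * cs$tc
    dgi <- dct * cs$gg
    dgf <- dct * cs$c_prev
    dgg <- dct * cs$gi
    dc <- dct * cs$gf
    dG <- cbind(dgi * cs$gi * (1 - cs$gi),
                dgf * cs$gf * (1 - cs$gf),
                dgg * (1 - cs$gg^2),
                dgo * cs$go * (1 - cs$go))
    grads$Wx <- grads$Wx + crossprod(xs[[t]], dG)
    grads$Wh <- grads$Wh + crossprod(cs$h_prev, dG)
    grads$b <- grads$b + colSums(dG)
    dh <- dG %*% t(par$Wh)
  }
  grads
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Multiplies the learning rate by `factor` whenever the monitored loss has
#' failed to improve for `patience` consecutive epochs. Exposed as a pure
#' function over a loss sequence for inspection and testing.
#'
#' @param losses numeric vector of per-epoch monitored losses.
#' @param lr initial learning rate.
#' @param factor multiplicative reduction (default 0.1).
#' @param patience epochs without improvement tolerated before reducing
#'   (default 4).
#' @return Numeric vector: the learning rate in force at each epoch.
#' @export
plateau_schedule <- function(losses, lr, factor = 0.1, patience = 4L) {
  best <- Inf
  wait <- 0L
  out <- numeric(length(losses))
  for (i in seq_along(losses)) {
    out[i] <- lr
    if (losses[i] < best - 1e-10) {
      best <- losses[i]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0L
      }
    }
  }
  out
}
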