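#' Configuration for synthetic per-frame prediction streams
#'
#' Prediction streams are generated independently of any images so that
#' temporal aggregation and the evaluation metrics can be studied at scale
#' without training a model. Per-frame adenoma probabilities are drawn from a
#' Beta distribution centred on the lesion's true class and coupled in time
#' through a Gaussian AR(1) copula, giving marginally-Beta probabilities with
#' tunable lag-1 correlation.
#'
#' @param n_lesions number of simulated lesions.
#' @param frames_per_lesion frames per lesion (single integer).
#' @param mean_correct mean probability assigned to the true class; the Beta
#'   mean is `mean_correct` for adenomas and `1 - mean_correct` for
#'   non-adenomas. `1` with `concentration = Inf` makes probabilities equal
#'   the label exactly.
#' @param concentration Beta concentration (a + b); larger is less noisy;
#'   `Inf` collapses to the mean.
#' @param temporal_correlation AR(1) coefficient of the latent Gaussian
#'   process, in `[0, 1)`.
#' @param class_balance fraction of lesions labelled adenoma.
#' @param seed integer seed; fully determines the stream.
#' @return A `stream_config` list.
#' @export
stream_config <- function(n_lesions = 100L,
                          frames_per_lesion = 30L,
                          mean_correct = 0.72,
                          concentration = 3,
                          temporal_correlation = 0.3,
                          class_balance = 0.76,
                          seed = 1L) {
  if (mean_correct < 0 || mean_correct > 1) stopf("mean_correct must lie in [0, 1]")
  if (temporal_correlation < 0 || temporal_correlation >= 1) {
    stopf("temporal_correlation must lie in [0, 1)")
  }
  structure(list(n_lesions = as.integer(n_lesions),
                 frames_per_lesion = as.integer(frames_per_lesion),
                 mean_correct = mean_correct,
                 concentration = concentration,
                 temporal_correlation = temporal_correlation,
                 class_balance = class_balance,
                 seed = as.integer(seed)),
            class = "stream_config")
}

#' Generate a synthetic prediction stream
#'
#' @param config a [stream_config()].
#' @return A data.frame of per-frame prediction records with columns
#'   `lesion_id`, `frame_index`, `probability` (of adenoma) and `label`,
#'   grouped by lesion and ordered by frame.
#' @export
generate_prediction_stream <- function(config) {
  stopifnot(inherits(config, "stream_config"))
  n <- config$n_lesions
  k <- config$frames_per_lesion
  rho <- config$temporal_correlation
  phi <- config$concentration
  with_seed(config$seed, {
    labels <- as.integer(runif(n) < config$class_balance)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      mu <- if (labels[i] == 1L) config$mean_correct else 1 - config$mean_correct
      z <- numeric(k)
      z[1L] <- rnorm(1)
      if (k > 1L) {
        eps <- rnorm(k - 1L)
        for (t in 2:k) z[t] <- rho * z[t - 1L] + sqrt(1 - rho^2) * eps[t - 1L]
      }
      if (is.infinite(phi)) {
        p <- rep(mu, k)
      } else if (mu <= 0 || mu >= 1) {
        p <- stats::qbeta(stats::pnorm(z), max(mu * phi, 1e-12),
                          max((1 - mu) * phi, 1e-12))
        p[!is.finite(p)] <- mu
      } else {
        p <- stats::qbeta(stats::pnorm(z), mu * phi, (1 - mu) * phi)
      }
      out[[i]] <- data.frame(lesion_id = sprintf("sim%05d", i),
                             frame_index = seq_len(k) - 1L,
                             probability = p,
                             label = labels[i],
                             stringsAsFactors = FALSE)
    }
    structure(do.call(rbind, out), class = c("prediction_stream", "data.frame"))
  })
}
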