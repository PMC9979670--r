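check_probs <- function(probs) {
  if (length(probs) == 0L) stopf("probability list must be non-empty")
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  invisible(probs)
}

#' Soft averaging of per-frame probabilities
#'
#' The temporally weighted clip output is the arithmetic mean
#' `z = (1/k) * sum(p_i)` of the per-frame adenoma probabilities.
#'
#' @param probs numeric vector of per-frame probabilities in `[0, 1]`.
#' @return `z` in `[0, 1]`.
#' @export
soft_average <- function(probs) {
  check_probs(probs)
  sum(probs) / length(probs)
}

#' Plurality vote over thresholded per-frame predictions
#'
#' Each frame probability is mapped to a binary vote with the same boundary
#' rule as [apply_threshold()] (`p <= T` votes 0) and the majority label is
#' returned. Ties (possible only for even clip lengths) break toward class 1,
#' the clinically conservative choice.
#'
#' @param probs numeric vector of per-frame probabilities.
#' @param T vote threshold.
#' @return Binary label 0 or 1. Unlike the other combiners, no continuous
#'   output exists.
#' @export
plurality_vote <- function(probs, T = 0.5) {
  check_probs(probs)
  votes <- as.integer(probs > T)
  n1 <- sum(votes)
  n0 <- length(votes) - n1
  if (n1 >= n0) 1L else 0L
}

#' Extreme vote: the most confident frame wins
#'
#' Selects the frame prediction farthest from 0.5 (the maximiser of
#' `|p_i - 0.5|`) and returns that frame's probability; ties break toward the
#' earliest frame.
#'
#' @param probs numeric vector of per-frame probabilities.
#' @return The selected probability `z`.
#' @export
extreme_vote <- function(probs) {
  check_probs(probs)
  probs[which.max(abs(probs - 0.5))]
}

#' Threshold a continuous output into a binary label
#'
#' `y = 0` when `z <= T` and `y = 1` when `z > T`; the boundary `z = T` is
#' assigned to class 0.
#'
#' @param z continuous output in `[0, 1]`.
#' @param T threshold (default 0.5).
#' @return 0 or 1 (vectorised over `z`).
#' @export
apply_threshold <- function(z, T = 0.5) {
  if (anyNA(z) || any(z < 0 | z > 1)) stopf("z must lie in [0, 1]")
  as.integer(z > T)
}

#' Cross-fold ensemble by arithmetic mean
#'
#' @param probs numeric vector: one probability per fold model for the same
#'   evaluation unit.
#' @return The mean probability.
#' @export
fold_ensemble <- function(probs) {
  check_probs(probs)
  mean(probs)
}

#' Aggregate a per-frame prediction stream into per-clip results
#'
#' Applies one combination method over every sliding window of `k` frames
#' (stride 1 over the lesion's ordered predictions), mirroring the windows
#' that clip extraction produces on a clean run.
#'
#' @param frame_preds data.frame with columns `lesion_id`, `frame_index`,
#'   `probability` (and optionally `label`) for one lesion, ordered by frame.
#' @param k clip length.
#' @param method `"soft_average"`, `"plurality"` or `"extreme"`.
#' @param T threshold used for the binary output.
#' @return data.frame with one row per clip: `lesion_id`, `start_index`,
#'   `z` (`NA` for plurality, which is vote-only), `y`, and `label` when the
#'   input carries it.
#' @export
clip_stream_aggregate <- function(frame_preds, k, method = c("soft_average",
                                                             "plurality",
                                                             "extreme"),
                                  T = 0.5) {
  method <- match.arg(method)
  if (length(unique(frame_preds$lesion_id)) > 1L) {
    stopf("clip_stream_aggregate() expects a single lesion")
  }
  frame_preds <- frame_preds[order(frame_preds$frame_index), , drop = FALSE]
  n <- nrow(frame_preds)
  if (n < k) {
    return(data.frame(lesion_id = character(0), start_index = integer(0),
                      z = numeric(0), y = integer(0)))
  }
  starts <- seq_len(n - k + 1L)
  res <- lapply(starts, function(s) {
    p <- frame_preds$probability[s:(s + k - 1L)]
    if (method == "soft_average") {
      z <- soft_average(p); y <- apply_threshold(z, T)
    } else if (method == "extreme") {
      z <- extreme_vote(p); y <- apply_threshold(z, T)
    } else {
      z <- NA_real_; y <- plurality_vote(p, T)
    }
    data.frame(lesion_id = frame_preds$lesion_id[1L],
               start_index = frame_preds$frame_index[s], z = z, y = y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if ("label" %in% names(frame_preds)) out$label <- frame_preds$label[1L]
  out
}

#' Aggregate every lesion of a prediction stream
#'
#' @param stream data.frame of per-frame predictions for many lesions (as
#'   produced by [generate_prediction_stream()]).
#' @inheritParams clip_stream_aggregate
#' @return Row-bound per-clip results across lesions.
#' @export
stream_aggregate <- function(stream, k, method = "soft_average", T = 0.5) {
  parts <- lapply(split(stream, stream$lesion_id), clip_stream_aggregate,
                  k = k, method = method, T = T)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
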