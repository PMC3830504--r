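# Detector-versus-truth scoring: one-to-one event matching by peak time,
# then detection sensitivity, false-positive fraction and the per-class
# confusion matrix over matched pairs.

#' Match detected events against a reference event list
#'
#' Events are matched one-to-one by peak time: all detected/reference pairs
#' closer than `tolerance_s` are considered, nearest pairs first (ties
#' resolved toward the earlier reference event), and each event is used at
#' most once. Matching is class-agnostic; classification is scored
#' separately on the matched pairs via the confusion matrix.
#'
#' @param detected,truth `eog_events` data frames (or any data frame with
#'   `label`, `onset` and `peak` sample columns), sorted by onset.
#' @param fs Sampling rate in Hz; defaults to the `fs` attribute of
#'   `detected`.
#' @param tolerance_s Maximum peak-time separation of a matched pair in
#'   seconds; default 0.1.
#'
#' @return An object of class `match_result`: list with `tp`, `fp`, `fn`,
#'   `pairs` (data frame of matched index pairs with their time offsets and
#'   labels), `sensitivity` (`tp / (tp + fn)`), `fp_rate` (`fp / (tp + fp)`,
#'   the false-discovery fraction of detections) and `confusion` (5 x 5
#'   truth-by-detected count matrix over matched pairs).
#' @export
match_events <- function(detected, truth, fs = NULL, tolerance_s = 0.1) {
  if (tolerance_s < 0) stop("tolerance_s must be non-negative", call. = FALSE)
  fs <- fs %||% attr(detected, "fs") %||% attr(truth, "fs")
  if (is.null(fs)) stop("fs is required to compare peak times", call. = FALSE)
  n_d <- nrow(detected)
  n_t <- nrow(truth)
  classes <- event_classes()
  confusion <- matrix(0L, 5, 5, dimnames = list(truth = classes,
                                                detected = classes))
  pairs <- data.frame(detected = integer(0), truth = integer(0),
                      dt_s = numeric(0), detected_label = character(0),
                      truth_label = character(0))
  if (n_d > 0 && n_t > 0) {
    td <- (detected$peak - 1) / fs
    tt <- (truth$peak - 1) / fs
    dmat <- abs(outer(td, tt, `-`))
    cand <- which(dmat <= tolerance_s, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dist <- dmat[cand]
      ord <- order(dist, truth$onset[cand[, 2]], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      d_used <- rep(FALSE, n_d)
      t_used <- rep(FALSE, n_t)
      for (r in seq_len(nrow(cand))) {
        di <- cand[r, 1]; ti <- cand[r, 2]
        if (d_used[di] || t_used[ti]) next
        d_used[di] <- TRUE
        t_used[ti] <- TRUE
        pairs <- rbind(pairs, data.frame(
          detected = di, truth = ti, dt_s = td[di] - tt[ti],
          detected_label = detected$label[di],
          truth_label = truth$label[ti]))
      }
    }
  }
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs$truth), , drop = FALSE]
    rownames(pairs) <- NULL
    for (r in seq_len(nrow(pairs))) {
      confusion[pairs$truth_label[r], pairs$detected_label[r]] <-
        confusion[pairs$truth_label[r], pairs$detected_label[r]] + 1L
    }
  }
  tp <- nrow(pairs)
  fp <- n_d - tp
  fn <- n_t - tp
  structure(list(
    tp = tp, fp = fp, fn = fn, pairs = pairs,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fp_rate = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
    confusion = confusion), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp = %d, fp = %d, fn = %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  sensitivity = %.3f, fp_rate = %.3f\n",
              x$sensitivity, x$fp_rate))
  invisible(x)
}

#' Per-class classification sensitivity over matched pairs
#'
#' Among matched pairs whose reference label equals `class`, the fraction
#' whose detected label also equals `class`. Detection and classification
#' are thereby scored in two stages: an event can be found (matched) yet
#' misclassified.
#'
#' @param result A [match_events()] result.
#' @param class One of [event_classes()].
#' @return A fraction in \[0, 1\], or `NA` if no matched pair has that
#'   reference class.
#' @export
classification_sensitivity <- function(result, class) {
  stopifnot(inherits(result, "match_result"))
  class <- match.arg(class, event_classes())
  denom <- sum(result$confusion[class, ])
  if (denom == 0) return(NA_real_)
  result$confusion[class, class] / denom
}
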