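# Classification: each extracted feature is assigned to one of five classes.
# Horizontal and vertical saccade candidates whose intervals overlap merge
# into an oblique saccade; a horizontal candidate overlapping a blink is a
# saccade-with-blink; the rest keep their axis label.

new_eog_events <- function(df, fs) {
  base <- data.frame(label = character(0), onset = integer(0),
                     offset = integer(0), peak = integer(0),
                     direction_sign = integer(0), axis = character(0))
  if (is.null(df) || nrow(df) == 0L) df <- base
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "fs") <- fs
  class(df) <- c("eog_events", "data.frame")
  df
}

#' Count events by class
#'
#' @param events An `eog_events` data frame.
#' @return Named integer vector over the five classes of [event_classes()].
#' @export
event_counts <- function(events) {
  counts <- table(factor(events$label, levels = event_classes()))
  stats::setNames(as.integer(counts), event_classes())
}

#' @export
print.eog_events <- function(x, ...) {
  cat(sprintf("<eog_events> %d events @ %g Hz\n", nrow(x), attr(x, "fs")))
  cnt <- event_counts(x)
  for (cl in names(cnt)) if (cnt[[cl]] > 0) cat(sprintf("  %-20s %d\n", cl, cnt[[cl]]))
  invisible(x)
}

intervals_overlap <- function(lb1, rb1, lb2, rb2, min_overlap = 1L) {
  pmin(rb1, rb2) - pmax(lb1, lb2) + 1L >= min_overlap
}

#' Classify extracted features into the five event classes
#'
#' A horizontal and a vertical saccade candidate occurring simultaneously
#' (intervals overlapping by at least one sample, adjustable through
#' `overlap_min_s`) merge into one oblique saccade spanning the union of the
#' two intervals. A horizontal candidate overlapping a blink becomes a
#' saccade-with-blink; blink coexistence takes precedence over obliqueness.
#' Remaining candidates keep their axis class, and blinks form the fourth
#' class. Every input candidate is consumed exactly once.
#'
#' @param h,v Saccade candidate data frames from
#'   [extract_saccade_candidates()] (vertical candidates after
#'   [detect_blinks()]).
#' @param blinks Blink data frame from [detect_blinks()].
#' @param fs Sampling rate in Hz.
#' @param overlap_min_s Minimum overlap, in seconds, for two intervals to
#'   count as simultaneous (default 0: a single shared sample suffices).
#'
#' @return An `eog_events` data frame sorted by onset with columns `label`,
#'   `onset`, `offset`, `peak`, `direction_sign`, `axis` and (for oblique
#'   saccades) the component peak indices `peak_h`/`peak_v`.
#' @export
classify_events <- function(h, v, blinks, fs, overlap_min_s = 0) {
  min_overlap <- max(1L, as.integer(ceiling(overlap_min_s * fs)))
  # same-polarity overlaps within one axis mean detection failed to merge;
  # opposite-polarity neighbours may legitimately share boundary samples
  for (cand in list(h, v)) {
    if (!is.null(cand) && nrow(cand) > 1L) {
      o <- order(cand$lb)
      overl <- cand$lb[o][-1] <= cand$rb[o][-nrow(cand)]
      same_pol <- cand$polarity[o][-1] == cand$polarity[o][-nrow(cand)]
      if (any(overl & same_pol)) {
        stop("internal error: overlapping same-polarity candidates within ",
             "one axis; detection should have merged them", call. = FALSE)
      }
    }
  }
  n_h <- if (is.null(h)) 0L else nrow(h)
  n_v <- if (is.null(v)) 0L else nrow(v)
  n_b <- if (is.null(blinks)) 0L else nrow(blinks)
  h_used <- rep(FALSE, n_h)
  v_used <- rep(FALSE, n_v)
  rows <- list()
  add <- function(label, onset, offset, peak, sign, axis,
                  peak_h = NA_integer_, peak_v = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, onset = as.integer(onset), offset = as.integer(offset),
      peak = as.integer(peak), direction_sign = as.integer(sign),
      axis = axis, peak_h = peak_h, peak_v = peak_v)
  }

  # blink coexistence first: an h candidate inside/overlapping a blink
  if (n_h > 0L && n_b > 0L) {
    for (i in seq_len(n_h)) {
      ov <- which(intervals_overlap(h$lb[i], h$rb[i],
                                    blinks$onset, blinks$offset, min_overlap))
      if (length(ov) > 0L) {
        h_used[i] <- TRUE
        add("SACCADE_WITH_BLINK", h$lb[i], h$rb[i], h$peak_index[i],
            h$direction_sign[i], "h")
      }
    }
  }
  # obliqueness: remaining h overlapping v
  if (n_h > 0L && n_v > 0L) {
    for (i in which(!h_used)) {
      ov <- which(!v_used & intervals_overlap(h$lb[i], h$rb[i],
                                              v$lb, v$rb, min_overlap))
      if (length(ov) > 0L) {
        j <- ov[1]
        h_used[i] <- TRUE
        v_used[j] <- TRUE
        dominant_h <- abs(h$peak_value[i]) >= abs(v$peak_value[j])
        add("OBLIQUE_SACCADE",
            min(h$lb[i], v$lb[j]), max(h$rb[i], v$rb[j]),
            if (dominant_h) h$peak_index[i] else v$peak_index[j],
            h$direction_sign[i],
            if (dominant_h) "h" else "v",
            peak_h = h$peak_index[i], peak_v = v$peak_index[j])
      }
    }
  }
  if (n_h > 0L) {
    for (i in which(!h_used)) {
      add("HORIZONTAL_SACCADE", h$lb[i], h$rb[i], h$peak_index[i],
          h$direction_sign[i], "h")
    }
  }
  if (n_v > 0L) {
    for (j in which(!v_used)) {
      add("VERTICAL_SACCADE", v$lb[j], v$rb[j], v$peak_index[j],
          v$direction_sign[j], "v")
    }
  }
  if (n_b > 0L) {
    for (b in seq_len(n_b)) {
      add("BLINK", blinks$onset[b], blinks$offset[b], blinks$peak[b], 1L, "v")
    }
  }
  new_eog_events(if (length(rows)) do.call(rbind, rows) else NULL, fs)
}

#' Apply physiological duration filters
#'
#' Saccades outside a physiological duration window are overwhelmingly
#' detector artifacts (very short noise spikes) or drifts; restricting
#' saccade durations to 30-80 ms retains saccades of roughly 5-15 degrees
#' while discarding most false detections. An optional minimum blink
#' duration removes very short false blinks. Bounds are inclusive and the
#' filter is idempotent.
#'
#' @param events An `eog_events` data frame.
#' @param saccade_min_s,saccade_max_s Inclusive duration window for the
#'   saccade classes (horizontal, vertical, oblique); defaults 0.030 and
#'   0.080 s. Set either to `NULL` to disable the saccade filter.
#' @param blink_min_s Minimum blink duration in seconds, or `NULL` (default)
#'   to leave blinks unfiltered.
#' @param fs Sampling rate in Hz; defaults to the events' `fs` attribute.
#' @return The filtered `eog_events`.
#' @export
apply_duration_filters <- function(events, saccade_min_s = 0.030,
                                   saccade_max_s = 0.080,
                                   blink_min_s = NULL, fs = NULL) {
  fs <- fs %||% attr(events, "fs")
  if (nrow(events) == 0L) return(events)
  dur <- if ("duration_s" %in% names(events) && all(!is.na(events$duration_s)))
    events$duration_s else (events$offset - events$onset) / fs
  keep <- rep(TRUE, nrow(events))
  saccade_classes <- c("HORIZONTAL_SACCADE", "VERTICAL_SACCADE",
                       "OBLIQUE_SACCADE")
  if (!is.null(saccade_min_s) && !is.null(saccade_max_s)) {
    if (saccade_min_s > saccade_max_s) {
      stop("saccade_min_s must not exceed saccade_max_s", call. = FALSE)
    }
    is_sac <- events$label %in% saccade_classes
    keep[is_sac] <- dur[is_sac] >= saccade_min_s & dur[is_sac] <= saccade_max_s
  }
  if (!is.null(blink_min_s)) {
    is_blink <- events$label == "BLINK"
    keep[is_blink] <- keep[is_blink] & dur[is_blink] >= blink_min_s
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fs") <- fs
  class(out) <- c("eog_events", "data.frame")
  out
}
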