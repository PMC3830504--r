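# Feature extraction: events are "bounded peaks" - local extrema above the
# calibrated threshold, delimited on each side by the first sample at or
# below a bound level set to a fraction (default 10%) of the peak amplitude.

#' Find bounded peaks in a signal
#'
#' Locates every local extremum of `|samples|` above `threshold` and walks
#' outward for its boundaries: the left bound (LB) is the first sample at or
#' below `bound_frac * |peak|`, and the right-boundary search terminates when
#' (1) the signal returns to the bound level, (2) a sample exceeds the
#' current peak value - in which case the peak is promoted to the larger
#' extremum and the search continues, absorbing double-peaked events - or
#' (3) the maximum peak duration is exceeded, in which case the peak is
#' discarded. Overlapping accepted peaks of the same polarity are merged,
#' keeping the larger peak.
#'
#' @param samples Numeric vector (any signal domain: velocity or position).
#' @param fs Sampling rate in Hz.
#' @param threshold Detection threshold in signal units (> 0).
#' @param bound_frac Bound level as a fraction of the peak amplitude;
#'   default 0.10.
#' @param max_peak_duration_s Maximum allowed LB-to-RB span in seconds for a
#'   single peak; default 0.80.
#' @param max_promoted_duration_s Maximum span once a peak has absorbed a
#'   second, larger peak (double-peaked events); defaults to
#'   `max_peak_duration_s`. Blink extraction widens it to the maximum blink
#'   duration so double-peaked blinks stay intact while single peaks remain
#'   capped.
#'
#' @return A data frame with one row per accepted peak, sorted by
#'   `peak_index`: columns `peak_index`, `lb`, `rb` (1-based sample
#'   indices), `polarity` (+1/-1), `peak_value` (signed, signal units) and
#'   `bound_level`.
#' @export
find_bounded_peaks <- function(samples, fs, threshold, bound_frac = 0.10,
                               max_peak_duration_s = 0.80,
                               max_promoted_duration_s = max_peak_duration_s) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  x <- as.numeric(samples)
  a <- abs(x)
  n <- length(a)
  max_span <- floor(max_peak_duration_s * fs + 1e-9)
  max_span_promoted <- max(max_span,
                           floor(max_promoted_duration_s * fs + 1e-9))
  empty <- data.frame(peak_index = integer(0), lb = integer(0),
                      rb = integer(0), polarity = integer(0),
                      peak_value = numeric(0), bound_level = numeric(0))
  if (n < 3L) return(empty)

  # candidate extrema of |x| above threshold (plateaus: leftmost sample)
  r <- rle(a)
  k <- length(r$values)
  if (k < 3L) return(empty)
  run_start <- cumsum(c(1L, r$lengths[-k]))
  interior <- 2:(k - 1L)
  is_max <- r$values[interior] > r$values[interior - 1L] &
            r$values[interior] > r$values[interior + 1L] &
            r$values[interior] > threshold
  cand <- run_start[interior][is_max]
  if (length(cand) == 0L) return(empty)

  rows <- vector("list", length(cand))
  n_rows <- 0L
  last_rb <- 0L
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    if (p <= last_rb) { i <- i + 1L; next }
    pv <- a[p]
    bl <- bound_frac * pv
    # left search, limited by the maximum span
    lb <- NA_integer_
    j <- p - 1L
    while (j >= 1L && p - j <= max_span) {
      if (a[j] <= bl) { lb <- j; break }
      j <- j - 1L
    }
    if (is.na(lb)) { i <- i + 1L; next }
    # right search with peak promotion; the span cap widens only once a
    # second peak has been absorbed (double-peaked events)
    rb <- NA_integer_
    j <- p + 1L
    cap <- max_span
    while (j <= n && j - lb <= cap) {
      if (a[j] > pv) {            # rule 2: promote to the larger extremum
        p <- j; pv <- a[j]; bl <- bound_frac * pv
        cap <- max_span_promoted
      } else if (a[j] <= bl) {    # rule 1: bound reached
        rb <- j
        break
      }
      j <- j + 1L
    }
    if (is.na(rb)) { i <- i + 1L; next }   # rule 3: max duration exceeded
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- c(p, lb, rb)
    last_rb <- rb
    # skip candidates absorbed by this peak
    while (i <= length(cand) && cand[i] <= rb) i <- i + 1L
  }
  if (n_rows == 0L) return(empty)
  m <- do.call(rbind, rows[seq_len(n_rows)])
  out <- data.frame(peak_index = m[, 1], lb = m[, 2], rb = m[, 3])
  out$polarity <- ifelse(x[out$peak_index] >= 0, 1L, -1L)
  out$peak_value <- x[out$peak_index]
  out$bound_level <- bound_frac * abs(out$peak_value)
  out <- out[order(out$peak_index), , drop = FALSE]

  # merge overlapping same-polarity peaks, keeping the larger one
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    prev <- 1L
    for (idx in 2:nrow(out)) {
      if (out$lb[idx] <= out$rb[prev] &&
          out$polarity[idx] == out$polarity[prev]) {
        union_span <- max(out$rb[idx], out$rb[prev]) -
                      min(out$lb[idx], out$lb[prev])
        winner <- if (abs(out$peak_value[idx]) > abs(out$peak_value[prev]))
          idx else prev
        loser <- if (winner == idx) prev else idx
        if (union_span <= max_span_promoted) {
          out$lb[winner] <- min(out$lb[idx], out$lb[prev])
          out$rb[winner] <- max(out$rb[idx], out$rb[prev])
        }
        keep[loser] <- FALSE
        prev <- winner
      } else {
        prev <- idx
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Extract saccade candidates from a velocity signal
#'
#' Every bounded peak (positive or negative) of the velocity trace above the
#' calibrated threshold is a saccade candidate; the peak polarity gives the
#' movement direction along that axis.
#'
#' @param vel A `velocity_signal` (see [differentiate()]).
#' @param threshold Velocity threshold in microvolts/second (from
#'   [estimate_thresholds()]).
#' @param bound_frac,max_peak_duration_s Passed to [find_bounded_peaks()].
#' @return A data frame of candidates: bounded-peak columns plus `axis`
#'   (`"h"` or `"v"`) and `direction_sign`.
#' @export
extract_saccade_candidates <- function(vel, threshold, bound_frac = 0.10,
                                       max_peak_duration_s = 0.80) {
  stopifnot(inherits(vel, "velocity_signal"))
  peaks <- find_bounded_peaks(vel$samples, vel$fs, threshold,
                              bound_frac = bound_frac,
                              max_peak_duration_s = max_peak_duration_s)
  peaks$axis <- rep(vel$source, nrow(peaks))
  peaks$direction_sign <- peaks$polarity
  peaks
}

#' Separate blinks from vertical saccade candidates
#'
#' A blink drives the vertical velocity up and then down; a vertical saccade
#' drives it only one way. Each positive vertical velocity candidate is
#' paired with the nearest following negative candidate inside the maximum
#' blink duration window; for each such up-and-down pair the intervening
#' upward peak of the positional vertical signal is located with
#' [find_bounded_peaks()]. If that positional peak exceeds the calibrated
#' blink amplitude threshold the pair is consumed and a blink is emitted,
#' with onset and offset at the positional peak's bounds; otherwise the
#' velocity candidates are left untouched as saccade candidates.
#'
#' @param eog_v Detrended, denoised vertical positional signal (microvolts).
#' @param vel_v The vertical `velocity_signal`.
#' @param thresholds A [estimate_thresholds()] `threshold_set`.
#' @param fs Sampling rate in Hz.
#' @param max_blink_duration_s Maximum blink duration in seconds;
#'   default 1.2.
#' @param bound_frac,max_peak_duration_s Passed to the velocity-domain
#'   bounded-peak search.
#' @param v_candidates Optional pre-extracted vertical candidates (as from
#'   [extract_saccade_candidates()]); extracted internally when `NULL`.
#'
#' @return A list with `blinks` (data frame: `onset`, `offset`, `peak`,
#'   `v_peak_value`, `up_peak_index`, `down_peak_index`) and `v_candidates`
#'   (the surviving vertical saccade candidates).
#' @export
detect_blinks <- function(eog_v, vel_v, thresholds, fs,
                          max_blink_duration_s = 1.2, bound_frac = 0.10,
                          max_peak_duration_s = 0.80, v_candidates = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (is.null(v_candidates)) {
    v_candidates <- extract_saccade_candidates(
      vel_v, thresholds$v_saccade, bound_frac = bound_frac,
      max_peak_duration_s = max_peak_duration_s)
  }
  blink_window <- floor(max_blink_duration_s * fs + 1e-9)
  empty_blinks <- data.frame(onset = integer(0), offset = integer(0),
                             peak = integer(0), v_peak_value = numeric(0),
                             up_peak_index = integer(0),
                             down_peak_index = integer(0))
  if (nrow(v_candidates) == 0L) {
    return(list(blinks = empty_blinks, v_candidates = v_candidates))
  }
  # positional up-peaks above the blink threshold; a single positional peak
  # obeys the ordinary peak-duration cap, a double-peaked one may extend to
  # the maximum blink duration (sustained gaze plateaus bracketed by two
  # saccades do not qualify as blinks this way)
  pos_peaks <- find_bounded_peaks(eog_v, fs, thresholds$blink,
                                  bound_frac = bound_frac,
                                  max_peak_duration_s =
                                    min(max_peak_duration_s,
                                        max_blink_duration_s),
                                  max_promoted_duration_s =
                                    max_blink_duration_s)
  pos_peaks <- pos_peaks[pos_peaks$polarity > 0, , drop = FALSE]

  ups <- which(v_candidates$polarity > 0)
  downs <- which(v_candidates$polarity < 0)
  used <- rep(FALSE, nrow(v_candidates))
  pos_used <- rep(FALSE, nrow(pos_peaks))
  blinks <- list()
  for (u in ups) {
    after <- downs[!used[downs] &
                   v_candidates$peak_index[downs] > v_candidates$peak_index[u]]
    if (length(after) == 0L) next
    d <- after[1]                      # nearest following down-peak
    if (v_candidates$rb[d] - v_candidates$lb[u] > blink_window) next
    if (nrow(pos_peaks) == 0L) next
    hit <- which(!pos_used &
                 pos_peaks$peak_index >= v_candidates$lb[u] &
                 pos_peaks$peak_index <= v_candidates$rb[d])
    if (length(hit) == 0L) next
    hit <- hit[1]
    if (pos_peaks$peak_value[hit] <= thresholds$blink) next
    pos_used[hit] <- TRUE
    # the whole up-and-down excursion belongs to the blink: consume every
    # vertical velocity candidate peaking inside the positional blink span
    # (double-peaked blinks leave more than one up- or down-peak); peaks
    # outside the span are distinct movements even if their bounds touch it
    used <- used | (v_candidates$peak_index >= pos_peaks$lb[hit] &
                    v_candidates$peak_index <= pos_peaks$rb[hit])
    used[u] <- TRUE
    used[d] <- TRUE
    blinks[[length(blinks) + 1L]] <- data.frame(
      onset = pos_peaks$lb[hit], offset = pos_peaks$rb[hit],
      peak = pos_peaks$peak_index[hit],
      v_peak_value = pos_peaks$peak_value[hit],
      up_peak_index = v_candidates$peak_index[u],
      down_peak_index = v_candidates$peak_index[d])
  }
  blinks <- if (length(blinks)) do.call(rbind, blinks) else empty_blinks
  list(blinks = blinks,
       v_candidates = v_candidates[!used, , drop = FALSE])
}
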