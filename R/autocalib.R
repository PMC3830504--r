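# Auto-calibration: amplitude thresholds for saccades and blinks are
# estimated from the recording itself. All local peak amplitudes are sorted
# and scaled to [0, 1]; the resulting curve rises slowly through the dense
# noise floor and steeply through the sparse event peaks, and the knee
# between the two regimes is located by a two-line least-squares pivot
# search. The threshold is placed 2% above the knee amplitude.

#' Collect local peak amplitudes of the absolute signal
#'
#' Extracts `|x[i]|` at every interior index where the absolute signal is
#' strictly larger than both neighbours. A flat plateau maximum contributes
#' its leftmost sample once.
#'
#' @param samples Numeric vector, length >= 3.
#' @return Numeric vector of peak amplitudes in input units.
#' @export
collect_peak_amplitudes <- function(samples) {
  a <- abs(as.numeric(samples))
  n <- length(a)
  if (n < 3L) stop("need at least 3 samples to find local maxima",
                   call. = FALSE)
  r <- rle(a)
  k <- length(r$values)
  if (k < 3L) return(numeric(0))
  interior <- 2:(k - 1L)
  is_max <- r$values[interior] > r$values[interior - 1L] &
            r$values[interior] > r$values[interior + 1L]
  r$values[interior][is_max]
}

#' Build the sorted, scaled peak-amplitude curve
#'
#' Peak amplitudes are sorted ascending and divided by their maximum so the
#' curve spans \[0, 1\]; the original maximum is kept as `scale_max` so that
#' scaled amplitudes can be mapped back to signal units.
#'
#' @param amplitudes Numeric vector of peak amplitudes.
#' @param min_peaks Minimum number of peaks required to calibrate
#'   (default 30); below this the recording is declared too short.
#' @return An object of class `peak_curve`: list with `values` (ascending,
#'   in \[0, 1\]), `scale_max` (signal units mapped to 1.0), `n_raw` and `n`.
#' @export
build_peak_curve <- function(amplitudes, min_peaks = 30) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < min_peaks) {
    stop("only ", length(amplitudes), " peaks found; at least ", min_peaks,
         " are needed to auto-calibrate - provide a longer recording",
         call. = FALSE)
  }
  s <- sort(amplitudes)
  scale_max <- s[length(s)]
  if (scale_max <= 0) {
    stop("all peak amplitudes are zero; cannot calibrate", call. = FALSE)
  }
  structure(list(values = s / scale_max, scale_max = scale_max,
                 n_raw = length(s), n = length(s)),
            class = "peak_curve")
}

#' @export
print.peak_curve <- function(x, ...) {
  cat(sprintf("<peak_curve> n = %d (raw %d), scale_max = %.3g\n",
              x$n, x$n_raw, x$scale_max))
  invisible(x)
}

#' Trim large artifact peaks from the top of a peak curve
#'
#' Scanning downward from the largest scaled peak, values are discarded while
#' the gap to the next lower peak is at least `delta`; the scan stops at the
#' first adjacent pair closer than `delta`, which is retained together with
#' everything below it. Isolated huge artifacts sit far above the continuum
#' of genuine peaks and are removed; the dense body of the curve is not
#' touched. By default the curve is re-scaled to \[0, 1\] afterwards so the
#' pivot amplitude stays interpretable when artifacts were removed.
#'
#' @param curve A [build_peak_curve()] result.
#' @param delta Gap (in scaled units of the incoming curve) at or above which
#'   a top peak is an outlier; default 0.03.
#' @param rescale Re-scale to \[0, 1\] after trimming (default `TRUE`).
#' @return A `peak_curve` with outliers removed; `n` and `scale_max` updated,
#'   `n_raw` preserved.
#' @export
trim_artifacts <- function(curve, delta = 0.03, rescale = TRUE) {
  stopifnot(inherits(curve, "peak_curve"))
  v <- curve$values
  n <- length(v)
  keep <- n
  while (keep >= 2L && (v[keep] - v[keep - 1L]) >= delta) {
    keep <- keep - 1L
  }
  if (keep == n) return(curve)
  v <- v[seq_len(keep)]
  scale_max <- curve$scale_max
  if (rescale) {
    top <- v[length(v)]
    if (top <= 0) stop("peak curve degenerate after trimming", call. = FALSE)
    scale_max <- scale_max * top
    v <- v / top
  }
  structure(list(values = v, scale_max = scale_max,
                 n_raw = curve$n_raw, n = length(v)),
            class = "peak_curve")
}

# Summed residual sums of squares of the two straight-line fits obtained by
# splitting y[1..N] (x = rank) at every candidate n: left fit on 1..n, right
# fit on (n+1)..N. Closed form via prefix sums; O(N) over all splits.
two_line_sse <- function(y, splits) {
  n_tot <- length(y)
  x <- as.numeric(seq_len(n_tot))
  c_x <- cumsum(x); c_y <- cumsum(y)
  c_xx <- cumsum(x * x); c_xy <- cumsum(x * y); c_yy <- cumsum(y * y)
  seg_sse <- function(i, j) {           # vectors i, j of equal length
    n <- j - i + 1
    sx <- c_x[j] - ifelse(i > 1, c_x[i - 1], 0)
    sy <- c_y[j] - ifelse(i > 1, c_y[i - 1], 0)
    sxx <- c_xx[j] - ifelse(i > 1, c_xx[i - 1], 0)
    sxy <- c_xy[j] - ifelse(i > 1, c_xy[i - 1], 0)
    syy <- c_yy[j] - ifelse(i > 1, c_yy[i - 1], 0)
    vxx <- sxx - sx^2 / n
    vxy <- sxy - sx * sy / n
    vyy <- syy - sy^2 / n
    sse <- ifelse(vxx > 0, vyy - vxy^2 / vxx, vyy)
    pmax(sse, 0)
  }
  seg_sse(rep(1L, length(splits)), splits) +
    seg_sse(splits + 1L, rep(n_tot, length(splits)))
}

#' Locate the noise/event pivot on a peak curve
#'
#' For every candidate split index `n` in `[n_min, N - n_min]` a straight
#' line is fit (rank as abscissa) to the lower segment `values[1..n]` and
#' another to the upper segment `values[(n+1)..N]`; the split minimizing the
#' summed least-squares error is the candidate pivot. Ties (within relative
#' tolerance 1e-9) are broken toward the smaller index, which yields the
#' more conservative (lower) threshold. The final pivot amplitude is placed
#' `margin` (default 2%) above the candidate's amplitude, and mapped back to
#' signal units through the curve's `scale_max`.
#'
#' @param curve A (typically [trim_artifacts()]-ed) `peak_curve` with
#'   `n >= 2 * n_min`.
#' @param n_min Minimum segment length for each line fit; default 10.
#' @param margin Multiplicative safety margin above the knee amplitude;
#'   default 1.02.
#' @return An object of class `pivot_result`: list with `n_star` (pivot
#'   rank), `d_n_amplitude` (scaled knee amplitude), `d_p_amplitude`
#'   (`margin * d_n_amplitude`), `threshold` (signal units) and `lse_total`.
#' @export
find_pivot <- function(curve, n_min = 10, margin = 1.02) {
  stopifnot(inherits(curve, "peak_curve"))
  v <- curve$values
  n_tot <- length(v)
  if (n_tot < 2 * n_min) {
    stop("peak curve has ", n_tot, " points; at least ", 2 * n_min,
         " are needed for the pivot search - provide a longer recording",
         call. = FALSE)
  }
  splits <- n_min:(n_tot - n_min)
  sse <- two_line_sse(v, splits)
  best <- min(sse)
  tol <- best * 1e-9 + 1e-12
  n_star <- splits[which(sse <= best + tol)[1]]
  d_n <- v[n_star]
  d_p <- margin * d_n
  structure(list(n_star = n_star, d_n_amplitude = d_n, d_p_amplitude = d_p,
                 threshold = d_p * curve$scale_max,
                 lse_total = sse[match(n_star, splits)]),
            class = "pivot_result")
}

#' @export
print.pivot_result <- function(x, ...) {
  cat(sprintf("<pivot_result> n* = %d, d_n = %.4f, d_p = %.4f, threshold = %.4g\n",
              x$n_star, x$d_n_amplitude, x$d_p_amplitude, x$threshold))
  invisible(x)
}

calibrate_channel <- function(samples, channel,
                              delta = 0.03, n_min = 10, margin = 1.02,
                              min_peaks = 30, rescale_after_trim = TRUE) {
  amps <- tryCatch(collect_peak_amplitudes(samples), error = function(e) {
    stop("channel ", channel, ": ", conditionMessage(e), call. = FALSE)
  })
  curve <- tryCatch(build_peak_curve(amps, min_peaks = min_peaks),
                    error = function(e) {
    stop("channel ", channel, ": ", conditionMessage(e), call. = FALSE)
  })
  curve <- trim_artifacts(curve, delta = delta, rescale = rescale_after_trim)
  pivot <- tryCatch(find_pivot(curve, n_min = n_min, margin = margin),
                    error = function(e) {
    stop("channel ", channel, ": ", conditionMessage(e), call. = FALSE)
  })
  list(curve = curve, pivot = pivot, threshold = pivot$threshold)
}

#' Estimate the three amplitude thresholds from a preprocessed recording
#'
#' The horizontal and vertical saccade thresholds are calibrated on the
#' absolute velocity signals (microvolts/second); the blink threshold on the
#' positive part of the detrended vertical positional signal (microvolts),
#' since blinks deflect the up-minus-down derivation upward. Each channel is
#' calibrated independently with the collect / sort-and-scale / trim /
#' pivot-search chain.
#'
#' @param clean Detrended, denoised [eog_recording()] (from
#'   [preprocess_recording()]).
#' @param vel_h,vel_v The corresponding `velocity_signal`s.
#' @param delta Outlier trimming gap (scaled units); default 0.03.
#' @param n_min Minimum pivot segment length; default 10.
#' @param margin Pivot safety margin; default 1.02.
#' @param min_peaks Minimum peak count per channel; default 30.
#' @param blink_use_abs Calibrate the blink threshold on `|eog_v|` instead of
#'   its positive part (default `FALSE`).
#' @param rescale_after_trim Re-scale the peak curve after artifact trimming
#'   (default `TRUE`).
#'
#' @return An object of class `threshold_set`: list with `h_saccade`,
#'   `v_saccade` (microvolts/second) and `blink` (microvolts); per-channel
#'   peak curves and pivot results are attached as the `"diagnostics"`
#'   attribute.
#' @export
estimate_thresholds <- function(clean, vel_h, vel_v,
                                delta = 0.03, n_min = 10, margin = 1.02,
                                min_peaks = 30, blink_use_abs = FALSE,
                                rescale_after_trim = TRUE) {
  stopifnot(inherits(clean, "eog_recording"),
            inherits(vel_h, "velocity_signal"),
            inherits(vel_v, "velocity_signal"))
  blink_signal <- if (blink_use_abs) abs(clean$eog_v) else pmax(clean$eog_v, 0)
  h <- calibrate_channel(vel_h$samples, "h_saccade (EOG_h velocity)",
                         delta, n_min, margin, min_peaks, rescale_after_trim)
  v <- calibrate_channel(vel_v$samples, "v_saccade (EOG_v velocity)",
                         delta, n_min, margin, min_peaks, rescale_after_trim)
  b <- calibrate_channel(blink_signal, "blink (EOG_v)",
                         delta, n_min, margin, min_peaks, rescale_after_trim)
  structure(list(h_saccade = h$threshold, v_saccade = v$threshold,
                 blink = b$threshold),
            diagnostics = list(h = h, v = v, blink = b),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> h_saccade = %.1f uV/s, v_saccade = %.1f uV/s, blink = %.1f uV\n",
    x$h_saccade, x$v_saccade, x$blink))
  invisible(x)
}
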