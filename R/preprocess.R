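#' Remove slow baseline drift with a high-degree polynomial
#'
#' Electrode polarization and skin-impedance changes add a slow wandering
#' baseline to DC-coupled EOG. The drift is modelled by a least-squares
#' polynomial (default degree 20, high enough to track realistic drift while
#' leaving step-like eye movements in the residual) and subtracted. The time
#' axis is normalized to \[-1, 1\] before fitting so that the Vandermonde
#' system stays well conditioned at high degree; the fit itself is solved by
#' QR decomposition.
#'
#' @param samples Numeric vector in microvolts.
#' @param degree Polynomial degree (>= 1); default 20.
#'
#' @return An object of class `baseline_fit`: list with `degree`,
#'   `coefficients` (monomial coefficients over normalized time, ascending
#'   powers), `fitted`, `residual` (the detrended signal) and `r_squared`
#'   (1 - SS_res/SS_tot; defined as 0 for a constant input).
#' @export
remove_baseline <- function(samples, degree = 20) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  if (n <= degree + 1) {
    stop("input too short (", n, " samples) for a degree-", degree,
         " baseline fit; need more than ", degree + 1, call. = FALSE)
  }
  t_norm <- seq(-1, 1, length.out = n)
  V <- outer(t_norm, 0:degree, `^`)
  qr_v <- qr(V)
  if (qr_v$rank < degree + 1) {
    stop("baseline fit is rank deficient (rank ", qr_v$rank, " < ",
         degree + 1, "); lower the degree", call. = FALSE)
  }
  coef <- qr.coef(qr_v, samples)
  fitted <- drop(V %*% coef)
  residual <- samples - fitted
  ss_tot <- sum((samples - mean(samples))^2)
  r_squared <- if (ss_tot <= 0) 0 else max(0, min(1, 1 - sum(residual^2) / ss_tot))
  structure(list(degree = degree, coefficients = coef, fitted = fitted,
                 residual = residual, r_squared = r_squared),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> degree %d, R^2 = %.4f, %d samples\n",
              x$degree, x$r_squared, length(x$residual)))
  invisible(x)
}

# Haar band truncation as a recursive block-average projection. Zeroing the
# j finest detail levels of a Haar decomposition and reconstructing is
# exactly the replacement of each 2^j block by its mean; lengths that are
# not multiples of 2 carry the odd tail sample through untouched at each
# level. The Haar filters are two taps long, so no boundary extension is
# needed and the operation is an exact linear projection (idempotent).
haar_block_smooth <- function(x, levels) {
  n <- length(x)
  if (levels < 1L || n < 2L) return(x)
  m <- n %/% 2L
  odd_idx <- seq(1L, 2L * m, by = 2L)
  approx <- (x[odd_idx] + x[odd_idx + 1L]) / 2
  approx <- haar_block_smooth(approx, levels - 1L)
  out <- numeric(n)
  out[odd_idx] <- approx
  out[odd_idx + 1L] <- approx
  if (n %% 2L == 1L) out[n] <- x[n]
  out
}

#' Haar wavelet denoising by high-band truncation
#'
#' Decomposes the signal with Haar wavelets and zeroes every detail level
#' whose frequency band lies entirely above the cutoff, then reconstructs.
#' Level `j` (1 = finest) covers approximately
#' `[fs / 2^(j+1), fs / 2^j]` Hz; a level is removed when its band lower
#' edge `fs / 2^(j+1)` is at or above `cutoff_hz`. At a 500 Hz sampling rate
#' with the default 100 Hz cutoff this removes level 1 (125-250 Hz) only,
#' preserving the sub-100 Hz band where saccade and blink energy lives.
#' When `fs / 2 <= cutoff_hz` there is nothing to remove and the signal is
#' returned unchanged. The truncation is an exact projection:
#' `wavelet_denoise(wavelet_denoise(x)) == wavelet_denoise(x)`.
#'
#' @param samples Numeric vector in microvolts.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Frequency above which wavelet detail bands are removed;
#'   default 100 Hz.
#' @return Denoised numeric vector, same length as the input.
#' @export
wavelet_denoise <- function(samples, fs, cutoff_hz = 100) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty input", call. = FALSE)
  stopifnot(fs > 0, cutoff_hz > 0)
  levels <- floor(log2(fs / (2 * cutoff_hz)) + 1e-9)
  if (levels < 1) return(samples)
  haar_block_smooth(samples, as.integer(levels))
}

#' Differentiate a signal into an eye-velocity trace
#'
#' Central first difference scaled by the sampling rate, so a positional
#' signal in microvolts becomes a velocity signal in microvolts per second;
#' one-sided differences are used at the two ends so the velocity trace has
#' the same length as its source. The central difference matters after Haar
#' band truncation: the truncated signal is piecewise constant over sample
#' pairs, on which a forward difference degenerates into an alternating
#' zero / double-slope comb, whereas the central difference recovers the
#' underlying slope at every sample exactly.
#'
#' @param samples Numeric vector (microvolts), length >= 2.
#' @param fs Sampling rate in Hz.
#' @param source Which channel the signal came from, `"h"` or `"v"`
#'   (bookkeeping only).
#' @return An object of class `velocity_signal`: list with `samples`
#'   (microvolts/second), `fs` and `source`.
#' @export
differentiate <- function(samples, fs, source = c("h", "v")) {
  source <- match.arg(source)
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate",
                   call. = FALSE)
  v <- numeric(n)
  if (n > 2L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  v[1L] <- (x[2L] - x[1L]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  structure(list(samples = v, fs = fs, source = source),
            class = "velocity_signal")
}

#' @export
print.velocity_signal <- function(x, ...) {
  cat(sprintf("<velocity_signal> source %s, %d samples @ %g Hz, max |v| = %.1f uV/s\n",
              x$source, length(x$samples), x$fs, max(abs(x$samples))))
  invisible(x)
}

#' Preprocess a recording: detrend, denoise, differentiate
#'
#' Applies, per channel: polynomial baseline removal, then Haar high-band
#' truncation, then differentiation. This is the artifact-removal front end
#' of the pipeline; every later stage (auto-calibration, detection) consumes
#' its outputs.
#'
#' @param rec An [eog_recording()].
#' @param degree Baseline polynomial degree (default 20).
#' @param cutoff_hz Wavelet truncation cutoff in Hz (default 100).
#' @return A list with `clean` (detrended, denoised [eog_recording()]),
#'   `vel_h` and `vel_v` (the two [differentiate()]d `velocity_signal`s) and
#'   `baseline_h`/`baseline_v` (the two `baseline_fit`s).
#' @export
preprocess_recording <- function(rec, degree = 20, cutoff_hz = 100) {
  stopifnot(inherits(rec, "eog_recording"))
  bh <- remove_baseline(rec$eog_h, degree = degree)
  bv <- remove_baseline(rec$eog_v, degree = degree)
  ch <- wavelet_denoise(bh$residual, rec$fs, cutoff_hz = cutoff_hz)
  cv <- wavelet_denoise(bv$residual, rec$fs, cutoff_hz = cutoff_hz)
  clean <- eog_recording(ch, cv, fs = rec$fs, start_time = rec$start_time,
                         meta = rec$meta)
  list(clean = clean,
       vel_h = differentiate(ch, rec$fs, source = "h"),
       vel_v = differentiate(cv, rec$fs, source = "v"),
       baseline_h = bh, baseline_v = bv)
}
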