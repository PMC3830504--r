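#' Two-channel EOG recording
#'
#' Container for a synchronized pair of horizontal and vertical
#' electro-oculogram traces sampled at a common rate. The horizontal channel
#' (`eog_h`) is the bipolar right-minus-left derivation, the vertical channel
#' (`eog_v`) the up-minus-down derivation; both are in microvolts. Every
#' analysis stage in the package consumes and returns this container.
#'
#' @param eog_h Numeric vector, horizontal EOG in microvolts.
#' @param eog_v Numeric vector, vertical EOG in microvolts; same length as
#'   `eog_h`.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param start_time Offset of the first sample in seconds (default 0).
#' @param meta Named list of free-form metadata (subject id, device, ...).
#'
#' @return An object of class `eog_recording`: a list with elements `eog_h`,
#'   `eog_v`, `fs`, `start_time` and `meta`.
#'
#' @examples
#' rec <- eog_recording(eog_h = sin(1:100 / 10), eog_v = cos(1:100 / 10),
#'                      fs = 500)
#' n_samples(rec)
#' @export
eog_recording <- function(eog_h, eog_v, fs, start_time = 0, meta = list()) {
  eog_h <- as.numeric(eog_h)
  eog_v <- as.numeric(eog_v)
  if (length(eog_h) == 0L) {
    stop("recording must contain at least one sample", call. = FALSE)
  }
  if (length(eog_h) != length(eog_v)) {
    stop("eog_h and eog_v must have equal length (got ",
         length(eog_h), " and ", length(eog_v), ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (anyNA(eog_h) || anyNA(eog_v) ||
      any(!is.finite(eog_h)) || any(!is.finite(eog_v))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  structure(
    list(eog_h = eog_h, eog_v = eog_v, fs = as.numeric(fs),
         start_time = as.numeric(start_time), meta = meta),
    class = "eog_recording"
  )
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf("<eog_recording> %d samples @ %g Hz (%.2f s)\n",
              n_samples(x), x$fs, n_samples(x) / x$fs))
  cat(sprintf("  eog_h: [%.1f, %.1f] uV   eog_v: [%.1f, %.1f] uV\n",
              min(x$eog_h), max(x$eog_h), min(x$eog_v), max(x$eog_v)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An [eog_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "eog_recording"))
  length(rec$eog_h)
}

#' Derive bipolar EOG channels from four monopolar electrodes
#'
#' Combines the four periocular electrode traces into the standard bipolar
#' derivation: horizontal EOG is the right minus the left canthus electrode,
#' vertical EOG the electrode above the eye minus the one below. Blinks and
#' upward gaze then appear as positive deflections on the vertical channel.
#'
#' @param right,left,up,down Numeric vectors of equal length, monopolar
#'   electrode potentials in microvolts.
#' @param fs Sampling rate in Hz.
#' @param start_time,meta Passed through to [eog_recording()].
#'
#' @return An [eog_recording()] with `eog_h = right - left` and
#'   `eog_v = up - down`.
#' @export
derive_bipolar <- function(right, left, up, down, fs, start_time = 0,
                           meta = list()) {
  lens <- c(length(right), length(left), length(up), length(down))
  if (length(unique(lens)) != 1L) {
    stop("all four electrode channels must have equal length (got ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  eog_recording(eog_h = right - left, eog_v = up - down, fs = fs,
                start_time = start_time, meta = meta)
}

#' The five event classes
#'
#' @return Character vector of the five event labels, in canonical order:
#'   horizontal, vertical and oblique saccades, blinks, and horizontal
#'   saccades coinciding with a blink.
#' @export
event_classes <- function() {
  c("HORIZONTAL_SACCADE", "VERTICAL_SACCADE", "OBLIQUE_SACCADE",
    "BLINK", "SACCADE_WITH_BLINK")
}
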