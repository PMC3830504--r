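# End-to-end pipeline and its configuration.

config_ranges <- function() {
  list(
    "baseline.degree"          = c(1, 50),
    "denoise.cutoff_hz"        = c(1, Inf),
    "calib.outlier_delta"      = c(0, 1),
    "calib.pivot_margin"       = c(1, 2),
    "calib.n_min"              = c(2, Inf),
    "calib.min_peaks"          = c(4, Inf),
    "detect.bound_frac"        = c(0.01, 0.9),
    "detect.max_peak_duration_s" = c(0.05, 10),
    "detect.max_blink_duration_s" = c(0.05, 10),
    "detect.overlap_min_s"     = c(0, 1),
    "filters.saccade_min_s"    = c(0, 1),
    "filters.saccade_max_s"    = c(0, 1)
  )
}

#' Pipeline configuration
#'
#' All tunables of the detection pipeline under one validated flat
#' namespace of dotted keys. Defaults: degree-20 baseline polynomial,
#' 100 Hz wavelet cutoff, 0.03 outlier gap, 2% pivot margin, 10% bound
#' value, 0.80 s maximum peak duration, 1.2 s maximum blink duration.
#' The physiological duration filters (30-80 ms saccades) are off by
#' default in the library API; the command line's robust profile enables
#' them.
#'
#' @param ... Dotted-key overrides, e.g.
#'   `eog_config(detect.bound_frac = 0.15)`.
#' @return A named list of class `eog_config`.
#' @export
eog_config <- function(...) {
  cfg <- list(
    baseline.degree = 20,
    denoise.cutoff_hz = 100,
    denoise.wavelet = "haar",
    calib.outlier_delta = 0.03,
    calib.pivot_margin = 1.02,
    calib.n_min = 10,
    calib.min_peaks = 30,
    calib.blink_use_abs = FALSE,
    calib.rescale_after_trim = TRUE,
    detect.bound_frac = 0.10,
    detect.max_peak_duration_s = 0.80,
    detect.max_blink_duration_s = 1.2,
    detect.overlap_min_s = 0,
    filters.enabled = FALSE,
    filters.saccade_min_s = 0.030,
    filters.saccade_max_s = 0.080,
    filters.blink_min_s = NA
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    cfg[[key]] <- overrides[[key]]
  }
  ranges <- config_ranges()
  for (key in names(ranges)) {
    val <- cfg[[key]]
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < ranges[[key]][1] || val > ranges[[key]][2]) {
      stop("configuration key ", key, " = ", format(cfg[[key]]),
           " outside its valid range [", ranges[[key]][1], ", ",
           ranges[[key]][2], "]", call. = FALSE)
    }
  }
  if (!identical(cfg$denoise.wavelet, "haar")) {
    stop("only the haar wavelet is supported", call. = FALSE)
  }
  if (cfg$filters.saccade_min_s > cfg$filters.saccade_max_s) {
    stop("filters.saccade_min_s must not exceed filters.saccade_max_s",
         call. = FALSE)
  }
  structure(cfg, class = c("eog_config", "list"))
}

#' Run the full auto-calibrating detection pipeline
#'
#' Preprocesses the recording (baseline removal, wavelet truncation,
#' differentiation), auto-calibrates the three amplitude thresholds from the
#' signal itself, extracts saccade candidates and blinks, classifies them
#' into the five event classes, optionally applies the physiological
#' duration filters, and fills the per-event measures. No user calibration
#' or manual threshold is involved at any point.
#'
#' @param rec An [eog_recording()].
#' @param config An [eog_config()].
#' @return An object of class `eog_analysis`: list with `events` (an
#'   `eog_events` data frame with measures), `thresholds`
#'   (a `threshold_set`), `counts` (per-class), `config` and
#'   `stage_counts` (candidate counts per stage).
#' @export
detect_events <- function(rec, config = eog_config()) {
  stopifnot(inherits(rec, "eog_recording"))
  if (!inherits(config, "eog_config")) config <- eog_config(config)
  pre <- preprocess_recording(rec, degree = config$baseline.degree,
                              cutoff_hz = config$denoise.cutoff_hz)
  thresholds <- estimate_thresholds(
    pre$clean, pre$vel_h, pre$vel_v,
    delta = config$calib.outlier_delta,
    n_min = config$calib.n_min,
    margin = config$calib.pivot_margin,
    min_peaks = config$calib.min_peaks,
    blink_use_abs = config$calib.blink_use_abs,
    rescale_after_trim = config$calib.rescale_after_trim)
  h_cand <- extract_saccade_candidates(
    pre$vel_h, thresholds$h_saccade,
    bound_frac = config$detect.bound_frac,
    max_peak_duration_s = config$detect.max_peak_duration_s)
  bl <- detect_blinks(
    pre$clean$eog_v, pre$vel_v, thresholds, rec$fs,
    max_blink_duration_s = config$detect.max_blink_duration_s,
    bound_frac = config$detect.bound_frac,
    max_peak_duration_s = config$detect.max_peak_duration_s)
  events <- classify_events(h_cand, bl$v_candidates, bl$blinks, rec$fs,
                            overlap_min_s = config$detect.overlap_min_s)
  events <- compute_measures(events, pre$clean, pre$vel_h, pre$vel_v)
  if (isTRUE(config$filters.enabled)) {
    blink_min <- config$filters.blink_min_s
    events <- apply_duration_filters(
      events,
      saccade_min_s = config$filters.saccade_min_s,
      saccade_max_s = config$filters.saccade_max_s,
      blink_min_s = if (is.na(blink_min)) NULL else blink_min)
  }
  structure(list(
    events = events,
    thresholds = thresholds,
    counts = event_counts(events),
    config = config,
    stage_counts = c(h_candidates = nrow(h_cand),
                     v_candidates = nrow(bl$v_candidates),
                     blinks = nrow(bl$blinks),
                     events = nrow(events))),
    class = "eog_analysis")
}

#' @export
print.eog_analysis <- function(x, ...) {
  cat("<eog_analysis>\n")
  print(x$thresholds)
  cnt <- x$counts
  for (cl in names(cnt)) cat(sprintf("  %-20s %d\n", cl, cnt[[cl]]))
  invisible(x)
}
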