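# Per-event temporal and kinematic measures, and the voltage-to-degree
# calibration from reference saccades of known amplitude.

#' Fill per-event temporal and kinematic measures
#'
#' For every event: `duration_s = (offset - onset)/fs`. For saccades, peak
#' velocity is the maximum absolute velocity on the event's axis within the
#' event (for oblique saccades the per-axis maxima are reported alongside
#' their Euclidean combination), and acceleration/deceleration are the
#' maximum/minimum of the forward-differenced velocity within the event
#' (microvolts/second^2). For blinks, the eye closing time is the time from
#' onset to the positional peak and the opening time from the peak to the
#' offset; they sum to the duration by construction. Event amplitude is the
#' positional signal change from left to right bound on the dominant axis
#' (saccades are steps); for blinks, whose positional profile is a pulse,
#' it is the peak value above the mean of the two bound values.
#'
#' @param events An `eog_events` data frame.
#' @param clean Detrended, denoised [eog_recording()].
#' @param vel_h,vel_v `velocity_signal`s matching `clean`.
#' @return `events` with measure columns `duration_s`, `peak_velocity_uv_s`,
#'   `amplitude_uv`, `acceleration_uv_s2`, `deceleration_uv_s2`,
#'   `closing_time_s`, `opening_time_s` and (oblique only)
#'   `peak_velocity_h_uv_s`/`peak_velocity_v_uv_s`.
#' @export
compute_measures <- function(events, clean, vel_h, vel_v) {
  stopifnot(inherits(events, "eog_events"), inherits(clean, "eog_recording"))
  fs <- attr(events, "fs") %||% clean$fs
  n <- nrow(events)
  cols <- c("duration_s", "peak_velocity_uv_s", "peak_velocity_h_uv_s",
            "peak_velocity_v_uv_s", "amplitude_uv", "acceleration_uv_s2",
            "deceleration_uv_s2", "closing_time_s", "opening_time_s")
  for (cl in cols) events[[cl]] <- rep(NA_real_, n)
  if (n == 0L) return(events)
  len <- n_samples(clean)
  if (any(events$onset < 1L) || any(events$offset > len)) {
    stop("event outside the recording range", call. = FALSE)
  }
  vh <- vel_h$samples
  vv <- vel_v$samples
  for (i in seq_len(n)) {
    span <- events$onset[i]:events$offset[i]
    events$duration_s[i] <- (events$offset[i] - events$onset[i]) / fs
    label <- events$label[i]
    axis <- events$axis[i]
    pos <- if (axis == "h") clean$eog_h else clean$eog_v
    if (label == "BLINK") {
      events$closing_time_s[i] <- (events$peak[i] - events$onset[i]) / fs
      events$opening_time_s[i] <- (events$offset[i] - events$peak[i]) / fs
      # defined as the sum so closing + opening == duration holds exactly;
      # equal to (offset - onset)/fs within one ulp
      events$duration_s[i] <- events$closing_time_s[i] +
        events$opening_time_s[i]
      events$peak_velocity_uv_s[i] <- max(abs(vv[span]))
      bound_mean <- (pos[events$onset[i]] + pos[events$offset[i]]) / 2
      events$amplitude_uv[i] <- pos[events$peak[i]] - bound_mean
      acc <- diff(vv[span]) * fs
      if (length(acc)) {
        events$acceleration_uv_s2[i] <- max(acc)
        events$deceleration_uv_s2[i] <- min(acc)
      }
    } else {
      vel <- if (axis == "h") vh else vv
      if (label == "OBLIQUE_SACCADE") {
        pv_h <- max(abs(vh[span]))
        pv_v <- max(abs(vv[span]))
        events$peak_velocity_h_uv_s[i] <- pv_h
        events$peak_velocity_v_uv_s[i] <- pv_v
        events$peak_velocity_uv_s[i] <- sqrt(pv_h^2 + pv_v^2)
      } else {
        events$peak_velocity_uv_s[i] <- max(abs(vel[span]))
      }
      events$amplitude_uv[i] <- abs(pos[events$offset[i]] -
                                    pos[events$onset[i]])
      acc <- diff(vel[span]) * fs
      if (length(acc)) {
        events$acceleration_uv_s2[i] <- max(acc)
        events$deceleration_uv_s2[i] <- min(acc)
      }
    }
  }
  events
}

#' Calibrate the voltage-to-degree gain from reference saccades
#'
#' EOG amplitudes are in microvolts; expressing saccade kinematics in the
#' conventional degrees-per-second requires the corneo-retinal gain. It is
#' estimated from a small set of reference saccades of known amplitude
#' (canonically a handful of 10-degree horizontal saccades):
#' `uv_per_deg = mean(amplitude_uv) / reference_amplitude_deg`.
#'
#' @param reference_events `eog_events` rows with `amplitude_uv` filled
#'   (see [compute_measures()]); typically horizontal saccades made to a
#'   known target displacement.
#' @param reference_amplitude_deg Nominal amplitude of the reference
#'   saccades in degrees; default 10.
#' @return An object of class `calibration_gain`: list with `uv_per_deg`,
#'   `n_reference` and `reference_amplitude_deg`.
#' @export
calibrate_gain <- function(reference_events, reference_amplitude_deg = 10) {
  if (is.null(reference_events) || nrow(reference_events) == 0L) {
    stop("at least one reference saccade is required to calibrate the gain",
         call. = FALSE)
  }
  amp <- reference_events$amplitude_uv
  if (is.null(amp) || anyNA(amp)) {
    stop("reference events must have amplitude_uv computed ",
         "(run compute_measures first)", call. = FALSE)
  }
  gain <- mean(amp) / reference_amplitude_deg
  if (gain <= 0) stop("non-positive calibration gain", call. = FALSE)
  structure(list(uv_per_deg = gain, n_reference = nrow(reference_events),
                 reference_amplitude_deg = reference_amplitude_deg),
            class = "calibration_gain")
}

#' @export
print.calibration_gain <- function(x, ...) {
  cat(sprintf("<calibration_gain> %.2f uV/deg (from %d reference saccades of %g deg)\n",
              x$uv_per_deg, x$n_reference, x$reference_amplitude_deg))
  invisible(x)
}

#' Convert saccade peak velocities to degrees per second
#'
#' @param events An `eog_events` data frame with `peak_velocity_uv_s`.
#' @param gain A [calibrate_gain()] result.
#' @return `events` with a `peak_velocity_deg_s` column added for saccade
#'   classes.
#' @export
convert_to_degrees <- function(events, gain) {
  stopifnot(inherits(gain, "calibration_gain"))
  events$peak_velocity_deg_s <- rep(NA_real_, nrow(events))
  is_sac <- events$label %in% c("HORIZONTAL_SACCADE", "VERTICAL_SACCADE",
                                "OBLIQUE_SACCADE", "SACCADE_WITH_BLINK")
  events$peak_velocity_deg_s[is_sac] <-
    events$peak_velocity_uv_s[is_sac] / gain$uv_per_deg
  events
}

#' Summarize an event table per class
#'
#' @param events An `eog_events` data frame with measures filled.
#' @param total_duration_s Recording length in seconds (for rates); taken
#'   from the `fs` attribute and maximum offset when `NULL` (then a lower
#'   bound).
#' @return A data frame with one row per class in canonical order: `count`,
#'   `rate_per_min`, `duration_mean_s`, `duration_sd_s`,
#'   `peak_velocity_mean_uv_s`, `peak_velocity_sd_uv_s` (means/SDs are `NA`
#'   when undefined).
#' @export
summarize_events <- function(events, total_duration_s = NULL) {
  fs <- attr(events, "fs")
  if (is.null(total_duration_s)) {
    total_duration_s <- if (nrow(events) > 0L) max(events$offset) / fs else NA_real_
  }
  classes <- event_classes()
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1L) stats::sd(x) else NA_real_)
  }
  out <- data.frame(label = classes, count = 0L, rate_per_min = NA_real_,
                    duration_mean_s = NA_real_, duration_sd_s = NA_real_,
                    peak_velocity_mean_uv_s = NA_real_,
                    peak_velocity_sd_uv_s = NA_real_)
  for (i in seq_along(classes)) {
    sel <- events$label == classes[i]
    out$count[i] <- sum(sel)
    if (!is.na(total_duration_s) && total_duration_s > 0) {
      out$rate_per_min[i] <- sum(sel) / (total_duration_s / 60)
    }
    if (any(sel)) {
      d <- msd(events$duration_s[sel])
      out$duration_mean_s[i] <- d[1]; out$duration_sd_s[i] <- d[2]
      if ("peak_velocity_uv_s" %in% names(events)) {
        v <- msd(events$peak_velocity_uv_s[sel])
        out$peak_velocity_mean_uv_s[i] <- v[1]
        out$peak_velocity_sd_uv_s[i] <- v[2]
      }
    }
  }
  out
}
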