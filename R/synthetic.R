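# Ground-truth synthetic EOG: main-sequence saccades (logistic position
# steps), asymmetric blink pulses, slow sinusoidal baseline drift,
# band-limited broadband noise, powerline interference and sparse
# high-amplitude artifact spikes, with every injected event annotated.

# Normative amplitude -> duration map for horizontal saccades (ms), with
# between-saccade standard deviations; linearly interpolated in between.
saccade_duration_table <- function() {
  data.frame(amplitude_deg = c(2.5, 5, 7.5, 10),
             duration_ms = c(37, 45, 51, 55),
             sd_ms = c(13, 10, 7, 12))
}

# Width factor of the logistic pulse: the 10%-of-peak velocity bound sits at
# sech^2(k t / 2) = 0.1, i.e. k * duration = 4 * acosh(sqrt(10)).
logistic_width_constant <- function() 4 * acosh(sqrt(10))

interp_saccade_duration <- function(amplitude_deg) {
  tab <- saccade_duration_table()
  list(
    mean_s = stats::approx(tab$amplitude_deg, tab$duration_ms, amplitude_deg,
                           rule = 2)$y / 1000,
    sd_s = stats::approx(tab$amplitude_deg, tab$sd_ms, amplitude_deg,
                         rule = 2)$y / 1000)
}

#' Synthetic saccade waveform
#'
#' Positional profile of a saccade as a smooth logistic step of height
#' `amplitude_deg * gain_uv_per_deg`, projected onto the horizontal and
#' vertical channels by the movement direction. The step steepness is set so
#' that the velocity pulse measured at its 10%-of-peak bounds lasts
#' `duration_s`; when no duration is given it follows the normative
#' amplitude-duration map (37 ms at 2.5 deg up to 55 ms at 10 deg,
#' interpolated linearly).
#'
#' @param amplitude_deg Saccade amplitude in degrees of visual angle (> 0).
#' @param direction_deg Movement direction in degrees (0 = rightward,
#'   90 = upward).
#' @param fs Sampling rate in Hz.
#' @param gain_uv_per_deg EOG gain in microvolts per degree; default 13.
#' @param duration_s Velocity-pulse duration (10% bounds) in seconds;
#'   `NULL` (default) uses the normative map.
#'
#' @return A list: `h`, `v` (positional pulse windows in microvolts, rising
#'   from 0 to the per-axis step height), `duration_s`, `peak_index` (index
#'   of the velocity peak inside the window), `peak_velocity_uv_s` (analytic
#'   maximum of the vector velocity), `step_h_uv`, `step_v_uv`.
#' @export
saccade_waveform <- function(amplitude_deg, direction_deg, fs,
                             gain_uv_per_deg = 13, duration_s = NULL) {
  if (!is.numeric(amplitude_deg) || amplitude_deg <= 0) {
    stop("saccade amplitude must be positive", call. = FALSE)
  }
  if (is.null(duration_s)) {
    duration_s <- interp_saccade_duration(amplitude_deg)$mean_s
  }
  amp_uv <- amplitude_deg * gain_uv_per_deg
  k <- logistic_width_constant() / duration_s
  half <- ceiling(duration_s * fs)
  t <- (seq(-half, half) / fs)
  prof <- stats::plogis(k * t)
  step_h <- amp_uv * cospi(direction_deg / 180)
  step_v <- amp_uv * sinpi(direction_deg / 180)
  list(h = step_h * prof, v = step_v * prof,
       duration_s = duration_s,
       peak_index = half + 1L,
       peak_velocity_uv_s = amp_uv * k / 4,
       step_h_uv = step_h, step_v_uv = step_v)
}

#' Synthetic blink waveform
#'
#' An asymmetric smooth pulse on the vertical channel: a half-cosine rise
#' (eyelid closing) over `asymmetry * duration_s` followed by a half-cosine
#' fall (opening) over the remainder. The default asymmetry of 0.4 makes
#' closing faster than opening, as in real blinks.
#'
#' @param amplitude_uv Pulse height in microvolts.
#' @param duration_s Total pulse duration in seconds, within \[0.1, 1.0\].
#' @param asymmetry Fraction of the duration spent closing; default 0.4.
#' @param fs Sampling rate in Hz.
#' @return A list: `v` (the pulse, microvolts), `peak_index`, `duration_s`.
#' @export
blink_waveform <- function(amplitude_uv, duration_s, asymmetry = 0.4,
                           fs = 500) {
  if (duration_s < 0.1 || duration_s > 1.0) {
    stop("blink duration must lie in [0.1, 1.0] s, got ", duration_s,
         call. = FALSE)
  }
  stopifnot(asymmetry > 0, asymmetry < 1)
  n <- round(duration_s * fs)
  rise_n <- max(2L, round(asymmetry * n))
  fall_n <- max(2L, n - rise_n)
  t_rise <- seq(0, 1, length.out = rise_n + 1L)
  t_fall <- seq(0, 1, length.out = fall_n + 1L)[-1]
  pulse <- amplitude_uv * c((1 - cospi(t_rise)) / 2, (1 + cospi(t_fall)) / 2)
  list(v = pulse, peak_index = rise_n + 1L, duration_s = duration_s)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic EOG generator.
#' Defaults emulate a DC-coupled 500 Hz laboratory recording of a gaze task:
#' main-sequence saccades of 2.5-10 degrees along eight directions at a gain
#' of 13 uV/deg, blinks of ~300 uV lasting ~250 ms, slow (< 0.05 Hz)
#' baseline drift of ~100 uV, 0.4 uV RMS broadband white noise, 0.3 uV of
#' residual 50 Hz powerline pickup and occasional large artifact spikes.
#'
#' @param fs Sampling rate in Hz (default 500).
#' @param duration_s Recording length in seconds (default 60).
#' @param n_saccades,n_blinks,n_artifacts Event counts (defaults 40, 15, 2).
#' @param saccade_amplitudes_deg Amplitudes sampled per saccade (default
#'   `c(2.5, 5, 7.5, 10)`).
#' @param directions_deg Directions sampled per saccade (default the eight
#'   45-degree multiples).
#' @param gain_uv_per_deg EOG gain (default 13).
#' @param drift List with `amplitude_uv` (approximate peak-to-peak, default
#'   100) and `max_freq_hz` (default 0.05).
#' @param noise List with `white_sd_uv` (broadband noise RMS, default 0.4,
#'   a shielded-laboratory floor),
#'   `bandwidth_hz` (optional low-pass corner for the noise; `NULL`, the
#'   default, leaves it flat to Nyquist), `powerline_amp_uv` (default 0.3,
#'   a shielded-laboratory residual), `powerline_hz` (default 50).
#' @param blink List with `amplitude_uv` (default 300), `amplitude_sd_uv`
#'   (default 30), `duration_mean_s` (default 0.25), `duration_sd_s`
#'   (default 0.05), `asymmetry` (default 0.4).
#' @param duration_jitter Draw saccade durations with the normative
#'   between-saccade SD (default `TRUE`); `FALSE` uses the map means
#'   exactly.
#' @param min_gap_s Minimum gap between placed events (default 0.15 s).
#' @param seed Integer seed for reproducible generation, or `NULL`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(fs = 500, duration_s = 60, n_saccades = 40,
                       saccade_amplitudes_deg = c(2.5, 5, 7.5, 10),
                       directions_deg = seq(0, 315, by = 45),
                       n_blinks = 15, n_artifacts = 2,
                       gain_uv_per_deg = 13,
                       drift = list(amplitude_uv = 100, max_freq_hz = 0.05),
                       noise = list(white_sd_uv = 0.4, bandwidth_hz = NULL,
                                    powerline_amp_uv = 0.3, powerline_hz = 50),
                       blink = list(amplitude_uv = 300, amplitude_sd_uv = 30,
                                    duration_mean_s = 0.25,
                                    duration_sd_s = 0.05, asymmetry = 0.4),
                       duration_jitter = TRUE, min_gap_s = 0.15,
                       seed = NULL) {
  defaults <- formals(sim_config)
  merge_opts <- function(given, def) {
    out <- def
    for (nm in names(given)) out[nm] <- list(given[[nm]])
    out
  }
  drift <- merge_opts(drift, eval(defaults$drift))
  noise <- merge_opts(noise, eval(defaults$noise))
  blink <- merge_opts(blink, eval(defaults$blink))
  stopifnot(fs > 0, duration_s > 0, n_saccades >= 0, n_blinks >= 0,
            n_artifacts >= 0, gain_uv_per_deg > 0,
            all(saccade_amplitudes_deg > 0))
  structure(list(fs = fs, duration_s = duration_s, n_saccades = n_saccades,
                 saccade_amplitudes_deg = saccade_amplitudes_deg,
                 directions_deg = directions_deg, n_blinks = n_blinks,
                 n_artifacts = n_artifacts,
                 gain_uv_per_deg = gain_uv_per_deg, drift = drift,
                 noise = noise, blink = blink,
                 duration_jitter = isTRUE(duration_jitter),
                 min_gap_s = min_gap_s, seed = seed),
            class = "sim_config")
}

# sample() treats a scalar first argument as 1:x; guard against that
pick_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

band_limited_noise <- function(n, fs, sd_uv, bandwidth_hz) {
  if (sd_uv <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (!is.null(bandwidth_hz) && bandwidth_hz > 0 && bandwidth_hz < fs / 2) {
    bf <- signal::butter(4, 2 * bandwidth_hz / fs, type = "low")
    w <- as.numeric(signal::filtfilt(bf, w))
  }
  s <- stats::sd(w)
  if (s > 0) w * (sd_uv / s) else w
}

#' Generate a ground-truth-annotated synthetic EOG recording
#'
#' Events (saccades, blinks, artifact spikes) are placed at uniformly random
#' non-overlapping onsets separated by at least the configured gap. Saccade
#' amplitude and direction are drawn from the configured sets; the direction
#' is reversed when a step would carry gaze further from centre, emulating a
#' fixation-and-return gaze task and keeping the positional signal bounded.
#' Drift is the sum of up to five random-phase sinusoids below the
#' configured maximum frequency. Generation is fully deterministic for a
#' fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list: `recording` (an [eog_recording()]), `truth` (an
#'   `eog_events` data frame with true `label`, `onset`, `offset`, `peak`,
#'   `duration_s`, `amplitude_deg`, `direction_deg`, `direction_sign` and
#'   analytic `peak_velocity_uv_s`), `artifacts` (spike sample indices) and
#'   `config`.
#' @export
generate_eog <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config$seed)
  }
  fs <- config$fs
  n_total <- round(config$duration_s * fs)
  gap <- round(config$min_gap_s * fs)

  # build event descriptors in random order, then place them
  kinds <- sample(c(rep("saccade", config$n_saccades),
                    rep("blink", config$n_blinks),
                    rep("artifact", config$n_artifacts)))
  waves <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    if (kinds[i] == "saccade") {
      amp <- pick_one(config$saccade_amplitudes_deg)
      dir <- pick_one(config$directions_deg)
      durs <- interp_saccade_duration(amp)
      dur <- if (config$duration_jitter) {
        min(max(stats::rnorm(1, durs$mean_s, durs$sd_s), 0.020), 0.100)
      } else durs$mean_s
      waves[[i]] <- list(kind = "saccade", amplitude_deg = amp,
                         direction_deg = dir, duration_s = dur,
                         width = 2L * ceiling(dur * fs) + 1L)
    } else if (kinds[i] == "blink") {
      dur <- min(max(stats::rnorm(1, config$blink$duration_mean_s,
                                  config$blink$duration_sd_s), 0.12), 0.60)
      amp <- max(stats::rnorm(1, config$blink$amplitude_uv,
                              config$blink$amplitude_sd_uv),
                 config$blink$amplitude_uv / 2)
      wf <- blink_waveform(amp, dur, config$blink$asymmetry, fs)
      waves[[i]] <- list(kind = "blink", amplitude_uv = amp,
                         duration_s = dur, wf = wf, width = length(wf$v))
    } else {
      # ragged spike: each sample has its own amplitude so the velocity
      # peaks of its edges differ, as for real movement artifacts
      w_art <- sample(1:3, 1L)
      base <- stats::runif(1, 5, 10) * config$blink$amplitude_uv *
        sample(c(-1, 1), 1)
      waves[[i]] <- list(kind = "artifact", width = w_art,
                         shape = base * stats::runif(w_art, 0.35, 1))
    }
  }
  widths <- vapply(waves, function(w) w$width, numeric(1))
  k <- length(waves)
  required <- sum(widths) + gap * (k + 1)
  free <- n_total - required
  if (k > 0 && free < 0) {
    stop("cannot place ", k, " events of total width ", sum(widths),
         " samples in a ", n_total, "-sample recording with ", gap,
         "-sample gaps; lengthen the recording or reduce event counts",
         call. = FALSE)
  }
  starts <- integer(0)
  if (k > 0) {
    cuts <- sort(stats::runif(k, 0, free))
    starts <- as.integer(gap + floor(cuts) +
                         cumsum(c(0, widths[-k] + gap)) + 1L)
  }

  h <- numeric(n_total)
  v <- numeric(n_total)
  truth <- list()
  artifacts <- integer(0)
  cum_h <- 0; cum_v <- 0
  for (i in seq_along(waves)) {
    w <- waves[[i]]
    s0 <- starts[i]
    if (w$kind == "saccade") {
      dir <- w$direction_deg
      dh <- w$amplitude_deg * config$gain_uv_per_deg * cospi(dir / 180)
      dv <- w$amplitude_deg * config$gain_uv_per_deg * sinpi(dir / 180)
      # revert toward centre when moving away (fixation-and-return task)
      if (abs(cum_h + dh) + abs(cum_v + dv) >
          abs(cum_h - dh) + abs(cum_v - dv)) {
        dir <- (dir + 180) %% 360
        dh <- -dh; dv <- -dv
      }
      wf <- saccade_waveform(w$amplitude_deg, dir, fs,
                             config$gain_uv_per_deg, w$duration_s)
      idx <- s0:(s0 + w$width - 1L)
      h[idx] <- h[idx] + wf$h
      v[idx] <- v[idx] + wf$v
      if (s0 + w$width <= n_total) {
        after <- (s0 + w$width):n_total
        h[after] <- h[after] + wf$step_h_uv
        v[after] <- v[after] + wf$step_v_uv
      }
      cum_h <- cum_h + dh; cum_v <- cum_v + dv
      centre <- s0 + wf$peak_index - 1L
      half_dur <- round(w$duration_s / 2 * fs)
      label <- if (dir %% 180 == 0) "HORIZONTAL_SACCADE"
               else if (dir %% 180 == 90) "VERTICAL_SACCADE"
               else "OBLIQUE_SACCADE"
      truth[[length(truth) + 1L]] <- data.frame(
        label = label, onset = centre - half_dur, offset = centre + half_dur,
        peak = centre,
        direction_sign = if (label == "VERTICAL_SACCADE")
          as.integer(sign(sinpi(dir / 180))) else
          as.integer(sign(cospi(dir / 180))),
        duration_s = w$duration_s, amplitude_deg = w$amplitude_deg,
        direction_deg = dir, peak_velocity_uv_s = wf$peak_velocity_uv_s)
    } else if (w$kind == "blink") {
      idx <- s0:(s0 + w$width - 1L)
      v[idx] <- v[idx] + w$wf$v
      truth[[length(truth) + 1L]] <- data.frame(
        label = "BLINK", onset = s0, offset = s0 + w$width - 1L,
        peak = s0 + w$wf$peak_index - 1L, direction_sign = 1L,
        duration_s = w$duration_s, amplitude_deg = NA_real_,
        direction_deg = NA_real_,
        peak_velocity_uv_s = NA_real_)
    } else {
      idx <- s0:(s0 + w$width - 1L)
      chan <- sample(c("h", "v"), 1)
      if (chan == "h") h[idx] <- h[idx] + w$shape
      else v[idx] <- v[idx] + w$shape
      artifacts <- c(artifacts, s0)
    }
  }

  t <- seq_len(n_total) / fs
  add_drift <- function() {
    if (config$drift$amplitude_uv <= 0) return(numeric(n_total))
    n_sin <- sample(3:5, 1)
    freqs <- stats::runif(n_sin, 0.005, config$drift$max_freq_hz)
    amps <- stats::runif(n_sin)
    amps <- amps / sum(amps) * config$drift$amplitude_uv / 2
    phases <- stats::runif(n_sin, 0, 2 * pi)
    out <- numeric(n_total)
    for (j in seq_len(n_sin)) {
      out <- out + amps[j] * sin(2 * pi * freqs[j] * t + phases[j])
    }
    out
  }
  h <- h + add_drift() +
    band_limited_noise(n_total, fs, config$noise$white_sd_uv,
                       config$noise$bandwidth_hz) +
    config$noise$powerline_amp_uv *
      sin(2 * pi * config$noise$powerline_hz * t + stats::runif(1, 0, 2 * pi))
  v <- v + add_drift() +
    band_limited_noise(n_total, fs, config$noise$white_sd_uv,
                       config$noise$bandwidth_hz) +
    config$noise$powerline_amp_uv *
      sin(2 * pi * config$noise$powerline_hz * t + stats::runif(1, 0, 2 * pi))

  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  truth_ev <- new_eog_events(truth_df, fs)
  list(recording = eog_recording(h, v, fs = fs,
                                 meta = list(synthetic = TRUE)),
       truth = truth_ev, artifacts = artifacts, config = config)
}
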