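# Shared fixtures and independent oracles.

# Wrap a numeric vector as a peak_curve without the min-peak check.
as_peak_curve <- function(values, scale_max = 1) {
  structure(list(values = as.numeric(values), scale_max = scale_max,
                 n_raw = length(values), n = length(values)),
            class = "peak_curve")
}

make_thresholds <- function(h = 1000, v = 1000, blink = 100) {
  structure(list(h_saccade = h, v_saccade = v, blink = blink),
            class = "threshold_set")
}

# Independent two-line least-squares pivot scan built on lm.fit.
brute_pivot <- function(v, n_min = 10) {
  N <- length(v)
  sse <- rep(NA_real_, N)
  for (n in n_min:(N - n_min)) {
    x1 <- 1:n
    x2 <- (n + 1):N
    f1 <- stats::lm.fit(cbind(1, x1), v[x1])
    f2 <- stats::lm.fit(cbind(1, x2), v[x2])
    sse[n] <- sum(f1$residuals^2) + sum(f2$residuals^2)
  }
  best <- min(sse, na.rm = TRUE)
  which(sse <= best * (1 + 1e-9) + 1e-12)[1]
}

# Exhaustive maximum bipartite matching size (recursion over detected
# events); feasible for <= ~20 events per side.
brute_max_matching <- function(dmat, tol) {
  ok <- dmat <= tol
  n_d <- nrow(ok)
  best <- 0L
  recurse <- function(i, used_t, count) {
    if (count + (n_d - i + 1L) <= best) return()
    if (i > n_d) {
      if (count > best) best <<- count
      return()
    }
    for (j in which(ok[i, ] & !used_t)) {
      used_t[j] <- TRUE
      recurse(i + 1L, used_t, count + 1L)
      used_t[j] <- FALSE
    }
    recurse(i + 1L, used_t, count)
  }
  if (n_d > 0 && ncol(ok) > 0) recurse(1L, rep(FALSE, ncol(ok)), 0L)
  best
}

# DFT band energy between f_lo and f_hi (two-sided) in Hz.
band_energy <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  sel <- (f >= f_lo & f <= f_hi) | (f >= fs - f_hi & f <= fs - f_lo)
  sum(Mod(stats::fft(x)[sel])^2)
}

# Clean single-saccade recording: one horizontal saccade, no noise/drift.
clean_saccade_recording <- function(amplitude_deg = 10, duration_s = 0.055,
                                    direction_deg = 0, fs = 500,
                                    total_s = 4) {
  wf <- saccade_waveform(amplitude_deg, direction_deg, fs,
                         duration_s = duration_s)
  n <- round(total_s * fs)
  h <- numeric(n); v <- numeric(n)
  s0 <- round(n / 2) - wf$peak_index
  idx <- (s0 + 1):(s0 + length(wf$h))
  h[idx] <- wf$h; v[idx] <- wf$v
  h[(max(idx) + 1):n] <- wf$step_h_uv
  v[(max(idx) + 1):n] <- wf$step_v_uv
  list(rec = eog_recording(h, v, fs), wf = wf,
       peak = s0 + wf$peak_index)
}

benchmark_config <- function(seed) {
  sim_config(seed = seed, n_artifacts = 0,
             saccade_amplitudes_deg = c(5, 7.5, 10))
}
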