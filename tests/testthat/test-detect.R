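test_that("bounded peaks delimit a triangular pulse at its 10% crossings", {
  fs <- 500
  # rise over [0, 0.1] s, fall over [0.1, 0.2] s, built from exact ratios so
  # both 10% crossings carry the same floating-point value
  tri <- c((0:50) / 50, (49:0) / 50, numeric(49))
  pk <- find_bounded_peaks(tri, fs, threshold = 0.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_index, 51L)             # t = 0.1 s
  expect_equal(pk$lb, 6L)                      # t = 0.01 s, value 0.10
  expect_equal(pk$rb, 96L)                     # t = 0.19 s
  expect_equal((pk$rb - pk$lb) / fs, 0.18)
  expect_equal(pk$polarity, 1L)
  expect_equal(pk$bound_level, 0.1)
  expect_error(find_bounded_peaks(tri, fs, threshold = 0), "positive")
})

test_that("peaks that never return to their bound are discarded", {
  fs <- 500
  # rises to 0.5 then stays high for more than 0.8 s
  x <- c(seq(0, 0.5, length.out = 50), rep(0.5, 600), seq(0.5, 0.4, length.out = 50))
  pk <- find_bounded_peaks(x, fs, threshold = 0.3)
  expect_equal(nrow(pk), 0L)
})

test_that("double peaks are absorbed with promotion to the taller one", {
  fs <- 500
  bump <- function(center_s, height, width_s, t) {
    pmax(0, height * (1 - abs(t - center_s) / width_s))
  }
  t <- (0:499) / fs
  # two bumps 150 ms apart; valley stays above the 10% bound
  x <- pmax(bump(0.3, 1.0, 0.12, t), bump(0.45, 1.2, 0.12, t))
  pk <- find_bounded_peaks(x, fs, threshold = 0.5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_index, which.max(x))
  expect_lt(pk$lb, round(0.3 * fs))
  expect_gt(pk$rb, round(0.45 * fs))
})

test_that("saccade candidates inherit polarity and count from the signal", {
  cs <- clean_saccade_recording(10, 0.055)
  pre <- preprocess_recording(cs$rec, degree = 5)
  cand <- extract_saccade_candidates(pre$vel_h, 1000)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$direction_sign, 1L)
  expect_equal(cand$axis, "h")
  # leftward then rightward pair
  left <- clean_saccade_recording(10, 0.055, direction_deg = 180)
  end_h <- left$rec$eog_h[n_samples(left$rec)]
  joint <- eog_recording(c(left$rec$eog_h, end_h + cs$rec$eog_h),
                         c(left$rec$eog_v, cs$rec$eog_v), 500)
  prej <- preprocess_recording(joint, degree = 5)
  cj <- extract_saccade_candidates(prej$vel_h, 1000)
  expect_equal(cj$direction_sign, c(-1L, 1L))
  # a seeded batch of saccades above threshold is recovered exactly
  sim <- generate_eog(sim_config(seed = 3, n_saccades = 30, n_blinks = 0,
                                 n_artifacts = 0, directions_deg = c(0, 180),
                                 saccade_amplitudes_deg = 10,
                                 duration_jitter = FALSE,
                                 drift = list(amplitude_uv = 0),
                                 noise = list(white_sd_uv = 0,
                                              powerline_amp_uv = 0)))
  pres <- preprocess_recording(sim$recording, degree = 5)
  cs30 <- extract_saccade_candidates(pres$vel_h, 1000)
  expect_equal(nrow(cs30), 30L)
})

test_that("blink separation follows the amplitude-threshold rule", {
  fs <- 500
  n <- 3000
  th <- make_thresholds(h = 1000, v = 1000, blink = 100)
  # a 300 uV blink pulse -> one blink, vertical candidates consumed
  v <- numeric(n)
  wf <- blink_waveform(300, 0.25, fs = fs)
  v[1001:(1000 + length(wf$v))] <- wf$v
  vel <- differentiate(v, fs, source = "v")
  out <- detect_blinks(v, vel, th, fs)
  expect_equal(nrow(out$blinks), 1L)
  expect_equal(nrow(out$v_candidates), 0L)
  expect_gt(out$blinks$v_peak_value, 100)
  # closed [onset, offset] spans the pulse
  expect_lte(out$blinks$onset, 1000 + wf$peak_index)
  expect_gte(out$blinks$offset, 1000 + wf$peak_index)

  # a sustained step: up-velocity peak without a qualifying positional
  # pulse -> no blink, candidate survives
  v2 <- 100 * stats::plogis((seq_len(n) - 1000) / 4)
  vel2 <- differentiate(v2, fs, source = "v")
  out2 <- detect_blinks(v2, vel2, th, fs)
  expect_equal(nrow(out2$blinks), 0L)
  expect_equal(nrow(out2$v_candidates), 1L)
})

test_that("interleaved blinks and vertical steps separate cleanly", {
  fs <- 500
  th <- make_thresholds(h = 1000, v = 800, blink = 150)
  n <- 40000
  v <- numeric(n)
  n_bl <- 8; n_vs <- 8
  truth_blinks <- integer(0)
  pos <- 2000
  level <- 0
  for (i in 1:8) {
    wf <- blink_waveform(300, 0.25, fs = fs)
    v[pos:(pos + length(wf$v) - 1)] <- v[pos:(pos + length(wf$v) - 1)] + wf$v
    truth_blinks <- c(truth_blinks, pos + wf$peak_index - 1L)
    pos <- pos + 2400
    # vertical step up then, 1.5 s later (outside the blink window), back down
    sw <- saccade_waveform(5, 90, fs, duration_s = 0.045)
    idx <- pos:(pos + length(sw$v) - 1)
    v[idx] <- v[idx] + sw$v
    v[(max(idx) + 1):n] <- v[(max(idx) + 1):n] + sw$step_v_uv
    pos2 <- pos + 750
    sw2 <- saccade_waveform(5, 270, fs, duration_s = 0.045)
    idx2 <- pos2:(pos2 + length(sw2$v) - 1)
    v[idx2] <- v[idx2] + sw2$v
    v[(max(idx2) + 1):n] <- v[(max(idx2) + 1):n] + sw2$step_v_uv
    pos <- pos + 2400
  }
  vel <- differentiate(v, fs, source = "v")
  out <- detect_blinks(v, vel, th, fs)
  expect_equal(nrow(out$blinks), 8L)
  expect_equal(nrow(out$v_candidates), 16L)
  # every blink peak matches an injected one within a few samples
  expect_true(all(sapply(out$blinks$peak,
                         function(p) min(abs(p - truth_blinks)) <= 3)))
})

test_that("bounded peaks respect their invariants on random signals", {
  fs <- 500
  set.seed(17)
  for (rep in 1:8) {
    x <- as.numeric(stats::filter(rnorm(4000), rep(1 / 5, 5), sides = 2))
    x[is.na(x)] <- 0
    pk <- find_bounded_peaks(x, fs, threshold = stats::sd(x))
    if (nrow(pk) == 0) next
    expect_true(all(pk$lb < pk$peak_index & pk$peak_index < pk$rb))
    expect_true(all((pk$rb - pk$lb) / fs <= 0.80 + 1e-12))
    expect_true(all(abs(x[pk$lb]) <= pk$bound_level + 1e-12))
    expect_true(all(abs(x[pk$rb]) <= pk$bound_level + 1e-12))
    # translation invariance: embedding later shifts everything exactly
    sh <- 137
    pk2 <- find_bounded_peaks(c(numeric(sh), x), fs, threshold = stats::sd(x))
    if (nrow(pk2) == nrow(pk)) {
      expect_equal(pk2$peak_index, pk$peak_index + sh)
      expect_equal(pk2$lb, pk$lb + sh)
    }
    # monotonicity: a higher threshold never yields more peaks
    pk_hi <- find_bounded_peaks(x, fs, threshold = 2 * stats::sd(x))
    expect_lte(nrow(pk_hi), nrow(pk))
  }
})
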