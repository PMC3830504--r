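make_events <- function(df, fs = 500) {
  attr(df, "fs") <- fs
  class(df) <- c("eog_events", "data.frame")
  df
}

test_that("temporal measures are exact arithmetic on sample indices", {
  fs <- 500
  n <- 2000
  clean <- eog_recording(numeric(n) + 1, numeric(n) + 1, fs)
  vh <- differentiate(clean$eog_h, fs, "h")
  vv <- differentiate(clean$eog_v, fs, "v")
  ev <- make_events(data.frame(label = c("HORIZONTAL_SACCADE", "BLINK"),
                               onset = c(100L, 100L), offset = c(190L, 250L),
                               peak = c(150L, 150L), direction_sign = 1L,
                               axis = c("h", "v")))
  out <- compute_measures(ev, clean, vh, vv)
  expect_equal(out$duration_s, c(0.18, 0.30))
  expect_equal(out$closing_time_s[2], 0.10)
  expect_equal(out$opening_time_s[2], 0.20)
  expect_equal(out$closing_time_s[2] + out$opening_time_s[2],
               out$duration_s[2])
  expect_error(compute_measures(make_events(transform(ev, offset = 99999L)),
                                clean, vh, vv), "outside")
})

test_that("saccade kinematics match the analytic logistic profile", {
  # a noise-free recording offers too few peaks for auto-calibration, so
  # detection runs here with an explicit threshold
  cs <- clean_saccade_recording(10, 0.055)
  pre <- preprocess_recording(cs$rec, degree = 5)
  cand <- extract_saccade_candidates(pre$vel_h, 1000)
  ev <- classify_events(cand, NULL, NULL, fs = 500)
  ev <- compute_measures(ev, pre$clean, pre$vel_h, pre$vel_v)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$label, "HORIZONTAL_SACCADE")
  expect_equal(ev$peak_velocity_uv_s, cs$wf$peak_velocity_uv_s,
               tolerance = 0.05)
  expect_equal(ev$amplitude_uv, 130, tolerance = 0.05 * 130)
  # acceleration positive before the peak, deceleration negative after
  expect_gt(ev$acceleration_uv_s2, 0)
  expect_lt(ev$deceleration_uv_s2, 0)
  # blink closing/opening from an asymmetric pulse
  fs <- 500; n <- 3000
  v <- numeric(n)
  wf <- blink_waveform(300, 0.3, asymmetry = 0.4, fs = fs)
  v[1001:(1000 + length(wf$v))] <- wf$v
  bl <- detect_blinks(v, differentiate(v, fs, "v"),
                      make_thresholds(blink = 100), fs)
  evb <- classify_events(NULL, bl$v_candidates, bl$blinks, fs)
  clean <- eog_recording(numeric(n), v, fs)
  evb <- compute_measures(evb, clean, differentiate(clean$eog_h, fs, "h"),
                          differentiate(v, fs, "v"))
  evb <- evb[evb$label == "BLINK", ]
  expect_equal(nrow(evb), 1L)
  expect_lt(evb$closing_time_s, evb$opening_time_s)
  expect_equal(evb$closing_time_s + evb$opening_time_s, evb$duration_s)
  expect_equal(evb$amplitude_uv, 300, tolerance = 0.05 * 300)
})

test_that("gain calibration converts velocities to degrees per second", {
  refs <- make_events(data.frame(label = "HORIZONTAL_SACCADE",
                                 onset = c(1L, 2L, 3L, 4L),
                                 offset = 10L + 1:4, peak = 5L + 1:4,
                                 direction_sign = 1L, axis = "h",
                                 amplitude_uv = c(120, 130, 140, 130)))
  g <- calibrate_gain(refs)
  expect_equal(g$uv_per_deg, 13)
  expect_equal(g$n_reference, 4L)
  ev <- make_events(data.frame(label = "HORIZONTAL_SACCADE", onset = 1L,
                               offset = 30L, peak = 15L, direction_sign = 1L,
                               axis = "h", peak_velocity_uv_s = 3000))
  conv <- convert_to_degrees(ev, g)
  expect_equal(conv$peak_velocity_deg_s, 3000 / 13, tolerance = 1e-12)
  # single reference
  expect_equal(calibrate_gain(refs[1, ][, ], reference_amplitude_deg = 12)$uv_per_deg,
               10)
  expect_error(calibrate_gain(refs[0, ]), "at least one")
  # degree-domain velocity invariant under amplitude rescaling
  ev2 <- ev; ev2$peak_velocity_uv_s <- 2 * ev$peak_velocity_uv_s
  refs2 <- refs; refs2$amplitude_uv <- 2 * refs$amplitude_uv
  conv2 <- convert_to_degrees(ev2, calibrate_gain(refs2))
  expect_equal(conv2$peak_velocity_deg_s, conv$peak_velocity_deg_s)
})

test_that("gain recovery from simulated recordings is accurate", {
  errs <- sapply(1:10, function(seed) {
    sim <- generate_eog(sim_config(seed = seed, n_saccades = 20, n_blinks = 0,
                                   n_artifacts = 0,
                                   saccade_amplitudes_deg = 10,
                                   directions_deg = c(0, 180)))
    res <- detect_events(sim$recording)
    refs <- res$events[res$events$label == "HORIZONTAL_SACCADE", ]
    calibrate_gain(refs)$uv_per_deg
  })
  expect_lt(max(abs(errs - 13) / 13), 0.10)
})

test_that("summaries agree with direct statistics", {
  ev <- make_events(data.frame(
    label = c("BLINK", "BLINK", "HORIZONTAL_SACCADE"),
    onset = c(100L, 600L, 1200L), offset = c(200L, 750L, 1230L),
    peak = c(150L, 660L, 1215L), direction_sign = 1L, axis = c("v", "v", "h"),
    duration_s = c(0.2, 0.3, 0.06), peak_velocity_uv_s = c(5e3, 6e3, 3e3)))
  s <- summarize_events(ev, total_duration_s = 60)
  bl <- s[s$label == "BLINK", ]
  expect_equal(bl$count, 2L)
  expect_equal(bl$rate_per_min, 2)
  expect_equal(bl$duration_mean_s, 0.25)
  expect_equal(bl$duration_sd_s, sd(c(0.2, 0.3)))
  hs <- s[s$label == "HORIZONTAL_SACCADE", ]
  expect_equal(hs$peak_velocity_mean_uv_s, 3000)
  expect_true(is.na(hs$peak_velocity_sd_uv_s))   # single event: SD absent
  s0 <- summarize_events(ev[0, ], total_duration_s = 60)
  expect_true(all(s0$count == 0L))
  expect_true(all(is.na(s0$duration_mean_s)))
  # single blink of 0.2 s
  s1 <- summarize_events(ev[1, ], total_duration_s = 30)
  expect_equal(s1$count[s1$label == "BLINK"], 1L)
  expect_equal(s1$duration_mean_s[s1$label == "BLINK"], 0.2)
})

test_that("time measures scale as 1/fs for fixed indices", {
  for (fs in c(250, 500, 1000)) {
    clean <- eog_recording(numeric(1000), numeric(1000), fs)
    vh <- differentiate(clean$eog_h, fs, "h")
    vv <- differentiate(clean$eog_v, fs, "v")
    ev <- make_events(data.frame(label = "BLINK", onset = 100L,
                                 offset = 300L, peak = 180L,
                                 direction_sign = 1L, axis = "v"), fs = fs)
    out <- compute_measures(ev, clean, vh, vv)
    expect_equal(out$duration_s, 200 / fs)
    expect_equal(out$closing_time_s, 80 / fs)
  }
})
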