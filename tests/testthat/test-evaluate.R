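toy_events <- function(peaks, labels = "HORIZONTAL_SACCADE", fs = 500) {
  df <- data.frame(label = rep(labels, length.out = length(peaks)),
                   onset = as.integer(peaks - 5L),
                   offset = as.integer(peaks + 5L),
                   peak = as.integer(peaks), direction_sign = 1L)
  df <- df[order(df$onset), ]
  attr(df, "fs") <- fs
  class(df) <- c("eog_events", "data.frame")
  df
}

test_that("matching identical event lists is the identity", {
  ev <- toy_events(c(100, 600, 1200), c("HORIZONTAL_SACCADE", "BLINK",
                                        "VERTICAL_SACCADE"))
  m <- match_events(ev, ev)
  expect_equal(m$tp, 3L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$fp_rate, 0.0)
  expect_equal(sum(diag(m$confusion)), 3L)
  expect_equal(sum(m$confusion), 3L)
  expect_error(match_events(ev, ev, tolerance_s = -1), "non-negative")
})

test_that("counts follow the constructed 8-of-10 example", {
  truth <- toy_events(seq(500, by = 500, length.out = 10))
  detected <- toy_events(c(seq(500, by = 500, length.out = 8) + 10, 4750))
  m <- match_events(detected, truth)
  expect_equal(m$tp, 8L)
  expect_equal(m$fn, 2L)
  expect_equal(m$fp, 1L)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$fp_rate, 1 / 9)
  # conservation
  expect_equal(m$tp + m$fp, nrow(detected))
  expect_equal(m$tp + m$fn, nrow(truth))
  # symmetry: swapping roles swaps fp and fn
  ms <- match_events(truth, detected)
  expect_equal(ms$tp, m$tp)
  expect_equal(ms$fp, m$fn)
  expect_equal(ms$fn, m$fp)
})

test_that("tolerance is monotone and matching is one-to-one", {
  set.seed(41)
  truth <- toy_events(sort(sample(500:20000, 15)))
  detected <- toy_events(truth$peak + sample(-60:60, 15, replace = TRUE))
  tps <- sapply(c(0.02, 0.05, 0.1, 0.2),
                function(tol) match_events(detected, truth, tolerance_s = tol)$tp)
  expect_true(all(diff(tps) >= 0))
  m <- match_events(detected, truth)
  expect_equal(anyDuplicated(m$pairs$detected), 0L)
  expect_equal(anyDuplicated(m$pairs$truth), 0L)
})

test_that("greedy matching attains the optimal cardinality on small cases", {
  # events at least 300 ms apart with perturbations inside the tolerance:
  # candidate sets are disjoint, so the greedy pairing is provably optimal
  set.seed(53)
  fs <- 500
  for (rep in 1:100) {
    n_t <- sample(3:15, 1)
    truth_pk <- 200 + cumsum(sample(150:800, n_t, replace = TRUE))
    keep <- runif(n_t) < 0.85
    det_pk <- truth_pk[keep] + sample(-45:45, sum(keep), replace = TRUE)
    det_pk <- c(det_pk, max(truth_pk) + cumsum(sample(150:400, sample(1:3, 1),
                                                      replace = TRUE)))
    truth <- toy_events(truth_pk)
    detected <- toy_events(sort(det_pk))
    m <- match_events(detected, truth, tolerance_s = 0.1)
    dmat <- abs(outer((detected$peak - 1) / fs, (truth_pk - 1) / fs, `-`))
    expect_equal(m$tp, brute_max_matching(dmat, 0.1))
  }
  # on dense adversarial instances the greedy count can trail the optimal
  # assignment by at most the length of an alternating chain; observed
  # within one of optimal across random dense cases
  for (rep in 1:50) {
    n_t <- sample(3:12, 1)
    truth_pk <- sort(sample(200:4000, n_t))
    det_pk <- sort(truth_pk + sample(-60:60, n_t, replace = TRUE))
    m <- match_events(toy_events(det_pk), toy_events(truth_pk),
                      tolerance_s = 0.1)
    dmat <- abs(outer((det_pk - 1) / fs, (truth_pk - 1) / fs, `-`))
    opt <- brute_max_matching(dmat, 0.1)
    expect_lte(m$tp, opt)
    expect_gte(m$tp, opt - 1L)
  }
})

test_that("classification sensitivity reads the confusion matrix", {
  truth <- toy_events(seq(500, by = 500, length.out = 4), "OBLIQUE_SACCADE")
  detected <- toy_events(seq(500, by = 500, length.out = 4) + 5,
                         c("OBLIQUE_SACCADE", "OBLIQUE_SACCADE",
                           "OBLIQUE_SACCADE", "HORIZONTAL_SACCADE"))
  m <- match_events(detected, truth)
  expect_equal(classification_sensitivity(m, "OBLIQUE_SACCADE"), 0.75)
  expect_true(is.na(classification_sensitivity(m, "BLINK")))
  md <- match_events(truth, truth)
  for (cl in "OBLIQUE_SACCADE") {
    expect_equal(classification_sensitivity(md, cl), 1.0)
  }
})

test_that("small oblique saccades classify worse than large ones", {
  # the vertical EOG component is physiologically weaker than the
  # horizontal one; weakening the vertical *event* gain against an
  # unchanged noise floor (attenuating the whole channel would be
  # absorbed by the scale-equivariant calibration) drives the vertical
  # component of small obliques below threshold, so they classify as
  # horizontal while large obliques survive
  hits <- matrix(0, 2, 2, dimnames = list(c("2.5", "10"), c("ok", "n")))
  for (seed in 1:6) {
    ev <- generate_eog(sim_config(seed = seed, n_saccades = 40, n_blinks = 0,
                                  n_artifacts = 0,
                                  saccade_amplitudes_deg = c(2.5, 10),
                                  directions_deg = c(45, 135, 225, 315),
                                  drift = list(amplitude_uv = 0),
                                  noise = list(white_sd_uv = 0,
                                               powerline_amp_uv = 0)))
    nz <- generate_eog(sim_config(seed = seed + 1000, n_saccades = 0,
                                  n_blinks = 0, n_artifacts = 0))
    rec <- eog_recording(ev$recording$eog_h + nz$recording$eog_h,
                         0.35 * ev$recording$eog_v + nz$recording$eog_v, 500)
    res <- detect_events(rec)
    m <- match_events(res$events, ev$truth)
    for (a in c("2.5", "10")) {
      sel <- m$pairs$truth_label == "OBLIQUE_SACCADE" &
             ev$truth$amplitude_deg[m$pairs$truth] == as.numeric(a)
      hits[a, "n"] <- hits[a, "n"] + sum(sel)
      hits[a, "ok"] <- hits[a, "ok"] +
        sum(m$pairs$detected_label[sel] == "OBLIQUE_SACCADE")
    }
  }
  expect_gt(hits["10", "ok"] / hits["10", "n"],
            hits["2.5", "ok"] / hits["2.5", "n"])
})
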