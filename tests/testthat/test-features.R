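# Toy trial: rate 50 Hz, strikes every 25 samples (0.5 s steps), simple
# closed-form channels so expected features can be computed by hand.
toy_trial <- function(n = 150) {
  make_uniform_trial(
    n,
    ml = rep(2, n),                 # constant
    ap = (seq_len(n) - 1) * 0.1,    # ramp
    vert = rep(c(-1, 1), length.out = n),
    tilt = seq(0, 1, length.out = n),
    rotation = rep(0, n),
    obliquity = rep(5, n)
  )
}

toy_strikes <- function(k = 5)
  footstrike_series(seq(1L, by = 25L, length.out = k))

test_that("segmentation partitions strikes into alternating-side windows", {
  tr <- toy_trial()
  s10 <- footstrike_series(seq(1L, by = 14L, length.out = 10L))
  w <- segment_steps(s10, tr)
  expect_equal(nrow(w), 9)
  expect_equal(w$start, s10$sample_index[-10])
  expect_equal(w$end, s10$sample_index[-1])
  expect_true(all(w$side[-1] != w$side[-9]))  # strict alternation
  # mean ML in the first window is +2 -> first side is left
  expect_equal(w$side[1], "left")
  expect_error(segment_steps(footstrike_series(c(1L, 20L, 40L)), tr),
               "at least 4")
})

test_that("step durations follow the strike spacing", {
  tr <- toy_trial()
  w <- segment_steps(toy_strikes(3 + 1), tr)
  expect_equal(w$duration, rep(0.5, 3))
})

test_that("temporal features follow their defining arithmetic", {
  w <- data.frame(start = c(1, 26, 51, 81), end = c(26, 51, 81, 101),
                  side = c("left", "right", "left", "right"),
                  duration = c(0.5, 0.5, 0.6, 0.4))
  # window 1: 0.5 s step -> cadence 120; no contralateral context yet
  f1 <- temporal_features(1, w)
  expect_equal(unname(f1["cadence"]), 120)
  expect_equal(unname(f1["step_time_left"]), 0.5)
  expect_true(is.na(f1["step_time_right"]))
  expect_true(is.na(f1["stride_time"]))
  # window 2: R = L = 0.5 -> symmetry 0
  f2 <- temporal_features(2, w)
  expect_equal(unname(f2["symmetry_index"]), 0)
  # window 3: stride = d1 + d2 = 1.0; R = 0.5, L = 0.6
  f3 <- temporal_features(3, w)
  expect_equal(unname(f3["stride_time"]), 1.0)
  # window 4: R = 0.4, L = 0.6 -> |R-L|/(0.5(R+L)) * 100 = 40
  f4 <- temporal_features(4, w)
  expect_equal(unname(f4["symmetry_index"]), 40)
})

test_that("descriptive statistics match hand computation", {
  tr <- toy_trial()
  d <- descriptive_features(list(start = 1L, end = 26L), tr)
  expect_equal(unname(d["min_ml"]), 2)
  expect_equal(unname(d["max_ml"]), 2)
  expect_equal(unname(d["mean_ml"]), 2)
  expect_equal(unname(d["sd_ml"]), 0)
  expect_equal(unname(d["rms_ml"]), 2)
  # ramp 0, 0.1, ..., 2.4
  expect_equal(unname(d["min_ap"]), 0)
  expect_equal(unname(d["max_ap"]), 2.4)
  expect_equal(unname(d["mean_ap"]), 1.2)
  expect_equal(unname(d["rms_ap"]), sqrt(sum((0:24 * 0.1)^2) / 25))
  # alternating -1, 1 (25 samples: 13 of -1, 12 of +1)
  expect_equal(unname(d["mean_vert"]), (-13 + 12) / 25)
  expect_equal(unname(d["rms_vert"]), 1)
  expect_equal(unname(d["range_obliquity"]), 0)
  expect_length(d, 27)
  expect_true(d["min_ap"] <= d["mean_ap"] && d["mean_ap"] <= d["max_ap"])
})

test_that("spectral features behave on pure tones", {
  rate <- 50
  n <- 50  # 1 s window -> fundamental 1 Hz
  tm <- (seq_len(n) - 1) / rate
  w <- list(start = 1L, end = n + 1L)
  # tone at the fundamental: all harmonic energy is odd -> REOH ~ 0
  tr1 <- make_uniform_trial(n + 1, ap = c(sin(2 * pi * 1 * tm), 0))
  f1 <- frequency_features(w, tr1)
  expect_lt(unname(f1["reoh_ap"]), 1e-6)
  # tone at twice the fundamental: all energy even -> REOH explodes
  tr2 <- make_uniform_trial(n + 1, ap = c(sin(2 * pi * 2 * tm), 0))
  f2 <- frequency_features(w, tr2)
  expect_gt(unname(f2["reoh_ap"]), 1e3)
  # single spectral line: cumulative power jumps at that line's bin
  f0 <- 5
  tr3 <- make_uniform_trial(n + 1, ap = c(sin(2 * pi * f0 * tm), 0))
  f3 <- frequency_features(w, tr3)
  expect_equal(unname(f3["fft_quartile_ap"]), f0, tolerance = 0.5)
  expect_length(f3, 30)
})

test_that("short windows yield missing spectral features with a warning", {
  tr <- toy_trial(20)
  expect_warning(f <- frequency_features(list(start = 1L, end = 6L), tr),
                 "too short")
  expect_true(all(is.na(f)))
  expect_length(f, 30)
})

test_that("the step matrix is 62 wide with a stable schema", {
  sim <- generate_trial(gait_params(duration = 60), seed = 21)
  tr <- preprocess_trial(sim$raw)
  strikes <- clean_footstrikes(detect_candidates(tr), tr)
  sm <- extract_step_matrix(tr, strikes)
  expect_equal(ncol(sm), 62)
  expect_equal(nrow(sm), nrow(strikes) - 1)
  expect_equal(colnames(sm), step_feature_names())
  # missing markers only in the earliest windows' temporal slots
  expect_true(all(!is.na(sm[-(1:2), ])))
  # second trial: identical column order
  sim2 <- generate_trial(gait_params(duration = 60), seed = 22)
  tr2 <- preprocess_trial(sim2$raw)
  sm2 <- extract_step_matrix(tr2, clean_footstrikes(detect_candidates(tr2),
                                                    tr2))
  expect_identical(colnames(sm2), colnames(sm))
})

test_that("first-row step features match the hand-computed toy values", {
  tr <- toy_trial()
  sm <- extract_step_matrix(tr, toy_strikes(5))
  expect_equal(unname(sm[1, "cadence"]), 120)
  expect_equal(unname(sm[1, "min_ap"]), 0)
  expect_equal(unname(sm[1, "max_ap"]), 2.4)
  expect_equal(unname(sm[1, "mean_ml"]), 2)
  expect_equal(unname(sm[1, "sd_ml"]), 0)
  expect_equal(unname(sm[2, "symmetry_index"]), 0)
  expect_equal(unname(sm[3, "stride_time"]), 1.0)
})

test_that("aggregation produces the 248-feature trial vector", {
  sim <- generate_trial(gait_params(duration = 60), seed = 23)
  tr <- preprocess_trial(sim$raw)
  res <- trial_features(tr)
  expect_length(res$features, 248)
  expect_equal(names(res$features), trial_feature_names())
  base <- "cadence"
  expect_true(res$features[paste0(base, "__min")] <=
                res$features[paste0(base, "__mean")])
  expect_true(res$features[paste0(base, "__mean")] <=
                res$features[paste0(base, "__max")])
})

test_that("aggregates of a toy step matrix match hand computation", {
  sm <- matrix(NA_real_, 2, 62, dimnames = list(NULL, step_feature_names()))
  sm[1, ] <- seq_len(62)
  sm[2, ] <- seq_len(62) + 1
  agg <- aggregate_trial(sm)
  expect_length(agg$features, 248)
  expect_equal(unname(agg$features["cadence__min"]), 1)
  expect_equal(unname(agg$features["cadence__max"]), 2)
  expect_equal(unname(agg$features["cadence__mean"]), 1.5)
  expect_equal(unname(agg$features["cadence__sd"]), sd(c(1, 2)))
  expect_equal(agg$step_count, 2)
  # identical steps -> sd 0 and min = max = mean
  sm2 <- rbind(sm[1, ], sm[1, ], sm[1, ])
  colnames(sm2) <- step_feature_names()
  agg2 <- aggregate_trial(sm2)
  expect_equal(unname(agg2$features["symmetry_index__sd"]), 0)
  expect_equal(unname(agg2$features["symmetry_index__min"]),
               unname(agg2$features["symmetry_index__max"]))
  # a feature with fewer than 2 usable steps is an error
  sm3 <- sm
  sm3[, "reoh_ap"] <- NA_real_
  expect_error(aggregate_trial(sm3), "reoh_ap")
})

test_that("features are invariant to shifting the trial in time", {
  sim <- generate_trial(gait_params(duration = 30), seed = 25)
  tr <- preprocess_trial(sim$raw)
  strikes <- clean_footstrikes(detect_candidates(tr), tr)
  sm <- extract_step_matrix(tr, strikes, first_side = "left")
  k <- 7L
  shifted <- tr
  for (ch in c("ml", "ap", "vert", "tilt", "rotation", "obliquity"))
    shifted[[ch]] <- c(numeric(k), tr[[ch]])
  shifted$n_samples <- tr$n_samples + k
  s2 <- footstrike_series(strikes$sample_index + k)
  sm2 <- extract_step_matrix(shifted, s2, first_side = "left")
  expect_equal(sm2, sm, tolerance = 1e-9)
})

test_that("acceleration scaling acts only on amplitude-type features", {
  sim <- generate_trial(gait_params(duration = 30), seed = 26)
  tr <- preprocess_trial(sim$raw)
  strikes <- clean_footstrikes(detect_candidates(tr), tr)
  sm <- extract_step_matrix(tr, strikes, first_side = "left")
  cc <- 3
  scaled <- tr
  for (ch in c("ml", "ap", "vert")) scaled[[ch]] <- cc * tr[[ch]]
  sm2 <- extract_step_matrix(scaled, strikes, first_side = "left")
  amp_feats <- c(outer(c("min_", "max_", "mean_", "sd_", "rms_",
                         "fft_max_", "fft_sd_"),
                       c("ml", "ap", "vert"), paste0))
  amp_feats <- intersect(amp_feats, colnames(sm))
  expect_equal(sm2[, amp_feats], cc * sm[, amp_feats], tolerance = 1e-9)
  inv_feats <- c("cadence", "stride_time", "symmetry_index",
                 paste0("fft_quartile_", c("ml", "ap", "vert")),
                 paste0("fft_peak_distinction_", c("ml", "ap", "vert")),
                 paste0("reoh_", c("ml", "ap", "vert")),
                 paste0("mean_", c("tilt", "rotation", "obliquity")))
  expect_equal(sm2[, inv_feats], sm[, inv_feats], tolerance = 1e-9)
})

test_that("perfectly periodic gait gives near-constant per-step features", {
  sim <- generate_trial(gait_params(cadence = 100, step_time_cv = 0,
                                    asymmetry = 0, noise_sd = 0,
                                    sampling_jitter = 0, duration = 60),
                        seed = 3)
  tr <- preprocess_trial(sim$raw)
  strikes <- clean_footstrikes(detect_candidates(tr), tr)
  sm <- extract_step_matrix(tr, strikes)
  core <- sm[5:(nrow(sm) - 4), ]  # avoid filter edge windows
  # sway-driven channels alternate sign with stance side, so steps repeat
  # with period two: features must be constant within each side
  for (rows in list(seq(1, nrow(core), 2), seq(2, nrow(core), 2))) {
    rel_sd <- apply(core[rows, ], 2,
                    function(v) sd(v) / (1 + abs(mean(v))))
    expect_lt(max(rel_sd), 1e-6)
  }
})
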