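gaussian_bump <- function(n, center, sd = 5, amp = 1) {
  amp * exp(-((seq_len(n) - center)^2) / (2 * sd^2))
}

test_that("detection returns nothing on a flat AP channel", {
  tr <- make_uniform_trial(500)
  expect_equal(nrow(detect_candidates(tr)), 0)
})

test_that("a single isolated bump yields exactly one candidate at its apex", {
  tr <- make_uniform_trial(500, ap = gaussian_bump(500, 250))
  cand <- detect_candidates(tr)
  expect_equal(cand$sample_index, 250L)
  expect_equal(cand$source, "detected")
})

test_that("detection recovers at least 95% of true strikes within 100 ms", {
  sim <- generate_trial(gait_params(duration = 120), seed = 5)
  tr <- preprocess_trial(sim$raw)
  cand <- detect_candidates(tr)
  m <- strike_f1(cand$sample_index, sim$truth$strike_times)
  expect_gte(m$recall, 0.95)
})

test_that("extra predictions collapse to the candidate nearest the apex", {
  ap <- gaussian_bump(300, 102, sd = 8)
  tr <- make_uniform_trial(300, ap = ap)
  keep <- remove_extra_predictions(footstrike_series(c(100L, 103L)), tr)
  expect_equal(keep$sample_index, 103L)
  # equidistant pair: tie broken toward the earlier candidate
  keep2 <- remove_extra_predictions(footstrike_series(c(100L, 104L)), tr)
  expect_equal(keep2$sample_index, 100L)
})

test_that("candidates adjacent to distinct apexes pass through unchanged", {
  ap <- gaussian_bump(400, 100, sd = 8) + gaussian_bump(400, 200, sd = 8) +
    gaussian_bump(400, 300, sd = 8)
  tr <- make_uniform_trial(400, ap = ap)
  cand <- footstrike_series(c(99L, 201L, 300L))
  out <- remove_extra_predictions(cand, tr)
  expect_equal(out$sample_index, cand$sample_index)
  expect_equal(nrow(remove_extra_predictions(footstrike_series(integer(0)),
                                             tr)), 0)
})

test_that("the gap rule flags exactly the stated durations", {
  # strikes at 0, 0.5, 1.0, 1.8 s: durations [0.5, 0.5, 0.8]; the third is
  # >= 1.5 x the second, so one insertion is attempted inside it
  rate <- 50
  ap <- gaussian_bump(120, 71, sd = 3)  # apex at 1.4 s inside the gap
  tr <- make_uniform_trial(120, ap = ap)
  strikes <- footstrike_series(c(1L, 26L, 51L, 91L))
  out <- insert_missed_steps(strikes, tr, cleanup_config())
  expect_equal(nrow(out), 5)
  expect_equal(out$sample_index[4], 71L)
  expect_equal(out$source[4], "inserted")

  # durations [0.5, 0.5, 0.7]: 0.7 < 0.75, nothing flagged
  strikes2 <- footstrike_series(c(1L, 26L, 51L, 86L))
  out2 <- insert_missed_steps(strikes2, tr, cleanup_config())
  expect_equal(out2$sample_index, strikes2$sample_index)
})

test_that("fewer than 3 strikes pass through with a warning", {
  tr <- make_uniform_trial(200, ap = gaussian_bump(200, 100))
  s <- footstrike_series(c(10L, 50L))
  expect_warning(out <- insert_missed_steps(s, tr), "fewer than 3")
  expect_equal(out$sample_index, s$sample_index)
})

test_that("a deleted strike is recovered within 100 ms", {
  sim <- generate_trial(gait_params(duration = 60, step_time_cv = 0.02),
                        seed = 9)
  tr <- preprocess_trial(sim$raw)
  truth_idx <- round(sim$truth$strike_times * tr$rate) + 1L
  gapped <- footstrike_series(truth_idx[-25], source = "external",
                              n_samples = tr$n_samples)
  out <- insert_missed_steps(gapped, tr, cleanup_config())
  dropped_t <- sim$truth$strike_times[25]
  expect_lt(min(abs((out$sample_index - 1) / tr$rate - dropped_t)), 0.1)
})

test_that("cleanup is idempotent and ground-truth candidates pass through", {
  sim <- generate_trial(gait_params(duration = 90), seed = 13)
  tr <- preprocess_trial(sim$raw)
  cand <- detect_candidates(tr)
  once <- clean_footstrikes(cand, tr)
  twice <- clean_footstrikes(once, tr)
  expect_equal(twice$sample_index, once$sample_index)

  # candidates equal to the already-clean series -> unchanged
  again <- clean_footstrikes(once, tr)
  expect_equal(again$sample_index, once$sample_index)
})

test_that("noiseless periodic gait is recovered exactly at index level", {
  # cadence 100 puts every strike exactly on the 50 Hz sample grid
  # (0.3 + 0.6 k seconds), so index-level equality is well defined
  sim <- generate_trial(gait_params(cadence = 100, step_time_cv = 0,
                                    asymmetry = 0, noise_sd = 0,
                                    sampling_jitter = 0, duration = 60),
                        seed = 2)
  tr <- preprocess_trial(sim$raw)
  out <- clean_footstrikes(detect_candidates(tr), tr)
  truth_idx <- round(sim$truth$strike_times * tr$rate) + 1L
  expect_equal(out$sample_index, truth_idx)
})

test_that("cleanup restores 95% F1 on corrupted candidates", {
  set.seed(77)
  f1s <- sapply(1:3, function(k) {
    sim <- generate_trial(gait_params(duration = 120), seed = 100 + k)
    tr <- preprocess_trial(sim$raw)
    truth_idx <- round(sim$truth$strike_times * tr$rate) + 1L
    n <- length(truth_idx)
    keep <- sort(sample(n, round(0.95 * n)))          # 5% deleted
    spurious <- sample(tr$n_samples, round(0.05 * n)) # 5% spurious
    corrupted <- footstrike_series(sort(unique(c(truth_idx[keep],
                                                 spurious))),
                                   source = "external",
                                   n_samples = tr$n_samples)
    out <- clean_footstrikes(corrupted, tr)
    strike_f1(out$sample_index, sim$truth$strike_times)$f1
  })
  expect_gte(mean(f1s), 0.95)
})

test_that("cleanup preserves ordering, bounds, and count monotonicity", {
  set.seed(31)
  sim <- generate_trial(gait_params(duration = 60), seed = 17)
  tr <- preprocess_trial(sim$raw)
  for (rep in 1:5) {
    cand_idx <- sort(sample(tr$n_samples, 80))
    cand <- footstrike_series(cand_idx, source = "external",
                              n_samples = tr$n_samples)
    removed <- remove_extra_predictions(cand, tr)
    expect_lte(nrow(removed), nrow(cand))
    if (nrow(removed) >= 3) {
      inserted <- insert_missed_steps(removed, tr)
      expect_gte(nrow(inserted), nrow(removed))
    }
    out <- clean_footstrikes(cand, tr)
    expect_true(all(diff(out$sample_index) > 0))
    expect_true(all(out$sample_index >= 1 &
                      out$sample_index <= tr$n_samples))
  }
})

test_that("cleaned strikes respect the locking-period separation", {
  sim <- generate_trial(gait_params(duration = 60), seed = 19)
  tr <- preprocess_trial(sim$raw)
  cfg <- cleanup_config()
  out <- clean_footstrikes(detect_candidates(tr, cfg), tr, cfg)
  L <- round(cfg$locking_fraction * median(diff(out$sample_index)))
  expect_true(all(diff(out$sample_index) >= L))
})

test_that("foot-strike CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- footstrike_series(c(10L, 40L, 90L), source = c("detected",
                                                      "inserted",
                                                      "external"),
                         side = c("left", "right", "unassigned"))
  write_footstrikes(s, path)
  r <- read_footstrikes(path)
  expect_equal(as.data.frame(r), as.data.frame(s))
})
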