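# Shared fixture builders and small independent oracles.

# Build a uniform_trial directly from channel vectors (defaults: zeros).
make_uniform_trial <- function(n, rate = 50, ml = NULL, ap = NULL,
                               vert = NULL, tilt = NULL, rotation = NULL,
                               obliquity = NULL, id = "toy") {
  z <- numeric(n)
  chans <- list(ml = ml %||% z, ap = ap %||% z, vert = vert %||% z,
                tilt = tilt %||% z, rotation = rotation %||% z,
                obliquity = obliquity %||% z)
  gaitconf:::new_uniform_trial(id, rate, chans)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a minimal well-formed trial CSV; `mutate` can drop/alter columns.
write_toy_trial_csv <- function(path, time_s, drop_cols = character(0)) {
  n <- length(time_s)
  df <- data.frame(time_s = time_s, ax = seq_len(n), ay = 9.81, az = 0.1,
                   gx = 0, gy = 0, gz = 0, azimuth_deg = 1, pitch_deg = 2,
                   roll_deg = 3)
  df <- df[, setdiff(names(df), drop_cols), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Greedy one-to-one matching of predicted strike indices to true strike
# times; returns precision/recall/F1 at the given tolerance.
strike_f1 <- function(pred_idx, true_times, rate = 50, tol_s = 0.1) {
  pred_t <- (pred_idx - 1) / rate
  used <- rep(FALSE, length(true_times))
  tp <- 0L
  for (p in pred_t) {
    d <- abs(true_times - p)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  precision <- if (length(pred_t)) tp / length(pred_t) else 0
  recall <- if (length(true_times)) tp / length(true_times) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}

# Independent brute-force CFS merit straight from the formula, computing
# the correlations on the spot (no shared code with the implementation).
oracle_cfs_merit <- function(subset, X, y) {
  yb <- as.numeric(factor(y)) - 1
  k <- length(subset)
  rcf <- sapply(subset, function(j) {
    r <- suppressWarnings(cor(X[, j], yb))
    if (is.finite(r)) abs(r) else 0
  })
  rff <- 0
  if (k > 1) {
    pairs <- utils::combn(subset, 2)
    rff <- mean(apply(pairs, 2, function(pr) {
      r <- suppressWarnings(cor(X[, pr[1]], X[, pr[2]]))
      if (is.finite(r)) abs(r) else 0
    }))
  }
  k * mean(rcf) / sqrt(k + k * (k - 1) * rff)
}

# Exhaustive-search CFS optimum over all non-empty subsets (p <= 12).
oracle_cfs_best <- function(X, y) {
  p <- ncol(X)
  best <- list(merit = -Inf, subset = integer(0))
  for (size in seq_len(p)) {
    subs <- utils::combn(p, size)
    for (ci in seq_len(ncol(subs))) {
      m <- oracle_cfs_merit(subs[, ci], X, y)
      if (m > best$merit + 1e-12) best <- list(merit = m, subset = subs[, ci])
    }
  }
  best
}

# Default separated small cohort for quick end-to-end tests: short trials,
# same class-parameter structure as the full-scale defaults.
quick_cohort_spec <- function(n_per_class = 5, duration = 90, seed = 11) {
  cohort_spec(
    n_per_class = n_per_class,
    params_high = gait_params(cadence = 105, step_time_cv = 0.04,
                              asymmetry = 0.04, ml_sway_amp = 0.8,
                              duration = duration),
    params_low = gait_params(cadence = 88, step_time_cv = 0.09,
                             asymmetry = 0.12, ml_sway_amp = 1.5,
                             duration = duration),
    seed = seed
  )
}
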