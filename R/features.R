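signal_channels <- function() body_channels()  # ml, ap, vert + 3 angles
accel_channels <- function() c("ml", "ap", "vert")
angle_channels <- function() c("tilt", "rotation", "obliquity")

#' Names of the 62 per-step gait features
#'
#' Five temporal features, 27 descriptive statistics, and 30 frequency-domain
#' features (five per body-frame channel), in fixed schema order.
#'
#' @return Character vector of length 62.
#' @export
step_feature_names <- function() {
  temporal <- c("cadence", "step_time_right", "step_time_left",
                "stride_time", "symmetry_index")
  descr <- c(paste0("min_", accel_channels()),
             paste0("max_", accel_channels()),
             paste0("mean_", signal_channels()),
             paste0("range_", angle_channels()),
             paste0("sd_", signal_channels()),
             paste0("rms_", signal_channels()))
  freq <- as.vector(t(outer(
    c("fft_quartile_", "fft_max_", "fft_sd_", "fft_peak_distinction_",
      "reoh_"),
    signal_channels(), paste0)))
  c(temporal, descr, freq)
}

#' Names of the 248 aggregated trial features
#'
#' Each per-step feature aggregated with min, max, mean, and standard
#' deviation over all steps of a trial, named `<base>__<stat>`.
#'
#' @return Character vector of length 248.
#' @export
trial_feature_names <- function() {
  as.vector(t(outer(step_feature_names(),
                    c("min", "max", "mean", "sd"),
                    function(b, s) paste0(b, "__", s))))
}

#' Segment a trial into step windows
#'
#' A step spans consecutive (contralateral) foot strikes: window `i` is the
#' half-open sample interval `[s_i, s_{i+1})`. Sides alternate strictly; the
#' side of the first window defaults to a heuristic on the sign of the mean
#' ML acceleration inside it (ML sway alternates by stance side), and can be
#' overridden.
#'
#' @param strikes A cleaned `footstrike_series` with at least 4 strikes.
#' @param trial The parent `uniform_trial`.
#' @param first_side `"auto"` (default heuristic), `"left"`, or `"right"`.
#' @return A data.frame with columns `start`, `end`, `side`, `duration`
#'   (seconds), one row per step, class `step_windows`.
#' @export
segment_steps <- function(strikes, trial, first_side = "auto") {
  stopifnot(inherits(strikes, "footstrike_series"),
            inherits(trial, "uniform_trial"))
  idx <- strikes$sample_index
  if (length(idx) < 4)
    stop("trial ", trial$participant_id, ": need at least 4 foot strikes ",
         "for step segmentation, got ", length(idx))
  start <- idx[-length(idx)]
  end <- idx[-1]
  if (first_side == "auto") {
    ml_mean <- mean(trial$ml[start[1]:(end[1] - 1L)])
    first_side <- if (ml_mean >= 0) "left" else "right"
  }
  sides <- rep_len(if (first_side == "left") c("left", "right")
                   else c("right", "left"), length(start))
  structure(data.frame(start = start, end = end, side = sides,
                       duration = (end - start) / trial$rate,
                       stringsAsFactors = FALSE),
            class = c("step_windows", "data.frame"))
}

#' Temporal features of one step
#'
#' Cadence (60 / step time, steps per minute), the most recent right and
#' left step times at or before this step, stride time (interval between
#' the strike opening this step and the previous ipsilateral strike), and
#' the step-time symmetry index `|R - L| / (0.5 (R + L)) * 100` (percent).
#' The earliest windows, which lack a contralateral step or a previous
#' ipsilateral strike, carry `NA` in the undefined slots.
#'
#' @param i Step index into `windows`.
#' @param windows A `step_windows` data.frame.
#' @return Named numeric vector of length 5.
#' @export
temporal_features <- function(i, windows) {
  d <- windows$duration
  if (any(d <= 0)) stop("non-positive step duration")
  side_i <- windows$side[i]
  own <- d[i]
  contra <- if (i >= 2) d[i - 1L] else NA_real_
  st_right <- if (side_i == "right") own else contra
  st_left <- if (side_i == "left") own else contra
  stride <- if (i >= 3) d[i - 1L] + d[i - 2L] else NA_real_
  sym <- if (i >= 2) abs(st_right - st_left) /
    (0.5 * (st_right + st_left)) * 100 else NA_real_
  c(cadence = 60 / own, step_time_right = st_right, step_time_left = st_left,
    stride_time = stride, symmetry_index = sym)
}

#' Descriptive statistics of one step window
#'
#' The 27 per-step descriptive statistics: min/max of the three
#' accelerations, mean/SD/RMS of all six channels, and range of the three
#' orientation angles.
#'
#' @param window One row of a `step_windows` data.frame (list with `start`,
#'   `end`).
#' @param trial The parent `uniform_trial`.
#' @return Named numeric vector of length 27.
#' @export
descriptive_features <- function(window, trial) {
  sl <- seq(window$start, window$end - 1L)
  chans <- lapply(stats::setNames(signal_channels(), signal_channels()),
                  function(ch) trial[[ch]][sl])
  out <- c(
    vapply(chans[accel_channels()], min, numeric(1)),
    vapply(chans[accel_channels()], max, numeric(1)),
    vapply(chans, mean, numeric(1)),
    vapply(chans[angle_channels()], function(v) max(v) - min(v), numeric(1)),
    vapply(chans, stats::sd, numeric(1)),
    vapply(chans, function(v) sqrt(mean(v^2)), numeric(1))
  )
  names(out) <- c(paste0("min_", accel_channels()),
                  paste0("max_", accel_channels()),
                  paste0("mean_", signal_channels()),
                  paste0("range_", angle_channels()),
                  paste0("sd_", signal_channels()),
                  paste0("rms_", signal_channels()))
  out
}

# One-sided amplitude spectrum of a mean-removed window zero-padded to
# `nfft` (or the window length, if longer). Returns amplitudes and bin
# frequencies.
amplitude_spectrum <- function(x, rate, nfft) {
  n <- length(x)
  nfft <- max(nfft, n)
  xp <- c(x - mean(x), numeric(nfft - n))
  amp <- Mod(stats::fft(xp))[seq_len(nfft %/% 2 + 1L)]
  list(amp = amp, freq = (seq_along(amp) - 1L) * rate / nfft)
}

# Even/odd harmonic energy ratio relative to the step fundamental
# (1 / window duration), from the unpadded window's DFT evaluated at the
# exact harmonic bins so that integer-cycle components do not leak.
reoh_ratio <- function(x, n_harmonics = 10) {
  n <- length(x)
  x <- x - mean(x)
  m <- seq_len(min(n_harmonics, n %/% 2))
  if (length(m) < 2) return(NA_real_)
  # harmonic m sits at DFT bin m of the n-point transform
  power <- vapply(m, function(k) {
    w <- exp(-2i * pi * k * (seq_len(n) - 1L) / n)
    Mod(sum(x * w))^2
  }, numeric(1))
  even <- sum(power[m %% 2 == 0])
  odd <- sum(power[m %% 2 == 1])
  even / max(odd, .Machine$double.eps)
}

#' Frequency-domain features of one step window
#'
#' For each of the six channels, from the one-sided amplitude spectrum of
#' the mean-removed, zero-padded window: the quartile FFT frequency (lowest
#' frequency at which cumulative squared amplitude reaches 25% of the
#' total), the maximum amplitude, the standard deviation of amplitudes,
#' peak distinction `(max - mean) / mean`, and the ratio of even- to
#' odd-harmonic energy (REOH) relative to the step fundamental
#' (1 / window duration, harmonics 1-10, denominator guarded by machine
#' epsilon).
#'
#' @param window One row of a `step_windows` data.frame.
#' @param trial The parent `uniform_trial`.
#' @param fft_len Zero-padding length for the amplitude spectrum.
#' @return Named numeric vector of length 30, or all-`NA` (with a warning)
#'   for windows shorter than 8 samples.
#' @export
frequency_features <- function(window, trial, fft_len = 128) {
  nm <- as.vector(t(outer(
    c("fft_quartile_", "fft_max_", "fft_sd_", "fft_peak_distinction_",
      "reoh_"),
    signal_channels(), paste0)))
  sl <- seq(window$start, window$end - 1L)
  if (length(sl) < 8) {
    warning("step window of ", length(sl),
            " samples too short for frequency features")
    return(stats::setNames(rep(NA_real_, 30), nm))
  }
  out <- numeric(0)
  for (ch in signal_channels()) {
    x <- trial[[ch]][sl]
    sp <- amplitude_spectrum(x, trial$rate, fft_len)
    p <- sp$amp^2
    tot <- sum(p)
    quart <- if (tot > 0) sp$freq[which(cumsum(p) >= 0.25 * tot)[1]] else 0
    m <- mean(sp$amp)
    pd <- if (m > 0) (max(sp$amp) - m) / m else 0
    out <- c(out, quart, max(sp$amp), stats::sd(sp$amp), pd, reoh_ratio(x))
  }
  names(out) <- as.vector(outer(
    c("fft_quartile_", "fft_max_", "fft_sd_", "fft_peak_distinction_",
      "reoh_"),
    signal_channels(), paste0))
  out[nm]
}

#' Extract the per-step feature matrix of a trial
#'
#' Computes the 62-feature vector for every step window: 5 temporal, 27
#' descriptive, 30 frequency-domain features, in the fixed
#' [step_feature_names()] order. `NA` markers appear only in the earliest
#' windows' temporal slots (undefined stride/symmetry context) and in
#' windows too short for spectral estimates.
#'
#' @param trial A filtered `uniform_trial`.
#' @param strikes A cleaned `footstrike_series`.
#' @param fft_len Zero-padding length for spectral features.
#' @param first_side Passed to [segment_steps()].
#' @return A numeric matrix, one row per step, 62 named columns.
#' @export
extract_step_matrix <- function(trial, strikes, fft_len = 128,
                                first_side = "auto") {
  windows <- segment_steps(strikes, trial, first_side = first_side)
  n <- nrow(windows)
  out <- matrix(NA_real_, n, 62,
                dimnames = list(NULL, step_feature_names()))
  for (i in seq_len(n)) {
    w <- windows[i, ]
    out[i, ] <- c(temporal_features(i, windows),
                  descriptive_features(w, trial),
                  frequency_features(w, trial, fft_len))
  }
  out
}

#' Aggregate per-step features to the 248-feature trial vector
#'
#' The minimum, maximum, mean, and standard deviation of each of the 62
#' per-step features over all steps of the trial, named `<base>__<stat>`.
#' `NA` step values (earliest-window temporal slots) are excluded from the
#' aggregation.
#'
#' @param step_matrix A per-step feature matrix from
#'   [extract_step_matrix()].
#' @return A list with `features` (named numeric vector of length 248) and
#'   `step_count`.
#' @export
aggregate_trial <- function(step_matrix) {
  stopifnot(is.matrix(step_matrix), ncol(step_matrix) == 62)
  n_ok <- colSums(!is.na(step_matrix))
  if (any(n_ok < 2))
    stop("base feature(s) with fewer than 2 non-missing steps: ",
         paste(colnames(step_matrix)[n_ok < 2], collapse = ", "))
  agg <- rbind(
    min = apply(step_matrix, 2, min, na.rm = TRUE),
    max = apply(step_matrix, 2, max, na.rm = TRUE),
    mean = colMeans(step_matrix, na.rm = TRUE),
    sd = apply(step_matrix, 2, stats::sd, na.rm = TRUE)
  )
  v <- as.vector(agg[c("min", "max", "mean", "sd"), ])
  names(v) <- trial_feature_names()
  list(features = v, step_count = nrow(step_matrix))
}

#' Full feature extraction for one preprocessed trial
#'
#' Candidate detection, cleanup, segmentation, per-step features, and trial
#' aggregation in one call.
#'
#' @param trial A filtered `uniform_trial`.
#' @param cleanup A [cleanup_config()].
#' @param candidates Optional externally supplied `footstrike_series`; when
#'   `NULL` the baseline AP-peak detector is used.
#' @param fft_len Zero-padding length for spectral features.
#' @return A list with `features` (length 248), `step_count`, `strikes`
#'   (the cleaned `footstrike_series`).
#' @export
trial_features <- function(trial, cleanup = cleanup_config(),
                           candidates = NULL, fft_len = 128) {
  if (is.null(candidates)) candidates <- detect_candidates(trial, cleanup)
  strikes <- clean_footstrikes(candidates, trial, cleanup)
  sm <- extract_step_matrix(trial, strikes, fft_len = fft_len)
  agg <- aggregate_trial(sm)
  list(features = agg$features, step_count = agg$step_count,
       strikes = strikes)
}
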