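#' Default device-to-body axis mapping
#'
#' Maps the trial CSV's device columns onto pelvis body-frame channels for a
#' portrait phone worn at the posterior pelvis: device x -> medio-lateral
#' (ML), y -> vertical (Vert), z -> anterior-posterior (AP); orientation
#' pitch -> tilt (sagittal plane), azimuth -> rotation (transverse plane),
#' roll -> obliquity (frontal plane).
#'
#' @return A named list with `accel` and `orientation` character vectors
#'   mapping body-channel names to CSV column names.
#' @export
default_axis_map <- function() {
  list(
    accel = c(ml = "ax", vert = "ay", ap = "az"),
    orientation = c(tilt = "pitch_deg", rotation = "azimuth_deg",
                    obliquity = "roll_deg")
  )
}

#' Preprocessing configuration
#'
#' @param target_rate_hz Fixed resampling rate in Hz.
#' @param filter_order Butterworth filter order (even, >= 2).
#' @param cutoff_hz Low-pass cutoff frequency in Hz; must be below the
#'   Nyquist frequency of `target_rate_hz`.
#' @param axis_map Device-to-body axis mapping, see [default_axis_map()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate_hz = 50, filter_order = 4,
                              cutoff_hz = 4, axis_map = default_axis_map()) {
  if (cutoff_hz >= target_rate_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency (target_rate_hz / 2)")
  if (filter_order < 2 || filter_order %% 2 != 0)
    stop("filter_order must be even and >= 2")
  structure(list(target_rate_hz = target_rate_hz, filter_order = filter_order,
                 cutoff_hz = cutoff_hz, axis_map = axis_map),
            class = "preprocess_config")
}

trial_csv_columns <- function() {
  c("time_s", "ax", "ay", "az", "gx", "gy", "gz",
    "azimuth_deg", "pitch_deg", "roll_deg")
}

new_raw_trial <- function(participant_id, time, ml, ap, vert,
                          tilt, rotation, obliquity, gyro) {
  n <- length(time)
  stopifnot(n >= 2)
  lens <- c(length(ml), length(ap), length(vert), length(tilt),
            length(rotation), length(obliquity), nrow(gyro))
  if (any(lens != n))
    stop("all channels must have the same length as the timestamps")
  if (any(diff(time) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(participant_id = participant_id, time = time,
                 ml = ml, ap = ap, vert = vert, tilt = tilt,
                 rotation = rotation, obliquity = obliquity, gyro = gyro),
            class = "raw_trial")
}

#' Load a raw smartphone trial from CSV
#'
#' Reads one trial recording (header
#' `time_s,ax,ay,az,gx,gy,gz,azimuth_deg,pitch_deg,roll_deg`) and maps the
#' device accelerometer and orientation columns onto body-frame channels
#' (ML/AP/Vert accelerations, tilt/rotation/obliquity angles).
#'
#' @param path Path to the trial CSV.
#' @param axis_map Device-to-body mapping, see [default_axis_map()].
#' @param participant_id Identifier attached to the trial; defaults to the
#'   file name without extension.
#' @return A `raw_trial` object with strictly increasing timestamps.
#' @export
load_trial <- function(path, axis_map = default_axis_map(),
                       participant_id = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  dt <- data.table::fread(path, colClasses = "numeric", showProgress = FALSE)
  missing_cols <- setdiff(trial_csv_columns(), names(dt))
  if (length(missing_cols) > 0)
    stop("trial CSV schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(vapply(dt, function(col) any(!is.finite(col)), logical(1)))
  if (length(bad) > 0) {
    row <- which(!is.finite(dt[[bad[1]]]))[1]
    stop("malformed value in ", path, " at data row ", row,
         " (column ", names(dt)[bad[1]], ")")
  }
  tm <- dt$time_s
  if (any(diff(tm) <= 0)) {
    row <- which(diff(tm) <= 0)[1] + 1L
    stop("non-increasing timestamps in ", path, " at data row ", row)
  }
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  am <- axis_map
  new_raw_trial(
    participant_id, tm,
    ml = dt[[am$accel[["ml"]]]],
    ap = dt[[am$accel[["ap"]]]],
    vert = dt[[am$accel[["vert"]]]],
    tilt = dt[[am$orientation[["tilt"]]]],
    rotation = dt[[am$orientation[["rotation"]]]],
    obliquity = dt[[am$orientation[["obliquity"]]]],
    gyro = cbind(gx = dt$gx, gy = dt$gy, gz = dt$gz)
  )
}

body_channels <- function() {
  c("ml", "ap", "vert", "tilt", "rotation", "obliquity")
}

new_uniform_trial <- function(participant_id, rate, channels, gyro = NULL) {
  n <- length(channels$ml)
  stopifnot(all(vapply(channels, length, integer(1)) == n), rate > 0)
  structure(c(list(participant_id = participant_id, rate = rate,
                   n_samples = n), channels, list(gyro = gyro)),
            class = "uniform_trial")
}

#' Resample a raw trial to a fixed rate
#'
#' Linearly interpolates every channel onto the uniform grid
#' `t_k = t_0 + k / rate`, `k = 0 .. floor((t_last - t_0) * rate)`. The grid
#' never extends beyond the last recorded timestamp, so no samples are
#' extrapolated.
#'
#' @param raw A `raw_trial`.
#' @param cfg A [preprocess_config()].
#' @return A `uniform_trial` at `cfg$target_rate_hz`.
#' @export
resample_fixed_rate <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "raw_trial"))
  rate <- cfg$target_rate_hz
  t0 <- raw$time[1]
  t_last <- raw$time[length(raw$time)]
  if ((t_last - t0) <= 2 / rate)
    stop("trial too short to resample: duration ", signif(t_last - t0, 4),
         " s at target rate ", rate, " Hz")
  # small epsilon so grids landing exactly on t_last survive rounding noise
  n_out <- floor((t_last - t0) * rate + 1e-9) + 1L
  grid <- t0 + (seq_len(n_out) - 1L) / rate
  interp <- function(v)
    stats::approx(raw$time, v, xout = grid, method = "linear", rule = 2)$y
  channels <- lapply(stats::setNames(body_channels(), body_channels()),
                     function(ch) interp(raw[[ch]]))
  gyro <- apply(raw$gyro, 2, interp)
  new_uniform_trial(raw$participant_id, rate, channels, gyro = gyro)
}

butter_coefs <- function(cfg, rate) {
  signal::butter(cfg$filter_order, cfg$cutoff_hz / (rate / 2), type = "low")
}

# Samples for the filter's impulse response to decay below `tol`, from the
# largest pole radius of the recursion.
impulse_settle_length <- function(bf, tol = 1e-12) {
  r <- max(Mod(polyroot(rev(bf$a))))
  if (r >= 1) stop("unstable filter design")
  ceiling(log(tol) / log(r))
}

filtfilt_reflect <- function(x, bf, pad) {
  n <- length(x)
  # odd (point-symmetric) reflection about the end samples
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-lag Butterworth low-pass filtering
#'
#' Applies the configured Butterworth low-pass filter forward then backward
#' (zero net phase, squared magnitude response) to the six body-frame
#' channels of a uniform trial. Edges are handled by odd-reflection padding
#' three times the filter's effective impulse length, which suppresses the
#' startup transients of both passes.
#'
#' @param trial A `uniform_trial`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `uniform_trial`.
#' @export
lowpass_zero_lag <- function(trial, cfg = preprocess_config()) {
  stopifnot(inherits(trial, "uniform_trial"))
  bf <- butter_coefs(cfg, trial$rate)
  pad <- 3L * impulse_settle_length(bf)
  if (trial$n_samples <= pad)
    stop("trial too short for stable forward-backward filtering: need more ",
         "than ", pad, " samples, got ", trial$n_samples)
  for (ch in body_channels())
    trial[[ch]] <- filtfilt_reflect(trial[[ch]], bf, pad)
  trial
}

#' Preprocess one trial end to end
#'
#' Convenience wrapper: resample to the fixed rate, then zero-lag low-pass
#' filter. Accepts either a `raw_trial` or a path to a trial CSV.
#'
#' @param x A `raw_trial` or a file path.
#' @param cfg A [preprocess_config()].
#' @return A filtered `uniform_trial`.
#' @export
preprocess_trial <- function(x, cfg = preprocess_config()) {
  if (is.character(x)) x <- load_trial(x, cfg$axis_map)
  lowpass_zero_lag(resample_fixed_rate(x, cfg), cfg)
}
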