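#' Gait-signal generator parameters
#'
#' Parameters of the harmonic-plus-pulse gait signal model used to emulate
#' pelvis-worn smartphone recordings of a six-minute walk.
#'
#' @param cadence Steps per minute.
#' @param step_time_cv Fractional SD of step durations (lognormal jitter).
#' @param asymmetry Fractional right/left step-time difference: right steps
#'   average `(1 + asymmetry/2)`, left `(1 - asymmetry/2)` times the mean
#'   step time.
#' @param ap_pulse_amp Amplitude (m/s^2) of the foot-strike-locked Gaussian
#'   pulses on the anterior-posterior channel.
#' @param ml_sway_amp Medio-lateral sway amplitude (m/s^2), at stride
#'   frequency (sign alternates with stance side).
#' @param vert_amp Vertical oscillation amplitude (m/s^2) at step frequency,
#'   on top of gravity.
#' @param orientation_amp Orientation oscillation amplitudes in degrees for
#'   tilt, rotation, obliquity (length 3).
#' @param noise_sd White-noise SD (m/s^2) added to the accelerations.
#' @param sampling_jitter Fractional SD of inter-sample intervals around
#'   the nominal 20 ms.
#' @param duration Trial duration in seconds (default 360, a 6MWT).
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(cadence = 100, step_time_cv = 0.05,
                        asymmetry = 0.05, ap_pulse_amp = 2.5,
                        ml_sway_amp = 1.0, vert_amp = 1.5,
                        orientation_amp = c(4, 6, 3), noise_sd = 0.15,
                        sampling_jitter = 0.1, duration = 360) {
  stopifnot(cadence > 0, step_time_cv >= 0, step_time_cv < 0.5,
            asymmetry >= 0, asymmetry < 1, duration > 0,
            length(orientation_amp) == 3)
  structure(as.list(environment()), class = "gait_params")
}

lognormal_around <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic 6MWT trial with ground truth
#'
#' Foot-strike times are an alternating-side renewal process with mean step
#' time `60 / cadence`, per-side means split by `asymmetry`, and lognormal
#' jitter with coefficient of variation `step_time_cv`. Signals: vertical =
#' gravity plus a sinusoid at step frequency; AP = Gaussian pulses (SD
#' 0.05 s, i.e. ~0.1 s wide) centred on each foot strike plus a small
#' harmonic at step frequency; ML = sway at stride frequency whose sign
#' alternates with stance side; orientation channels = smooth sinusoids at
#' stride frequency. All oscillatory components are phased by the gait
#' cycle itself (interpolated between the jittered strike times), so
#' harmonic peaks stay locked to foot strikes. White noise is added to the
#' sample clock carries lognormal jitter around 20 ms, emulating a
#' variably-sampled smartphone recording near 50 Hz.
#'
#' @param params A [gait_params()].
#' @param seed Integer seed; identical seeds give identical trials.
#' @param participant_id Identifier for the trial.
#' @return A list with `raw` (a `raw_trial` in body-frame channels) and
#'   `truth` (list: `strike_times` seconds, `sides`, `params`).
#' @export
generate_trial <- function(params = gait_params(), seed = 1L,
                           participant_id = "sim") {
  stopifnot(inherits(params, "gait_params"))
  set.seed(as.integer(seed))
  T_step <- 60 / params$cadence
  f_step <- params$cadence / 60
  f_stride <- f_step / 2

  # alternating-side renewal process for strike times
  n_max <- ceiling(params$duration / T_step) + 20L
  sides <- rep_len(c("left", "right"), n_max)
  side_mean <- ifelse(sides == "right", T_step * (1 + params$asymmetry / 2),
                      T_step * (1 - params$asymmetry / 2))
  gaps <- lognormal_around(n_max, 1, params$step_time_cv) * side_mean
  t1 <- T_step / 2
  strike_times <- t1 + c(0, cumsum(gaps[-n_max]))
  keep <- strike_times <= params$duration - T_step / 2 + 1e-9
  strike_times <- strike_times[keep]
  sides <- sides[keep]

  # jittered sample clock around 20 ms
  n_samp <- ceiling(params$duration / 0.02) + 100L
  dt <- lognormal_around(n_samp, 0.02, params$sampling_jitter)
  tm <- c(0, cumsum(dt))
  tm <- tm[tm <= params$duration]
  n <- length(tm)

  # gait phase: step count as a continuous function of time, interpolated
  # between the jittered strike times so every harmonic stays locked to
  # the gait cycle (a wall-clock phase would drift off the renewal
  # process and put harmonic peaks mid-gap)
  s_of_t <- stats::approx(strike_times, seq_along(strike_times) - 1,
                          xout = tm, rule = 2)$y
  step_phase <- 2 * pi * s_of_t     # one cycle per step, peaks at strikes
  stride_phase <- pi * s_of_t       # one cycle per stride
  vert <- 9.81 + params$vert_amp * sin(step_phase)
  ml <- params$ml_sway_amp * sin(stride_phase)
  ap <- 0.2 * params$ap_pulse_amp * cos(step_phase)
  pulse_sd <- 0.05
  for (s in strike_times) {
    win <- which(tm >= s - 5 * pulse_sd & tm <= s + 5 * pulse_sd)
    ap[win] <- ap[win] +
      params$ap_pulse_amp * exp(-(tm[win] - s)^2 / (2 * pulse_sd^2))
  }
  if (params$noise_sd > 0) {
    ml <- ml + stats::rnorm(n, 0, params$noise_sd)
    ap <- ap + stats::rnorm(n, 0, params$noise_sd)
    vert <- vert + stats::rnorm(n, 0, params$noise_sd)
  }
  oa <- params$orientation_amp
  tilt <- 5 + oa[1] * sin(stride_phase + 0.5)
  rotation <- oa[2] * sin(stride_phase)
  obliquity <- oa[3] * sin(stride_phase + 2.0)
  gyro <- cbind(gx = 0.3 * cos(stride_phase),
                gy = 0.5 * sin(stride_phase + 1.0),
                gz = 0.2 * cos(stride_phase + 0.3))

  raw <- new_raw_trial(participant_id, tm, ml = ml, ap = ap, vert = vert,
                       tilt = tilt, rotation = rotation,
                       obliquity = obliquity, gyro = gyro)
  list(raw = raw,
       truth = list(strike_times = strike_times, sides = sides,
                    params = params, seed = as.integer(seed)))
}

#' Class-conditional cohort specification
#'
#' Default class parameters encode the expected gait differences between
#' balance-confidence groups in lower-limb prosthesis users: the
#' low-confidence class walks slower (lower cadence) with more variable
#' step timing, more right/left asymmetry, and more medio-lateral sway.
#'
#' @param n_per_class Trials per class (>= 3).
#' @param params_high,params_low [gait_params()] for the high- and
#'   low-confidence classes.
#' @param abc_range_high,abc_range_low Uniform sampling ranges (percent)
#'   for the ABC scores of each class; the high range sits at or above the
#'   80% threshold, the low range below it.
#' @param seed Cohort seed; all per-trial seeds derive from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 20,
                        params_high = gait_params(cadence = 105,
                                                  step_time_cv = 0.04,
                                                  asymmetry = 0.04,
                                                  ml_sway_amp = 0.8),
                        params_low = gait_params(cadence = 88,
                                                 step_time_cv = 0.09,
                                                 asymmetry = 0.12,
                                                 ml_sway_amp = 1.5),
                        abc_range_high = c(80, 100),
                        abc_range_low = c(15, 79.5),
                        seed = 1L) {
  stopifnot(n_per_class >= 3)
  structure(list(n_per_class = n_per_class, params_high = params_high,
                 params_low = params_low, abc_range_high = abc_range_high,
                 abc_range_low = abc_range_low, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null cohort specification (no class signal)
#'
#' Both classes share identical gait parameters; only the ABC scores (and
#' hence labels) differ. Classifier accuracy on such a cohort should sit at
#' the majority-class rate.
#'
#' @inheritParams cohort_spec
#' @param params Shared [gait_params()] for both classes.
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(n_per_class = 20, params = gait_params(),
                             seed = 1L) {
  cohort_spec(n_per_class = n_per_class, params_high = params,
              params_low = params, seed = seed)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_class` trials per class with class-conditional gait
#' parameters, ABC scores sampled consistently with the class labels, and
#' an optional self-reported fall history carried as metadata only.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `sim_cohort`: `trials` (list of
#'   [generate_trial()] results) and `manifest` (data.frame
#'   `participant_id,class,abc_score,fall_history,seed`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_total <- 2L * spec$n_per_class
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  classes <- rep(c("high", "low"), each = spec$n_per_class)
  ids <- sprintf("P%03d", seq_len(n_total))
  abc <- ifelse(classes == "high",
                stats::runif(n_total, spec$abc_range_high[1],
                             spec$abc_range_high[2]),
                stats::runif(n_total, spec$abc_range_low[1],
                             spec$abc_range_low[2]))
  fall <- stats::runif(n_total) < ifelse(classes == "high", 0.25, 0.40)
  trials <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- if (classes[i] == "high") spec$params_high else spec$params_low
    trials[[i]] <- generate_trial(p, seed = trial_seeds[i],
                                  participant_id = ids[i])
    trials[[i]]$truth$class <- classes[i]
  }
  manifest <- data.frame(participant_id = ids, class = classes,
                         abc_score = abc, fall_history = fall,
                         seed = trial_seeds, stringsAsFactors = FALSE)
  structure(list(trials = trials, manifest = manifest),
            class = "sim_cohort")
}

#' Write a trial to the device-frame CSV schema
#'
#' Serializes a body-frame `raw_trial` back to the on-disk trial schema
#' (`time_s,ax,ay,az,gx,gy,gz,azimuth_deg,pitch_deg,roll_deg`) by
#' inverting the axis map, so the file round-trips through [load_trial()].
#'
#' @param raw A `raw_trial`.
#' @param path Output CSV path.
#' @param axis_map The device-to-body mapping to invert.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(raw, path, axis_map = default_axis_map()) {
  stopifnot(inherits(raw, "raw_trial"))
  cols <- list(time_s = raw$time,
               gx = raw$gyro[, 1], gy = raw$gyro[, 2], gz = raw$gyro[, 3])
  for (body in names(axis_map$accel))
    cols[[axis_map$accel[[body]]]] <- raw[[body]]
  for (body in names(axis_map$orientation))
    cols[[axis_map$orientation[[body]]]] <- raw[[body]]
  dt <- data.table::as.data.table(cols)[, trial_csv_columns(), with = FALSE]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits one trial CSV per participant (`trial_<id>.csv`), the per-trial
#' ground-truth strikes (`truth_<id>.csv`: `time_s,side`), a cohort file
#' (`cohort.csv`: `participant_id,abc_score,fall_history`), and a manifest.
#'
#' @param cohort A `sim_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trials) {
    id <- tr$raw$participant_id
    write_trial_csv(tr$raw, file.path(dir, paste0("trial_", id, ".csv")))
    utils::write.csv(data.frame(time_s = tr$truth$strike_times,
                                side = tr$truth$sides),
                     file.path(dir, paste0("truth_", id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$manifest[, c("participant_id", "abc_score",
                                       "fall_history")],
                   file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
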