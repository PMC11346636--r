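#' Foot-strike cleanup configuration
#'
#' @param gap_factor A gap is flagged as containing a missed step when the
#'   inter-strike duration is at least `gap_factor` times the immediately
#'   preceding inter-strike duration. Dimensionless, > 1.
#' @param locking_fraction Refractory (locking) period around existing
#'   strikes, as a fraction of the trial's median inter-strike duration.
#' @param max_insert_passes Upper bound on missed-step insertion passes.
#' @param prominence_factor Minimum peak prominence for an AP local maximum
#'   to count as a foot-strike apex, as a fraction of the AP channel's
#'   standard deviation.
#' @return A list of class `cleanup_config`.
#' @export
cleanup_config <- function(gap_factor = 1.5, locking_fraction = 0.5,
                           max_insert_passes = 10, prominence_factor = 0.3) {
  if (gap_factor <= 1) stop("gap_factor must be > 1")
  if (locking_fraction <= 0 || locking_fraction >= 1)
    stop("locking_fraction must be in (0, 1)")
  structure(list(gap_factor = gap_factor, locking_fraction = locking_fraction,
                 max_insert_passes = max_insert_passes,
                 prominence_factor = prominence_factor),
            class = "cleanup_config")
}

#' Construct a foot-strike series
#'
#' @param strikes Strictly increasing sample indices (1-based) into a
#'   `uniform_trial`.
#' @param source Per-strike provenance: `detected`, `external`, or
#'   `inserted`.
#' @param side Per-strike side label: `left`, `right`, or `unassigned`.
#' @param n_samples Number of samples in the parent trial (index bound).
#' @return A data.frame of class `footstrike_series` with columns
#'   `sample_index`, `source`, `side`.
#' @export
footstrike_series <- function(strikes, source = "detected",
                              side = "unassigned", n_samples = NULL) {
  strikes <- as.integer(strikes)
  if (length(strikes) > 1 && any(diff(strikes) <= 0))
    stop("strike indices must be strictly increasing")
  if (!is.null(n_samples) && length(strikes) > 0 &&
      (min(strikes) < 1L || max(strikes) > n_samples))
    stop("strike indices out of range [1, n_samples]")
  source <- rep_len(as.character(source), length(strikes))
  side <- rep_len(as.character(side), length(strikes))
  stopifnot(all(source %in% c("detected", "external", "inserted")),
            all(side %in% c("left", "right", "unassigned")))
  structure(data.frame(sample_index = strikes, source = source, side = side,
                       stringsAsFactors = FALSE),
            class = c("footstrike_series", "data.frame"))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left_min <- h
    j <- p - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < left_min) left_min <- x[j]
      j <- j - 1L
    }
    if (j < 1L) left_min <- min(x[1:p])
    right_min <- h
    j <- p + 1L
    n <- length(x)
    while (j <= n && x[j] <= h) {
      if (x[j] < right_min) right_min <- x[j]
      j <- j + 1L
    }
    if (j > n) right_min <- min(x[p:n])
    h - max(left_min, right_min)
  }, numeric(1))
}

# Prominent local maxima of the AP channel: the "apexes" that anchor
# detection, extra-prediction grouping, and missed-step insertion.
ap_apexes <- function(trial, cfg = cleanup_config()) {
  ap <- trial$ap
  s <- stats::sd(ap)
  if (!is.finite(s) || s == 0) return(integer(0))
  peaks <- local_maxima(ap)
  if (length(peaks) == 0) return(integer(0))
  prom <- peak_prominence(ap, peaks)
  peaks[prom >= cfg$prominence_factor * s]
}

#' Detect candidate foot strikes from the AP acceleration channel
#'
#' Baseline candidate detector standing in for an external step-detection
#' model: a foot strike corresponds to a peak in the anterior-posterior
#' acceleration, so candidates are the AP local maxima whose prominence
#' exceeds an adaptive threshold (a fraction of the trial's AP standard
#' deviation).
#'
#' @param trial A filtered `uniform_trial`.
#' @param cfg A [cleanup_config()] (supplies the prominence threshold).
#' @return A `footstrike_series` with `source = "detected"`.
#' @export
detect_candidates <- function(trial, cfg = cleanup_config()) {
  stopifnot(inherits(trial, "uniform_trial"))
  footstrike_series(ap_apexes(trial, cfg), source = "detected",
                    n_samples = trial$n_samples)
}

nearest_apex <- function(idx, apexes) {
  # index into `apexes` of the nearest apex; ties -> earlier apex
  pos <- findInterval(idx, apexes)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(apexes))
  d_lo <- abs(idx - apexes[lo])
  d_hi <- abs(idx - apexes[hi])
  ifelse(d_lo <= d_hi, lo, hi)
}

#' Remove extra foot-strike predictions
#'
#' Consecutive predictions crowding a single AP acceleration peak (typically
#' immediately before or after the apex) are reduced to the one prediction
#' closest to that apex; equidistant ties keep the earlier prediction.
#' Candidates are grouped by their nearest prominent AP apex.
#'
#' @param candidates A `footstrike_series`.
#' @param trial The parent filtered `uniform_trial`.
#' @param cfg A [cleanup_config()].
#' @return A `footstrike_series` with at most one strike per apex
#'   neighborhood.
#' @export
remove_extra_predictions <- function(candidates, trial,
                                     cfg = cleanup_config()) {
  stopifnot(inherits(candidates, "footstrike_series"))
  if (nrow(candidates) <= 1) return(candidates)
  apexes <- ap_apexes(trial, cfg)
  if (length(apexes) == 0) return(candidates)
  grp <- nearest_apex(candidates$sample_index, apexes)
  keep <- unlist(lapply(split(seq_len(nrow(candidates)), grp), function(rows) {
    d <- abs(candidates$sample_index[rows] - apexes[grp[rows[1]]])
    rows[which.min(d)]  # which.min keeps the earlier row on ties
  }), use.names = FALSE)
  out <- candidates[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Insert missed foot strikes
#'
#' Flags inter-strike gaps at least `gap_factor` (default 1.5) times the
#' immediately preceding inter-strike duration as containing a missed step.
#' Within each flagged gap, outside an adaptive locking period around the
#' flanking strikes (a fraction of the trial's median inter-strike
#' duration), the largest prominent AP acceleration peak is inserted as a
#' new strike. Passes repeat, recomputing durations, until no gap is flagged
#' or `max_insert_passes` is reached.
#'
#' @param strikes A `footstrike_series` with at least 3 strikes.
#' @param trial The parent filtered `uniform_trial`.
#' @param cfg A [cleanup_config()].
#' @return A `footstrike_series` including inserted strikes
#'   (`source = "inserted"`).
#' @export
insert_missed_steps <- function(strikes, trial, cfg = cleanup_config()) {
  stopifnot(inherits(strikes, "footstrike_series"))
  if (nrow(strikes) < 3) {
    warning("fewer than 3 strikes; missed-step insertion skipped")
    return(strikes)
  }
  apexes <- ap_apexes(trial, cfg)
  for (pass in seq_len(cfg$max_insert_passes)) {
    idx <- strikes$sample_index
    d <- diff(idx)
    L <- max(1L, round(cfg$locking_fraction * stats::median(d)))
    flagged <- which(d[-1] >= cfg$gap_factor * d[-length(d)]) + 1L
    if (length(flagged) == 0) break
    inserted <- integer(0)
    for (g in flagged) {
      left <- idx[g]
      right <- idx[g + 1L]
      win <- apexes[apexes >= left + L & apexes <= right - L]
      if (length(win) == 0) next
      inserted <- c(inserted, win[which.max(trial$ap[win])])
    }
    inserted <- setdiff(inserted, idx)
    if (length(inserted) == 0) break
    add <- footstrike_series(sort(inserted), source = "inserted",
                             n_samples = trial$n_samples)
    strikes <- merge_strikes(strikes, add)
  }
  strikes
}

merge_strikes <- function(a, b) {
  m <- rbind(as.data.frame(a), as.data.frame(b))
  m <- m[order(m$sample_index), , drop = FALSE]
  m <- m[!duplicated(m$sample_index), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("footstrike_series", "data.frame")
  m
}

enforce_min_separation <- function(strikes, trial, L) {
  repeat {
    idx <- strikes$sample_index
    if (length(idx) < 2) return(strikes)
    v <- which(diff(idx) < L)
    if (length(v) == 0) return(strikes)
    i <- v[1]
    # keep the strike sitting on the higher AP value; ties keep the earlier
    drop_row <- if (trial$ap[idx[i]] >= trial$ap[idx[i + 1L]]) i + 1L else i
    strikes <- strikes[-drop_row, , drop = FALSE]
    rownames(strikes) <- NULL
  }
}

#' Clean a candidate foot-strike series
#'
#' Full post-processing used before feature calculation: extra-prediction
#' removal, then missed-step insertion, then enforcement of the locking
#' period as a minimum separation (dropping the lower-AP strike of any pair
#' closer than the locking period). The result is sorted and deduplicated,
#' and the operation is idempotent.
#'
#' @param candidates A `footstrike_series` (detected or externally
#'   supplied).
#' @param trial The parent filtered `uniform_trial`.
#' @param cfg A [cleanup_config()].
#' @return The cleaned `footstrike_series`.
#' @export
clean_footstrikes <- function(candidates, trial, cfg = cleanup_config()) {
  out <- remove_extra_predictions(candidates, trial, cfg)
  if (nrow(out) >= 3) out <- insert_missed_steps(out, trial, cfg)
  if (nrow(out) >= 2) {
    L <- max(1L, round(cfg$locking_fraction *
                         stats::median(diff(out$sample_index))))
    out <- enforce_min_separation(out, trial, L)
  }
  rownames(out) <- NULL
  out
}

#' Read / write foot-strike CSV files
#'
#' Round-trip stable CSV with columns `sample_index,source,side`.
#'
#' @param strikes A `footstrike_series`.
#' @param path File path.
#' @return `read_footstrikes` returns a `footstrike_series`;
#'   `write_footstrikes` returns `path` invisibly.
#' @export
write_footstrikes <- function(strikes, path) {
  utils::write.csv(as.data.frame(strikes), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_footstrikes
#' @export
read_footstrikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  footstrike_series(df$sample_index, source = df$source, side = df$side)
}
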