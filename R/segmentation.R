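# Onward-movement segmentation from the speed profile.
#
# The onward movement is bounded by crossings of a relative speed threshold
# (5% of peak speed by default): walking back in time from the peak, onset is
# the sample after the first sub-threshold sample; walking forward, end is
# the last sample that stays at or above threshold before the first
# sub-threshold sample. Implausible segments trigger an automatic fallback.

#' Movement onset from the speed profile
#'
#' @param rv Speed profile (non-negative).
#' @param peak Index of the peak speed (defaults to the first global argmax).
#' @param threshold_frac Fraction of the peak speed used as threshold
#'   (default 0.05).
#' @return Onset sample index; 1 if no sub-threshold sample precedes the peak.
#' @export
find_onset <- function(rv, peak = which.max(rv), threshold_frac = 0.05) {
  if (length(rv) == 0L) stop("empty speed profile")
  thr <- threshold_frac * rv[peak]
  below <- which(rv[seq_len(peak - 1L)] < thr)
  if (length(below) == 0L) 1L else max(below) + 1L
}

#' Movement end from the speed profile
#'
#' @inheritParams find_onset
#' @return End sample index: the last sample at/above threshold before the
#'   first sub-threshold sample after the peak; the last index if speed never
#'   drops below threshold.
#' @export
find_end <- function(rv, peak = which.max(rv), threshold_frac = 0.05) {
  n <- length(rv)
  if (n == 0L) stop("empty speed profile")
  thr <- threshold_frac * rv[peak]
  after <- if (peak < n) which(rv[(peak + 1L):n] < thr) else integer()
  if (length(after) == 0L) n else peak + min(after) - 1L
}

# Longest contiguous supra-threshold run (ties -> earliest); rescue used when
# the primary segment fails the plausibility gates.
.longest_run_segment <- function(rv, threshold_frac) {
  thr <- threshold_frac * max(rv)
  r <- rle(rv >= thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  j <- keep[which.max(r$lengths[keep])]
  onset <- starts[j]
  end <- ends[j]
  peak <- onset - 1L + which.max(rv[onset:end])
  list(onset = onset, end = end, peak = peak)
}

#' Segment the onward movement of one effector
#'
#' Peak = first global argmax of the speed profile; onset/end via
#' [find_onset()] and [find_end()]. If the segment fails the plausibility
#' gates (duration below `min_duration_s`, or displacement below
#' `min_displacement_frac` of the trial's RD range) the fallback re-detects
#' using the longest contiguous supra-threshold region; if that segment fails
#' the gates too (speed buried in noise), the whole trial is used — trials
#' begin and end at rest, so the full-trial RD difference remains an unbiased
#' displacement estimate. Rescued trials are flagged.
#'
#' @param series A [kinematic_series()] (or any list with `rd`, `rv`, `fs`).
#' @param config A [pipeline_config()].
#' @param profiles If `TRUE` (default), attach 100-point resampled RD and RV
#'   profiles of the segment.
#' @return Object of class `movement_segment`: `onset`, `end`, `peak`,
#'   `peak_speed`, `fallback`, and optionally `profile_rd`, `profile_rv`.
#' @export
segment_onward <- function(series, config = pipeline_config(),
                           profiles = TRUE) {
  rv <- series$rv
  rd <- series$rd
  if (max(rv) <= 0) stop("no movement detected: speed profile is identically zero")
  rng <- max(rd) - min(rd)
  gates_ok <- function(onset, end) {
    (end - onset) / series$fs >= config$min_duration_s &&
      (rng == 0 ||
         abs(rd[end] - rd[onset]) >= config$min_displacement_frac * rng)
  }
  peak <- which.max(rv)
  onset <- find_onset(rv, peak, config$threshold_frac)
  end <- find_end(rv, peak, config$threshold_frac)
  fallback <- FALSE
  if (!gates_ok(onset, end)) {
    seg <- .longest_run_segment(rv, config$threshold_frac)
    fallback <- TRUE
    if (gates_ok(seg$onset, seg$end)) {
      onset <- seg$onset
      end <- seg$end
      peak <- seg$peak
    } else {
      # speed is buried in noise: take the whole trial (rest at both ends)
      onset <- 1L
      end <- length(rv)
      peak <- which.max(rv)
    }
  }
  out <- list(
    onset = onset, end = end, peak = peak,
    peak_speed = rv[peak], fallback = fallback
  )
  if (profiles) {
    out$profile_rd <- resample_100(rd, onset, end)
    out$profile_rv <- resample_100(rv, onset, end)
  }
  structure(out, class = "movement_segment")
}

#' Resample a segmented profile to 100 time points
#'
#' Linear interpolation of `profile[onset..end]` onto `n_points` equally
#' spaced points including both endpoints.
#'
#' @param profile Numeric series.
#' @param onset,end Segment bounds (sample indices, `end - onset >= 2`).
#' @param n_points Number of output points (default 100).
#' @return Numeric vector of length `n_points`.
#' @export
resample_100 <- function(profile, onset, end, n_points = 100L) {
  if (end - onset < 2L) stop("degenerate segment: end - onset must be >= 2")
  idx <- onset:end
  stats::approx(idx, profile[idx],
                xout = seq(onset, end, length.out = n_points))$y
}
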