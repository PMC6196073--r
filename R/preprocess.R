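# Preprocessing: wrist-frame transform, zero-lag low-pass filtering,
# resultant displacement (RD) and resultant velocity (RV).
#
# Filtering precedes differentiation and is applied per axis. Positions are
# expressed relative to the wrist reference sensor before anything else.

.filter_cache <- new.env(parent = emptyenv())

.butter_coefs <- function(order, cutoff, fs) {
  key <- paste(order, cutoff, fs, sep = "|")
  bf <- .filter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
    .filter_cache[[key]] <- bf
  }
  bf
}

# One causal pass over the columns of a matrix, zero initial state after
# removing each column's first value (the filter has DC gain exactly 1, so
# the offset passes through unchanged); vectorized across columns so whole
# batches of trials are filtered in one recursion.
.butter_pass_mat <- function(bf, X) {
  b <- bf$b
  a <- bf$a
  n <- nrow(X)
  m <- ncol(X)
  x1 <- X[1, ]
  off <- matrix(x1, n, m, byrow = TRUE)
  Xc <- X - off
  U <- b[1] * Xc
  for (j in 2:length(b)) {
    U[j:n, ] <- U[j:n, ] + b[j] * Xc[1:(n - j + 1), , drop = FALSE]
  }
  Y <- U
  for (i in 2:n) {
    acc <- U[i, ]
    for (j in 2:length(a)) {
      if (i - j + 1L >= 1L) acc <- acc - a[j] * Y[i - j + 1L, ]
    }
    Y[i, ] <- acc
  }
  Y + off
}

# Zero-phase (forward-backward) pass over matrix columns with reflective
# (odd) padding of 3 * order samples at both ends.
.zerophase_mat <- function(X, fs, cutoff, order) {
  n <- nrow(X)
  p <- 3L * order
  bf <- .butter_coefs(order, cutoff, fs)
  m <- ncol(X)
  front <- 2 * matrix(X[1, ], p, m, byrow = TRUE) - X[(p + 1):2, , drop = FALSE]
  back <- 2 * matrix(X[n, ], p, m, byrow = TRUE) - X[(n - 1):(n - p), , drop = FALSE]
  E <- rbind(front, X, back)
  Y <- .butter_pass_mat(bf, E)
  Y <- .butter_pass_mat(bf, Y[rev(seq_len(nrow(Y))), , drop = FALSE])
  # Y is in reversed time; undo the reversal and drop the padding.
  Y[(nrow(Y) - p):(p + 1), , drop = FALSE]
}

#' Zero-lag low-pass Butterworth filter
#'
#' Second-order (by default) Butterworth response applied forward and
#' backward, giving zero phase shift at every frequency and squared
#' magnitude attenuation. Edges are handled by reflective (odd) padding of
#' `3 * order` samples on both ends.
#'
#' @param x Numeric series (one position axis).
#' @param fs Sampling frequency, Hz.
#' @param cutoff Cutoff frequency, Hz (default 5).
#' @param order Filter order for each pass (default 2).
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 5, order = 2) {
  n <- length(x)
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  if (n <= 3L * order + 1L) stop("series too short for stable filter edge handling")
  as.numeric(.zerophase_mat(matrix(x, ncol = 1), fs, cutoff, order))
}

.lowpass_matrix <- function(P, fs, cutoff, order) {
  n <- nrow(P)
  if (fs <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  if (n <= 3L * order + 1L) stop("series too short for stable filter edge handling")
  .zerophase_mat(P, fs, cutoff, order)
}

#' Express a recording in the wrist (reference-sensor) frame
#'
#' Subtracts the reference sensor's simultaneous position from every sensor;
#' the reference itself becomes identically zero. Kinematic measures are
#' thereby invariant to rigid translations of the whole hand (and of the lab
#' frame).
#'
#' @param rec A [trial_recording()] containing the `"reference"` sensor.
#' @return A new `trial_recording` in the wrist frame.
#' @export
to_wrist_frame <- function(rec) {
  ref <- rec$positions[["reference"]]
  if (is.null(ref)) {
    stop(sprintf("trial %s: missing sensor(s): reference", rec$trial_index))
  }
  rec$positions <- lapply(rec$positions, function(P) P - ref)
  rec
}

#' Five-point-stencil derivative
#'
#' Central five-point stencil on interior samples,
#' `f'(t) = (-f(t+2h) + 8 f(t+h) - 8 f(t-h) + f(t-2h)) / (12 h)`, exact for
#' polynomials up to degree 4. The two samples at each edge use one-sided
#' differences of progressively lower order (4-point, then 3-point), so the
#' output has the input's length.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency, Hz (`h = 1/fs`).
#' @return Derivative series, same length as `x`.
#' @export
stencil_derivative <- function(x, fs) {
  n <- length(x)
  if (n < 5L) stop("five-point stencil needs at least 5 samples")
  h <- 1 / fs
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (-x[i + 2] + 8 * x[i + 1] - 8 * x[i - 1] + x[i - 2]) / (12 * h)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * h)
  d[2] <- (-2 * x[1] - 3 * x[2] + 6 * x[3] - x[4]) / (6 * h)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * h)
  d[n - 1] <- (-2 * x[n] - 3 * x[n - 1] + 6 * x[n - 2] - x[n - 3]) / (-6 * h)
  d
}

.stencil_matrix <- function(P, fs) {
  cbind(
    stencil_derivative(P[, 1], fs),
    stencil_derivative(P[, 2], fs),
    stencil_derivative(P[, 3], fs)
  )
}

#' Resultant displacement from the rest position
#'
#' Per-sample Euclidean distance from the rest point:
#' `RD(t) = sqrt((x - x0)^2 + (y - y0)^2 + (z - z0)^2)`.
#'
#' @param xyz n x 3 matrix of (filtered) positions, cm, wrist frame.
#' @param rest Length-3 rest position `(x0, y0, z0)` in the same frame.
#' @return Non-negative numeric series, cm.
#' @export
resultant_displacement <- function(xyz, rest) {
  xyz <- rbind(xyz) # tolerate a single sample given as a vector
  stopifnot(ncol(xyz) == 3L, length(rest) == 3L)
  sqrt((xyz[, 1] - rest[1])^2 + (xyz[, 2] - rest[2])^2 + (xyz[, 3] - rest[3])^2)
}

#' Resultant velocity (speed profile)
#'
#' Euclidean norm of the per-axis five-point-stencil derivatives. The rest
#' position is accepted for interface symmetry with
#' [resultant_displacement()] but does not affect the derivative of a
#' constant-shifted series.
#'
#' @param xyz n x 3 matrix of (filtered) positions, cm.
#' @param rest Ignored (kept for interface symmetry); default `NULL`.
#' @param fs Sampling frequency, Hz.
#' @return Non-negative speed series, cm/s.
#' @export
resultant_velocity <- function(xyz, rest = NULL, fs) {
  D <- .stencil_matrix(xyz, fs)
  sqrt(D[, 1]^2 + D[, 2]^2 + D[, 3]^2)
}

#' Build the kinematic series (RD, RV) for one effector
#'
#' Runs the preprocessing chain for the thumb tip or the task's target
#' phalanx: wrist-frame transform, per-axis zero-lag low-pass filter, rest
#' position as the mean of the first `rest_samples` filtered samples, then
#' resultant displacement and velocity.
#'
#' @param rec A [trial_recording()].
#' @param effector `"thumb"` (thumb distal sensor) or `"finger"` (the task's
#'   target phalanx sensor).
#' @param config A [pipeline_config()].
#' @return Object of class `kinematic_series`: list with `effector`, `rd`,
#'   `rv`, `fs`, `rest`.
#' @export
kinematic_series <- function(rec, effector = c("thumb", "finger"),
                             config = pipeline_config()) {
  effector <- match.arg(effector)
  s <- if (effector == "thumb") "thumb_distal" else
    target_sensor(rec$finger, rec$phalanx)
  ref <- rec$positions[["reference"]]
  if (is.null(ref)) {
    stop(sprintf("trial %s: missing sensor(s): reference", rec$trial_index))
  }
  P <- rec$positions[[s]]
  if (is.null(P)) {
    stop(sprintf("trial %s: missing sensor(s): %s", rec$trial_index, s))
  }
  Pf <- .lowpass_matrix(P - ref, rec$fs, config$cutoff_hz, config$filter_order)
  rest <- colMeans(Pf[seq_len(min(config$rest_samples, nrow(Pf))), , drop = FALSE])
  structure(
    list(
      effector = effector,
      rd = resultant_displacement(Pf, rest),
      rv = resultant_velocity(Pf, fs = rec$fs),
      fs = rec$fs,
      rest = rest
    ),
    class = "kinematic_series"
  )
}
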