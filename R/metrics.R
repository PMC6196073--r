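# Per-trial outcome measures: effector displacements, displacement ratios
# with Fisher z-transform, and spectral-arc-length movement smoothness.

#' Effector displacement over the onward movement
#'
#' `RD(end of movement) - RD(onset of movement)`.
#'
#' @param rd Resultant displacement series, cm.
#' @param seg A [segment_onward()] result (or any list with `onset`, `end`).
#' @return Displacement in cm.
#' @export
effector_displacement <- function(rd, seg) {
  rd[seg$end] - rd[seg$onset]
}

#' Displacement ratio of thumb and finger
#'
#' The thumb's share of the total absolute displacement:
#' `D_T = |thumb| / (|thumb| + |finger|)` and `D_F = 1 - D_T`. Quantifies the
#' relative contribution of each effector to the opposition movement.
#'
#' @param thumb_disp Thumb displacement, cm.
#' @param finger_disp Finger (target phalanx) displacement, cm.
#' @return List with elements `d_t` and `d_f`; `d_t + d_f == 1` exactly.
#' @export
displacement_ratio <- function(thumb_disp, finger_disp) {
  a <- abs(thumb_disp)
  b <- abs(finger_disp)
  tot <- a + b
  if (any(tot == 0)) {
    stop("undefined displacement ratio: both displacements are zero")
  }
  d_t <- a / tot
  # complement rather than b/tot so d_t + d_f is exactly 1 in floating point
  list(d_t = d_t, d_f = 1 - d_t)
}

#' Fisher z-transform of a displacement ratio
#'
#' `z = 0.5 * ln((1 + d) / (1 - d))`, mapping the bounded ratio to an
#' unbounded scale before parametric testing. `d` is clamped to
#' `1 - 1e-9` before the logarithm so a ratio of exactly 1 (finger
#' displacement zero) yields a finite, order-preserving value.
#'
#' @param d Ratio(s) in `[0, 1]`.
#' @return Transformed value(s), `>= 0`.
#' @export
fisher_z <- function(d) {
  if (any(d < 0 | d > 1)) stop("displacement ratio outside [0, 1]")
  dc <- pmin(d, 1 - 1e-9)
  0.5 * log((1 + dc) / (1 - dc))
}

#' Spectral arc length (SAL) movement smoothness
#'
#' The negative arc length of the amplitude- and frequency-normalized Fourier
#' magnitude spectrum of the segmented speed profile. The profile is
#' zero-padded to the next power of two at least `pad_factor` times its
#' length; the magnitude spectrum is divided by its DC value, restricted to
#' `0 <= f <= f_max`, and the frequency axis is scaled to `[0, 1]`. Values
#' are `<= -1`; they move towards zero as the movement gets smoother.
#'
#' @param rv_segment Speed profile of the onward movement (length >= 4, not
#'   identically zero).
#' @param fs Sampling frequency, Hz.
#' @param f_max Spectral cutoff, Hz (default 10: movement content is already
#'   low-pass filtered at 5 Hz upstream).
#' @param pad_factor Zero-padding density factor (default 16).
#' @param adaptive_cutoff If `TRUE`, additionally truncate the spectrum after
#'   the last point whose normalized magnitude reaches `amp_threshold`
#'   (adaptive-cutoff variant; off by default).
#' @param amp_threshold Amplitude threshold for the adaptive variant.
#' @return SAL, a dimensionless negative number.
#' @export
spectral_arc_length <- function(rv_segment, fs, f_max = 10, pad_factor = 16,
                                adaptive_cutoff = FALSE, amp_threshold = 0.05) {
  L <- length(rv_segment)
  if (L < 4L) stop("segment too short for a spectral estimate")
  pad_to <- 2^ceiling(log2(pad_factor * L))
  V <- Mod(stats::fft(c(rv_segment, numeric(pad_to - L))))
  if (V[1] == 0) stop("zero speed profile: spectrum has no DC component")
  nf <- floor(f_max * pad_to / fs) + 1L
  Vh <- V[seq_len(nf)] / V[1]
  fh <- ((seq_len(nf) - 1L) * fs / pad_to) / f_max
  if (adaptive_cutoff) {
    last <- max(which(Vh >= amp_threshold))
    Vh <- Vh[seq_len(last)]
    fh <- fh[seq_len(last)] / fh[last]
  }
  -sum(sqrt(diff(fh)^2 + diff(Vh)^2))
}
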