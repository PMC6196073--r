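# Shared fixtures and independent oracles.

# Independent brute-force 5%-threshold segmentation: vectorized scan over the
# whole profile, no walking logic shared with the implementation.
brute_threshold_segment <- function(rv, threshold_frac = 0.05) {
  pk <- which.max(rv)
  thr <- threshold_frac * rv[pk]
  pre <- which(rv[seq_len(pk - 1)] < thr)
  on <- if (length(pre)) max(pre) + 1L else 1L
  post <- which(rv[(pk + 1):length(rv)] < thr)
  en <- if (length(post)) pk + min(post) - 1L else length(rv)
  c(onset = on, end = en)
}

# Random proper rotation matrix.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Render a single-effector 3D reach: rest + minimum-jerk path along a fixed
# direction, optional isotropic sensor noise.
render_reach <- function(A, dur, t0, fs = 100, n = 300, noise_sd = 0,
                         rest = c(2, 3, 1), u = c(0.5, 0.7, 0.5)) {
  u <- u / sqrt(sum(u^2))
  xyz <- matrix(rest, n, 3, byrow = TRUE) +
    outer(minimum_jerk(0, A, t0, dur, fs, n), u)
  if (noise_sd > 0) xyz <- xyz + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  xyz
}

# Filtered speed profile of a rendered reach (the analysis chain's view).
reach_speed <- function(xyz, fs = 100) {
  Pf <- cbind(lowpass(xyz[, 1], fs), lowpass(xyz[, 2], fs),
              lowpass(xyz[, 3], fs))
  resultant_velocity(Pf, fs = fs)
}

# Small session configuration for structural tests.
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_participants = 2L, trials_per_task = 2L),
                            list(...))
  do.call(sim_config, args)
}

# Noise-free, jitter-free configuration: the pipeline should recover the
# configured ratios almost exactly.
exact_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 1L, noise_sd = 0, participant_sd = 0,
         trial_sd = 0, onset_jitter = 0),
    list(...)
  )
  do.call(sim_config, args)
}

# Factor level sets used by the ANOVA fixtures.
FINGERS_T <- c("index", "middle", "ring", "little")
PHAL_T <- c("distal", "middle", "proximal")

# Long-format 4 x 3 within-participant cells from a participant x 12 matrix
# (columns finger-major: index.distal, index.middle, ...).
.mk_cells <- function(Y, fl = FINGERS_T, pl = PHAL_T) {
  do.call(rbind, lapply(seq_len(nrow(Y)), function(i) {
    data.frame(
      participant = sprintf("P%02d", i),
      finger = rep(fl, each = length(pl)),
      phalanx = rep(pl, length(fl)),
      value = Y[i, ], stringsAsFactors = FALSE
    )
  }))
}
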