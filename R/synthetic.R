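# Synthetic opposition-movement sessions with recorded ground truth.
#
# Each trial: the thumb-distal sensor and the task's target phalanx sensor
# travel towards each other along the line joining their rest positions, with
# minimum-jerk submovement profiles; the thumb covers a share r of the total
# amplitude and the finger 1 - r. All other sensors rest at fixed,
# anatomically plausible offsets from the wrist. Isotropic Gaussian noise is
# added per axis per sample on every sensor, including the wrist reference.

.mj_shape <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 + tau * (-15 + 6 * tau))
}

#' Minimum-jerk point-to-point trajectory
#'
#' `x(t) = x0 + (xf - x0) * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = (t - t0)/dur` clipped to `[0, 1]`; constant outside the movement
#' window. The speed profile is the symmetric bell with peak
#' `1.875 * (xf - x0) / dur` at the midpoint.
#'
#' @param x0,xf Start and end positions, cm.
#' @param t0 Movement onset, s (>= 0).
#' @param dur Movement duration, s (> 0).
#' @param fs Sampling frequency, Hz.
#' @param n_samples Series length.
#' @return Position sequence of length `n_samples`.
#' @export
minimum_jerk <- function(x0, xf, t0, dur, fs, n_samples) {
  if (dur <= 0) stop("invalid window: dur must be positive")
  if (t0 < 0 || t0 + dur > n_samples / fs) {
    stop("invalid window: movement must fit inside the trial")
  }
  t <- (seq_len(n_samples) - 1) / fs
  x0 + (xf - x0) * .mj_shape((t - t0) / dur)
}

#' Superpose minimum-jerk submovements
#'
#' Sum of minimum-jerk displacement increments; overlapping submovements
#' superpose additively. The first spec's start position anchors the series.
#'
#' @param specs List of submovement specs, each a list/vector with `x0`,
#'   `xf`, `t0`, `dur`.
#' @param fs Sampling frequency, Hz.
#' @param n_samples Series length.
#' @return Position sequence of length `n_samples`.
#' @export
compose_submovements <- function(specs, fs, n_samples) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  t <- (seq_len(n_samples) - 1) / fs
  x <- rep(specs[[1]][["x0"]], n_samples)
  for (sp in specs) {
    if (sp[["dur"]] <= 0) stop("invalid window: dur must be positive")
    x <- x + (sp[["xf"]] - sp[["x0"]]) * .mj_shape((t - sp[["t0"]]) / sp[["dur"]])
  }
  x
}

# Equal-amplitude submovement specs spanning [t0, t0 + span]: k submovements
# of duration span - (k-1)*gap, staggered by gap, amplitudes total/k. The
# default stagger gap = span/(k+1) makes every submovement overlap its
# neighbour by half its duration, producing an undulating but contiguous
# speed profile regardless of k.
submovement_specs <- function(total_amp, k, t0, span, gap = NULL) {
  if (is.null(gap)) gap <- span / (k + 1)
  dur <- span - (k - 1) * gap
  if (dur <= 0) stop("submovement window invalid: span too short for k submovements")
  if (k > 1 && dur <= gap) {
    stop("submovements would not overlap: reduce count or gap")
  }
  lapply(seq_len(k), function(i) {
    list(x0 = 0, xf = total_amp / k, t0 = t0 + (i - 1) * gap, dur = dur)
  })
}

# Scalar path length profile: 0 at rest rising to total_amp.
.path_profile <- function(total_amp, k, t0, span, gap = NULL, fs, n_samples) {
  compose_submovements(submovement_specs(total_amp, k, t0, span, gap),
                       fs, n_samples)
}

#' Default task-to-ratio map
#'
#' True thumb share r per task, anchored on the reported group means of the
#' Fisher-z displacement ratios (fingers: index 0.87 to little 1.23, linear
#' in between; phalanges: distal 0.62, middle 0.89, proximal 1.54) and
#' combined additively on the z scale, so the map carries finger and phalanx
#' main effects but no interaction.
#'
#' @return data.frame with columns `code`, `finger`, `phalanx`, `r`.
#' @export
default_ratio_map <- function() {
  zf <- c(index = 0.87, middle = 0.99, ring = 1.11, little = 1.23)
  zp <- c(distal = 0.62, middle = 0.89, proximal = 1.54)
  g <- task_grid()
  z <- zp[g$phalanx] + (zf[g$finger] - mean(zf))
  g$r <- tanh(z)
  g[, c("code", "finger", "phalanx", "r")]
}

#' Constant-ratio map (null generator)
#'
#' @param r Thumb share in (0, 1) for every task (default 0.5).
#' @return data.frame like [default_ratio_map()]'s.
#' @export
ratio_map_constant <- function(r = 0.5) {
  stopifnot(r > 0, r < 1)
  g <- task_grid()
  g$r <- r
  g[, c("code", "finger", "phalanx", "r")]
}

#' Default submovement-count map
#'
#' The thumb always moves as a single minimum-jerk unit. Finger effectors get
#' more submovements (rougher profiles) towards proximal phalanges and for
#' ring/little fingers: `min(4, 1 + phalanx index + [ring or little])`,
#' mirroring the reported smoothness asymmetry. Capped at 4 so consecutive
#' submovements always overlap within the movement span.
#'
#' @return data.frame with columns `code`, `finger`, `phalanx`,
#'   `thumb_submovements`, `finger_submovements`.
#' @export
default_submovement_map <- function() {
  g <- task_grid()
  pidx <- match(g$phalanx, PHALANGES)
  ulnar <- as.integer(g$finger %in% c("ring", "little"))
  g$thumb_submovements <- 1L
  g$finger_submovements <- pmin(4L, 1L + pidx + ulnar)
  g[, c("code", "finger", "phalanx", "thumb_submovements", "finger_submovements")]
}

#' Constant submovement map
#'
#' @param k Submovement count (>= 1) for both effectors in every task.
#' @return data.frame like [default_submovement_map()]'s.
#' @export
submovement_map_constant <- function(k = 1L) {
  stopifnot(k >= 1)
  g <- task_grid()
  g$thumb_submovements <- as.integer(k)
  g$finger_submovements <- as.integer(k)
  g[, c("code", "finger", "phalanx", "thumb_submovements", "finger_submovements")]
}

#' Rest positions of all 16 sensors
#'
#' Fixed, anatomically plausible layout of a supinated right hand in the lab
#' frame (cm): wrist reference at (9, 6, 11) as in the experimental setup,
#' digits splayed with finger columns 2 cm apart and the thumb radial and
#' proximal to them.
#'
#' @return 16 x 3 numeric matrix (columns x, y, z), rownames are sensor ids.
#' @export
rest_layout <- function() {
  base <- c(9, 6, 11)
  fx <- c(index = 3, middle = 1, ring = -1, little = -3)
  fy <- c(distal = 11.5, middle = 9.5, proximal = 7)
  ty <- c(distal = 6.5, middle = 4.5, proximal = 2.5)
  ids <- sensor_ids()
  m <- matrix(0, length(ids), 3, dimnames = list(ids, c("x", "y", "z")))
  for (id in ids) {
    if (id == "reference") {
      off <- c(0, 0, 0)
    } else {
      parts <- strsplit(id, "_", fixed = TRUE)[[1]]
      if (parts[1] == "thumb") {
        off <- c(6.5, ty[[parts[2]]], 2)
      } else {
        off <- c(fx[[parts[1]]], fy[[parts[2]]], 1.5)
      }
    }
    m[id, ] <- base + off
  }
  m
}

#' Simulation configuration
#'
#' Defaults reproduce the experimental protocol: 8 participants, 12 tasks,
#' 15 trials per task, 3-s trials at 100 Hz.
#'
#' @param n_participants Number of simulated participants (default 8).
#' @param trials_per_task Repetitions per task (default 15).
#' @param fs Sampling frequency, Hz (default 100).
#' @param duration Trial duration, s (default 3).
#' @param noise_sd Isotropic sensor noise SD per axis, cm (default 0.005).
#' @param amplitude_total Total (thumb + finger) movement amplitude, cm:
#'   a scalar, or a named vector by task code (default 8).
#' @param ratio_map Task-to-true-thumb-share map, see [default_ratio_map()].
#' @param submovement_map Submovement counts per task and effector, see
#'   [default_submovement_map()].
#' @param movement_span Duration of the composite onward movement, s
#'   (default 1.2).
#' @param submovement_gap Stagger between successive submovement onsets, s;
#'   `NULL` (the default) uses `movement_span / (count + 1)`, which keeps the
#'   undulating speed profile contiguous for any submovement count.
#' @param onset_base Earliest movement onset, s (default 0.6; must leave the
#'   initial rest window intact).
#' @param onset_jitter Uniform onset jitter width, s (default 0.2).
#' @param participant_sd SD of the participant-level random offset applied to
#'   the task ratio on the Fisher-z scale (default 0.1).
#' @param trial_sd SD of the trial-level ratio jitter on the z scale
#'   (default 0.05).
#' @param seed Optional integer seed; sessions are bit-reproducible under a
#'   fixed seed.
#' @param sensors `"all"` (full 16-sensor recordings) or `"minimal"` (only
#'   thumb-distal, target phalanx and reference; the sensors the analysis
#'   reads).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 8L, trials_per_task = 15L,
                       fs = 100, duration = 3,
                       noise_sd = 0.005, amplitude_total = 8,
                       ratio_map = default_ratio_map(),
                       submovement_map = default_submovement_map(),
                       movement_span = 1.2, submovement_gap = NULL,
                       onset_base = 0.6, onset_jitter = 0.2,
                       participant_sd = 0.1, trial_sd = 0.05,
                       seed = NULL, sensors = c("all", "minimal")) {
  sensors <- match.arg(sensors)
  stopifnot(
    n_participants >= 1, trials_per_task >= 1, fs > 0, duration > 0,
    noise_sd >= 0, movement_span > 0,
    is.null(submovement_gap) || submovement_gap > 0,
    onset_base >= 0.25, onset_jitter >= 0,
    participant_sd >= 0, trial_sd >= 0
  )
  if (abs(fs * duration - round(fs * duration)) > 1e-9) {
    stop("fs * duration must be an integral sample count")
  }
  if (onset_base + onset_jitter + movement_span > duration) {
    stop("movement window does not fit inside the trial")
  }
  if (any(amplitude_total <= 0) || any(amplitude_total > 20)) {
    stop("amplitude_total outside hand-scale bounds (0, 20] cm")
  }
  stopifnot(all(c("code", "r") %in% names(ratio_map)),
            all(task_grid()$code %in% ratio_map$code),
            all(ratio_map$r > 0 & ratio_map$r < 1))
  stopifnot(all(c("code", "thumb_submovements", "finger_submovements") %in%
                  names(submovement_map)),
            all(task_grid()$code %in% submovement_map$code))
  kmax <- max(submovement_map$thumb_submovements,
              submovement_map$finger_submovements)
  if (kmax < 1) stop("submovement counts must be >= 1")
  if (kmax > 1 && !is.null(submovement_gap)) {
    dur_min <- movement_span - (kmax - 1) * submovement_gap
    if (dur_min <= submovement_gap) {
      stop("submovement map too dense: submovements would not overlap ",
           "within movement_span")
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_per_task = as.integer(trials_per_task),
      fs = fs, duration = duration, n_samples = as.integer(round(fs * duration)),
      noise_sd = noise_sd, amplitude_total = amplitude_total,
      ratio_map = ratio_map, submovement_map = submovement_map,
      movement_span = movement_span, submovement_gap = submovement_gap,
      onset_base = onset_base, onset_jitter = onset_jitter,
      participant_sd = participant_sd, trial_sd = trial_sd,
      seed = seed, sensors = sensors
    ),
    class = "sim_config"
  )
}

.task_amplitude <- function(cfg, code) {
  if (length(cfg$amplitude_total) == 1L) {
    unname(cfg$amplitude_total)
  } else {
    cfg$amplitude_total[[code]]
  }
}

# Draw the trial-level latent parameters (before any sensor noise).
draw_trial_params <- function(finger, phalanx, cfg, participant_offset = 0) {
  code <- task_code(finger, phalanx)
  rmap <- cfg$ratio_map
  smap <- cfg$submovement_map
  r0 <- rmap$r[match(code, rmap$code)]
  z <- atanh(r0) + participant_offset + stats::rnorm(1, 0, cfg$trial_sd)
  r <- min(max(tanh(z), 0.02), 0.98)
  t0 <- cfg$onset_base + stats::runif(1, 0, cfg$onset_jitter)
  i <- match(code, smap$code)
  list(
    finger = finger, phalanx = phalanx, code = code,
    r = r, t0 = t0,
    amplitude = .task_amplitude(cfg, code),
    k_thumb = smap$thumb_submovements[i],
    k_finger = smap$finger_submovements[i]
  )
}

# Per-task geometry in the wrist frame: rest offsets of the two moving
# sensors and the unit vector from thumb tip to target.
.task_geometry <- function() {
  lay <- rest_layout()
  ref <- lay["reference", ]
  g <- task_grid()
  geom <- vector("list", nrow(g))
  names(geom) <- g$code
  for (i in seq_len(nrow(g))) {
    tgt <- target_sensor(g$finger[i], g$phalanx[i])
    u <- lay[tgt, ] - lay["thumb_distal", ]
    geom[[i]] <- list(
      thumb0 = lay["thumb_distal", ] - ref,
      finger0 = lay[tgt, ] - ref,
      u = u / sqrt(sum(u^2))
    )
  }
  geom
}

# Wrist-relative thumb and finger traces for one trial, as an n x 6 matrix
# [thumb xyz | finger xyz], noise included. Draws noise in the same order as
# make_trial (thumb sensor, target sensor, reference), so both render paths
# produce identical trials from the same RNG state.
.simulate_relative <- function(params, cfg, geom = .task_geometry()) {
  n <- cfg$n_samples
  gm <- geom[[params$code]]
  s_t <- .path_profile(params$r * params$amplitude, params$k_thumb,
                       params$t0, cfg$movement_span, cfg$submovement_gap,
                       cfg$fs, n)
  s_f <- .path_profile((1 - params$r) * params$amplitude, params$k_finger,
                       params$t0, cfg$movement_span, cfg$submovement_gap,
                       cfg$fs, n)
  M <- cbind(
    matrix(gm$thumb0, n, 3, byrow = TRUE) + outer(s_t, gm$u),
    matrix(gm$finger0, n, 3, byrow = TRUE) - outer(s_f, gm$u)
  )
  if (cfg$noise_sd > 0) {
    Nt <- matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3)
    Nf <- matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3)
    Nr <- matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3)
    M <- M + cbind(Nt - Nr, Nf - Nr)
  }
  M
}

# Render a trial from drawn parameters; noise is the only randomness here.
make_trial <- function(params, cfg, participant = "P01", trial_index = 1L) {
  n <- cfg$n_samples
  lay <- rest_layout()
  tgt <- target_sensor(params$finger, params$phalanx)
  u <- lay[tgt, ] - lay["thumb_distal", ]
  u <- u / sqrt(sum(u^2))
  s_t <- .path_profile(params$r * params$amplitude, params$k_thumb,
                       params$t0, cfg$movement_span, cfg$submovement_gap,
                       cfg$fs, n)
  s_f <- .path_profile((1 - params$r) * params$amplitude, params$k_finger,
                       params$t0, cfg$movement_span, cfg$submovement_gap,
                       cfg$fs, n)
  sens <- if (cfg$sensors == "minimal") {
    unique(c("thumb_distal", tgt, "reference"))
  } else {
    sensor_ids()
  }
  pos <- vector("list", length(sens))
  names(pos) <- sens
  for (s in sens) {
    P <- matrix(lay[s, ], n, 3, byrow = TRUE)
    if (s == "thumb_distal") P <- P + outer(s_t, u)
    if (s == tgt) P <- P - outer(s_f, u)
    if (cfg$noise_sd > 0) {
      P <- P + matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3)
    }
    pos[[s]] <- P
  }
  rec <- trial_recording(participant, trial_index, params$finger,
                         params$phalanx, cfg$fs, pos)
  truth <- data.frame(
    trial = as.integer(trial_index), participant = participant,
    task = params$code,
    onset_s = params$t0, end_s = params$t0 + cfg$movement_span,
    thumb_displacement = params$r * params$amplitude,
    finger_displacement = (1 - params$r) * params$amplitude,
    r = params$r,
    thumb_submovements = params$k_thumb,
    finger_submovements = params$k_finger,
    stringsAsFactors = FALSE
  )
  list(recording = rec, truth = truth)
}

#' Simulate one opposition trial
#'
#' @param finger,phalanx Target finger and phalanx.
#' @param cfg A [sim_config()].
#' @param participant Participant id attached to the recording.
#' @param trial_index Trial number.
#' @param participant_offset Participant-level ratio offset on the z scale.
#' @return List with `recording` (a [trial_recording()]) and `truth` (one-row
#'   data.frame of ground-truth onset/end, displacements, ratio and
#'   submovement counts).
#' @export
simulate_trial <- function(finger, phalanx, cfg = sim_config(),
                           participant = "P01", trial_index = 1L,
                           participant_offset = 0) {
  params <- draw_trial_params(finger, phalanx, cfg, participant_offset)
  make_trial(params, cfg, participant, trial_index)
}

#' Simulate a full session
#'
#' `n_participants x 12 tasks x trials_per_task` trials; each participant's
#' task order is block randomized (every block a fresh permutation of the 12
#' tasks). Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `recordings` (list of [trial_recording()]), `manifest`
#'   (data.frame trial/participant/task) and `truth` (one row per trial).
#' @export
simulate_session <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- task_grid()
  n_trials <- cfg$n_participants * 12L * cfg$trials_per_task
  recs <- vector("list", n_trials)
  truths <- vector("list", n_trials)
  id <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    off <- stats::rnorm(1, 0, cfg$participant_sd)
    order <- unlist(lapply(seq_len(cfg$trials_per_task),
                           function(i) sample.int(12L)))
    for (ti in order) {
      id <- id + 1L
      tr <- simulate_trial(g$finger[ti], g$phalanx[ti], cfg,
                           participant = pid, trial_index = id,
                           participant_offset = off)
      recs[[id]] <- tr$recording
      truths[[id]] <- tr$truth
    }
  }
  truth <- do.call(rbind, truths)
  manifest <- truth[, c("trial", "participant", "task")]
  list(recordings = recs, manifest = manifest, truth = truth)
}
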