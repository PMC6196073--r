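# End-to-end orchestration: preprocess -> segment -> metrics -> stats ->
# report. All steps are pure functions of (data, config); a fixed (seed,
# config) pair reproduces every output bit for bit.

#' Analysis configuration
#'
#' Defaults reproduce the protocol constants: 5 Hz second-order zero-lag
#' low-pass filter, 5% relative velocity threshold, 100-point profile
#' resampling. Unknown keys are rejected.
#'
#' @param ... Overrides for the keys: `threshold_frac` (0.05),
#'   `min_duration_s` (0.1), `min_displacement_frac` (0.5), `cutoff_hz` (5),
#'   `filter_order` (2), `rest_samples` (20), `sal_f_max_hz` (10),
#'   `sal_pad_factor` (16), `adaptive_cutoff` (FALSE), `keep_profiles`
#'   (FALSE), `posthoc_method` ("bonferroni").
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    threshold_frac = 0.05,
    min_duration_s = 0.1,
    # a genuine onward segment carries nearly the whole RD range (> 95% on
    # clean data); noise-truncated segments scatter well below half of it
    min_displacement_frac = 0.5,
    cutoff_hz = 5,
    filter_order = 2,
    rest_samples = 20L,
    sal_f_max_hz = 10,
    sal_pad_factor = 16,
    adaptive_cutoff = FALSE,
    keep_profiles = FALSE,
    posthoc_method = "bonferroni"
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown config key(s): ",
           paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "))
    }
    defaults[names(over)] <- over
  }
  structure(defaults, class = "pipeline_config")
}

# Post-filter chain for one effector: rest position, RD/RV, segmentation,
# displacement and SAL. Pf is the already wrist-referenced, filtered n x 3
# position matrix.
.metrics_from_filtered <- function(Pf, fs, config) {
  rest <- colMeans(Pf[seq_len(min(config$rest_samples, nrow(Pf))), , drop = FALSE])
  rd <- sqrt((Pf[, 1] - rest[1])^2 + (Pf[, 2] - rest[2])^2 + (Pf[, 3] - rest[3])^2)
  D <- .stencil_matrix(Pf, fs)
  rv <- sqrt(D[, 1]^2 + D[, 2]^2 + D[, 3]^2)
  seg <- segment_onward(list(rd = rd, rv = rv, fs = fs), config,
                        profiles = config$keep_profiles)
  list(
    displacement = rd[seg$end] - rd[seg$onset],
    sal = spectral_arc_length(rv[seg$onset:seg$end], fs,
                              f_max = config$sal_f_max_hz,
                              pad_factor = config$sal_pad_factor,
                              adaptive_cutoff = config$adaptive_cutoff),
    segment = seg
  )
}

# Lean per-effector chain used by analyze_trial: subtract reference, filter,
# then the post-filter chain.
.analyze_effector <- function(P, ref, fs, config) {
  Pf <- .lowpass_matrix(P - ref, fs, config$cutoff_hz, config$filter_order)
  .metrics_from_filtered(Pf, fs, config)
}

#' Compute all per-trial metrics for one recording
#'
#' Thumb and target phalanx are processed independently, each from its own
#' speed profile.
#'
#' @param rec A [trial_recording()].
#' @param config A [pipeline_config()].
#' @return Named list: displacements, `d_t`, `d_f`, `z_d_t`, `z_d_f`,
#'   `sal_thumb`, `sal_finger`, `fallback` flag, and the two
#'   `movement_segment` objects.
#' @export
analyze_trial <- function(rec, config = pipeline_config()) {
  ref <- rec$positions[["reference"]]
  if (is.null(ref)) {
    stop(sprintf("trial %s: missing sensor(s): reference", rec$trial_index))
  }
  tgt <- target_sensor(rec$finger, rec$phalanx)
  for (s in c("thumb_distal", tgt)) {
    if (is.null(rec$positions[[s]])) {
      stop(sprintf("trial %s: missing sensor(s): %s", rec$trial_index, s))
    }
  }
  th <- .analyze_effector(rec$positions[["thumb_distal"]], ref, rec$fs, config)
  fi <- .analyze_effector(rec$positions[[tgt]], ref, rec$fs, config)
  ratio <- displacement_ratio(th$displacement, fi$displacement)
  list(
    participant = rec$participant,
    task = task_code(rec$finger, rec$phalanx),
    trial = rec$trial_index,
    thumb_displacement = th$displacement,
    finger_displacement = fi$displacement,
    d_t = ratio$d_t, d_f = ratio$d_f,
    z_d_t = fisher_z(ratio$d_t), z_d_f = fisher_z(ratio$d_f),
    sal_thumb = th$sal, sal_finger = fi$sal,
    fallback = th$segment$fallback || fi$segment$fallback,
    segment_thumb = th$segment, segment_finger = fi$segment
  )
}

# Wide one-row-per-trial table -> tidy long ResultsTable.
.wide_to_long <- function(wide) {
  long <- data.table::rbindlist(list(
    wide[, .(participant, task, trial, effector = "thumb",
             measure = "displacement", value = thumb_displacement)],
    wide[, .(participant, task, trial, effector = "finger",
             measure = "displacement", value = finger_displacement)],
    wide[, .(participant, task, trial, effector = "thumb",
             measure = "D", value = d_t)],
    wide[, .(participant, task, trial, effector = "finger",
             measure = "D", value = d_f)],
    wide[, .(participant, task, trial, effector = "thumb",
             measure = "z_D", value = z_d_t)],
    wide[, .(participant, task, trial, effector = "finger",
             measure = "z_D", value = z_d_f)],
    wide[, .(participant, task, trial, effector = "thumb",
             measure = "SAL", value = sal_thumb)],
    wide[, .(participant, task, trial, effector = "finger",
             measure = "SAL", value = sal_finger)]
  ))
  data.table::setorder(long, participant, task, trial, effector, measure)
  long
}

.collect_rows <- function(rows, excluded) {
  wide <- data.table::rbindlist(rows)
  list(
    results = if (nrow(wide)) .wide_to_long(wide) else
      data.table::data.table(participant = character(), task = character(),
                             trial = integer(), effector = character(),
                             measure = character(), value = numeric()),
    wide = wide,
    excluded = if (length(excluded)) data.table::rbindlist(excluded) else
      data.table::data.table(trial = integer(), error = character()),
    fallback_rate = if (nrow(wide)) mean(wide$fallback) else NA_real_
  )
}

#' Analyze a set of recordings
#'
#' Runs the full preprocessing/segmentation/metrics chain on every recording.
#' Trials whose analysis fails are collected (with their error message) in an
#' `excluded` table instead of aborting the run, so every manifest trial is
#' accounted for either in `results` or in `excluded`.
#'
#' @param recs List of [trial_recording()] objects.
#' @param config A [pipeline_config()].
#' @return List: `results` (tidy long table), `wide` (one row per trial),
#'   `excluded`, and the `fallback_rate` (share of trials where segmentation
#'   used the fallback).
#' @export
analyze_recordings <- function(recs, config = pipeline_config()) {
  rows <- vector("list", length(recs))
  excluded <- list()
  for (i in seq_along(recs)) {
    m <- tryCatch(analyze_trial(recs[[i]], config), error = function(e) e)
    if (inherits(m, "error")) {
      excluded[[length(excluded) + 1L]] <- data.table::data.table(
        trial = recs[[i]]$trial_index, error = conditionMessage(m)
      )
    } else {
      m$segment_thumb <- NULL
      m$segment_finger <- NULL
      rows[[i]] <- data.table::as.data.table(m)
    }
  }
  .collect_rows(rows[!vapply(rows, is.null, logical(1))], excluded)
}

#' File-based analysis entry point
#'
#' Reads a trajectory TSV + manifest, analyzes every trial, and (optionally)
#' writes the tidy results table.
#'
#' @param trajectories Trajectory TSV path.
#' @param manifest Manifest TSV path.
#' @param out Optional output path for the results TSV.
#' @param config A [pipeline_config()].
#' @return As [analyze_recordings()].
#' @export
run_analyze <- function(trajectories, manifest, out = NULL,
                        config = pipeline_config()) {
  recs <- read_trials(trajectories, manifest)
  res <- analyze_recordings(recs, config)
  if (!is.null(out)) write_results(res$results, out)
  res
}

#' Simulate a session and analyze it in one pass
#'
#' Streams trial by trial (simulate, analyze, discard the raw recording), so
#' full sessions can be replicated without holding 1,440 recordings in
#' memory. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()]; only the sensors the analysis reads
#'   (thumb-distal, target phalanx, reference) are rendered, and each
#'   participant's trials are low-pass filtered in one batched pass.
#' @param config A [pipeline_config()].
#' @return As [analyze_recordings()], plus `truth` (the generator's ground
#'   truth, one row per trial).
#' @export
simulate_and_analyze <- function(cfg = sim_config(),
                                 config = pipeline_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g <- task_grid()
  per_part <- 12L * cfg$trials_per_task
  n_trials <- cfg$n_participants * per_part
  n <- cfg$n_samples

  participant <- character(n_trials)
  task <- character(n_trials)
  thumb_disp <- finger_disp <- sal_th <- sal_fi <- numeric(n_trials)
  fallback <- ok <- logical(n_trials)
  t_onset <- t_end <- t_thdisp <- t_fidisp <- t_r <- numeric(n_trials)
  t_kth <- t_kfi <- integer(n_trials)
  excluded <- list()
  geom <- .task_geometry()

  id <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    off <- stats::rnorm(1, 0, cfg$participant_sd)
    order <- unlist(lapply(seq_len(cfg$trials_per_task),
                           function(i) sample.int(12L)))
    # phase 1: simulate the participant's trials (thumb and finger relative
    # to the reference), stacked column-wise for one batched filter pass
    M <- matrix(0, n, 6L * per_part)
    ids <- integer(per_part)
    for (j in seq_along(order)) {
      ti <- order[j]
      id <- id + 1L
      ids[j] <- id
      params <- draw_trial_params(g$finger[ti], g$phalanx[ti], cfg, off)
      M[, (6L * (j - 1L) + 1L):(6L * j)] <- .simulate_relative(params, cfg, geom)
      participant[id] <- pid
      task[id] <- params$code
      t_onset[id] <- params$t0
      t_end[id] <- params$t0 + cfg$movement_span
      t_thdisp[id] <- params$r * params$amplitude
      t_fidisp[id] <- (1 - params$r) * params$amplitude
      t_r[id] <- params$r
      t_kth[id] <- params$k_thumb
      t_kfi[id] <- params$k_finger
    }
    Mf <- .zerophase_mat(M, cfg$fs, config$cutoff_hz, config$filter_order)
    # phase 2: per-trial metrics from the filtered traces
    for (j in seq_along(order)) {
      tid <- ids[j]
      cols <- (6L * (j - 1L) + 1L):(6L * j)
      res <- tryCatch({
        th <- .metrics_from_filtered(Mf[, cols[1:3], drop = FALSE], cfg$fs, config)
        fi <- .metrics_from_filtered(Mf[, cols[4:6], drop = FALSE], cfg$fs, config)
        list(th = th, fi = fi)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1L]] <- data.table::data.table(
          trial = tid, error = conditionMessage(res)
        )
      } else {
        thumb_disp[tid] <- res$th$displacement
        finger_disp[tid] <- res$fi$displacement
        sal_th[tid] <- res$th$sal
        sal_fi[tid] <- res$fi$sal
        fallback[tid] <- res$th$segment$fallback || res$fi$segment$fallback
        ok[tid] <- TRUE
      }
    }
  }
  ratio <- displacement_ratio(thumb_disp[ok], finger_disp[ok])
  wide <- data.table::data.table(
    participant = participant[ok], task = task[ok], trial = which(ok),
    thumb_displacement = thumb_disp[ok], finger_displacement = finger_disp[ok],
    d_t = ratio$d_t, d_f = ratio$d_f,
    z_d_t = fisher_z(ratio$d_t), z_d_f = fisher_z(ratio$d_f),
    sal_thumb = sal_th[ok], sal_finger = sal_fi[ok],
    fallback = fallback[ok]
  )
  truth <- data.frame(
    trial = seq_len(n_trials), participant = participant, task = task,
    onset_s = t_onset, end_s = t_end,
    thumb_displacement = t_thdisp, finger_displacement = t_fidisp,
    r = t_r, thumb_submovements = t_kth, finger_submovements = t_kfi,
    stringsAsFactors = FALSE
  )
  list(
    results = .wide_to_long(wide),
    wide = wide,
    excluded = if (length(excluded)) data.table::rbindlist(excluded) else
      data.table::data.table(trial = integer(), error = character()),
    fallback_rate = mean(wide$fallback),
    truth = truth
  )
}

#' Run the full statistical design on a results table
#'
#' Two-way (finger x phalanx) repeated-measures ANOVAs for the Fisher-z
#' displacement ratios and the SAL of each effector; twelve one-way
#' (effector) ANOVAs on the z ratios, one per task; Huynh-Feldt adjustment
#' throughout; post-hoc pairwise comparisons per factor.
#'
#' @param results Tidy long results table (see [analyze_recordings()]).
#' @param config A [pipeline_config()] (uses `posthoc_method`).
#' @return List of data.frames: `two_way`, `effector`, `pairwise`.
#' @export
run_stats <- function(results, config = pipeline_config()) {
  pm <- participant_means(results)
  n_part <- length(unique(pm$participant))
  if (n_part < 2L) {
    stop("design error: at least 2 participants are required")
  }
  combos <- list(
    z_d_t = c("z_D", "thumb"), z_d_f = c("z_D", "finger"),
    sal_thumb = c("SAL", "thumb"), sal_finger = c("SAL", "finger")
  )
  cells_of <- function(ms, ef) {
    d <- pm[measure == ms & effector == ef]
    tk <- parse_task(d$task)
    data.frame(participant = d$participant, finger = tk$finger,
               phalanx = tk$phalanx, value = d$value,
               stringsAsFactors = FALSE)
  }
  two_way <- data.table::rbindlist(lapply(names(combos), function(nm) {
    cl <- cells_of(combos[[nm]][1], combos[[nm]][2])
    cbind(measure = nm, rm_anova_2way(cl))
  }))
  eff <- data.table::rbindlist(lapply(task_grid()$code, function(code) {
    d <- pm[measure == "z_D" & task == code]
    cbind(task = code,
          rm_anova_effector(data.frame(participant = d$participant,
                                       effector = d$effector,
                                       value = d$value,
                                       stringsAsFactors = FALSE)))
  }))
  pairwise <- data.table::rbindlist(lapply(names(combos), function(nm) {
    cl <- cells_of(combos[[nm]][1], combos[[nm]][2])
    rbind(
      cbind(measure = nm, factor = "finger",
            posthoc_pairwise(cl, "finger", config$posthoc_method)),
      cbind(measure = nm, factor = "phalanx",
            posthoc_pairwise(cl, "phalanx", config$posthoc_method))
    )
  }))
  list(two_way = two_way, effector = eff, pairwise = pairwise)
}

#' Summary tables of group means and SEMs
#'
#' Participant means per task cell, then the group mean and standard error of
#' the mean (SD across participants / sqrt(n)) per task, effector and
#' measure - the quantities shown as columns and error bars in the study's
#' figures.
#'
#' @param results Tidy long results table.
#' @return data.table with columns `task`, `finger`, `phalanx`, `effector`,
#'   `measure`, `mean`, `sem`, `n`.
#' @export
run_report <- function(results) {
  pm <- participant_means(results)
  rep <- pm[, .(mean = mean(value),
                sem = stats::sd(value) / sqrt(.N),
                n = .N),
            by = .(task, effector, measure)]
  tk <- parse_task(rep$task)
  rep[, `:=`(finger = tk$finger, phalanx = tk$phalanx)]
  data.table::setcolorder(rep, c("task", "finger", "phalanx", "effector",
                                 "measure", "mean", "sem", "n"))
  data.table::setorder(rep, measure, effector, task)
  rep[]
}
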