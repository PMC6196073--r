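# Reading and writing trial recordings and tidy result tables.
#
# Trajectory TSV dialect: columns trial, time_s, sensor, x_cm, y_cm, z_cm
# (one row per sample per sensor). Manifest TSV: trial, participant, task
# (two-letter code). The integer sample index is authoritative; time_s is
# index/fs. Positions are centimetres throughout.

.TRAJ_COLS <- c("trial", "time_s", "sensor", "x_cm", "y_cm", "z_cm")
.MANIFEST_COLS <- c("trial", "participant", "task")
.RESULT_COLS <- c("participant", "task", "trial", "effector", "measure", "value")
.MEASURES <- c("displacement", "D", "z_D", "SAL")

#' Construct a single-trial recording
#'
#' @param participant Participant identifier.
#' @param trial_index Trial number (>= 1).
#' @param finger,phalanx Target finger and phalanx of the task.
#' @param fs Sampling frequency in Hz.
#' @param positions Named list of n x 3 numeric matrices (columns x, y, z in
#'   cm), one per sensor id; all matrices must have the same row count.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(participant, trial_index, finger, phalanx, fs,
                            positions) {
  stopifnot(is.numeric(fs), fs > 0, trial_index >= 1)
  task_code(finger, phalanx)
  ns <- vapply(positions, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop(sprintf("trial %s: ragged sample counts across sensors", trial_index))
  }
  structure(
    list(
      participant = as.character(participant),
      trial_index = as.integer(trial_index),
      finger = finger, phalanx = phalanx,
      fs = fs, duration = ns[[1]] / fs,
      n_samples = ns[[1]],
      positions = positions
    ),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> participant %s, trial %d, task %s (%d sensors, %d samples @ %g Hz)\n",
    x$participant, x$trial_index, task_code(x$finger, x$phalanx),
    length(x$positions), x$n_samples, x$fs
  ))
  invisible(x)
}

#' Read trial recordings from a trajectory TSV and manifest
#'
#' Validates structure: the full 16-sensor complement, equal sample counts
#' per sensor, strictly increasing time stamps, and known task codes.
#'
#' @param path Trajectory TSV (columns `trial`, `time_s`, `sensor`, `x_cm`,
#'   `y_cm`, `z_cm`).
#' @param manifest Manifest TSV (columns `trial`, `participant`, `task`).
#' @return List of [trial_recording()] objects, in manifest order.
#' @export
read_trials <- function(path, manifest) {
  traj <- data.table::fread(path, sep = "\t")
  man <- data.table::fread(manifest, sep = "\t",
                           colClasses = list(character = "task"))
  miss <- setdiff(.TRAJ_COLS, names(traj))
  if (length(miss)) {
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(.MANIFEST_COLS, names(man))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  tasks <- parse_task(man$task) # errors on unknown codes
  extra <- setdiff(unique(traj$trial), man$trial)
  if (length(extra)) {
    stop("trial(s) present in trajectories but not in manifest: ",
         paste(extra, collapse = ", "))
  }
  all_sensors <- sensor_ids()
  data.table::setkey(traj, trial)
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$trial[i]
    sub <- traj[.(id)]
    if (nrow(sub) == 0L || all(is.na(sub$sensor))) {
      stop(sprintf("trial %s: no trajectory rows", id))
    }
    missing_s <- setdiff(all_sensors, unique(sub$sensor))
    if (length(missing_s)) {
      stop(sprintf("trial %s: missing sensor(s): %s",
                   id, paste(missing_s, collapse = ", ")))
    }
    counts <- sub[, .N, by = sensor]
    if (length(unique(counts$N)) != 1L) {
      off <- counts[counts$N != stats::median(counts$N)]$sensor
      stop(sprintf("trial %s: ragged sample counts (sensor %s)",
                   id, paste(off, collapse = ", ")))
    }
    pos <- vector("list", length(all_sensors))
    names(pos) <- all_sensors
    fs <- NA_real_
    for (s in all_sensors) {
      rows <- sub[sensor == s]
      dt_s <- diff(rows$time_s)
      if (any(dt_s <= 0)) {
        stop(sprintf("trial %s: non-monotone time stamps (sensor %s)", id, s))
      }
      # time_s is derived (index/fs); recover fs robustly from the median step
      fs <- round(1 / stats::median(dt_s), 6)
      pos[[s]] <- cbind(x = rows$x_cm, y = rows$y_cm, z = rows$z_cm)
    }
    out[[i]] <- trial_recording(
      participant = man$participant[i], trial_index = id,
      finger = tasks$finger[i], phalanx = tasks$phalanx[i],
      fs = fs, positions = pos
    )
  }
  out
}

#' Write trial recordings to the trajectory TSV dialect
#'
#' Emits the same dialect [read_trials()] consumes; a write-read round trip
#' reproduces every numeric field (data.table writes full precision).
#'
#' @param recs List of [trial_recording()] objects (may be empty).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trials <- function(recs, path) {
  if (length(recs) == 0L) {
    empty <- data.table::data.table(
      trial = integer(), time_s = numeric(), sensor = character(),
      x_cm = numeric(), y_cm = numeric(), z_cm = numeric()
    )
    data.table::fwrite(empty, path, sep = "\t")
    return(invisible(path))
  }
  parts <- lapply(recs, function(r) {
    t_s <- (seq_len(r$n_samples) - 1) / r$fs
    data.table::rbindlist(lapply(names(r$positions), function(s) {
      P <- r$positions[[s]]
      data.table::data.table(
        trial = r$trial_index, time_s = t_s, sensor = s,
        x_cm = P[, 1], y_cm = P[, 2], z_cm = P[, 3]
      )
    }))
  })
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t")
  invisible(path)
}

#' Write the manifest for a set of recordings
#'
#' @param recs List of [trial_recording()] objects.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(recs, path) {
  man <- data.table::data.table(
    trial = vapply(recs, `[[`, integer(1), "trial_index"),
    participant = vapply(recs, `[[`, character(1), "participant"),
    task = vapply(recs, function(r) task_code(r$finger, r$phalanx), character(1))
  )
  data.table::fwrite(man, path, sep = "\t")
  invisible(path)
}

.validate_results <- function(table) {
  dt <- data.table::as.data.table(table)
  miss <- setdiff(.RESULT_COLS, names(dt))
  if (length(miss)) {
    stop("results table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(dt)) {
    key <- dt[, paste(participant, task, trial, effector, measure)]
    if (anyDuplicated(key)) {
      stop("duplicate (participant, task, trial, effector, measure) rows")
    }
    bad <- setdiff(unique(dt$measure), .MEASURES)
    if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  }
  dt[, .RESULT_COLS, with = FALSE]
}

#' Write a tidy long results table
#'
#' One row per (participant, task, trial, effector, measure); rejects
#' duplicate keys.
#'
#' @param table Long results table (see [analyze_recordings()]).
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  dt <- .validate_results(table)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Results TSV path.
#' @return A data.table in long format.
#' @export
read_results <- function(path) {
  .validate_results(data.table::fread(path, sep = "\t",
                                      colClasses = list(character = "task")))
}
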