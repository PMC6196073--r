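# Task and sensor vocabulary for the opposition-movement protocol.
#
# A task is "move the thumb tip and one target phalanx towards each other":
# 4 target fingers x 3 target phalanges = 12 tasks. Sensors sit on every
# phalanx of all five digits (15) plus one reference sensor on the wrist.

FINGERS <- c("index", "middle", "ring", "little")
PHALANGES <- c("distal", "middle", "proximal")
DIGITS <- c("thumb", FINGERS)

.finger_code <- c(index = "I", middle = "M", ring = "R", little = "L")
.phalanx_code <- c(distal = "D", middle = "M", proximal = "P")

#' Enumerate the twelve opposition tasks
#'
#' @return A data.frame with one row per task and columns `finger`
#'   (index/middle/ring/little), `phalanx` (distal/middle/proximal) and
#'   `code`, the two-letter label (finger letter then phalanx letter,
#'   e.g. `"ID"` = index finger, distal phalanx).
#' @export
#' @examples
#' task_grid()
task_grid <- function() {
  g <- expand.grid(
    phalanx = PHALANGES, finger = FINGERS,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )[, c("finger", "phalanx")]
  g$code <- task_code(g$finger, g$phalanx)
  rownames(g) <- NULL
  g
}

#' Encode a task as its two-letter label
#'
#' @param finger Target finger name(s).
#' @param phalanx Target phalanx name(s).
#' @return Character vector of two-letter codes, e.g. `"LP"` for
#'   little finger, proximal phalanx.
#' @export
task_code <- function(finger, phalanx) {
  if (!all(finger %in% FINGERS)) {
    stop("unknown finger: ", paste(setdiff(finger, FINGERS), collapse = ", "))
  }
  if (!all(phalanx %in% PHALANGES)) {
    stop("unknown phalanx: ", paste(setdiff(phalanx, PHALANGES), collapse = ", "))
  }
  paste0(.finger_code[finger], .phalanx_code[phalanx])
}

#' Decode two-letter task labels
#'
#' @param code Character vector of two-letter task codes (e.g. `"ID"`, `"LP"`).
#' @return A data.frame with columns `finger`, `phalanx`, `code`.
#' @export
parse_task <- function(code) {
  code <- as.character(code)
  f <- names(.finger_code)[match(substr(code, 1, 1), .finger_code)]
  p <- names(.phalanx_code)[match(substr(code, 2, 2), .phalanx_code)]
  bad <- is.na(f) | is.na(p) | nchar(code) != 2L
  if (any(bad)) {
    stop("unknown task code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  data.frame(finger = f, phalanx = p, code = code, stringsAsFactors = FALSE)
}

#' All sensor identifiers
#'
#' @return Character vector of the 16 sensor ids: `<digit>_<segment>` for the
#'   five digits and three segments, plus `"reference"` (wrist).
#' @export
sensor_ids <- function() {
  c(as.vector(t(outer(DIGITS, PHALANGES, paste, sep = "_"))), "reference")
}

#' Sensor id of a task's target phalanx
#'
#' @param finger Target finger name.
#' @param phalanx Target phalanx name.
#' @return Sensor id string, e.g. `"ring_middle"`.
#' @export
target_sensor <- function(finger, phalanx) {
  task_code(finger, phalanx) # validates
  paste(finger, phalanx, sep = "_")
}
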