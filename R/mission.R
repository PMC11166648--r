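#' Mission timepoint vocabulary
#'
#' The seven blood-draw timepoints of the mission, as a fixed bijection
#' between the field's "L-n / R+n" labels (n days before launch / after
#' return) and signed days relative to launch/return. The dz machinery and
#' the simulators only need the signed days, so an alternative label map can
#' be supplied to every function that takes one, for reuse on other missions.
#'
#' @format Named integer vector, label -> signed days.
#' @export
MISSION_TIMEPOINTS <- c(
  "L-92"  = -92L,
  "L-44"  = -44L,
  "L-3"   =  -3L,
  "R+1"   =   1L,
  "R+45"  =  45L,
  "R+82"  =  82L,
  "R+194" = 194L
)

#' Mission phase from signed days
#'
#' Phase is a pure function of the signed day: `preflight` for negative
#' days, `return` for day +1 (day of landing), `recovery` for anything
#' later.
#'
#' @param time_days integer vector of signed days.
#' @return character vector in `{preflight, return, recovery}`.
#' @export
phase_of_day <- function(time_days) {
  stopifnot(is.numeric(time_days))
  ifelse(time_days < 0, "preflight", ifelse(time_days == 1, "return", "recovery"))
}

#' Convert timepoint labels to signed days
#'
#' @param labels character vector of timepoint labels.
#' @param label_map named integer vector mapping labels to signed days
#'   (default [MISSION_TIMEPOINTS]).
#' @return integer vector of signed days.
#' @export
timepoint_days <- function(labels, label_map = MISSION_TIMEPOINTS) {
  bad <- setdiff(unique(labels), names(label_map))
  if (length(bad) > 0) {
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  }
  unname(label_map[labels])
}

#' Construct a full-factorial mission design
#'
#' One sample per subject per timepoint, the layout of the mission's
#' direct-RNA assay (4 crew members, 7 draws). Sample ids are
#' `<subject>_<label>`.
#'
#' @param subjects character vector of subject ids (default `C001`..`C004`).
#' @param timepoints character vector of timepoint labels; must be names of
#'   `label_map`.
#' @param label_map named integer vector, label -> signed days.
#' @return data.frame with columns `sample_id`, `subject_id`,
#'   `timepoint_label`, `time_days`, `phase`, ordered by subject then day.
#' @export
mission_design <- function(subjects = sprintf("C%03d", 1:4),
                           timepoints = names(MISSION_TIMEPOINTS),
                           label_map = MISSION_TIMEPOINTS) {
  stopifnot(length(subjects) >= 1, !anyDuplicated(subjects))
  days <- timepoint_days(timepoints, label_map)
  grid <- expand.grid(timepoint_label = timepoints, subject_id = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$time_days <- timepoint_days(grid$timepoint_label, label_map)
  grid <- grid[order(match(grid$subject_id, subjects), grid$time_days), ]
  data.frame(
    sample_id = paste(grid$subject_id, grid$timepoint_label, sep = "_"),
    subject_id = grid$subject_id,
    timepoint_label = grid$timepoint_label,
    time_days = grid$time_days,
    phase = phase_of_day(grid$time_days),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
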