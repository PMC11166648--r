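#' Flag samples failing the read-length QC rule
#'
#' Samples whose average read length falls below the threshold are excluded
#' from catalog analyses (the study's rule that removed one 279 bp sample).
#'
#' @param sample_sheet sample sheet data.frame with `avg_read_length_bp`
#'   present and non-missing for every sample.
#' @param min_avg_read_len exclusion threshold in bp (default 400).
#' @return character vector of excluded sample ids; attribute `values`
#'   carries their read lengths.
#' @export
flag_low_quality <- function(sample_sheet, min_avg_read_len = 400) {
  if (!"avg_read_length_bp" %in% names(sample_sheet) ||
      anyNA(sample_sheet$avg_read_length_bp)) {
    stop("avg_read_length_bp must be present for every sample")
  }
  low <- sample_sheet$avg_read_length_bp < min_avg_read_len
  excluded <- sample_sheet$sample_id[low]
  if (length(excluded) > 0) {
    message("excluding ", length(excluded), " sample(s) by read length: ",
            paste0(excluded, " (",
                   sample_sheet$avg_read_length_bp[low], " bp)",
                   collapse = ", "))
  }
  attr(excluded, "values") <-
    stats::setNames(sample_sheet$avg_read_length_bp[low], excluded)
  excluded
}

catalog_samples_at <- function(catalog, timepoint, excluded) {
  s <- catalog$samples
  s[s$timepoint_label == timepoint & !(s$sample_id %in% excluded), ]
}

#' Cross-crew consensus transcript presence at a timepoint
#'
#' A transcript reaches consensus at a timepoint when it is present in at
#' least one retained sample of every retained subject there. Subjects
#' whose samples at the timepoint were all excluded by QC drop out of the
#' consensus requirement.
#'
#' @param catalog a [transcript_catalog()].
#' @param timepoint timepoint label.
#' @param excluded sample ids excluded by QC (see [flag_low_quality()]).
#' @param min_subjects optional relaxation: require presence in at least
#'   this many subjects instead of all retained subjects.
#' @return character vector of transcript ids.
#' @export
consensus_presence <- function(catalog, timepoint, excluded = character(),
                               min_subjects = NULL) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  s <- catalog_samples_at(catalog, timepoint, excluded)
  if (nrow(s) == 0) stop("no retained samples at timepoint ", timepoint)
  subjects <- unique(s$subject_id)
  need <- if (is.null(min_subjects)) length(subjects) else
    min(min_subjects, length(subjects))
  per_subject <- vapply(subjects, function(subj) {
    cols <- s$sample_id[s$subject_id == subj]
    rowSums(catalog$presence[, cols, drop = FALSE]) > 0
  }, logical(nrow(catalog$presence)))
  ids <- catalog$transcripts$transcript_id
  ids[rowSums(per_subject) >= need]
}

#' Per-timepoint unique transcripts within a window
#'
#' A transcript is unique to timepoint T within the window when it reaches
#' cross-crew consensus at T and is absent from every retained sample at
#' every other timepoint of the window. With
#' `drop_timepoint_on_exclusion`, any window timepoint with a QC-excluded
#' sample is removed from the window entirely before the analysis (the
#' stricter variant that drops a whole draw after one bad sample).
#'
#' @param catalog a [transcript_catalog()].
#' @param window ordered vector of >= 2 timepoint labels, all in the
#'   catalog.
#' @param excluded QC-excluded sample ids.
#' @param min_subjects consensus relaxation, see [consensus_presence()].
#' @param drop_timepoint_on_exclusion drop window timepoints containing an
#'   excluded sample.
#' @return object of class `unique_transcript_report`: list with `window`
#'   and `unique_by_timepoint` (named list of data.frames `transcript_id`,
#'   `class_code`).
#' @export
unique_transcripts <- function(catalog, window, excluded = character(),
                               min_subjects = NULL,
                               drop_timepoint_on_exclusion = FALSE) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  missing <- setdiff(window, unique(catalog$samples$timepoint_label))
  if (length(missing) > 0) {
    stop("window timepoint(s) not in catalog: ",
         paste(missing, collapse = ", "))
  }
  if (drop_timepoint_on_exclusion && length(excluded) > 0) {
    bad_tp <- unique(catalog$samples$timepoint_label[
      catalog$samples$sample_id %in% excluded])
    window <- setdiff(window, bad_tp)
  }
  if (length(window) < 2) stop("window must contain at least 2 timepoints")
  codes <- stats::setNames(catalog$transcripts$class_code,
                           catalog$transcripts$transcript_id)
  unique_by_tp <- lapply(window, function(tp) {
    cons <- consensus_presence(catalog, tp, excluded, min_subjects)
    others <- setdiff(window, tp)
    other_samples <- unlist(lapply(others, function(o) {
      catalog_samples_at(catalog, o, excluded)$sample_id
    }))
    present_elsewhere <- rowSums(
      catalog$presence[, other_samples, drop = FALSE]) > 0
    uniq <- setdiff(cons,
                    catalog$transcripts$transcript_id[present_elsewhere])
    data.frame(transcript_id = uniq, class_code = unname(codes[uniq]),
               stringsAsFactors = FALSE)
  })
  names(unique_by_tp) <- window
  structure(list(window = window, unique_by_timepoint = unique_by_tp),
            class = "unique_transcript_report")
}

#' Class-code tally of a transcript set
#'
#' Zero-filled counts over the full GffCompare alphabet.
#'
#' @param transcript_set character vector of transcript ids; all must be
#'   in the catalog.
#' @param catalog a [transcript_catalog()].
#' @return named integer vector over [CLASS_CODES]; sums to the set size.
#' @export
class_code_tally <- function(transcript_set, catalog) {
  stopifnot(inherits(catalog, "transcript_catalog"))
  idx <- match(transcript_set, catalog$transcripts$transcript_id)
  if (anyNA(idx)) {
    stop("transcript(s) not in catalog: ",
         paste(transcript_set[is.na(idx)], collapse = ", "))
  }
  tab <- table(factor(catalog$transcripts$class_code[idx],
                      levels = CLASS_CODES))
  stats::setNames(as.integer(tab), CLASS_CODES)
}
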