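#' GffCompare class-code alphabet
#'
#' The one-letter codes GffCompare assigns to a transfrag's relation to the
#' reference annotation (`=` exact intron-chain match, `c` contained,
#' `j` novel junction, `u` fully novel, etc.).
#' @export
CLASS_CODES <- c("=", "c", "k", "m", "n", "j", "e", "o", "s", "x",
                 "i", "y", "p", "r", "u")

#' Read a sample sheet
#'
#' Tab-separated, header row; required columns `sample_id`, `subject_id`,
#' `timepoint_label`. `time_days` and `phase` are filled from the label map
#' (any values present in the file are overwritten — the bijection is
#' authoritative). An optional `avg_read_length_bp` QC column is kept.
#'
#' @param path TSV file path.
#' @param label_map named integer vector, label -> signed days.
#' @return validated data.frame (one row per sample).
#' @export
read_sample_sheet <- function(path, label_map = MISSION_TIMEPOINTS) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "subject_id", "timepoint_label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!(df$timepoint_label %in% names(label_map)))
  if (length(bad) > 0) {
    stop(sprintf("unknown timepoint label %s in sample sheet row %d",
                 dQuote(df$timepoint_label[bad[1]]), bad[1]))
  }
  df$time_days <- timepoint_days(df$timepoint_label, label_map)
  df$phase <- phase_of_day(df$time_days)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  key <- paste(df$subject_id, df$timepoint_label)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, timepoint) pair: ", key[duplicated(key)][1])
  }
  if ("avg_read_length_bp" %in% names(df)) {
    bad <- which(!is.na(df$avg_read_length_bp) & df$avg_read_length_bp <= 0)
    if (length(bad) > 0) {
      stop("non-positive avg_read_length_bp in sample sheet row ", bad[1])
    }
  }
  df
}

#' Write a sample sheet
#' @param df sample sheet data.frame.
#' @param path output TSV path.
#' @export
write_sample_sheet <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set database
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' Duplicate genes within a line are de-duplicated with a warning;
#' duplicate set names across lines are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene ids), with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields")
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate set name in GMT: ", names_[duplicated(names_)][1])
  }
  sets <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    genes <- fields[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene id(s) within set ", names_[i],
              "; de-duplicated", call. = FALSE)
      genes <- unique(genes)
    }
    if (length(genes) < 1) stop("empty gene set: ", names_[i])
    sets[[i]] <- genes
  }
  names(sets) <- names_
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), names_)
  sets
}

#' Write a GMT gene-set database
#' @param db named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions.
#' @export
write_gmt <- function(db, path, description = attr(db, "description")) {
  if (is.null(description)) description <- stats::setNames(rep("na", length(db)), names(db))
  lines <- vapply(names(db), function(nm) {
    paste(c(nm, description[[nm]], db[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a count matrix
#'
#' Counts are non-negative reals (fractional counts arise from
#' multi-mapping-aware quantification); gene and sample ids are unique.
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @return the matrix, invisibly validated.
#' @export
validate_counts <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene id in count matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample id in count matrix")
  if (anyNA(m)) stop("NA entries in count matrix")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene %s, sample %s",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  m
}

#' Read a gene-by-sample count matrix
#'
#' TSV with a header row; first column is the gene id, remaining columns are
#' samples. Gene ids are opaque strings: versioned Ensembl ids are not
#' reconciled unless `strip_version` is set.
#'
#' @param path TSV file path.
#' @param strip_version drop a trailing `.N` version suffix from gene ids.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, strip_version = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a gene column and >=1 sample column")
  genes <- df[[1]]
  if (strip_version) genes <- sub("\\.\\d+$", "", genes)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell %s at gene %s, sample %s",
                 dQuote(vals[idx[1], idx[2]]), genes[idx[1]],
                 colnames(vals)[idx[2]]))
  }
  rownames(num) <- genes
  validate_counts(num)
}

#' Write a count matrix
#'
#' Values are serialized with 17 significant digits so that
#' `read_counts(write_counts(m))` round-trips to full double precision.
#'
#' @param m numeric matrix (genes x samples).
#' @param path output TSV path.
#' @param gene_column name of the first (gene id) column.
#' @export
write_counts <- function(m, path, gene_column = "gene_id") {
  validate_counts(m)
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m))
  df <- data.frame(rownames(m), chr, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c(gene_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a transcript catalog
#'
#' @param transcripts data.frame with columns `transcript_id`, `locus_id`,
#'   `ref_match` (NA if none), `class_code`.
#' @param presence logical matrix, transcripts x samples.
#' @param samples data.frame mapping `sample_id` to `subject_id` and
#'   `timepoint_label` (a sample-sheet subset).
#' @return object of class `transcript_catalog`.
#' @export
transcript_catalog <- function(transcripts, presence, samples) {
  stopifnot(is.data.frame(transcripts), is.logical(presence),
            is.data.frame(samples))
  need <- c("transcript_id", "locus_id", "ref_match", "class_code")
  stopifnot(all(need %in% names(transcripts)))
  bad <- setdiff(unique(transcripts$class_code), CLASS_CODES)
  if (length(bad) > 0) {
    stop("unknown class code(s): ", paste(dQuote(bad), collapse = ", "))
  }
  if (nrow(presence) != nrow(transcripts) ||
      ncol(presence) != nrow(samples)) {
    stop("presence matrix dimensions do not match transcripts/samples")
  }
  rownames(presence) <- transcripts$transcript_id
  colnames(presence) <- samples$sample_id
  structure(list(transcripts = transcripts, presence = presence,
                 samples = samples),
            class = "transcript_catalog")
}

#' Read a GffCompare-style .tracking file
#'
#' Tab-separated: transfrag id, locus id, reference match (`-` if none),
#' class code, then one column per sample (`-` = absent). Rows absent from
#' every sample are dropped with a warning. The class code must belong to
#' the GffCompare alphabet.
#'
#' @param path .tracking file path.
#' @param samples data.frame mapping the sample columns, in file order, to
#'   `sample_id`, `subject_id`, `timepoint_label` (e.g. a sample sheet).
#' @return a [transcript_catalog()].
#' @export
read_tracking <- function(path, samples) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_expected <- 4 + nrow(samples)
  ragged <- which(lengths(fields) != n_expected)
  if (length(ragged) > 0) {
    stop(sprintf("ragged row %d in tracking file: %d fields, expected %d",
                 ragged[1], lengths(fields)[ragged[1]], n_expected))
  }
  mat <- do.call(rbind, fields)
  codes <- mat[, 4]
  bad <- which(!(codes %in% CLASS_CODES))
  if (length(bad) > 0) {
    stop(sprintf("unknown class code %s in tracking row %d",
                 dQuote(codes[bad[1]]), bad[1]))
  }
  presence <- mat[, -(1:4), drop = FALSE] != "-"
  all_absent <- rowSums(presence) == 0
  if (any(all_absent)) {
    warning(sum(all_absent),
            " tracking row(s) absent from every sample; dropped",
            call. = FALSE)
    mat <- mat[!all_absent, , drop = FALSE]
    presence <- presence[!all_absent, , drop = FALSE]
  }
  transcripts <- data.frame(
    transcript_id = mat[, 1],
    locus_id = mat[, 2],
    ref_match = ifelse(mat[, 3] == "-", NA_character_, mat[, 3]),
    class_code = mat[, 4],
    stringsAsFactors = FALSE
  )
  transcript_catalog(transcripts, presence, samples)
}

#' Write a transcript catalog in .tracking layout
#' @param catalog a [transcript_catalog()].
#' @param path output path.
#' @export
write_tracking <- function(catalog, path) {
  tr <- catalog$transcripts
  pres <- ifelse(catalog$presence,
                 paste0("q:", tr$transcript_id)[row(catalog$presence)], "-")
  pres <- matrix(pres, nrow = nrow(tr))
  lines <- apply(cbind(tr$transcript_id, tr$locus_id,
                       ifelse(is.na(tr$ref_match), "-", tr$ref_match),
                       tr$class_code, pres),
                 1, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}
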