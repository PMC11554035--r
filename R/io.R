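#' Read a QRS annotation file
#'
#' Annotation files follow the bare-index `.tsv` convention of
#' sample-precision ECG databases: one non-negative integer sample index
#' (0-based) per line, no header, no sampling rate. The sampling rate always
#' travels separately in metadata or on the command line — it is never
#' inferred from the file. Blank lines are ignored; duplicated indices are
#' dropped with a warning; unsorted input is sorted with a warning.
#'
#' @param path Path to the annotation file.
#' @return Sorted unique non-negative integer sample indices.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- which(nzchar(lines))
  if (length(keep) == 0L) stop("annotation file is empty: ", path)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  bad <- which(!is.finite(vals) | vals != floor(vals) | vals < 0)
  if (length(bad)) {
    stop(sprintf("non-integer annotation token '%s' at line %d of %s",
                 lines[keep[bad[1]]], keep[bad[1]], path))
  }
  if (is.unsorted(vals)) {
    warning("annotation indices not sorted in ", path, "; sorting")
    vals <- sort(vals)
  }
  if (anyDuplicated(vals)) {
    warning("duplicate annotation indices in ", path, "; de-duplicating")
    vals <- unique(vals)
  }
  vals
}

#' Write a QRS annotation file
#'
#' One 0-based integer sample index per line (see [read_annotations()]).
#'
#' @param annotations Integer sample indices.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  a <- as_sample_indices(annotations, "annotations")
  writeLines(format(a, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Read an ECG signal file
#'
#' Signals are plain numeric text: one sample per line, or whitespace- or
#' tab-delimited columns with one channel per column. Values are read
#' exactly as printed — no unit conversion or rescaling is applied.
#'
#' @param path Path to the signal file.
#' @param column 0-based column to read (default 0, the first column).
#' @return Numeric vector of samples.
#' @export
read_signal <- function(path, column = 0) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("cannot parse signal file ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("signal file is empty: ", path)
  if (column < 0 || column >= ncol(df)) {
    stop(sprintf("column %d not present in %s (%d columns, 0-based)",
                 column, path, ncol(df)))
  }
  df[[column + 1L]]
}

#' Write a synthetic record to disk
#'
#' Writes the signal as full-precision plain numeric text (one sample per
#' line) and the annotations as a companion bare-index `.tsv`, matching the
#' evaluation readers so that write-then-read round-trips exactly.
#'
#' @param record An [annotated_record()].
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to the record label. Files are
#'   `<stem>.txt` (signal) and `<stem>_annotations.tsv`.
#' @return Invisibly, named character vector with paths `signal` and
#'   `annotations`.
#' @export
write_record <- function(record, dir, stem = NULL) {
  stopifnot(inherits(record, "annotated_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem)) stem <- record$label
  sig_path <- file.path(dir, paste0(stem, ".txt"))
  ann_path <- file.path(dir, paste0(stem, "_annotations.tsv"))
  writeLines(format(record$samples, digits = 17, scientific = TRUE,
                    trim = TRUE), sig_path)
  write_annotations(record$annotations, ann_path)
  invisible(c(signal = sig_path, annotations = ann_path))
}

#' Read a record bundle (signal + annotations)
#'
#' Loads a signal file and its companion annotation `.tsv` into an
#' [annotated_record()]. This is also the loader for records laid out in
#' the style of public sample-precision ECG databases (a signal column file
#' plus a bare-index annotation file per activity): point it at the two
#' files and supply the sampling rate. Downloading any such database is
#' optional — nothing in the package requires it.
#'
#' @param signal_path Path to the signal file.
#' @param ann_path Path to the annotation `.tsv`.
#' @param fs Sampling rate (samples/sec); must be supplied, never inferred.
#' @param column 0-based signal column (default 0).
#' @param label Record label; defaults to the signal file stem.
#' @param meta Optional metadata list.
#' @return An [annotated_record()].
#' @export
read_record_bundle <- function(signal_path, ann_path, fs, column = 0,
                               label = NULL, meta = list()) {
  samples <- read_signal(signal_path, column = column)
  anns <- read_annotations(ann_path)
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(signal_path))
  }
  annotated_record(samples, fs, anns, label = label, meta = meta)
}

#' Export metric results
#'
#' Writes a metric result table (rows as produced by [evaluate_record()] or
#' [suite_table()]) as delimited text or a structured JSON report.
#'
#' @param results Data frame of results.
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_metric_report <- function(results, path,
                                format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  switch(format,
    tsv = utils::write.table(results, path, sep = "\t", row.names = FALSE,
                             quote = FALSE),
    csv = utils::write.csv(results, path, row.names = FALSE),
    json = jsonlite::write_json(results, path, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA, na = "null")
  )
  invisible(path)
}
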