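#' Annotated ECG record
#'
#' Bundles a single-channel ECG voltage series with its sampling rate and the
#' ground-truth QRS annotations. Annotations are 0-based sample indices of the
#' R-peaks, following the bare-index `.tsv` convention used by sample-precision
#' ECG databases: an annotation value of `k` points at `samples[k + 1]` in R's
#' 1-based vector indexing.
#'
#' @param samples Numeric vector, the ECG voltage series (arbitrary units).
#' @param fs Sampling rate in samples per second, `> 0`.
#' @param annotations Strictly increasing integer vector of 0-based sample
#'   indices of true QRS complexes, all within `[0, length(samples))`.
#' @param label Free-text record identifier.
#' @param meta Optional named list of metadata (e.g. `morphology`, `regime`).
#'
#' @return An object of class `annotated_record` with fields `samples`, `fs`,
#'   `annotations`, `label`, `meta`.
#' @examples
#' rec <- annotated_record(sin(2 * pi * (0:999) / 250), fs = 250,
#'                         annotations = c(100L, 350L, 600L))
#' rec
#' @export
annotated_record <- function(samples, fs, annotations, label = "record",
                             meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  annotations <- as_sample_indices(annotations, "annotations")
  if (any(annotations >= length(samples))) {
    stop("annotation indices must lie within [0, length(samples))")
  }
  if (is.unsorted(annotations, strictly = TRUE)) {
    stop("`annotations` must be strictly increasing (no duplicate beats)")
  }
  structure(
    list(samples = samples, fs = fs, annotations = annotations,
         label = as.character(label)[1L], meta = meta),
    class = "annotated_record"
  )
}

#' @export
print.annotated_record <- function(x, ...) {
  cat(sprintf("<annotated_record '%s'>\n", x$label))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), %d annotated beats\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              length(x$annotations)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Detection set
#'
#' Ordered detector output for one record: 0-based sample indices of detected
#' QRS complexes. `corrected` holds the delay-corrected indices after
#' [median_delay_correct()]; corrected indices keep the relative spacing of
#' `raw` (a single constant is subtracted) and may be non-integer.
#'
#' @param raw Integer vector of detection sample indices, sorted ascending,
#'   no duplicates.
#' @param detector_name Name of the producing detector.
#' @param corrected Optional numeric vector of delay-corrected indices, same
#'   length as `raw`.
#'
#' @return Object of class `detection_set`.
#' @export
detection_set <- function(raw, detector_name = "unknown", corrected = NULL) {
  raw <- as_sample_indices(raw, "raw")
  if (is.unsorted(raw, strictly = TRUE)) {
    stop("`raw` detection indices must be sorted ascending without duplicates")
  }
  if (!is.null(corrected)) {
    corrected <- as.numeric(corrected)
    if (length(corrected) != length(raw)) {
      stop("`corrected` must have the same length as `raw`")
    }
  }
  structure(
    list(raw = raw, corrected = corrected,
         detector_name = as.character(detector_name)[1L]),
    class = "detection_set"
  )
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set '%s'> %d detections%s\n", x$detector_name,
              length(x$raw),
              if (is.null(x$corrected)) "" else " (delay-corrected)"))
  invisible(x)
}

# Coerce annotation/detection input to a bare numeric vector of sample indices.
# Accepts integer-valued numerics; annotated_record/detection_set unwrap.
as_indices <- function(x) {
  if (inherits(x, "annotated_record")) return(x$annotations)
  if (inherits(x, "detection_set")) {
    return(if (!is.null(x$corrected)) x$corrected else x$raw)
  }
  as.numeric(x)
}

as_sample_indices <- function(x, what) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop(sprintf("`%s` contains non-finite values", what))
  if (any(x != floor(x))) {
    stop(sprintf("`%s` must contain integer sample indices", what))
  }
  if (any(x < 0)) stop(sprintf("`%s` contains negative sample indices", what))
  x
}
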