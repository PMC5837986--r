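#' Multichannel recording container
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate,
#' channel labels and (optionally) peri-ictal epoch annotations. This is the
#' raw input of the analysis pipeline.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Optional character vector, one label per channel.
#' @param annotations Optional [epoch_annotation()] marking the peri-ictal
#'   epoch boundaries.
#' @return An object of class `"recording"`.
#' @export
recording <- function(data, fs, channel_labels = NULL, annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 2L) stop("a recording needs at least 2 channels")
  stop_scalar(fs, "fs", positive = TRUE)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("`channel_labels` must have one entry per channel")
  rec <- structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         annotations = NULL),
    class = "recording")
  if (!is.null(annotations)) rec <- set_annotations(rec, annotations)
  rec
}

#' Peri-ictal epoch annotations
#'
#' Times (in seconds, relative to the start of the recording) delimiting the
#' pre-ictal epoch, the seizure, and the post-ictal epoch. Pre- and post-ictal
#' epochs are nominally 3 minutes long.
#'
#' @param preictal_start_s,seizure_onset_s,seizure_offset_s,postictal_end_s
#'   Strictly increasing boundary times in seconds.
#' @return An object of class `"epoch_annotation"`.
#' @export
epoch_annotation <- function(preictal_start_s, seizure_onset_s,
                             seizure_offset_s, postictal_end_s) {
  b <- c(preictal_start_s, seizure_onset_s, seizure_offset_s, postictal_end_s)
  if (!is.numeric(b) || length(b) != 4L || any(!is.finite(b)))
    stop("annotation boundaries must be finite numbers")
  if (any(diff(b) <= 0))
    stop("annotation boundaries must be strictly increasing ",
         "(preictal_start < seizure_onset < seizure_offset < postictal_end)")
  structure(
    list(preictal_start_s = preictal_start_s, seizure_onset_s = seizure_onset_s,
         seizure_offset_s = seizure_offset_s, postictal_end_s = postictal_end_s),
    class = "epoch_annotation")
}

set_annotations <- function(rec, ann) {
  stopifnot(inherits(rec, "recording"), inherits(ann, "epoch_annotation"))
  dur <- ncol(rec$data) / rec$fs
  if (ann$preictal_start_s < 0 || ann$postictal_end_s > dur + 1e-9)
    stop("annotation boundaries must lie within the recording (0 to ",
         signif(dur, 6), " s)")
  rec$annotations <- ann
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$annotations)) {
    a <- x$annotations
    cat(sprintf("  peri-ictal: pre [%g, %g) s, ictal [%g, %g) s, post [%g, %g] s\n",
                a$preictal_start_s, a$seizure_onset_s, a$seizure_onset_s,
                a$seizure_offset_s, a$seizure_offset_s, a$postictal_end_s))
  }
  invisible(x)
}

#' Read and write recordings as plain text
#'
#' The plain-matrix format has one header line of tab-separated channel
#' labels followed by one line per sample (tab-separated values, one column
#' per channel). Annotations travel in a JSON sidecar with keys
#' `preictal_start_s`, `seizure_onset_s`, `seizure_offset_s`,
#' `postictal_end_s`.
#'
#' @param path Path of the matrix file.
#' @param fs Sampling rate in Hz (not stored in the matrix file).
#' @param annotations_path Optional path of the JSON annotation sidecar.
#' @return `read_recording_tsv()` returns a [recording()];
#'   `write_recording_tsv()` returns `path` invisibly.
#' @export
read_recording_tsv <- function(path, fs, annotations_path = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  ann <- if (!is.null(annotations_path)) read_annotations_json(annotations_path)
  recording(t(as.matrix(tab)), fs = fs, channel_labels = colnames(tab),
            annotations = ann)
}

#' @rdname read_recording_tsv
#' @param rec A [recording()].
#' @export
write_recording_tsv <- function(rec, path, annotations_path = NULL) {
  stopifnot(inherits(rec, "recording"))
  tab <- as.data.frame(t(rec$data))
  names(tab) <- rec$channel_labels
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(annotations_path)) {
    if (is.null(rec$annotations)) stop("recording carries no annotations")
    write_annotations_json(rec$annotations, annotations_path)
  }
  invisible(path)
}

#' @rdname read_recording_tsv
#' @export
read_annotations_json <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("preictal_start_s", "seizure_onset_s", "seizure_offset_s",
            "postictal_end_s")
  if (!all(need %in% names(j)))
    stop("annotation JSON must contain keys: ", paste(need, collapse = ", "))
  epoch_annotation(j$preictal_start_s, j$seizure_onset_s,
                   j$seizure_offset_s, j$postictal_end_s)
}

#' @rdname read_recording_tsv
#' @param ann An [epoch_annotation()].
#' @export
write_annotations_json <- function(ann, path) {
  stopifnot(inherits(ann, "epoch_annotation"))
  jsonlite::write_json(unclass(ann), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
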