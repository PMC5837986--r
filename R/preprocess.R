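# Preprocessing: resampling, median re-referencing, zero-phase filtering,
# peri-ictal segmentation and subsegment ensembles.

# Apply a signal-package filter forward-backward (zero phase) to every channel.
filtfilt_channels <- function(data, filt) {
  t(apply(data, 1L, function(ch) signal::filtfilt(filt, ch)))
}

#' Down-sample a recording
#'
#' Anti-alias filters (zero-phase Butterworth low-pass at 0.45 times the
#' target rate) and then resamples onto the target time grid by linear
#' interpolation. Annotation times are in seconds and carry over unchanged.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz; must not exceed `rec$fs`.
#' @return A [recording()] at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  stop_scalar(target_fs, "target_fs", positive = TRUE)
  if (target_fs > rec$fs)
    stop("upsampling refused: `target_fs` (", target_fs,
         " Hz) exceeds the recording rate (", rec$fs, " Hz)")
  if (target_fs == rec$fs) return(rec)
  lp <- signal::butter(8, 0.45 * target_fs / (rec$fs / 2), type = "low")
  filtered <- filtfilt_channels(rec$data, lp)
  n <- ncol(rec$data)
  t_old <- (seq_len(n) - 1L) / rec$fs
  t_new <- seq(0, t_old[n], by = 1 / target_fs)
  out <- t(apply(filtered, 1L, function(ch) approx(t_old, ch, xout = t_new)$y))
  recording(out, fs = target_fs, channel_labels = rec$channel_labels,
            annotations = rec$annotations)
}

#' Median re-referencing
#'
#' Subtracts, at every sample, the cross-channel median from every channel.
#' Channels listed in `exclude_channels` do not contribute to the median but
#' are still re-referenced. Common (reference) signals shared by all channels
#' cancel exactly; the operation is idempotent.
#'
#' @param rec A [recording()].
#' @param exclude_channels Optional integer indices of channels excluded from
#'   the median (e.g. channels judged artifactual).
#' @return A [recording()] with zero cross-channel median at every sample.
#' @export
rereference_median <- function(rec, exclude_channels = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2L) stop("median re-referencing needs at least 2 channels")
  use <- setdiff(seq_len(nrow(rec$data)), exclude_channels)
  if (length(use) < 2L)
    stop("fewer than 2 channels left to form the median reference")
  med <- apply(rec$data[use, , drop = FALSE], 2L, median)
  rec$data <- sweep(rec$data, 2L, med)
  rec
}

#' Band-pass and notch filtering
#'
#' Zero-phase (forward-backward) Butterworth filtering: a 4th-order high-pass
#' and low-pass cascade implementing the band-pass, followed by a 2nd-order
#' band-stop notch. Defaults follow the peri-ictal protocol: pass band
#' 0.5-120 Hz, notch 48-52 Hz.
#'
#' @param rec A [recording()].
#' @param band Numeric length-2, pass-band edges in Hz.
#' @param notch Numeric length-2, stop-band edges in Hz; must lie inside
#'   `band`. `NULL` skips the notch (e.g. for data without power-line
#'   interference).
#' @return The filtered [recording()].
#' @export
bandpass_notch_filter <- function(rec, band = c(0.5, 120), notch = c(48, 52)) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("`band` must be increasing positive edges [low, high]")
  if (band[2] >= nyq)
    stop("band edge ", band[2], " Hz is at or above Nyquist (", nyq, " Hz)")
  if (!is.null(notch) &&
      (length(notch) != 2L || notch[1] >= notch[2] ||
       notch[1] <= band[1] || notch[2] >= band[2]))
    stop("`notch` must be an increasing interval inside `band` (or NULL)")
  hp <- signal::butter(4, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  out <- filtfilt_channels(rec$data, hp)
  out <- filtfilt_channels(out, lp)
  if (!is.null(notch)) {
    bs <- signal::butter(2, notch / nyq, type = "stop")
    out <- filtfilt_channels(out, bs)
  }
  rec$data <- out
  rec
}

epoch_bounds <- function(ann) {
  list(preictal = c(ann$preictal_start_s, ann$seizure_onset_s),
       ictal = c(ann$seizure_onset_s, ann$seizure_offset_s),
       postictal = c(ann$seizure_offset_s, ann$postictal_end_s))
}

#' Peri-ictal segmentation
#'
#' Cuts each annotated epoch independently into 8 s segments separated by
#' 1 s gaps (starts every 9 s from the epoch start). Segments never straddle
#' epoch boundaries; windows that would cross the boundary are dropped. An
#' epoch shorter than the segment length yields zero segments, with a
#' warning.
#'
#' @param rec An annotated [recording()].
#' @param segment_s Segment length in seconds (default 8).
#' @param gap_s Gap between consecutive segments in seconds (default 1).
#' @return A list of `"segment"` objects, each carrying `data`
#'   (channels x samples), `start_s`, `end_s` and `epoch_label` (one of
#'   `"preictal"`, `"ictal"`, `"postictal"`).
#' @export
segment_peri_ictal <- function(rec, segment_s = 8, gap_s = 1) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$annotations)) stop("recording carries no epoch annotations")
  stride <- segment_s + gap_s
  fs <- rec$fs
  out <- list()
  for (label in names(epoch_bounds(rec$annotations))) {
    b <- epoch_bounds(rec$annotations)[[label]]
    len <- b[2] - b[1]
    if (len < segment_s - 1e-9) {
      warning("epoch '", label, "' is shorter than ", segment_s,
              " s; no segments produced", call. = FALSE)
      next
    }
    n_seg <- floor((len - segment_s) / stride + 1e-9) + 1L
    for (i in seq_len(n_seg)) {
      start_s <- b[1] + (i - 1L) * stride
      i0 <- round(start_s * fs)
      idx <- seq.int(i0 + 1L, i0 + round(segment_s * fs))
      out[[length(out) + 1L]] <- structure(
        list(data = rec$data[, idx, drop = FALSE],
             start_s = start_s, end_s = start_s + segment_s,
             epoch_label = label, fs = fs),
        class = "segment")
    }
  }
  out
}

# Subsegment start samples: 10 windows of 2 s evenly spaced over [0, 6] s,
# i.e. start_i = i * (6/9) s rounded to the sample grid.
subsegment_starts <- function(fs, segment_s = 8, sub_s = 2, n_sub = 10L) {
  spacing <- (segment_s - sub_s) / (n_sub - 1L)
  round((seq_len(n_sub) - 1L) * spacing * fs)
}

slice_subsegments <- function(data, fs, sub_s = 2, n_sub = 10L,
                              segment_s = 8) {
  starts <- subsegment_starts(fs, segment_s, sub_s, n_sub)
  len <- round(sub_s * fs)
  lapply(starts, function(s0) data[, seq.int(s0 + 1L, s0 + len), drop = FALSE])
}

#' Subsegment ensembles
#'
#' Divides an 8 s segment into 10 subsegments of 2 s distributed with
#' minimal overlap (uniform start spacing of 6/9 s), and applies the same
#' subsegment grid to each of the supplied surrogate matrices, yielding 10
#' original and 100 surrogate subsegments.
#'
#' @param seg A `"segment"` from [segment_peri_ictal()].
#' @param surrogates A list of surrogate matrices, each the same shape as
#'   `seg$data` (one surrogate version of the whole segment).
#' @return A list with elements `original` (10 matrices), `surrogate`
#'   (`10 * length(surrogates)` matrices) and `parent` (the segment).
#' @export
make_subsegments <- function(seg, surrogates) {
  stopifnot(inherits(seg, "segment"))
  if (!is.list(surrogates) || !length(surrogates))
    stop("`surrogates` must be a non-empty list of matrices")
  ok <- vapply(surrogates, function(m)
    is.matrix(m) && all(dim(m) == dim(seg$data)), logical(1))
  if (!all(ok))
    stop("every surrogate matrix must match the segment shape (",
         nrow(seg$data), " x ", ncol(seg$data), ")")
  original <- slice_subsegments(seg$data, seg$fs)
  surrogate <- unlist(lapply(surrogates, slice_subsegments, fs = seg$fs),
                      recursive = FALSE)
  list(original = original, surrogate = surrogate, parent = seg)
}
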