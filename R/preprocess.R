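#' @title EEG preprocessing
#' @description Amplitude-threshold artifact rejection, clean-segment
#'   selection and splicing into fixed-length epochs, following standard
#'   clinical qEEG practice: reject level +/-150 microvolts, segments of
#'   at least 600 ms, at least 1 min retained, 2-s epochs.
#' @name eeg_preprocess
NULL

#' Construct an EEG recording
#'
#' @param samples Numeric channels x samples matrix, in microvolts.
#' @param fs Sampling rate in Hz (default 256).
#' @param montage A [montage_1020()] object (rows of `samples` must
#'   match its labels).
#' @param reference Reference scheme of the data, `"linked-ears"` or
#'   `"average"`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, fs = 256,
                          montage = montage_1020(),
                          reference = c("linked-ears", "average")) {
  reference <- match.arg(reference)
  samples <- as.matrix(samples)
  if (nrow(samples) != length(montage$labels))
    stop("channel count does not match montage")
  if (fs <= 0) stop("fs must be positive")
  rownames(samples) <- montage$labels
  structure(list(samples = samples, fs = fs, montage = montage,
                 reference = reference), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s @ %g Hz, %s reference)\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$fs, x$fs, x$reference))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering applied per
#' channel; the acquisition front-end band is 1-40 Hz by default.
#'
#' @param rec An [eeg_recording()] or numeric matrix (channels x samples).
#' @param band Length-2 numeric, pass-band edges in Hz.
#' @param order Butterworth order of the underlying one-pass filter.
#' @param fs Sampling rate, taken from `rec` when it is a recording.
#' @return Same type as `rec`, filtered.
#' @export
bandpass_filter <- function(rec, band = c(1, 40), order = 4, fs = NULL) {
  x <- if (inherits(rec, "eeg_recording")) rec$samples else as.matrix(rec)
  fs <- if (inherits(rec, "eeg_recording")) rec$fs else fs
  if (is.null(fs)) stop("fs required for matrix input")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  if (inherits(rec, "eeg_recording")) { rec$samples <- y; rec } else y
}

#' Mark artifact samples by amplitude threshold
#'
#' A sample is bad iff any channel's absolute value strictly exceeds the
#' reject level (so a signal touching exactly +/-150 microvolts is kept:
#' the reject levels are the bounds of acceptance).  Non-finite samples
#' are marked bad.
#'
#' @param rec An [eeg_recording()].
#' @param amplitude_limit Reject level in microvolts (default 150).
#' @return Logical vector, `TRUE` where the sample is bad.
#' @export
detect_artifacts <- function(rec, amplitude_limit = 150) {
  stopifnot(inherits(rec, "eeg_recording"))
  a <- abs(rec$samples)
  bad <- apply(a, 2, function(v) any(!is.finite(v)) ||
                 any(v[is.finite(v)] > amplitude_limit))
  as.logical(bad)
}

#' Select clean segments
#'
#' Keeps maximal artifact-free runs of at least `min_segment_s` seconds.
#' If more than `min_total_s` of eligible data exists, segments are
#' sampled at random (seeded) until the minimum total is reached,
#' mirroring the random selection of 1 min from a 3-min record; with
#' `select_all = TRUE` every eligible run is retained.
#'
#' @param rec An [eeg_recording()].
#' @param mask Logical bad-sample mask from [detect_artifacts()].
#' @param min_segment_s Minimum run length in seconds (default 0.6).
#' @param min_total_s Minimum total retained, seconds (default 60).
#' @param seed Integer seed for the random selection.
#' @param select_all Keep all eligible runs instead of sampling.
#' @return A `clean_segments` object: data frame `segments` with
#'   half-open sample intervals `start`, `end` (0-based), flag
#'   `sufficient`, the seed, and the source recording.
#' @export
extract_clean_segments <- function(rec, mask, min_segment_s = 0.6,
                                   min_total_s = 60, seed = 0L,
                                   select_all = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"),
            length(mask) == ncol(rec$samples))
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  good <- which(r$values & r$lengths >= ceiling(min_segment_s * rec$fs))
  seg <- data.frame(start = starts[good], end = ends[good])
  if (!select_all && nrow(seg) > 0) {
    need <- min_total_s * rec$fs
    if (sum(seg$end - seg$start) > need) {
      ord <- local({
        old <- get_rng_state(); on.exit(set_rng_state(old))
        set.seed(as.integer(seed)); sample.int(nrow(seg))
      })
      keep <- ord[seq_len(which(cumsum((seg$end - seg$start)[ord]) >= need)[1])]
      seg <- seg[sort(keep), ]
    }
  }
  total <- sum(seg$end - seg$start)
  structure(list(segments = seg,
                 sufficient = total >= min_total_s * rec$fs,
                 total_samples = total, seed = as.integer(seed),
                 source = rec), class = "clean_segments")
}

#' @export
print.clean_segments <- function(x, ...) {
  cat(sprintf("clean segments: %d run(s), %.2f s retained (%s)\n",
              nrow(x$segments), x$total_samples / x$source$fs,
              if (x$sufficient) "sufficient" else "insufficient"))
  invisible(x)
}

#' Splice clean segments and cut fixed-length epochs
#'
#' Concatenates the retained segments and partitions the spliced record
#' into non-overlapping epochs of `epoch_length_s` seconds (default 2),
#' discarding a final partial epoch.  Epoch boundaries need not align
#' with segment boundaries; the sample positions of interior splice
#' joins are recorded so that spectral windowing can taper across them.
#'
#' @param segs A [extract_clean_segments()] result.
#' @param epoch_length_s Epoch length in seconds.
#' @param allow_insufficient Proceed even when less than the minimum
#'   total was retained.
#' @return An `epoch_set`: list of channels x samples matrices, plus
#'   `fs`, `montage`, `epoch_length_s` and `joints` (0-based sample
#'   indices, within the spliced record, where two segments meet).
#' @export
splice_and_epoch <- function(segs, epoch_length_s = 2,
                             allow_insufficient = TRUE) {
  stopifnot(inherits(segs, "clean_segments"))
  if (!segs$sufficient && !allow_insufficient)
    stop("insufficient clean data retained")
  rec <- segs$source
  nper <- round(rec$fs * epoch_length_s)
  if (nrow(segs$segments) == 0) {
    warning("no clean segments; empty epoch set")
    return(structure(list(epochs = list(), fs = rec$fs,
                          montage = rec$montage,
                          epoch_length_s = epoch_length_s,
                          joints = integer(0)), class = "epoch_set"))
  }
  pieces <- lapply(seq_len(nrow(segs$segments)), function(i)
    rec$samples[, (segs$segments$start[i] + 1):segs$segments$end[i],
                drop = FALSE])
  spliced <- do.call(cbind, pieces)
  lens <- vapply(pieces, ncol, 1L)
  joints <- cumsum(lens)[-length(lens)]    # 0-based interior joins
  n_ep <- ncol(spliced) %/% nper
  epochs <- lapply(seq_len(n_ep), function(i)
    spliced[, ((i - 1) * nper + 1):(i * nper), drop = FALSE])
  structure(list(epochs = epochs, fs = rec$fs, montage = rec$montage,
                 epoch_length_s = epoch_length_s,
                 joints = as.integer(joints)), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch set: %d epoch(s) of %g s @ %g Hz, %d splice joint(s)\n",
              length(x$epochs), x$epoch_length_s, x$fs, length(x$joints)))
  invisible(x)
}

#' One-call cleaning front end
#'
#' Band-pass filters, detects artifacts, extracts clean segments and
#' epochs a raw recording with the standard defaults.
#'
#' @param rec An [eeg_recording()].
#' @param amplitude_limit Reject level, microvolts.
#' @param min_segment_s,min_total_s,epoch_length_s,seed Passed through.
#' @param band Front-end band-pass in Hz, or `NULL` to skip filtering.
#' @return An `epoch_set`.
#' @export
clean_recording <- function(rec, amplitude_limit = 150, min_segment_s = 0.6,
                            min_total_s = 60, epoch_length_s = 2,
                            seed = 0L, band = NULL) {
  if (!is.null(band)) rec <- bandpass_filter(rec, band)
  mask <- detect_artifacts(rec, amplitude_limit)
  segs <- extract_clean_segments(rec, mask, min_segment_s, min_total_s, seed)
  splice_and_epoch(segs, epoch_length_s)
}

#' Read / write a recording as plain-text matrix plus montage sidecar
#'
#' The matrix CSV holds one row per channel (row names = labels); the
#' sidecar JSON stores `fs` and `reference`.
#'
#' @param rec An [eeg_recording()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  utils::write.csv(data.frame(label = rownames(rec$samples), rec$samples,
                              check.names = FALSE),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, reference = rec$reference),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$label, NULL)
  eeg_recording(m[montage_1020()$labels, , drop = FALSE], fs = meta$fs,
                reference = meta$reference)
}
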