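#' Construct a multichannel recording
#'
#' A `recording` bundles a channels-by-samples signal matrix with its sampling
#' rate, channel labels, and the seizure annotations (onset and termination, in
#' seconds from time zero of the record). All downstream operations — band
#' extraction, phase estimation, connectivity, segmentation — consume this
#' container.
#'
#' @param data numeric matrix, channels x samples (microvolts by convention,
#'   units are not enforced).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names; defaults to
#'   `"ch1" ... "chM"`.
#' @param onset_s,termination_s seizure onset and termination in seconds from
#'   the start of the record; `termination_s > onset_s >= 0` and both must lie
#'   within the record. May be `NULL` for un-annotated recordings.
#' @param t0_s absolute time of the first sample, in seconds. Zero for a fresh
#'   record; [crop_recording()] advances it so that annotations stay absolute.
#' @return an object of class `recording`.
#' @seealso [read_recording()], [remove_bad_channels()], [crop_recording()]
#' @export
new_recording <- function(data, fs, channel_labels = NULL,
                          onset_s = NULL, termination_s = NULL, t0_s = 0) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  assert_scalar_number(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  m <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(m))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != m || anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be ", m, " unique labels", call. = FALSE)
  }
  assert_scalar_number(t0_s, "t0_s")
  dur <- ncol(data) / fs
  if (!is.null(onset_s) || !is.null(termination_s)) {
    assert_scalar_number(onset_s, "onset_s")
    assert_scalar_number(termination_s, "termination_s")
    if (onset_s < 0 || termination_s <= onset_s) {
      stop("need termination_s > onset_s >= 0", call. = FALSE)
    }
    if (onset_s < t0_s || termination_s > t0_s + dur) {
      stop("seizure annotations fall outside the record ([",
           t0_s, ", ", t0_s + dur, "] s)", call. = FALSE)
    }
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         onset_s = onset_s, termination_s = termination_s, t0_s = t0_s),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", n_channels(x), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(duration_s(x), 2), " s)\n", sep = "")
  if (!is.null(x$onset_s)) {
    cat("  seizure: [", x$onset_s, ", ", x$termination_s, ") s\n", sep = "")
  }
  if (!is.null(attr(x, "band"))) cat("  band:", attr(x, "band"), "\n")
  invisible(x)
}

#' @rdname new_recording
#' @param rec a `recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname new_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Read a recording from disk
#'
#' Supports two on-disk forms: a headerless delimited text matrix (channels in
#' rows, samples in columns; whitespace-, comma- or tab-separated) with the
#' sampling rate and annotations supplied either as arguments or in a YAML
#' sidecar `<path>.yaml` with keys `fs`, `onset_s`, `termination_s`,
#' `channel_labels`; or an EDF file (16-bit continuous recordings, see
#' [read_edf()]). Arguments override sidecar values.
#'
#' @param path file path.
#' @param format `"auto"` (by extension; `.edf` selects EDF), `"matrix"` or
#'   `"edf"`.
#' @param fs sampling rate in Hz (matrix format; required unless in sidecar).
#' @param onset_s,termination_s seizure annotations in seconds.
#' @param channel_labels optional channel names.
#' @return a [new_recording()] object, channel order as stored in the file.
#' @export
read_recording <- function(path, format = c("auto", "matrix", "edf"),
                           fs = NULL, onset_s = NULL, termination_s = NULL,
                           channel_labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  if (format == "edf") {
    rec <- read_edf(path)
    dat <- rec$data
    fs <- fs %||% rec$fs
    channel_labels <- channel_labels %||% rec$channel_labels
  } else {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      fs <- fs %||% meta$fs
      onset_s <- onset_s %||% meta$onset_s
      termination_s <- termination_s %||% meta$termination_s
      channel_labels <- channel_labels %||% meta$channel_labels
    }
    if (is.null(fs)) {
      stop("matrix format needs `fs` (argument or YAML sidecar)", call. = FALSE)
    }
    dat <- as.matrix(utils::read.table(path, header = FALSE,
                                       colClasses = "numeric"))
    dimnames(dat) <- NULL
  }
  new_recording(dat, fs = fs, channel_labels = channel_labels,
                onset_s = onset_s, termination_s = termination_s)
}

#' Write a recording as a plain text matrix plus YAML sidecar
#'
#' Inverse of the matrix branch of [read_recording()]: a headerless
#' tab-delimited channels-by-samples matrix at `path` and metadata
#' (`fs`, annotations, labels) at `<path>.yaml`.
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @param digits signal values are written with this many significant digits.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 7) {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(signif(rec$data, digits), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fs = rec$fs, channel_labels = as.list(rec$channel_labels))
  if (!is.null(rec$onset_s)) {
    meta$onset_s <- rec$onset_s
    meta$termination_s <- rec$termination_s
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Drop bad channels from a recording
#'
#' Clinical ECoG grids often contain channels dominated by noise; analyses run
#' on the surviving channels. The exclusion list is the caller's
#' responsibility (see [flag_bad_channels()] for a simple variance-based
#' helper). Surviving channel order is preserved.
#'
#' @param rec a `recording`.
#' @param exclude character vector of channel labels to remove (may be empty).
#' @return the `recording` without the excluded channels.
#' @export
remove_bad_channels <- function(rec, exclude = character()) {
  stopifnot(inherits(rec, "recording"))
  exclude <- as.character(exclude)
  if (length(exclude) == 0) return(rec)
  unknown <- setdiff(exclude, rec$channel_labels)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(rec$channel_labels %in% exclude)
  if (!any(keep)) stop("cannot exclude every channel", call. = FALSE)
  out <- rec
  out$data <- rec$data[keep, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[keep]
  out
}

#' Flag channels with outlying variance
#'
#' A convenience screen for grossly noisy channels: computes the z-score of
#' each channel's log sample variance and returns the labels whose |z| exceeds
#' `z_thresh`. Intended as a starting point only — visual review remains the
#' gold standard for bad-channel rejection.
#'
#' @param rec a `recording`.
#' @param z_thresh flagging threshold on |z| (default 5).
#' @return character vector of flagged labels (possibly empty).
#' @export
flag_bad_channels <- function(rec, z_thresh = 5) {
  stopifnot(inherits(rec, "recording"))
  v <- log(apply(rec$data, 1, stats::var) + .Machine$double.eps)
  z <- (v - mean(v)) / stats::sd(v)
  if (!is.finite(stats::sd(v)) || stats::sd(v) == 0) return(character())
  rec$channel_labels[abs(z) > z_thresh]
}

#' Crop a recording to a time span
#'
#' Returns the samples covering `[start_s, end_s)`. `t0_s` of the result is
#' set to the crop start so that annotations and period boundaries remain in
#' absolute seconds.
#'
#' @param rec a `recording`.
#' @param start_s,end_s crop limits in absolute seconds.
#' @return a `recording` holding the cropped samples.
#' @export
crop_recording <- function(rec, start_s, end_s) {
  stopifnot(inherits(rec, "recording"))
  assert_scalar_number(start_s, "start_s")
  assert_scalar_number(end_s, "end_s")
  if (end_s <= start_s) stop("need end_s > start_s", call. = FALSE)
  i0 <- round((start_s - rec$t0_s) * rec$fs) + 1
  i1 <- round((end_s - rec$t0_s) * rec$fs)
  if (i0 < 1 || i1 > ncol(rec$data)) {
    stop("crop [", start_s, ", ", end_s, ") s exceeds the record", call. = FALSE)
  }
  out <- rec
  out$data <- rec$data[, i0:i1, drop = FALSE]
  out$t0_s <- rec$t0_s + (i0 - 1) / rec$fs
  # annotations kept if they survive the crop
  if (!is.null(rec$onset_s) &&
      (rec$onset_s < out$t0_s || rec$termination_s > out$t0_s + duration_s(out))) {
    out$onset_s <- NULL
    out$termination_s <- NULL
  }
  out
}
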