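# Minimal EDF (European Data Format) support: continuous 16-bit records with a
# uniform sampling rate across signals, which covers standard clinical ECoG
# exports. Header layout per the EDF specification (256-byte fixed header +
# 256 bytes per signal), data records as little-endian int16 scaled linearly
# from digital to physical range.

edf_field <- function(con, nchar) trimws(readChar(con, nchar, useBytes = TRUE))

#' Read an EDF file
#'
#' Reads a continuous EDF recording into a [new_recording()]. All signals must
#' share one sampling rate (signals such as annotation channels with a
#' different rate are not supported). Annotations (seizure onset/termination)
#' are not part of EDF proper; attach them via [read_recording()] arguments.
#'
#' @param path path to an EDF file.
#' @return a `recording` (without seizure annotations).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')",
                           call. = FALSE)
  edf_field(con, 80)  # patient id
  edf_field(con, 80)  # recording id
  edf_field(con, 8)   # start date
  edf_field(con, 8)   # start time
  edf_field(con, 8)   # header bytes
  edf_field(con, 44)  # reserved
  n_rec <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(n_rec) || n_rec < 1) stop("EDF with unknown record count",
                                      call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)              # transducer
  for (i in seq_len(ns)) edf_field(con, 8)               # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 80)              # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) edf_field(con, 8), ""))
  for (i in seq_len(ns)) edf_field(con, 32)              # reserved
  if (length(unique(spr)) != 1) {
    stop("EDF signals with mixed sampling rates are not supported",
         call. = FALSE)
  }
  n <- spr[1]
  fs <- n / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dat <- matrix(0, nrow = ns, ncol = n_rec * n)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * n, size = 2, signed = TRUE,
                     endian = "little")
    if (length(block) < ns * n) stop("truncated EDF data record", call. = FALSE)
    block <- matrix(block, nrow = n, ncol = ns)  # per signal, contiguous
    cols <- ((r - 1) * n + 1):(r * n)
    dat[, cols] <- t(block * rep(scale, each = n) +
                       rep(phys_min - dig_min * scale, each = n))
  }
  new_recording(dat, fs = fs, channel_labels = make.unique(labels))
}

#' Write a recording as EDF
#'
#' Writes a continuous 16-bit EDF file with one-second data records (the
#' sampling rate must therefore be a positive integer). Each channel is scaled
#' to its own physical range. Mainly used for interoperability checks and
#' round-trip tests; quantization to 16 bits makes the round trip lossy at the
#' level of the physical range divided by 2^16.
#'
#' @param rec a `recording` with integer `fs` and a whole number of seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  n_rec <- ncol(rec$data) / fs
  if (n_rec != round(n_rec)) {
    stop("EDF writer requires a whole number of seconds", call. = FALSE)
  }
  ns <- n_channels(rec)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  # numbers must fit the 8-byte header fields exactly
  num8 <- function(x) {
    vapply(x, function(v) {
      for (d in 7:1) {
        s <- formatC(v, digits = d, format = "g", width = 1)
        if (nchar(s) <= 8) return(s)
      }
      stop("cannot encode ", v, " in an 8-byte EDF field", call. = FALSE)
    }, "")
  }
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- rep(-32768L, ns)
  dig_max <- rep(32767L, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad("phasenet", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad(ns, 4),
    paste0(vapply(substr(rec$channel_labels, 1, 16), pad, "", w = 16),
           collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad("uV", 8), ns), collapse = ""),
    paste0(vapply(num8(phys_min), pad, "", w = 8), collapse = ""),
    paste0(vapply(num8(phys_max), pad, "", w = 8), collapse = ""),
    paste0(vapply(dig_min, pad, "", w = 8), collapse = ""),
    paste0(vapply(dig_max, pad, "", w = 8), collapse = ""),
    paste0(rep(pad("", 80), ns), collapse = ""),
    paste0(rep(pad(fs, 8), ns), collapse = ""),
    paste0(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  # header fields are re-parsed at reduced precision; quantize against them
  pm <- as.numeric(num8(phys_min))
  px <- as.numeric(num8(phys_max))
  scale <- (px - pm) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((t(rec$data[, cols, drop = FALSE]) - rep(pm, each = fs)) /
                   rep(scale, each = fs)) + rep(dig_min, each = fs)
    # header precision can round the physical range inward by an ulp
    dig <- pmin(pmax(dig, rep(dig_min, each = fs)), rep(dig_max, each = fs))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
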