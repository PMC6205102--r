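#' Segment a recording into peri-seizure analysis periods
#'
#' Builds the canonical period layout around an annotated seizure. With
#' seizure duration `D = termination_s - onset_s`:
#'
#' * `preseizure_full`  = `[onset - D, onset)` — same length as the seizure;
#' * `seizure`          = `[onset, termination)`;
#' * `postseizure_full` = `[termination, termination + D)`;
#' * `S1 ... S4`        = the seizure split into four even stages;
#' * `preS`             = `[onset - D/4, onset)` (abuts the onset);
#' * `postS`            = `[termination, termination + D/4)` (abuts the
#'   termination).
#'
#' The full-length pre/post periods drive the state analysis; the
#' quarter-length `preS`/`postS` enter the stage-wise statistics. Both
#' conventions are always computed. All boundaries are snapped to the sample
#' grid; when the seizure length in samples is not divisible by four, the
#' stage boundaries are placed by rounding the cumulative quarter points, so
#' stage lengths differ by at most one sample and S1-S4 exactly tile the
#' seizure.
#'
#' @param rec an annotated `recording`.
#' @param truncate if `TRUE`, pre/post periods that would extend beyond the
#'   record are clipped to it (with a warning) instead of erroring.
#' @return a data frame of class `period_segmentation` with columns `period`,
#'   `start_s`, `end_s` (half-open intervals, absolute seconds).
#' @export
segment_periods <- function(rec, truncate = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$onset_s)) {
    stop("recording has no seizure annotations", call. = FALSE)
  }
  fs <- rec$fs
  t0 <- rec$t0_s
  rec_end <- t0 + duration_s(rec)
  # work on the sample grid (offsets from t0)
  a <- round((rec$onset_s - t0) * fs)
  b <- round((rec$termination_s - t0) * fs)
  n <- b - a
  if (n < 4) stop("seizure shorter than 4 samples", call. = FALSE)
  quarter <- round(n / 4)
  qpts <- a + round(seq(0, 4) * n / 4)  # cumulative rounding of stage bounds
  tot <- ncol(rec$data)
  pre_start <- a - n
  post_end <- b + n
  if ((pre_start < 0 || post_end > tot) && !truncate) {
    stop("record too short for equal-length pre/postseizure periods; ",
         "need [", t0 + pre_start / fs, ", ", t0 + post_end / fs,
         ") s inside [", t0, ", ", rec_end, ") s ",
         "(use truncate = TRUE to clip)", call. = FALSE)
  }
  if (pre_start < 0 || post_end > tot) {
    warning("pre/postseizure periods clipped to the record", call. = FALSE)
    pre_start <- max(pre_start, 0)
    post_end <- min(post_end, tot)
  }
  s <- function(i) t0 + i / fs
  out <- data.frame(
    period = c("preseizure_full", "seizure", "postseizure_full",
               "preS", "S1", "S2", "S3", "S4", "postS"),
    start_s = s(c(pre_start, a, b,
                  max(a - quarter, pre_start), qpts[1], qpts[2], qpts[3],
                  qpts[4], b)),
    end_s = s(c(a, b, post_end,
                a, qpts[2], qpts[3], qpts[4], qpts[5],
                min(b + quarter, post_end))),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("period_segmentation", "data.frame"),
            fs = fs, onset_s = rec$onset_s, termination_s = rec$termination_s)
}

period_interval <- function(seg, period) {
  i <- match(period, seg$period)
  if (is.na(i)) stop("unknown period '", period, "'", call. = FALSE)
  c(seg$start_s[i], seg$end_s[i])
}

#' Assign window centers to a period
#'
#' @param centers_s numeric vector of window-center times (absolute seconds).
#' @param seg a [segment_periods()] result.
#' @param period a period name.
#' @return logical vector: center lies in the period's half-open interval.
#' @keywords internal
centers_in_period <- function(centers_s, seg, period) {
  iv <- period_interval(seg, period)
  centers_s >= iv[1] & centers_s < iv[2]
}
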