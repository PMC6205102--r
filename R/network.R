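#' Weighted node degrees per window
#'
#' In each window's network the nodes are channels and the edge weights are
#' the pairwise mean phase coherence values; the degree of a node is the sum
#' of the weights of its incident edges (the unit diagonal is excluded). The
#' per-window degree vector is the fingerprint later clustered into network
#' states.
#'
#' @param conn a [sliding_connectivity()] result.
#' @return an object of class `degree_series`: `degrees` (windows x M matrix),
#'   `window_centers_s`, `band`, `channel_labels`.
#' @export
degree_vectors <- function(conn) {
  stopifnot(inherits(conn, "connectivity_series"))
  w <- dim(conn$matrices)[3]
  m <- dim(conn$matrices)[1]
  deg <- matrix(0, nrow = w, ncol = m)
  for (i in seq_len(w)) deg[i, ] <- colSums(conn$matrices[, , i]) - 1
  colnames(deg) <- conn$channel_labels
  structure(list(degrees = deg, window_centers_s = conn$window_centers_s,
                 band = conn$band, channel_labels = conn$channel_labels),
            class = "degree_series")
}

#' Whole-network mean phase synchronization series
#'
#' Averages the node degrees in each window into one scalar, the network's
#' mean phase synchronization; equivalently `2/(M(M-1))` times the sum of the
#' upper-triangle edge weights, rescaled by `(M-1)`. Both the raw value (in
#' `[0, M-1]`) and the normalized value (`mean_ps / (M-1)`, in `[0, 1]`,
#' comparable across grid sizes) are returned.
#'
#' @param deg a [degree_vectors()] result with `M >= 2`.
#' @return a data frame of class `mean_ps_series` with columns
#'   `window_center_s`, `mean_ps`, `mean_ps_norm`; attributes `band`, `M`.
#' @export
mean_phase_synchronization <- function(deg) {
  stopifnot(inherits(deg, "degree_series"))
  m <- ncol(deg$degrees)
  if (m < 2) stop("need at least 2 channels", call. = FALSE)
  mps <- rowMeans(deg$degrees)
  out <- data.frame(window_center_s = deg$window_centers_s,
                    mean_ps = mps, mean_ps_norm = mps / (m - 1))
  structure(out, class = c("mean_ps_series", "data.frame"),
            band = deg$band, M = m)
}

#' Per-period summary of mean phase synchronization
#'
#' Averages the per-window mean phase synchronization over the windows whose
#' centers fall in each requested period (each window counts toward exactly
#' one period since the periods are disjoint half-open intervals). Periods
#' containing no window are reported as missing (`NA`), never as zero.
#'
#' @param mps a [mean_phase_synchronization()] result.
#' @param seg a [segment_periods()] result.
#' @param periods character vector of period names to summarize; defaults to
#'   the six stage-wise periods used in the group statistics.
#' @return a data frame of class `period_summary` with columns `period`,
#'   `mean_ps`, `mean_ps_norm`, `n_windows`.
#' @export
summarize_periods <- function(mps, seg,
                              periods = c("preS", "S1", "S2", "S3", "S4",
                                          "postS")) {
  stopifnot(inherits(mps, "mean_ps_series"),
            inherits(seg, "period_segmentation"))
  rows <- lapply(periods, function(p) {
    inside <- centers_in_period(mps$window_center_s, seg, p)
    n <- sum(inside)
    data.frame(period = p,
               mean_ps = if (n > 0) mean(mps$mean_ps[inside]) else NA_real_,
               mean_ps_norm = if (n > 0) mean(mps$mean_ps_norm[inside])
                              else NA_real_,
               n_windows = n)
  })
  out <- do.call(rbind, rows)
  if (all(out$n_windows == 0)) {
    stop("no window center falls in any requested period", call. = FALSE)
  }
  if (any(out$n_windows == 0)) {
    warning("period(s) without windows reported as missing: ",
            paste(out$period[out$n_windows == 0], collapse = ", "),
            call. = FALSE)
  }
  structure(out, class = c("period_summary", "data.frame"),
            band = attr(mps, "band"))
}
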