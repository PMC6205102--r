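#' Analytic signal via the FFT half-spectrum construction
#'
#' Returns `x + i * H(x)` where `H` is the Hilbert transform, computed by
#' zeroing the negative-frequency half of the spectrum (doubling the positive
#' half), the standard discrete analytic-signal construction.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel
#'
#' Computes the analytic signal of each channel over the full contiguous
#' segment (not per window — windowing the phases afterwards avoids per-window
#' Hilbert edge artifacts) and takes its four-quadrant angle as the
#' instantaneous phase, wrapped to (-pi, pi]. An edge margin at both ends is
#' marked invalid: the discrete analytic signal is circular, so samples near
#' the boundaries mix the two ends of the record.
#'
#' @param rec a `recording` (band-limited or broadband).
#' @param edge_margin_s margin at each end flagged invalid (default 0.25 s).
#' @return an object of class `phase_series`: `phases` (channels x samples,
#'   radians), `fs`, `t0_s`, `valid` (per-sample logical), `channel_labels`,
#'   and the band name if present.
#' @export
analytic_phase <- function(rec, edge_margin_s = 0.25) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$data)
  if (n < 64) stop("need at least 64 samples for phase estimation",
                   call. = FALSE)
  v <- apply(rec$data, 1, stats::var)
  if (any(v == 0)) {
    stop("constant channel(s), phase undefined: ",
         paste(rec$channel_labels[v == 0], collapse = ", "), call. = FALSE)
  }
  phases <- t(apply(rec$data, 1, function(x) Arg(analytic_signal(x))))
  margin <- round(edge_margin_s * rec$fs)
  valid <- rep(TRUE, n)
  if (margin > 0) {
    valid[seq_len(min(margin, n))] <- FALSE
    valid[seq.int(max(n - margin + 1, 1), n)] <- FALSE
  }
  structure(
    list(phases = phases, fs = rec$fs, t0_s = rec$t0_s, valid = valid,
         channel_labels = rec$channel_labels,
         band = attr(rec, "band") %||% "broadband"),
    class = "phase_series"
  )
}

#' Mean phase coherence of two phase series
#'
#' The modulus of the circular mean of the phase differences,
#' `lambda = | (1/N) * sum_t exp(i * (phi1[t] - phi2[t])) |`,
#' a number in \[0, 1\]: 1 for perfect phase locking (constant phase
#' difference, whatever its value), 0 for phase differences spread evenly
#' around the circle. Symmetric in its arguments and invariant to adding a
#' constant to either series.
#'
#' @param phi1,phi2 numeric vectors of instantaneous phase (radians), equal
#'   length `N >= 1`, finite.
#' @return scalar `lambda` in \[0, 1\].
#' @examples
#' phi <- 2 * pi * 10 * (0:499) / 500
#' mean_phase_coherence(phi, phi)            # 1: identical series
#' mean_phase_coherence(phi, phi + 1.2)      # 1: constant lag
#' mean_phase_coherence(numeric(500), 2 * pi * 7 * (0:499) / 500) # ~0
#' @export
mean_phase_coherence <- function(phi1, phi2) {
  if (length(phi1) != length(phi2)) {
    stop("phase series lengths differ (", length(phi1), " vs ",
         length(phi2), ")", call. = FALSE)
  }
  if (length(phi1) == 0) stop("empty phase series", call. = FALSE)
  if (any(!is.finite(phi1)) || any(!is.finite(phi2))) {
    stop("non-finite phases", call. = FALSE)
  }
  Mod(mean(exp(1i * (phi1 - phi2))))
}

#' Sliding-window grid
#'
#' Window bookkeeping for the connectivity series: windows of `window_s`
#' seconds with fractional `overlap`, aligned to the first sample. The number
#' of complete windows is `floor((n_samples - N) / step) + 1`; a final partial
#' window is never padded.
#'
#' @param n_samples total samples available.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 1).
#' @param overlap overlap fraction in \[0, 1) (default 0.5).
#' @return an object of class `window_grid`: `starts` (1-based sample
#'   indices), `n_per_window` (N), `step`, `window_s`, `overlap`, `fs`.
#' @examples
#' length(window_grid(5000, 500)$starts)  # 19 windows in 10 s
#' @export
window_grid <- function(n_samples, fs, window_s = 1, overlap = 0.5) {
  assert_scalar_number(window_s, "window_s")
  assert_scalar_number(overlap, "overlap")
  if (overlap < 0 || overlap >= 1) stop("need 0 <= overlap < 1", call. = FALSE)
  n <- round(window_s * fs)
  step <- round(n * (1 - overlap))
  if (n < 1 || step < 1) stop("window or step shorter than one sample",
                              call. = FALSE)
  if (n_samples < n) {
    stop("no complete ", window_s, "-s window fits in ", n_samples,
         " samples", call. = FALSE)
  }
  starts <- seq.int(1, n_samples - n + 1, by = step)
  structure(list(starts = starts, n_per_window = n, step = step,
                 window_s = window_s, overlap = overlap, fs = fs),
            class = "window_grid")
}

#' Sliding-window mean phase coherence connectivity
#'
#' Evaluates the mean phase coherence for every channel pair in every window,
#' yielding one symmetric M x M connectivity matrix per window with unit
#' diagonal. Windows containing any sample flagged invalid by the phase edge
#' margin are dropped (their count is recorded in the `dropped_windows`
#' field). The matrix stack is exactly symmetric by construction and entries
#' are clamped to \[0, 1\] against floating-point overshoot.
#'
#' @param phase a [analytic_phase()] result with `M >= 2` channels.
#' @param grid a [window_grid()]; built from `window_s`/`overlap` when `NULL`.
#' @param window_s,overlap used when `grid` is `NULL`.
#' @return an object of class `connectivity_series`: `matrices`
#'   (M x M x W array), `window_centers_s` (absolute seconds),
#'   `n_per_window`, `band`, `fs`, `channel_labels`, `dropped_windows`.
#' @export
sliding_connectivity <- function(phase, grid = NULL, window_s = 1,
                                 overlap = 0.5) {
  stopifnot(inherits(phase, "phase_series"))
  m <- nrow(phase$phases)
  if (m < 2) stop("connectivity needs at least 2 channels", call. = FALSE)
  n_samples <- ncol(phase$phases)
  if (is.null(grid)) grid <- window_grid(n_samples, phase$fs, window_s, overlap)
  stopifnot(inherits(grid, "window_grid"))
  n <- grid$n_per_window
  keep <- vapply(grid$starts,
                 function(s) all(phase$valid[s:(s + n - 1)]), TRUE)
  starts <- grid$starts[keep]
  if (length(starts) == 0) {
    stop("every window intersects the invalid edge margin", call. = FALSE)
  }
  z <- exp(1i * phase$phases)
  mats <- array(0, dim = c(m, m, length(starts)))
  for (w in seq_along(starts)) {
    zw <- z[, starts[w]:(starts[w] + n - 1), drop = FALSE]
    lam <- Mod(zw %*% Conj(t(zw))) / n
    lam <- (lam + t(lam)) / 2          # enforce exact symmetry
    lam[lam > 1] <- 1
    diag(lam) <- 1
    mats[, , w] <- lam
  }
  structure(
    list(matrices = mats,
         window_centers_s = phase$t0_s + (starts - 1 + n / 2) / phase$fs,
         n_per_window = n, band = phase$band, fs = phase$fs,
         channel_labels = phase$channel_labels,
         dropped_windows = sum(!keep)),
    class = "connectivity_series"
  )
}

#' @export
print.connectivity_series <- function(x, ...) {
  cat("<connectivity_series> ", dim(x$matrices)[3], " windows x ",
      dim(x$matrices)[1], " channels (band: ", x$band, ", N = ",
      x$n_per_window, " samples/window, ", x$dropped_windows,
      " edge windows dropped)\n", sep = "")
  invisible(x)
}
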