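#' Frequency band specification
#'
#' The conventional EEG/ECoG rhythms analysed by the pipeline. `broadband`
#' means no filtering at all: the raw signal after bad-channel removal.
#'
#' @param name band name; one of the standard names or any custom label.
#' @param low_hz,high_hz passband edges in Hz (ignored for `broadband`).
#' @return an object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 13)
#' @export
band_spec <- function(name, low_hz = NULL, high_hz = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (name != "broadband") {
    assert_scalar_number(low_hz, "low_hz")
    assert_scalar_number(high_hz, "high_hz")
    if (!(0 < low_hz && low_hz < high_hz)) {
      stop("need 0 < low_hz < high_hz", call. = FALSE)
    }
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  if (x$name == "broadband") cat("<band> broadband (unfiltered)\n")
  else cat("<band> ", x$name, " [", x$low_hz, ", ", x$high_hz, "] Hz\n",
           sep = "")
  invisible(x)
}

#' Standard analysis bands
#'
#' Broadband (unfiltered) plus theta 4-8, alpha 8-13, beta 13-30 and gamma
#' 30-45 Hz.
#'
#' @return a named list of [band_spec()] objects.
#' @export
standard_bands <- function() {
  list(
    broadband = band_spec("broadband"),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 13),
    beta = band_spec("beta", 13, 30),
    gamma = band_spec("gamma", 30, 45)
  )
}

#' Design the band-extraction FIR filter
#'
#' Linear-phase Hamming-window bandpass FIR via [signal::fir1()]. The
#' transition bandwidth defaults to `min(max(0.25 * low_hz, 2), low_hz)` Hz,
#' which keeps low bands (theta) selective without exploding the filter order;
#' the order follows the Hamming rule `L ~= 3.3 * fs / transition` rounded up
#' to even, so the group delay `L/2` is an integer number of samples.
#'
#' @param band a filtered [band_spec()].
#' @param fs sampling rate in Hz.
#' @param transition_hz optional transition bandwidth override, Hz.
#' @return list with `coef` (L+1 taps) and `order` (L, even).
#' @keywords internal
design_fir <- function(band, fs, transition_hz = NULL) {
  stopifnot(inherits(band, "band_spec"), band$name != "broadband")
  if (band$high_hz >= fs / 2) {
    stop("band '", band$name, "' upper edge ", band$high_hz,
         " Hz reaches Nyquist (fs = ", fs, " Hz)", call. = FALSE)
  }
  tb <- transition_hz %||% min(max(0.25 * band$low_hz, 2), band$low_hz)
  l <- ceiling(3.3 * fs / tb)
  if (l %% 2 == 1) l <- l + 1
  list(coef = signal::fir1(l, c(band$low_hz, band$high_hz) / (fs / 2),
                           type = "pass"),
       order = l)
}

#' Extract a frequency band with a zero-phase FIR filter
#'
#' Filters every channel with a linear-phase FIR bandpass and compensates the
#' integer group delay, so the output has zero phase lag relative to the input
#' (essential before phase-synchronization analysis: a lagged filter would
#' masquerade as phase differences). The default applies the filter once and
#' shifts by the group delay; `method = "filtfilt"` applies it
#' forward-backward instead. `broadband` returns the input unchanged.
#'
#' Roughly `order` samples at each end of the output are contaminated by the
#' filter edge; choose the phase edge margin (see [analytic_phase()])
#' accordingly for narrow low-frequency bands.
#'
#' @param rec a `recording`.
#' @param band a [band_spec()].
#' @param method `"onepass"` (single pass + delay compensation, default) or
#'   `"filtfilt"` (forward-backward).
#' @param transition_hz optional transition bandwidth in Hz (see
#'   [design_fir()]).
#' @return a `recording` with band-limited data and a `"band"` attribute.
#' @export
bandpass_filter <- function(rec, band, method = c("onepass", "filtfilt"),
                            transition_hz = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  method <- match.arg(method)
  if (band$name == "broadband") {
    attr(rec, "band") <- "broadband"
    return(rec)
  }
  des <- design_fir(band, rec$fs, transition_hz)
  l <- des$order
  n <- ncol(rec$data)
  if (n <= 3 * l) {
    stop("signal too short (", n, " samples) for the band '", band$name,
         "' filter (order ", l, "); need > ", 3 * l, " samples", call. = FALSE)
  }
  out <- rec
  half <- l / 2
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    if (method == "onepass") {
      y <- as.numeric(signal::filter(signal::Ma(des$coef), c(x, numeric(half))))
      out$data[i, ] <- y[(half + 1):(half + n)]
    } else {
      out$data[i, ] <- as.numeric(signal::filtfilt(signal::Ma(des$coef), x))
    }
  }
  attr(out, "band") <- band$name
  attr(out, "filter_order") <- l
  out
}
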