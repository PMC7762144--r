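#' Define a frequency band
#'
#' A band is an open interval \eqn{(a, b)} with \eqn{0 < a < b < \pi} on the
#' angular frequency scale. Bands may be specified in angular frequency,
#' on the normalized scale \eqn{(0, 0.5)} (cycles/sample, where
#' \eqn{\nu = \omega/2\pi}), or in Hz given a sampling rate
#' (\eqn{\omega = 2\pi f / f_s}).
#'
#' @param a,b band endpoints (in the units given by \code{unit}).
#' @param label optional band name, e.g. \code{"Beta"}.
#' @param unit one of \code{"angular"}, \code{"normalized"}, \code{"hz"}.
#' @param sampling_rate_hz sampling rate, required when \code{unit = "hz"}.
#' @return Object of class \code{"frequency_band"} with angular endpoints
#'   \code{a}, \code{b} and the \code{label}.
#' @examples
#' frequency_band(12, 30, "Beta", unit = "hz", sampling_rate_hz = 1000)
#' frequency_band(0.10, 0.14, unit = "normalized")
#' @export
frequency_band <- function(a, b, label = NULL,
                           unit = c("angular", "normalized", "hz"),
                           sampling_rate_hz = NULL) {
  unit <- match.arg(unit)
  conv <- switch(unit,
    angular = 1,
    normalized = 2 * pi,
    hz = {
      if (is.null(sampling_rate_hz)) {
        stop("sampling_rate_hz is required for Hz band definitions")
      }
      2 * pi / sampling_rate_hz
    }
  )
  a_ang <- a * conv
  b_ang <- b * conv
  if (!(0 < a_ang && a_ang < b_ang && b_ang < pi)) {
    stop("band must satisfy 0 < a < b < pi on the angular scale; got (",
         format(a_ang), ", ", format(b_ang), ")")
  }
  structure(list(a = a_ang, b = b_ang, label = label),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("Band %s: (%.4f, %.4f) angular = (%.4f, %.4f) normalized\n",
              if (is.null(x$label)) "" else x$label,
              x$a, x$b, x$a / (2 * pi), x$b / (2 * pi)))
  invisible(x)
}

#' Convert a band to another frequency scale
#'
#' @param band a \code{\link{frequency_band}}.
#' @param unit target unit, \code{"angular"}, \code{"normalized"} or
#'   \code{"hz"}.
#' @param sampling_rate_hz sampling rate, required for \code{"hz"}.
#' @return Numeric vector \code{c(a, b)} on the requested scale.
#' @export
band_endpoints <- function(band, unit = c("angular", "normalized", "hz"),
                           sampling_rate_hz = NULL) {
  stopifnot(inherits(band, "frequency_band"))
  unit <- match.arg(unit)
  switch(unit,
    angular = c(band$a, band$b),
    normalized = c(band$a, band$b) / (2 * pi),
    hz = {
      if (is.null(sampling_rate_hz)) stop("sampling_rate_hz required")
      c(band$a, band$b) * sampling_rate_hz / (2 * pi)
    }
  )
}

#' Load named band presets from a YAML file
#'
#' The file maps labels to Hz intervals, e.g. \code{Beta: [12, 30]}. With no
#' \code{path}, the bundled canonical EEG/LFP presets are used
#' (Theta 4-8, Alpha 8-12, Beta 12-30, Gamma 30-50 Hz).
#'
#' @param sampling_rate_hz sampling rate used to convert Hz to angular
#'   frequency.
#' @param path optional YAML file path.
#' @return Named list of \code{\link{frequency_band}} objects.
#' @export
band_presets <- function(sampling_rate_hz, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "eeg_bands.yaml", package = "specratio")
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    iv <- as.numeric(raw[[nm]])
    frequency_band(iv[1L], iv[2L], label = nm, unit = "hz",
                   sampling_rate_hz = sampling_rate_hz)
  })
  names(out) <- names(raw)
  out
}
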