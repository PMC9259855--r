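#' Define a frequency band
#'
#' @param name Band label, e.g. "alpha".
#' @param f_lo Lower band edge in Hz; must satisfy 0 < f_lo < f_hi.
#' @param f_hi Upper band edge in Hz.
#' @return An object of class \code{band_definition}.
#' @examples
#' band_definition("alpha", 8, 12)
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!is.character(name) || length(name) != 1L)
    stop("band_definition: 'name' must be a single string")
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || length(f_lo) != 1L ||
      length(f_hi) != 1L || !is.finite(f_lo) || !is.finite(f_hi))
    stop("band_definition: band edges must be single finite numbers")
  if (!(f_lo > 0 && f_lo < f_hi))
    stop("band_definition: need 0 < f_lo < f_hi (got ", f_lo, ", ", f_hi, ")")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Canonical electrophysiological frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 13-30 and gamma 31-80 Hz.
#'
#' @return Named list of \code{\link{band_definition}} objects.
#' @export
default_bands <- function() {
  list(delta = band_definition("delta", 1, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 12),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 31, 80))
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.list(band) && all(c("name", "f_lo", "f_hi") %in% names(band)))
    return(band_definition(band$name, band$f_lo, band$f_hi))
  stop("expected a band_definition (see band_definition())")
}
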