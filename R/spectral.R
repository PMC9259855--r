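# Spectral processing: sign-aligned label averaging, zero-phase FIR
# band-pass + notch + decimation, and analytic-signal envelopes.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Windowed-sinc (Hamming) linear-phase low-pass prototype, unit DC gain.
# fc is in cycles/sample (0 < fc < 0.5); n_taps must be odd.
fir_lowpass_taps <- function(fc, n_taps) {
  m <- seq_len(n_taps) - 1 - (n_taps - 1) / 2
  h <- 2 * fc * sinc(2 * fc * m)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_taps) - 1) / (n_taps - 1))
  h <- h * w
  h / sum(h)
}

fir_bandpass_taps <- function(f_lo, f_hi, fs, n_taps) {
  fir_lowpass_taps(f_hi / fs, n_taps) - fir_lowpass_taps(f_lo / fs, n_taps)
}

fir_bandstop_taps <- function(f_lo, f_hi, fs, n_taps) {
  delta <- numeric(n_taps)
  delta[(n_taps + 1) / 2] <- 1
  delta - fir_bandpass_taps(f_lo, f_hi, fs, n_taps)
}

fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  N <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(N - length(x)))) *
              fft(c(h, numeric(N - length(h)))), inverse = TRUE)) / N
  y[seq_len(n)]
}

# Zero-phase filtering: symmetric odd-length FIR applied centred, with
# reflection padding so edges see plausible data.  Still marks a half-width
# of samples at each end as edge-affected (see bandpass_notch_downsample).
filter_zerophase <- function(x, h) {
  n_taps <- length(h)
  half <- (n_taps - 1L) / 2L
  n <- length(x)
  if (half >= n) stop("filter longer than the signal")
  left <- x[(half + 1L):2L]
  right <- x[(n - 1L):(n - half)]
  y <- fft_convolve(c(left, x, right), h)
  y[(2L * half + 1L):(2L * half + n)]
}

# Default tap count: transition width ~ half the lower band edge (capped to
# [0.5, 2] Hz), Hamming rule n ~ 3.3 fs / transition; capped so the filter
# fits the signal.
default_n_taps <- function(f_lo, fs, n_samples) {
  tw <- max(0.5, min(f_lo / 2, 2))
  n_taps <- ceiling(3.3 * fs / tw)
  cap <- n_samples - 1L
  if (cap %% 2L == 0L) cap <- cap - 1L
  n_taps <- min(n_taps, cap)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  max(n_taps, 5L)
}

#' Align vertex time-series signs within a label and average
#'
#' Within a cortical label the per-vertex source orientations are ambiguous
#' up to sign, so vertex series cannot be averaged directly.  The dominant
#' temporal component is taken from the SVD of the data; every vertex series
#' whose dot product with the first left singular vector is negative is
#' inverted before averaging.  The global sign of the result is fixed
#' (deterministically) so the mean series correlates positively with the
#' dominant component; downstream envelopes are sign-invariant anyway.
#'
#' @param vertex_matrix Numeric matrix, vertices x samples (>= 2 vertices).
#' @return List with \code{aligned} (matrix, same shape), \code{mean}
#'   (numeric, the label time series) and \code{flipped} (logical per vertex).
#' @export
align_label_signs <- function(vertex_matrix) {
  X <- as.matrix(vertex_matrix)
  if (nrow(X) < 2L) stop("align_label_signs: need at least 2 vertices")
  if (!all(is.finite(X))) stop("align_label_signs: non-finite values")
  if (all(X == 0)) stop("align_label_signs: all-zero matrix")
  u1 <- svd(t(X), nu = 1L, nv = 0L)$u[, 1L]
  dots <- as.vector(X %*% u1)
  flipped <- dots < 0
  aligned <- X * ifelse(flipped, -1, 1)
  m <- colMeans(aligned)
  if (sum(m * u1) < 0) {          # fix the free global sign
    aligned <- -aligned
    m <- -m
    flipped <- !flipped
  }
  list(aligned = aligned, mean = m, flipped = flipped)
}

#' Band-pass filter, notch, and downsample a series
#'
#' Zero-phase FIR band-pass to the requested band; a band-stop notch
#' (default 60 Hz, 1 Hz wide) is applied only when the line frequency falls
#' inside the band.  The series is then decimated by the largest integer
#' factor that keeps the output rate strictly above three times the upper
#' band edge, comfortably clear of Nyquist.
#'
#' @param series Numeric vector or nodes x samples matrix.
#' @param fs_in Input sampling rate (Hz); must exceed 2 * f_hi.
#' @param band A \code{\link{band_definition}}.
#' @param notch_hz,notch_bw Line frequency and notch bandwidth in Hz.
#' @param n_taps Optional odd FIR length; default from the band's lower edge.
#' @return List: \code{series} (same shape, filtered and decimated),
#'   \code{fs_out}, \code{sample_mask} (FALSE within one filter half-width of
#'   the edges), \code{band}.
#' @export
bandpass_notch_downsample <- function(series, fs_in, band, notch_hz = 60,
                                      notch_bw = 1, n_taps = NULL) {
  band <- as_band(band)
  vec_in <- is.null(dim(series))
  X <- if (vec_in) matrix(series, nrow = 1L) else as.matrix(series)
  n <- ncol(X)
  if (fs_in <= 2 * band$f_hi)
    stop("bandpass_notch_downsample: fs_in = ", fs_in,
         " too low for band upper edge ", band$f_hi, " Hz")
  if (is.null(n_taps)) n_taps <- default_n_taps(band$f_lo, fs_in, n)
  if (n_taps %% 2L == 0L) stop("n_taps must be odd")
  h <- fir_bandpass_taps(band$f_lo, band$f_hi, fs_in, n_taps)
  half <- (n_taps - 1L) / 2L
  Y <- t(apply(X, 1L, filter_zerophase, h = h))
  if (notch_hz > band$f_lo && notch_hz < band$f_hi) {
    # the notch transition must fit inside its own (narrow) stop band
    n_taps_n <- ceiling(3.3 * fs_in / (notch_bw / 2))
    cap <- n - 1L
    if (cap %% 2L == 0L) cap <- cap - 1L
    n_taps_n <- min(n_taps_n, cap)
    if (n_taps_n %% 2L == 0L) n_taps_n <- n_taps_n + 1L
    hn <- fir_bandstop_taps(notch_hz - notch_bw / 2, notch_hz + notch_bw / 2,
                            fs_in, n_taps_n)
    Y <- t(apply(Y, 1L, filter_zerophase, h = hn))
    half <- max(half, (n_taps_n - 1L) / 2L)
  }
  mask <- rep(TRUE, n)
  edge <- min(half, n)
  mask[seq_len(edge)] <- FALSE
  mask[seq.int(n - edge + 1L, n)] <- FALSE
  # largest integer decimation with fs_out > 3 * f_hi
  q <- floor(fs_in / (3 * band$f_hi))
  if (q >= fs_in / (3 * band$f_hi)) q <- q - 1L
  if (q < 1L)
    stop("bandpass_notch_downsample: cannot satisfy fs_out > 3 * f_hi")
  keep <- seq.int(1L, n, by = q)
  Y <- Y[, keep, drop = FALSE]
  mask <- mask[keep]
  list(series = if (vec_in) drop(Y) else Y,
       fs_out = fs_in / q, sample_mask = mask, band = band)
}

# Discrete analytic signal via the frequency-domain Hilbert weighting.
hilbert_analytic <- function(x) {
  n <- length(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2 + 1L] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1L] <- 1; w[2:((n + 1L) / 2L)] <- 2
  }
  a <- fft(fft(x) * w, inverse = TRUE) / n
  complex(real = x, imaginary = Im(a))  # real part equals input exactly
}

#' Analytic signal of band-limited parcel series
#'
#' Combines each series x(t) with its Hilbert transform into the complex
#' series x(t) + i H[x(t)], whose modulus is the instantaneous amplitude
#' envelope and whose phase advances at the band's dominant frequency.
#'
#' @param series Numeric vector or nodes x samples matrix (band-limited).
#' @param fs Sampling rate in Hz.
#' @param band Optional \code{\link{band_definition}} carried as metadata.
#' @param sample_mask Optional logical per-sample validity vector.
#' @return An \code{analytic_series} object: complex \code{data} matrix,
#'   \code{fs}, \code{band}, \code{sample_mask}.
#' @export
analytic_signal <- function(series, fs, band = NULL, sample_mask = NULL) {
  X <- if (is.null(dim(series))) matrix(series, nrow = 1L) else
    as.matrix(series)
  if (!all(is.finite(X))) stop("analytic_signal: non-finite values")
  A <- t(apply(X, 1L, hilbert_analytic))
  if (nrow(X) == 1L) A <- matrix(A, nrow = 1L)
  if (is.null(sample_mask)) sample_mask <- rep(TRUE, ncol(X))
  if (length(sample_mask) != ncol(X))
    stop("analytic_signal: sample_mask length mismatch")
  structure(list(data = A, fs = fs,
                 band = if (is.null(band)) NULL else as_band(band),
                 sample_mask = sample_mask),
            class = "analytic_series")
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf("<analytic_series> %d node(s) x %d samples @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$band)) "" else paste0(" [", x$band$name, "]")))
  invisible(x)
}

#' Amplitude envelope of an analytic series
#'
#' @param x An \code{analytic_series} or complex matrix/vector.
#' @return Numeric matrix (or vector) of envelopes, Mod(x).
#' @export
envelope <- function(x) {
  if (inherits(x, "analytic_series")) Mod(x$data) else Mod(x)
}
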