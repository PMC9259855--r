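# Orthogonalized envelope correlation: the zero-lag component of one
# analytic signal is removed with respect to the other before the envelope
# Pearson correlation, which defeats the spurious instantaneous correlations
# produced by field spread / signal leakage.

#' Orthogonalize one analytic signal with respect to another
#'
#' Returns the envelope of Y after removal of its zero-lag (real-scaled)
#' component along X: elementwise |Im(Y conj(X) / |X|)|.  A real multiple of
#' X orthogonalizes to exactly zero; the quadrature signal iX orthogonalizes
#' to the full envelope |X|.
#'
#' @param x,y Equal-length complex analytic series.
#' @return Numeric envelope of the orthogonalized signal; samples where
#'   |x| is numerically zero (< 1e-12 of the peak envelope) are NA.
#' @export
orthogonalize <- function(x, y) {
  if (length(x) != length(y)) stop("orthogonalize: length mismatch")
  ex <- Mod(x)
  mx <- max(ex)
  if (mx == 0) stop("orthogonalize: reference signal is identically zero")
  out <- abs(Im(y * Conj(x))) / ex
  # floor float-noise residuals (e.g. y = c x) to an exact zero
  my <- max(Mod(y))
  if (my > 0) out[out < 1e-10 * my] <- 0
  out[ex < 1e-12 * mx] <- NA_real_
  out
}

#' Symmetrized orthogonalized envelope correlation of two analytic signals
#'
#' Pearson correlation between the envelope of one signal and the envelope
#' of the other signal orthogonalized with respect to it, computed in both
#' directions and averaged.  Insensitive to instantaneous (zero-lag) linear
#' mixing and to positive rescaling of either input.
#'
#' @param x,y Equal-length complex analytic series (>= 30 valid samples).
#' @return Correlation in [-1, 1], or NA if either orthogonalized envelope
#'   has zero variance (e.g. y is a real multiple of x, including y = x).
#' @export
pairwise_envelope_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("pairwise_envelope_correlation: length mismatch")
  oyx <- orthogonalize(x, y)
  oxy <- orthogonalize(y, x)
  keep <- !is.na(oyx) & !is.na(oxy)
  if (sum(keep) < 30L) return(NA_real_)
  ex <- Mod(x)[keep]; ey <- Mod(y)[keep]
  oyx <- oyx[keep]; oxy <- oxy[keep]
  if (sd(oyx) == 0 || sd(oxy) == 0 || sd(ex) == 0 || sd(ey) == 0)
    return(NA_real_)
  (cor(ex, oyx) + cor(ey, oxy)) / 2
}

#' Naive (non-orthogonalized) envelope correlation matrix
#'
#' Pearson correlations of the raw envelopes over the whole series; inflated
#' by zero-lag leakage and used as the comparison estimator.
#'
#' @param x An \code{analytic_series} or complex nodes x samples matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
naive_envelope_correlation <- function(x) {
  E <- envelope(x)
  cor(t(E))
}

# windowed Pearson correlations via cumulative sums; a, b numeric vectors,
# starts window start indices, len window length
windowed_cor <- function(a, b, starts, len) {
  csa <- c(0, cumsum(a));  csb <- c(0, cumsum(b))
  csa2 <- c(0, cumsum(a * a)); csb2 <- c(0, cumsum(b * b))
  csab <- c(0, cumsum(a * b))
  e <- starts + len
  Sa <- csa[e] - csa[starts];   Sb <- csb[e] - csb[starts]
  Sa2 <- csa2[e] - csa2[starts]; Sb2 <- csb2[e] - csb2[starts]
  Sab <- csab[e] - csab[starts]
  num <- Sab - Sa * Sb / len
  va <- Sa2 - Sa^2 / len
  vb <- Sb2 - Sb^2 / len
  den <- sqrt(pmax(va, 0) * pmax(vb, 0))
  r <- ifelse(den > 0 & is.finite(den), num / den, NA_real_)
  pmin(1, pmax(-1, r))
}

#' Sliding-window orthogonalized envelope connectivity
#'
#' Computes the symmetrized orthogonalized envelope correlation for node
#' pairs over an overlapping sliding window (default 30 s with a stride of
#' 1/8 of the window, long enough for several envelope cycles per window).
#' Windows are tiled from t = 0; a trailing partial window is discarded.
#' Any window that overlaps a masked (rejected) sample is excluded for all
#' pairs, mirroring epoch-level discontinuity exclusion.
#'
#' @param x An \code{analytic_series} (nodes x samples) or complex matrix.
#' @param fs Sampling rate; taken from \code{x} if it is an analytic_series.
#' @param window_s Window length in seconds (default 30).
#' @param stride_fraction Stride as a fraction of the window (default 1/8).
#' @param sample_mask Logical per-sample validity (TRUE = valid).
#' @param pairs Optional 2-column matrix of node index pairs to restrict the
#'   computation to; default all i < j pairs.
#' @return A \code{connectivity_array}: \code{data} (N x N x windows, NA for
#'   invalid windows/pairs), \code{valid} (logical per window),
#'   \code{starts}, \code{window_s}, \code{stride_fraction}, \code{fs},
#'   \code{band}.
#' @export
sliding_window_connectivity <- function(x, fs = NULL, window_s = 30,
                                        stride_fraction = 1 / 8,
                                        sample_mask = NULL, pairs = NULL) {
  band <- NULL
  if (inherits(x, "analytic_series")) {
    if (is.null(fs)) fs <- x$fs
    if (is.null(sample_mask)) sample_mask <- x$sample_mask
    band <- x$band
    x <- x$data
  }
  if (is.null(fs)) stop("sliding_window_connectivity: fs required")
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  n_nodes <- nrow(x)
  n <- ncol(x)
  w_len <- round(window_s * fs)
  if (n < w_len)
    stop("sliding_window_connectivity: series shorter than one window")
  stride <- window_s * stride_fraction * fs
  n_win <- floor((n - w_len) / stride + 1e-9) + 1L
  starts <- floor((seq_len(n_win) - 1) * stride) + 1L
  if (is.null(sample_mask)) sample_mask <- rep(TRUE, n)
  bad <- c(0, cumsum(!sample_mask))
  valid <- (bad[starts + w_len] - bad[starts]) == 0
  if (!any(valid))
    stop("sliding_window_connectivity: no valid windows")
  vstarts <- starts[valid]
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  re <- Re(x); im <- Im(x)
  E <- sqrt(re^2 + im^2)
  arr <- array(NA_real_, dim = c(n_nodes, n_nodes, n_win))
  eps <- 1e-12 * max(E)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    if (i == j) next
    cross <- re[i, ] * im[j, ] - im[i, ] * re[j, ]   # Im(x_j conj(x_i))
    o_ji <- abs(cross) / pmax(E[i, ], eps)
    o_ij <- abs(cross) / pmax(E[j, ], eps)
    c1 <- windowed_cor(E[i, ], o_ji, vstarts, w_len)
    c2 <- windowed_cor(E[j, ], o_ij, vstarts, w_len)
    arr[i, j, valid] <- arr[j, i, valid] <- (c1 + c2) / 2
  }
  structure(list(data = arr, valid = valid, starts = starts,
                 window_s = window_s, stride_fraction = stride_fraction,
                 fs = fs, band = band),
            class = "connectivity_array")
}

#' @export
print.connectivity_array <- function(x, ...) {
  cat(sprintf("<connectivity_array> %d nodes, %d window(s) (%d valid), %g s / stride %g s%s\n",
              dim(x$data)[1L], dim(x$data)[3L], sum(x$valid), x$window_s,
              x$window_s * x$stride_fraction,
              if (is.null(x$band)) "" else paste0(" [", x$band$name, "]")))
  invisible(x)
}

#' Collapse a connectivity array over time by the median
#'
#' Elementwise median of each pair's orthogonalized correlation across valid
#' windows, increasing signal-to-noise.  Pairs with no defined window value
#' (notably the diagonal) are stored as 0 by convention.
#'
#' @param arr A \code{connectivity_array}.
#' @return A \code{connectivity_matrix}: symmetric N x N numeric matrix with
#'   zero diagonal and attributes \code{band} and \code{n_windows}.
#' @export
collapse_median <- function(arr) {
  stopifnot(inherits(arr, "connectivity_array"))
  if (!any(arr$valid)) stop("collapse_median: no valid windows")
  M <- apply(arr$data, c(1L, 2L), median, na.rm = TRUE)
  M[is.na(M)] <- 0
  diag(M) <- 0
  connectivity_matrix(M, band = arr$band, n_windows = sum(arr$valid))
}

connectivity_matrix <- function(M, band = NULL, n_windows = NA_integer_) {
  M <- as.matrix(M)
  structure(M, class = c("connectivity_matrix", class(M)),
            band = band, n_windows = n_windows)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<connectivity_matrix> %d x %d%s, median over %s window(s)\n",
              nrow(x), ncol(x),
              if (is.null(b)) "" else paste0(" [", b$name, "]"),
              attr(x, "n_windows")))
  invisible(x)
}
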