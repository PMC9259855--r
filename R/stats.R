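# Age-trajectory statistics: Spearman correlation, nested bootstrap,
# maximum-statistics permutation correction across the whole comparison
# space, bootstrap-CI robust confirmation, and LOESS with cross-validated
# bandwidth.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties get averaged ranks).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return rho in [-1, 1], or NA if either variable has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_rho: length mismatch")
  if (length(x) < 3L) stop("spearman_rho: need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Nested bootstrap of the (age, metric) joint distribution
#'
#' Approximates the joint distribution of age with the age-dependent mean
#' network metric: each realization draws an age anchor from the observed
#' subjects, then resamples with replacement among the m nearest-age
#' subjects, yielding one (mean age, mean metric) pair.  The cloud of 1,024
#' realizations spans the age axis and visualizes the uncertainty of the
#' metric at every age.  A plain pooled bootstrap (resampling all subjects)
#' is available via \code{scheme = "pooled"}.
#'
#' @param ages,metrics Paired numeric vectors (n >= 5).
#' @param n_boot Number of realizations; default 1024.
#' @param seed Integer seed.
#' @param scheme "nested" (local age neighbourhoods) or "pooled".
#' @param m Neighbourhood size for the nested scheme; default
#'   max(5, round(n/10)).
#' @return A \code{bootstrap_cloud}: data.frame(x_mean, y_mean) plus the
#'   parameters used.
#' @export
nested_bootstrap <- function(ages, metrics, n_boot = 1024L, seed = 1L,
                             scheme = c("nested", "pooled"), m = NULL) {
  scheme <- match.arg(scheme)
  n <- length(ages)
  if (length(metrics) != n) stop("nested_bootstrap: length mismatch")
  if (n < 5L) stop("nested_bootstrap: need n >= 5")
  if (is.null(m)) m <- max(5L, round(n / 10))
  m <- min(m, n)
  set.seed(seed)
  x_mean <- numeric(n_boot)
  y_mean <- numeric(n_boot)
  ord <- order(ages)
  for (b in seq_len(n_boot)) {
    if (scheme == "nested") {
      anchor <- sample.int(n, 1L)
      nb <- order(abs(ages - ages[anchor]), seq_len(n))[seq_len(m)]
      draw <- nb[sample.int(m, m, replace = TRUE)]
    } else {
      draw <- sample.int(n, n, replace = TRUE)
    }
    x_mean[b] <- mean(ages[draw])
    y_mean[b] <- mean(metrics[draw])
  }
  structure(list(cloud = data.frame(x_mean = x_mean, y_mean = y_mean),
                 n_boot = n_boot, scheme = scheme, m = m, seed = seed),
            class = "bootstrap_cloud")
}

#' @export
print.bootstrap_cloud <- function(x, ...) {
  cat(sprintf("<bootstrap_cloud> %d realizations (%s scheme, m = %d)\n",
              x$n_boot, x$scheme, x$m))
  invisible(x)
}

#' @export
plot.bootstrap_cloud <- function(x, xlab = "mean age (years)",
                                 ylab = "mean metric", ...) {
  graphics::smoothScatter(x$cloud$x_mean, x$cloud$y_mean,
                          xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

std_ranks <- function(v) {
  r <- rank(v)
  s <- sd(r)
  if (s == 0) return(rep(NA_real_, length(v)))
  (r - mean(r)) / s
}

#' Maximum-statistics permutation correction over a comparison space
#'
#' Correlates age with every cell of the comparison grid (e.g. bands x
#' costs x metrics) by Spearman correlation, then controls the family-wise
#' error rate by permutation: in each of n_p realizations the ages are
#' shuffled once, the correlation is recomputed for every cell with that
#' single shuffle (required for the validity of maximum statistics), and the
#' maximum and minimum correlation over the whole space are recorded.  For
#' an observed cell, n counts the permutation maxima at or above a positive
#' rho (minima at or below a negative rho) and the corrected two-tailed
#' p-value is p_c = 2(n+1)/(n_p+1), capped at 1.
#'
#' @param metrics Numeric matrix, subjects x cells (cell names as column
#'   names), or a vector for a single cell.
#' @param ages Numeric vector, one age per subject.
#' @param n_p Number of permutations; default 10000.  Values below 100 give
#'   a warning.
#' @param seed Integer seed.
#' @param chunk Permutations processed per block (memory control).
#' @return A \code{corrected_correlation}: data.frame \code{table} with
#'   cell, rho, p_raw and p_c; null extrema \code{null_max}/\code{null_min};
#'   \code{n_p}.
#' @export
maxstat_correction <- function(metrics, ages, n_p = 10000L, seed = 1L,
                               chunk = 500L) {
  if (is.null(dim(metrics))) metrics <- matrix(metrics, ncol = 1L)
  metrics <- as.matrix(metrics)
  n <- nrow(metrics)
  if (length(ages) != n)
    stop("maxstat_correction: ages and metric rows mismatch (",
         length(ages), " vs ", n, ")")
  if (n < 3L) stop("maxstat_correction: need at least 3 subjects")
  if (n_p < 100L) warning("maxstat_correction: n_p < 100 is unreliable")
  if (is.null(colnames(metrics)))
    colnames(metrics) <- sprintf("cell%02d", seq_len(ncol(metrics)))
  M <- apply(metrics, 2L, std_ranks)          # subjects x cells
  a <- std_ranks(ages)
  if (all(is.na(a))) stop("maxstat_correction: zero age variance")
  obs <- as.vector(crossprod(M, a)) / (n - 1)
  set.seed(seed)
  null_max <- numeric(n_p)
  null_min <- numeric(n_p)
  raw_count <- numeric(ncol(M))
  done <- 0L
  Mna <- M
  Mna[is.na(Mna)] <- 0                        # zero-variance cells -> rho 0
  while (done < n_p) {
    k <- min(chunk, n_p - done)
    P <- vapply(seq_len(k), function(z) a[sample.int(n)], numeric(n))
    R <- crossprod(Mna, P) / (n - 1)          # cells x k
    null_max[done + seq_len(k)] <- apply(R, 2L, max)
    null_min[done + seq_len(k)] <- apply(R, 2L, min)
    raw_count <- raw_count + rowSums(abs(R) >= abs(obs) - 1e-12, na.rm = TRUE)
    done <- done + k
  }
  exceed <- vapply(obs, function(r) {
    if (is.na(r)) return(NA_real_)
    if (r >= 0) sum(null_max >= r - 1e-12) else sum(null_min <= r + 1e-12)
  }, numeric(1))
  p_c <- pmin(1, 2 * (exceed + 1) / (n_p + 1))
  p_raw <- pmin(1, (raw_count + 1) / (n_p + 1))
  p_raw[is.na(obs)] <- NA_real_
  structure(list(table = data.frame(cell = colnames(metrics), rho = obs,
                                    p_raw = p_raw, p_c = p_c,
                                    stringsAsFactors = FALSE),
                 null_max = null_max, null_min = null_min,
                 n_p = as.integer(n_p), seed = seed),
            class = "corrected_correlation")
}

#' @export
print.corrected_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("<corrected_correlation> %d cell(s), n_p = %d (min attainable p_c = %.2g)\n",
              nrow(x$table), x$n_p, 2 / (x$n_p + 1)))
  tab <- x$table
  sig <- tab[!is.na(tab$p_c) & tab$p_c < 0.05, ]
  if (nrow(sig)) {
    cat("  corrected-significant cells:\n")
    print(format(sig, digits = digits), row.names = FALSE)
  } else cat("  no corrected-significant cells at 0.05\n")
  invisible(x)
}

#' Bootstrap-CI confirmation of a correlation
#'
#' A deliberately conservative follow-up for cells that reach corrected
#' significance: the Spearman correlation is recomputed over subject
#' resamples and confirmed only if the percentile bootstrap confidence
#' interval excludes zero.
#'
#' @param x,y Paired numeric vectors (n >= 10).
#' @param n_boot Bootstrap resamples; default 1000.
#' @param seed Integer seed.
#' @param conf Confidence level; default 0.95.
#' @return List: \code{rho}, \code{ci} (two-sided percentile interval),
#'   \code{confirmed} flag, \code{n_boot}.
#' @export
robust_confirmation <- function(x, y, n_boot = 1000L, seed = 1L,
                                conf = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("robust_confirmation: length mismatch")
  if (n < 10L) stop("robust_confirmation: need n >= 10")
  set.seed(seed)
  rhos <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(spearman_rho(x[idx], y[idx]))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- quantile(rhos, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(rho = spearman_rho(x, y), ci = ci,
                 confirmed = ci[1] > 0 || ci[2] < 0,
                 n_boot = n_boot, conf = conf),
            class = "robust_confirmation")
}

#' @export
print.robust_confirmation <- function(x, ...) {
  cat(sprintf("<robust_confirmation> rho = %.3f, %d%% CI [%.3f, %.3f] -> %s\n",
              x$rho, round(100 * x$conf), x$ci[1], x$ci[2],
              if (x$confirmed) "confirmed" else "not confirmed"))
  invisible(x)
}

#' LOESS fit at a fixed bandwidth
#'
#' Local linear regression with tricube weights over the nearest
#' bandwidth-fraction of points (standard LOESS, degree 1), evaluated at the
#' observed x and on a uniform grid across the observed range.
#'
#' @param x,y Paired numeric vectors (n >= 5).
#' @param bandwidth Fraction of points per local fit, in (0, 1]; the local
#'   neighbourhood must contain at least 3 points.
#' @param grid_n Number of evaluation grid points; default 100.
#' @return A \code{loess_fit}: bandwidth, \code{fitted} (at observed x),
#'   \code{grid} data.frame(x, y), and the underlying \code{loess} object.
#' @export
loess_fit <- function(x, y, bandwidth, grid_n = 100L) {
  n <- length(x)
  if (length(y) != n) stop("loess_fit: length mismatch")
  if (n < 5L) stop("loess_fit: need n >= 5")
  if (!is.numeric(bandwidth) || bandwidth <= 0 || bandwidth > 1)
    stop("loess_fit: bandwidth must lie in (0, 1]")
  if (floor(bandwidth * n) < 3L)
    stop("loess_fit: local neighbourhood has fewer than 3 points")
  fit <- loess(y ~ x, data = data.frame(x = x, y = y), span = bandwidth,
               degree = 1, family = "gaussian",
               control = loess.control(surface = "direct"))
  gx <- seq(min(x), max(x), length.out = grid_n)
  structure(list(bandwidth = bandwidth,
                 fitted = unname(predict(fit, data.frame(x = x))),
                 grid = data.frame(x = gx,
                                   y = unname(predict(fit,
                                                      data.frame(x = gx)))),
                 model = fit),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("<loess_fit> bandwidth %.2f over %d points\n",
              x$bandwidth, length(x$fitted)))
  invisible(x)
}

#' @export
predict.loess_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  predict(object$model, newdata)
}

#' @export
plot.loess_fit <- function(x, xlab = "x", ylab = "y", ...) {
  mf <- stats::model.frame(x$model)
  graphics::plot(mf$x, mf$y, pch = 16, col = "grey60",
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$grid$x, x$grid$y, lwd = 2)
  invisible(x)
}

#' Cross-validated LOESS bandwidth selection
#'
#' Tests bandwidths 0.01 to 0.99 in steps of 0.01 by k-fold (default
#' 10-fold) cross-validation and returns the candidate with the least
#' summed out-of-fold squared error.  Folds are assigned by a seeded
#' shuffle; infeasible candidates (local neighbourhood below 3 points, or a
#' numerically failed fit) are skipped and logged.  Ties go to the smallest
#' bandwidth.
#'
#' @param x,y Paired numeric vectors (n >= k_folds).
#' @param grid Candidate bandwidths; default seq(0.01, 0.99, by = 0.01)
#'   (99 candidates).
#' @param k_folds Number of folds; default 10.
#' @param seed Integer seed for the fold shuffle.
#' @return List: \code{bandwidth} (selected), \code{cv} data.frame
#'   (bandwidth, sse, feasible), \code{k_folds}, \code{seed}.
#' @export
loess_cv <- function(x, y, grid = seq(0.01, 0.99, by = 0.01), k_folds = 10L,
                     seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("loess_cv: length mismatch")
  if (n < k_folds) stop("loess_cv: need n >= k_folds")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k_folds), n))
  sse <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    bw <- grid[g]
    err <- 0
    ok <- TRUE
    for (f in seq_len(k_folds)) {
      train <- folds != f
      if (floor(bw * sum(train)) < 3L) { ok <- FALSE; break }
      pred <- tryCatch({
        fit <- suppressWarnings(
          loess(y ~ x, data = data.frame(x = x[train], y = y[train]),
                span = bw, degree = 1, family = "gaussian",
                control = loess.control(surface = "direct")))
        suppressWarnings(predict(fit, data.frame(x = x[!train])))
      }, error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) { ok <- FALSE; break }
      err <- err + sum((y[!train] - pred)^2)
    }
    if (ok) sse[g] <- err
  }
  if (all(is.na(sse))) stop("loess_cv: no feasible bandwidth candidate")
  best <- which.min(sse)                       # ties -> first = smallest bw
  list(bandwidth = grid[best],
       cv = data.frame(bandwidth = grid, sse = sse, feasible = !is.na(sse)),
       k_folds = k_folds, seed = seed)
}
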