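test_that("orthogonalization contracts: real scaling, quadrature, oracle", {
  set.seed(1)
  x <- complex(real = rnorm(500), imaginary = rnorm(500))
  y <- complex(real = rnorm(500), imaginary = rnorm(500))

  expect_equal(orthogonalize(x, 2 * x), rep(0, 500))        # zero-lag copy
  expect_equal(orthogonalize(x, 1i * x), Mod(x))            # quadrature
  expect_equal(orthogonalize(x, y), abs(Im(y * Conj(x))) / Mod(x))
  expect_error(orthogonalize(complex(real = rep(0, 5)), y[1:5]), "zero")
  expect_error(orthogonalize(x, y[-1]), "mismatch")
})

test_that("pairwise envelope correlation is symmetric, self-invalid, scale-free", {
  set.seed(2)
  x <- complex(real = rnorm(400), imaginary = rnorm(400))
  y <- complex(real = rnorm(400), imaginary = rnorm(400))

  expect_identical(pairwise_envelope_correlation(x, y),
                   pairwise_envelope_correlation(y, x))
  expect_true(is.na(pairwise_envelope_correlation(x, x)))   # zero variance
  expect_true(is.na(pairwise_envelope_correlation(x, 3 * x)))
  c1 <- pairwise_envelope_correlation(x, y)
  expect_equal(pairwise_envelope_correlation(2.5 * x, y), c1)
  expect_equal(pairwise_envelope_correlation(x, 0.3 * y), c1)
  expect_true(abs(c1) <= 1)
  expect_true(is.na(pairwise_envelope_correlation(x[1:20], y[1:20])))
})

test_that("sliding windows tile correctly and honour the mask", {
  fs <- 100
  an <- noise_analytic(2, 300, fs, seed = 3)
  arr <- sliding_window_connectivity(an, window_s = 30,
                                     stride_fraction = 1 / 8)
  expect_equal(dim(arr$data)[3], 73)           # floor((300-30)/3.75)+1
  expect_true(all(arr$valid))

  an30 <- noise_analytic(2, 30, fs, seed = 4)
  arr30 <- sliding_window_connectivity(an30)
  expect_equal(dim(arr30$data)[3], 1)          # exactly one window

  # a masked discontinuity at t = 100 s excludes every overlapping window
  mask <- rep(TRUE, 300 * fs); mask[100 * fs] <- FALSE
  arr_m <- sliding_window_connectivity(an, sample_mask = mask)
  w <- round(30 * fs)
  overlap <- arr_m$starts <= 100 * fs & (arr_m$starts + w - 1) >= 100 * fs
  expect_identical(arr_m$valid, !overlap)
  expect_true(all(is.na(arr_m$data[1, 2, overlap])))

  short <- noise_analytic(2, 10, fs, seed = 5)
  expect_error(sliding_window_connectivity(short), "shorter than one window")
  expect_error(sliding_window_connectivity(an, sample_mask = rep(FALSE, 300 * fs)),
               "no valid windows")
})

test_that("windowed correlations agree with the direct per-window computation", {
  fs <- 60
  an <- noise_analytic(3, 120, fs, seed = 6)
  arr <- sliding_window_connectivity(an, window_s = 30)
  w <- round(30 * fs)
  for (win in c(1, 5, dim(arr$data)[3])) {
    idx <- seq.int(arr$starts[win], arr$starts[win] + w - 1)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      direct <- pairwise_envelope_correlation(an$data[p[1], idx],
                                              an$data[p[2], idx])
      expect_equal(arr$data[p[1], p[2], win], direct, tolerance = 1e-10)
    }
  }
})

test_that("median collapse matches a sort-based oracle and keeps symmetry", {
  fs <- 60
  an <- noise_analytic(4, 150, fs, seed = 7)
  arr <- sliding_window_connectivity(an, window_s = 30)
  M <- collapse_median(arr)
  expect_equal(unclass(M), t(unclass(M)), ignore_attr = TRUE)
  expect_true(all(diag(M) == 0))
  expect_true(all(abs(M) <= 1))
  for (i in 1:3) for (j in (i + 1):4) {
    vals <- arr$data[i, j, arr$valid]
    vals <- vals[!is.na(vals)]
    s <- sort(vals); n <- length(s)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(M[i, j], med)
  }
  # identical windows collapse to the window value
  one <- arr$data[, , 1]
  arr2 <- arr
  for (k in seq_len(dim(arr2$data)[3])) arr2$data[, , k] <- one
  M2 <- collapse_median(arr2)
  one[is.na(one)] <- 0
  expect_equal(unclass(M2), one, ignore_attr = TRUE)
})

test_that("planted envelope coupling is detected and mixing is suppressed", {
  alpha <- band_alpha()
  C <- matrix(0, 10, 10); C[1, 2] <- C[2, 1] <- 0.8
  X <- generate_coupled_band_series(10, alpha, 300, 60,
                                    envelope_coupling = C, seed = 11)
  an <- analytic_signal(X, 60, band = alpha)
  M <- collapse_median(sliding_window_connectivity(an))
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[ut]
  coupled <- ut[, 1] == 1 & ut[, 2] == 2
  expect_gt(vals[coupled], quantile(vals[!coupled], 0.95))

  # zero-lag mixed independent pair: naive inflated, orthogonalized small
  L <- diag(10); L[1, 2] <- L[2, 1] <- 0.4; L <- L / rowSums(L)
  X2 <- generate_coupled_band_series(10, alpha, 300, 60,
                                     envelope_coupling = 0, leakage = L,
                                     seed = 12)
  an2 <- analytic_signal(X2, 60, band = alpha)
  naive <- naive_envelope_correlation(an2)[1, 2]
  orth <- collapse_median(sliding_window_connectivity(an2))[1, 2]
  expect_gt(naive, abs(orth))
  expect_lt(abs(orth), 0.1)
})
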