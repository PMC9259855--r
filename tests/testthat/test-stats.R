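test_that("spearman correlation matches the average-rank oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)       # monotone up
  expect_equal(spearman_rho(1:10, -(1:10)), -1)       # monotone down
  # hand-enumerated ranks: x = (1,2,2,3) -> (1, 2.5, 2.5, 4)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)))
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("nested bootstrap yields the stated cloud", {
  set.seed(1)
  ages <- runif(40, 7, 29)
  y <- 0.1 * ages + rnorm(40)
  bc <- nested_bootstrap(ages, y, n_boot = 1024, seed = 2)
  expect_equal(nrow(bc$cloud), 1024)
  bc2 <- nested_bootstrap(ages, y, n_boot = 1024, seed = 2)
  expect_identical(bc$cloud, bc2$cloud)              # seeded determinism

  # degenerate cohort: every realization identical
  deg <- nested_bootstrap(rep(10, 8), rep(2, 8), n_boot = 50, seed = 3)
  expect_equal(unique(deg$cloud$x_mean), 10)
  expect_equal(unique(deg$cloud$y_mean), 2)

  # cloud mean age approaches the sample mean age
  expect_lt(abs(mean(bc$cloud$x_mean) - mean(ages)),
            3 * sd(ages) / sqrt(1024) * 5)
  # the cloud spans the age axis (local neighbourhoods)
  expect_gt(diff(range(bc$cloud$x_mean)), diff(range(ages)) * 0.5)
})

test_that("maxstat correction reproduces the printed p-value formula", {
  set.seed(4)
  n <- 30
  ages <- runif(n, 7, 29)
  M <- cbind(a = 0.2 * ages + rnorm(n, sd = 0.01),    # near-perfect signal
             b = rnorm(n))
  res <- maxstat_correction(M, ages, n_p = 10000, seed = 5)
  # a monotone cell beats every permutation maximum: n = 0 exceedances
  expect_equal(res$table$p_c[1], 2 / 10001)
  expect_equal(min(res$table$p_c), 2 / (res$n_p + 1)) # attainable minimum
  expect_lte(max(res$table$p_c), 1)                   # cap at 1

  # a hopeless cell is capped at 1, not above
  anti <- matrix(rep(mean(ages), n) + rnorm(n, sd = 1e-8), ncol = 1)
  res2 <- maxstat_correction(cbind(x = rnorm(n)), ages, n_p = 200, seed = 6)
  expect_lte(res2$table$p_c, 1)

  expect_warning(maxstat_correction(M, ages, n_p = 50, seed = 1),
                 "unreliable")
  expect_error(maxstat_correction(M, ages[-1], n_p = 100), "mismatch")
})

test_that("p_c is monotone non-increasing in |rho| within a fixed null", {
  set.seed(7)
  n <- 40
  ages <- runif(n, 7, 29)
  slopes <- c(0.002, 0.01, 0.03, 0.1)
  M <- vapply(slopes, function(s) s * ages + rnorm(n, sd = 0.3), numeric(n))
  colnames(M) <- paste0("s", slopes)
  res <- maxstat_correction(M, ages, n_p = 2000, seed = 8)
  ord <- order(abs(res$table$rho))
  expect_true(all(diff(res$table$p_c[ord]) <= 1e-12))
})

test_that("permutations reuse one age shuffle across the whole space", {
  # two perfectly collinear cells must receive identical null treatment
  set.seed(9)
  n <- 25
  ages <- runif(n, 7, 29)
  y <- rnorm(n)
  M <- cbind(a = y, b = y)
  res <- maxstat_correction(M, ages, n_p = 500, seed = 10)
  expect_equal(res$table$rho[1], res$table$rho[2])
  expect_equal(res$table$p_c[1], res$table$p_c[2])
})

test_that("robust confirmation flags monotone data and reproduces", {
  set.seed(11)
  x <- runif(30, 7, 29)
  up <- robust_confirmation(x, x + rnorm(30, sd = 0.1), seed = 1)
  expect_true(up$confirmed)
  expect_gt(up$ci[1], 0)

  expect_error(robust_confirmation(x[1:5], x[1:5]), "n >= 10")
  ynull <- rnorm(30)
  rr <- robust_confirmation(x, ynull, n_boot = 500, seed = 3)
  expect_identical(rr$ci,
                   robust_confirmation(x, ynull, n_boot = 500, seed = 3)$ci)
})

test_that("false-confirmation rate of the bootstrap CI is near nominal", {
  set.seed(12)
  hits <- vapply(1:60, function(i) {
    x <- rnorm(60); y <- rnorm(60)
    robust_confirmation(x, y, n_boot = 300, seed = i)$confirmed
  }, logical(1))
  expect_lt(mean(hits), 0.18)                   # ~5% nominal, MC slack
})

test_that("LOESS reproduces lines exactly and tracks a smooth truth", {
  set.seed(13)
  x <- sort(runif(60, 0, 10))
  y_lin <- 2 + 3 * x
  f <- loess_fit(x, y_lin, bandwidth = 0.5)
  expect_equal(f$fitted, y_lin, tolerance = 1e-8)  # local-linear exactness

  # bandwidth 1 on noisy linear data approaches the least-squares line
  y_noisy <- y_lin + rnorm(60, sd = 0.5)
  f1 <- loess_fit(x, y_noisy, bandwidth = 1)
  ls <- lm(y_noisy ~ x)
  expect_lt(max(abs(f1$fitted - fitted(ls))), 0.35)

  expect_error(loess_fit(x, y_lin, bandwidth = 0.02), "fewer than 3")
  expect_error(loess_fit(x, y_lin, bandwidth = 1.5), "bandwidth")

  # noisy sine recovered below the noise floor at the CV-chosen bandwidth
  set.seed(14)
  xs <- sort(runif(200, 0, 2 * pi))
  truth <- sin(xs)
  ys <- truth + rnorm(200, sd = 0.2)
  cv <- loess_cv(xs, ys, seed = 15)
  fs_ <- loess_fit(xs, ys, cv$bandwidth)
  expect_lt(sqrt(mean((fs_$fitted - truth)^2)), 0.2)
})

test_that("bandwidth cross-validation scans 99 candidates deterministically", {
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_length(grid, 99)
  set.seed(16)
  x <- sort(runif(50, 0, 10))
  y <- 1 + 0.5 * x + rnorm(50, sd = 0.01)
  cv <- loess_cv(x, y, seed = 17)
  expect_equal(nrow(cv$cv), 99)
  expect_true(any(!cv$cv$feasible))             # tiny bandwidths skipped
  expect_equal(cv$bandwidth, cv$cv$bandwidth[which.min(cv$cv$sse)])
  cv2 <- loess_cv(x, y, seed = 17)
  expect_identical(cv$cv, cv2$cv)

  # wiggly truth selects a smaller bandwidth than smooth truth (median of reps)
  set.seed(18)
  bw_wiggly <- bw_smooth <- numeric(8)
  for (i in 1:8) {
    xs <- sort(runif(80, 0, 2 * pi))
    bw_wiggly[i] <- loess_cv(xs, sin(4 * xs) + rnorm(80, sd = 0.1),
                             seed = 20 + i)$bandwidth
    bw_smooth[i] <- loess_cv(xs, sin(xs / 2) + rnorm(80, sd = 0.1),
                             seed = 20 + i)$bandwidth
  }
  expect_lt(median(bw_wiggly), median(bw_smooth))
})
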