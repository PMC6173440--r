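test_that("long-timescale FC is Fisher-z Pearson correlation", {
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  set.seed(10)
  x <- matrix(stats::rnorm(3 * 50), 3, 50)
  fc <- long_timescale_fc(x)
  # hand-rolled covariance-based oracle
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- x[i, ]; xj <- x[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(fc$values[i, j], atanh(r), tolerance = 1e-12)
  }
  expect_true(all(is.na(diag(fc$values))))

  # near-duplicate node: large positive z, sign flips under negation
  y <- rbind(x, x[1, ] + 1e-6 * stats::rnorm(50))
  fcy <- long_timescale_fc(y)
  expect_gt(fcy$values[1, 4], 5)
  y2 <- y; y2[4, ] <- -y2[4, ]
  expect_lt(long_timescale_fc(y2)$values[1, 4], -5)

  xc <- x; xc[2, ] <- 7
  expect_error(long_timescale_fc(xc), "2")
})

test_that("tapered windows reproduce the printed count and limiting shapes", {
  # 1200 volumes at TR 0.72 minus the first ceil(10 / 0.72) = 14 volumes
  usable <- 1200 - ceiling(10 / 0.72)
  expect_equal(usable, 1186)
  win <- build_tapered_windows(window_spec(), usable)
  expect_equal(win$count, 369)
  expect_equal(win$support, 66 + 2 * 8)
  # weights positive, sum one, symmetric about the window center
  expect_true(all(win$weights >= 0))
  expect_equal(colSums(win$weights), rep(1, 369))
  expect_equal(win$weights[, 1], rev(win$weights[, 1]))
  # consecutive centers differ by exactly 3 TRs
  expect_equal(unique(diff(win$centers_trs)), 3)

  # sigma -> 0 limit: flat 66-TR rectangle inside the support
  w0 <- build_tapered_windows(window_spec(gauss_sigma_trs = 0), 200)
  taper <- w0$weights[, 1]
  expect_equal(taper[9:74], rep(1 / 66, 66))
  expect_equal(taper[c(1:8, 75:82)], rep(0, 16))

  expect_error(build_tapered_windows(window_spec(), 50), "shorter")
})

test_that("windowed correlation matches the weighted-correlation oracle", {
  set.seed(11)
  # uniform weights reduce to the plain Pearson correlation
  x <- matrix(stats::rnorm(3 * 66), 3, 66)
  spec_flat <- window_spec(rect_width_trs = 66, gauss_sigma_trs = 0,
                           kernel_halfwidth_trs = 0)
  trfc <- time_resolved_fc(x, spec_flat)
  expect_equal(dim(trfc$matrices)[3], 1)
  expect_equal(trfc$matrices[, , 1][upper.tri(diag(3))],
               atanh(stats::cor(t(x)))[upper.tri(diag(3))],
               tolerance = 1e-12)

  # single tapered window vs scalar-loop oracle
  spec1 <- window_spec(rect_width_trs = 10, gauss_sigma_trs = 2,
                       step_trs = 3, kernel_halfwidth_trs = 4)
  y <- matrix(stats::rnorm(3 * 18), 3, 18)
  t1 <- time_resolved_fc(y, spec1)
  w <- build_tapered_windows(spec1, 18)$weights[, 1]
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(t1$matrices[i, j, 1],
                 atanh(oracle_weighted_cor(y[i, 1:18], y[j, 1:18], w)),
                 tolerance = 1e-12)
})

test_that("white-noise regions give near-zero mean windowed connectivity", {
  set.seed(12)
  x <- matrix(stats::rnorm(20 * 1100), 20, 1100)
  trfc <- time_resolved_fc(x, window_spec())
  zbar <- mean(trfc$matrices, na.rm = TRUE)
  expect_lt(abs(zbar), 0.05)
})

test_that("FCD pools window-pair correlations outside one window width", {
  set.seed(13)
  # identical windows: every retained correlation is 1
  x1 <- matrix(stats::rnorm(4 * 30), 4, 30)
  xrep <- x1[, rep(1:6, 40)]                 # 6-periodic series
  spec <- window_spec(rect_width_trs = 6, gauss_sigma_trs = 0,
                      step_trs = 6, kernel_halfwidth_trs = 0)
  trfc <- time_resolved_fc(xrep, spec)
  fcd <- fcd_distribution(trfc)
  expect_true(all(abs(fcd$correlations - 1) < 1e-10))

  # retained pair count: W = 10 windows, exclusion lag 3 -> 28 pairs
  spec2 <- window_spec(rect_width_trs = 9, gauss_sigma_trs = 0,
                       step_trs = 3, kernel_halfwidth_trs = 0)
  y <- matrix(stats::rnorm(5 * 36), 5, 36)
  t2 <- time_resolved_fc(y, spec2)
  expect_equal(dim(t2$matrices)[3], 10)
  f2 <- fcd_distribution(t2)
  expect_equal(f2$exclusion_lag_windows, 3)
  expect_equal(length(f2$correlations), sum(10 - 3:9))
  # brute-force pair enumeration oracle
  up <- upper.tri(t2$matrices[, , 1])
  oracle <- c()
  for (a in 1:9) for (b in (a + 1):10)
    if (b - a >= 3)
      oracle <- c(oracle, stats::cor(t2$matrices[, , a][up],
                                     t2$matrices[, , b][up]))
  expect_equal(sort(f2$correlations), sort(oracle), tolerance = 1e-12)
  # no retained pair closer than the window width (in TRs)
  expect_true(all(outer(seq_len(10), seq_len(10), `-`)[
    abs(outer(seq_len(10), seq_len(10), `-`)) < 3] * 3 < 9))
})

test_that("KS distance equals the brute-force ECDF sup-difference", {
  set.seed(14)
  a <- stats::rnorm(40)
  b <- stats::rnorm(25, mean = 0.5)
  expect_equal(ks_distance(a, b), oracle_ks(a, b), tolerance = 1e-12)
  expect_equal(ks_distance(a, a), 0)
  expect_equal(ks_distance(a, a + 100), 1)
  expect_error(ks_distance(numeric(0), a), "empty")
})

test_that("Fisher z is monotone and clips degenerate correlations", {
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_warning(z1 <- fisher_z(1), "clip")
  expect_true(is.finite(z1))
})
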