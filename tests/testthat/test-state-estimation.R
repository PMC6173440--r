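fake_profile <- function(z, p) {
  structure(list(zscores = z, participation = p,
                 modularity = rep(0, nrow(z)), partitions = list(),
                 n_modules = integer(nrow(z)), step_seconds = 2.16),
            class = "cartography")
}

test_that("joint histograms bin all nodes with edge clipping", {
  n <- 25
  z <- matrix(0.0, 2, n); p <- matrix(0.5, 2, n)
  h <- joint_histogram(fake_profile(z, p))
  # all nodes share one (z, P): a single bin holds N
  expect_equal(max(h$counts[1, ]), n)
  expect_equal(rowSums(h$counts), rep(n, 2))

  # bin index convention: floor-based half-open bins
  bi <- netfluct:::bin_index
  expect_equal(bi(0, c(-5, 5), 100), floor((0 + 5) / 10 * 100) + 1)
  expect_equal(bi(0.5, c(0, 1), 100), floor(0.5 * 100) + 1)
  # out-of-range values fall into the nearest edge bin
  expect_equal(bi(-7, c(-5, 5), 100), 1)
  expect_equal(bi(12, c(-5, 5), 100), 100)
  zx <- matrix(c(-20, 20, 0, 0), 1)
  px <- matrix(c(0.5, 0.5, -1, 2), 1)
  hx <- joint_histogram(fake_profile(zx, px))
  expect_equal(sum(hx$counts), 4)
})

test_that("well-separated histogram groups cluster perfectly with the P-based labels", {
  set.seed(31)
  for (seed in 1:5) {
    W <- 30
    n <- 50
    z <- matrix(stats::rnorm(W * n, sd = 0.3), W, n)
    p <- matrix(0, W, n)
    truth <- rep(c("segregated", "integrated"), length.out = W)
    p[truth == "segregated", ] <- stats::runif(sum(truth == "segregated") * n,
                                               0.0, 0.2)
    p[truth == "integrated", ] <- stats::runif(sum(truth == "integrated") * n,
                                               0.6, 0.9)
    h <- joint_histogram(fake_profile(z, p))
    st <- estimate_states(h, rowMeans(p), restarts = 10, seed = seed)
    expect_equal(as.character(st$labels), truth)
    # determinism
    st2 <- estimate_states(h, rowMeans(p), restarts = 10, seed = seed)
    expect_identical(st$labels, st2$labels)
  }
  # labeling contract: the higher-P cluster is always "integrated"
})

test_that("identical windows give a flagged degenerate single cluster", {
  z <- matrix(1, 10, 20); p <- matrix(0.4, 10, 20)
  h <- joint_histogram(fake_profile(z, p))
  expect_warning(st <- estimate_states(h, rowMeans(p), restarts = 5,
                                       seed = 1),
                 "degenerate")
  expect_true(attr(st, "degenerate"))
})

test_that("modularity terciles split as written, ties to middle", {
  q <- c(9, 5, 1, 8, 4, 2, 7, 6, 3)
  st <- modularity_periods(q)
  expect_equal(sum(st$labels == "high"), 3)
  expect_equal(sum(st$labels == "middle"), 3)
  expect_equal(sum(st$labels == "low"), 3)
  expect_true(min(q[st$labels == "high"]) > max(q[st$labels == "middle"]))
  expect_true(min(q[st$labels == "middle"]) > max(q[st$labels == "low"]))
  # heavy ties at the boundary stay middle under strict inequalities
  qt <- c(1, 2, 2, 2, 2, 2, 2, 2, 3)
  stt <- modularity_periods(qt)
  expect_equal(as.character(stt$labels[2:8]), rep("middle", 7))
  # tercile labels are invariant to strictly monotone transforms
  expect_identical(modularity_periods(exp(q))$labels, st$labels)
  expect_identical(modularity_periods(10 * q - 3)$labels, st$labels)
})

test_that("transition statistics match hand counting", {
  # constant sequence
  st <- transition_stats(rep("A", 6), step_seconds = 2.16)
  expect_equal(st$transition_matrix["A", "A"], 1)
  expect_equal(st$mean_dwell_windows[["A"]], 6)
  # alternating sequence
  ab <- transition_stats(rep(c("A", "B"), 5), step_seconds = 2.16)
  expect_equal(ab$transition_matrix["A", "B"], 1)
  expect_equal(ab$transition_matrix["B", "A"], 1)
  expect_equal(ab$mean_dwell_windows[["A"]], 1)
  expect_equal(ab$mean_dwell_seconds[["A"]], 2.16)
  # hand-enumerated mixed sequence
  hs <- transition_stats(c("A", "A", "B", "B", "B", "A"),
                         step_seconds = 2.16)
  expect_equal(hs$transition_matrix["A", "A"], 1 / 2)
  expect_equal(hs$transition_matrix["A", "B"], 1 / 2)
  expect_equal(hs$transition_matrix["B", "B"], 2 / 3)
  expect_equal(hs$transition_matrix["B", "A"], 1 / 3)
  expect_equal(hs$mean_dwell_windows[["A"]], 1.5)
  expect_equal(hs$mean_dwell_windows[["B"]], 3)
  expect_equal(sum(hs$occupancy), 1)
  expect_equal(rowSums(hs$transition_matrix), c(A = 1, B = 1))
})

test_that("state centroids are edgewise medians", {
  set.seed(33)
  n <- 4
  mats <- array(stats::rnorm(n * n * 5), c(n, n, 5))
  for (k in 1:5) {
    mats[, , k] <- (mats[, , k] + t(mats[, , k])) / 2
    diag(mats[, , k]) <- NA
  }
  trfc <- structure(list(matrices = mats, window_centers_trs = 1:5,
                         spec = window_spec(), tr_seconds = 0.72),
                    class = "time_resolved_fc")
  labels <- c("s", "i", "s", "s", "i")
  cen <- state_centroids(trfc, labels)
  # single matches of the sort-based oracle on every edge
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cen$s$values[i, j],
                 sort(mats[i, j, c(1, 3, 4)])[2])
    expect_equal(cen$i$values[i, j], mean(sort(mats[i, j, c(2, 5)])))
  }
  # single-window state equals that window
  cen1 <- state_centroids(trfc, c("a", "b", "b", "b", "b"))
  expect_equal(cen1$a$values, mats[, , 1])
  # {1, 2, 10} median toy
  m3 <- array(0, c(2, 2, 3)); m3[1, 2, ] <- m3[2, 1, ] <- c(1, 2, 10)
  t3 <- structure(list(matrices = m3, window_centers_trs = 1:3,
                       spec = window_spec(), tr_seconds = 0.72),
                  class = "time_resolved_fc")
  expect_equal(state_centroids(t3, rep("x", 3))$x$values[1, 2], 2)
})

test_that("between-state contrasts detect a planted shift with FDR control", {
  set.seed(34)
  n <- 21
  sys <- rep(c("DMN", "VIS", "SMN"), each = 7)
  n_samp <- 12
  make_centroid <- function(shift) {
    v <- matrix(stats::rnorm(n * n, sd = 0.05), n, n)
    v <- (v + t(v)) / 2
    v[sys == "DMN", sys == "VIS"] <- v[sys == "DMN", sys == "VIS"] + shift
    v[sys == "VIS", sys == "DMN"] <- t(v[sys == "DMN", sys == "VIS"])
    diag(v) <- NA
    structure(list(values = v, scale = "fisher_z"), class = "fc_matrix")
  }
  ca <- lapply(seq_len(n_samp), function(i) make_centroid(0.3))
  cb <- lapply(seq_len(n_samp), function(i) make_centroid(0))
  res <- between_state_contrast(ca, cb, sys)
  expect_true(res$significant["DMN", "VIS"])
  expect_gt(res$t["DMN", "VIS"], 0)              # first-named state larger
  others <- res$significant
  others["DMN", "VIS"] <- others["VIS", "DMN"] <- FALSE
  expect_lte(sum(others, na.rm = TRUE), 1)       # planted-null level
  # identical centroids: nothing significant
  same <- between_state_contrast(ca, ca, sys)
  expect_false(any(same$significant, na.rm = TRUE))
  expect_error(between_state_contrast(ca[1:2], cb[1:2], sys), "3 samples")
})

test_that("SC-FC similarity correlates weights over connected edges", {
  sc <- toy_connectome(n_nodes = 40, seed = 35, intra_density = 0.8,
                       inter_density = 0.3)
  expect_gte(sum(sc$weights[upper.tri(sc$weights)] > 0), 200)
  fc_same <- sc$weights; diag(fc_same) <- NA
  expect_equal(sc_fc_similarity(sc, fc_same), 1)
  expect_equal(sc_fc_similarity(sc, -fc_same), -1)
  set.seed(36)
  hits <- mean(replicate(100, {
    abs(sc_fc_similarity(sc, matrix(stats::rnorm(40 * 40), 40, 40))) < 0.2
  }))
  expect_gte(hits, 0.95)
})

test_that("global absolute FC averages |z| per state", {
  m <- array(0.3, c(3, 3, 4))
  for (k in 1:4) diag(m[, , k]) <- NA
  trfc <- structure(list(matrices = m, window_centers_trs = 1:4,
                         spec = window_spec(), tr_seconds = 0.72),
                    class = "time_resolved_fc")
  g <- global_absolute_fc(trfc, rep("a", 4))
  expect_equal(g[["a"]], 0.3)
  expect_equal(global_absolute_fc(trfc, rep("a", 4)),
               {m2 <- trfc; m2$matrices <- -m2$matrices
                global_absolute_fc(m2, rep("a", 4))})
  # mixed-sign toy vs hand computation
  mm <- array(0, c(2, 2, 2))
  mm[1, 2, ] <- mm[2, 1, ] <- c(-0.4, 0.8)
  tm <- structure(list(matrices = mm, window_centers_trs = 1:2,
                       spec = window_spec(), tr_seconds = 0.72),
                  class = "time_resolved_fc")
  expect_equal(global_absolute_fc(tm, c("x", "x"))[["x"]], 0.6)
})
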