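two_cliques <- function(n_half = 4, bridge = 0) {
  n <- 2 * n_half
  w <- matrix(0, n, n)
  w[1:n_half, 1:n_half] <- 1
  w[(n_half + 1):n, (n_half + 1):n] <- 1
  diag(w) <- 0
  if (bridge != 0) {
    w[1, n_half + 1] <- w[n_half + 1, 1] <- bridge
  }
  w
}

test_that("signed modularity reduces to Newman-Girvan on all-positive graphs", {
  skip_if_not_installed("igraph")
  set.seed(20)
  for (rep in 1:5) {
    n <- 8
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    w[up] <- stats::rbinom(sum(up), 1, 0.4) * stats::runif(sum(up), 0.5, 2)
    w <- w + t(w)
    if (sum(w) == 0) next
    memb <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(signed_modularity(w, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("4-node signed toy: maximum over all 15 partitions matches enumeration", {
  # two positive dyads joined by one negative bridge
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  w[2, 3] <- w[3, 2] <- -0.5
  parts <- all_partitions(4)
  expect_equal(length(parts), 15)
  oracle <- oracle_best_partition(w)
  fit <- maximize_modularity(w, n_restarts = 30, seed = 2)
  expect_equal(fit$Q, oracle$Q, tolerance = 1e-12)
  expect_equal(oracle_ari(fit$membership, oracle$membership), 1)
  # direct evaluation agrees with the brute-force quality on every partition
  for (p in parts[c(1, 5, 9, 15)])
    expect_equal(signed_modularity(w, p), oracle_signed_Q(w, p),
                 tolerance = 1e-14)
})

test_that("negative edges between cliques favor the two-module partition", {
  w <- two_cliques(3, bridge = 0)
  w[1:3, 4:6] <- w[1:3, 4:6] - 0.5
  w[4:6, 1:3] <- t(w[1:3, 4:6])
  diag(w) <- 0
  split2 <- rep(1:2, each = 3)
  expect_gt(signed_modularity(w, split2),
            signed_modularity(w, rep(1, 6)))
})

test_that("disconnected positive cliques resolve to components with the exact Q", {
  w <- two_cliques(4)
  fit <- maximize_modularity(w, n_restarts = 20, seed = 5)
  expect_equal(fit$n_modules, 2)
  expect_equal(oracle_ari(fit$membership, rep(1:2, each = 4)), 1)
  expect_equal(fit$Q, oracle_signed_Q(w, rep(1:2, each = 4)),
               tolerance = 1e-12)
})

test_that("restarted Louvain finds the exhaustive maximum on small graphs", {
  set.seed(21)
  hits <- 0
  n_cases <- 40
  for (rep in seq_len(n_cases)) {
    n <- sample(5:7, 1)
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    w[up] <- stats::rbinom(sum(up), 1, 0.5) *
      stats::runif(sum(up), -1, 2)
    w <- w + t(w)
    if (sum(pmax(w, 0)) == 0) next
    oracle <- oracle_best_partition(w)
    fit <- maximize_modularity(w, n_restarts = 50, seed = 1000 + rep)
    if (abs(fit$Q - oracle$Q) < 1e-10) hits <- hits + 1
    expect_lte(fit$Q, oracle$Q + 1e-10)
    # never below the better of the trivial partitions
    expect_gte(fit$Q, max(oracle_signed_Q(w, seq_len(n)),
                          oracle_signed_Q(w, rep(1, n))) - 1e-10)
  }
  expect_gte(hits / n_cases, 0.95)
})

test_that("modularity is invariant to module relabeling and seeded", {
  w <- two_cliques(4, bridge = -0.3)
  memb <- rep(1:2, each = 4)
  perm <- c(2, 1)[memb]
  expect_equal(signed_modularity(w, memb), signed_modularity(w, perm))
  a <- maximize_modularity(w, n_restarts = 10, seed = 9)
  b <- maximize_modularity(w, n_restarts = 10, seed = 9)
  expect_identical(a, b)
  expect_error(signed_modularity(-two_cliques(4), rep(1, 8)), "positive")
})

test_that("within-module z-scores standardize within-module degrees", {
  # equal within-module degrees: z = 0
  w <- two_cliques(4)
  memb <- rep(1:2, each = 4)
  expect_equal(within_module_zscore(w, memb), rep(0, 8))

  # weighted 5-node toy vs hand-rolled mean/SD oracle
  set.seed(22)
  w5 <- matrix(0, 5, 5)
  up <- upper.tri(w5)
  w5[up] <- stats::runif(sum(up), -1, 2)
  w5 <- w5 + t(w5)
  m5 <- c(1, 1, 1, 2, 2)
  z <- within_module_zscore(w5, m5)
  for (mod in 1:2) {
    nodes <- which(m5 == mod)
    kappa <- sapply(nodes, function(i) sum(w5[i, setdiff(nodes, i)]))
    if (stats::sd(kappa) > 0) {
      expect_equal(z[nodes], (kappa - mean(kappa)) / stats::sd(kappa),
                   tolerance = 1e-12)
    } else {
      expect_equal(z[nodes], rep(0, length(nodes)))  # degenerate rule
    }
  }
  # standardization: per-module mean 0, SD 1 (module 1 has distinct degrees)
  expect_equal(mean(z[m5 == 1]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z[m5 == 1]), 1, tolerance = 1e-9)
  # singleton and zero-variance modules give z = 0
  expect_equal(within_module_zscore(w5, c(1, 1, 1, 2, 3))[4:5], c(0, 0))
})

test_that("participation coefficient matches its closed forms and the oracle", {
  w <- two_cliques(4)
  memb <- rep(1:2, each = 4)
  expect_equal(participation_coefficient(w, memb), rep(0, 8))

  # equal split across m modules: P = 1 - 1/m
  for (m in 2:4) {
    n <- m + 1
    w_star <- matrix(0, n, n)
    w_star[1, 2:n] <- w_star[2:n, 1] <- 1
    memb_star <- c(1, rep(seq_len(m), length.out = n - 1))
    # hub splits equally when each module holds the same number of leaves
    if ((n - 1) %% m == 0)
      expect_equal(participation_coefficient(w_star, memb_star)[1],
                   1 - 1 / m, tolerance = 1e-12)
  }

  # random toy vs direct formula with positive weights only
  set.seed(23)
  wr <- matrix(0, 6, 6)
  up <- upper.tri(wr)
  wr[up] <- stats::runif(sum(up), -1, 1)
  wr <- wr + t(wr)
  mr <- c(1, 1, 2, 2, 3, 3)
  p <- participation_coefficient(wr, mr)
  wp <- pmax(wr, 0)
  for (i in 1:6) {
    ktot <- sum(wp[i, ])
    if (ktot == 0) { expect_equal(p[i], 0); next }
    s <- sum(sapply(1:3, function(mod)
      (sum(wp[i, mr == mod]) / ktot)^2))
    expect_equal(p[i], 1 - s, tolerance = 1e-12)
  }
  # bound: P <= 1 - 1/n_modules
  expect_true(all(p <= 1 - 1 / 3 + 1e-12))
})

test_that("cartography profiles every window consistently", {
  set.seed(24)
  x <- matrix(stats::rnorm(12 * 140), 12, 140)
  spec <- window_spec(rect_width_trs = 20, gauss_sigma_trs = 3,
                      step_trs = 10, kernel_halfwidth_trs = 3)
  trfc <- time_resolved_fc(x, spec)
  prof <- cartography(trfc, n_restarts = 10, seed = 30)
  W <- dim(trfc$matrices)[3]
  expect_length(prof$modularity, W)
  expect_equal(dim(prof$zscores), c(W, 12))
  expect_true(all(prof$participation >= 0 & prof$participation <= 1))
  # per-module z means vanish where the module has >= 2 members
  for (wi in seq_len(W)) {
    memb <- prof$partitions[[wi]]
    for (mod in unique(memb))
      if (sum(memb == mod) >= 2)
        expect_lt(abs(mean(prof$zscores[wi, memb == mod])), 1e-9)
  }
  # reported Q equals direct evaluation of the winning partition
  expect_equal(prof$modularity[1],
               signed_modularity(trfc$matrices[, , 1],
                                 prof$partitions[[1]]),
               tolerance = 1e-10)
})
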