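#' Structural connectome container
#'
#' Bundles a symmetric nonnegative connection-weight matrix (fiber density),
#' a matrix of fiber lengths in millimetres, node identifiers, and per-node
#' intrinsic-system labels (e.g. the seven canonical resting-state systems
#' CON, DMN, LIM, DAN, VAN, SMN, VIS) into a validated S3 object.
#'
#' Invariants enforced: both matrices symmetric with zero diagonal, weights
#' nonnegative, lengths strictly positive exactly where weights are positive.
#'
#' @param weights N x N symmetric nonnegative matrix of connection weights.
#' @param lengths N x N symmetric matrix of fiber lengths (mm), positive
#'   wherever `weights` is positive.
#' @param node_ids character vector of N node labels (defaults to
#'   `"n1" ... "nN"`).
#' @param system_labels character vector of N system assignments.
#' @param hemisphere optional character vector of N hemisphere labels.
#' @return An object of class `structural_connectome` with fields
#'   `weights`, `lengths`, `node_ids`, `system_labels`, `hemisphere`.
#' @export
structural_connectome <- function(weights, lengths, node_ids = NULL,
                                  system_labels = NULL, hemisphere = NULL) {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  n <- nrow(weights)
  if (ncol(weights) != n || any(dim(lengths) != n))
    stop("weights and lengths must be square matrices of equal size")
  if (any(!is.finite(weights)) || any(!is.finite(lengths)))
    stop("weights and lengths must be finite")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-8 * max(1, max(abs(weights))))
    stop("weights must be symmetric")
  if (max(abs(lengths - t(lengths))) > 1e-8 * max(1, max(abs(lengths))))
    stop("lengths must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have zero diagonal")
  if (any(lengths[weights > 0] <= 0))
    stop("lengths must be strictly positive on every connected edge")
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  if (is.null(system_labels)) system_labels <- rep("unassigned", n)
  if (length(node_ids) != n || length(system_labels) != n)
    stop("node_ids and system_labels must have one entry per node")
  weights <- (weights + t(weights)) / 2
  lengths <- (lengths + t(lengths)) / 2
  dimnames(weights) <- dimnames(lengths) <- list(node_ids, node_ids)
  structure(list(weights = weights, lengths = lengths,
                 node_ids = as.character(node_ids),
                 system_labels = as.character(system_labels),
                 hemisphere = hemisphere),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Structural connectome: %d nodes, %d edges (density %.3f)\n",
              n, nz, nz / (n * (n - 1) / 2)))
  cat(sprintf("  mean nonzero weight: %.4g; mean fiber length: %.1f mm\n",
              mean(x$weights[x$weights > 0]),
              mean(x$lengths[x$weights > 0])))
  cat("  systems:", paste(names(table(x$system_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Fiber density between two regions
#'
#' Normalizes a tractography streamline count by the geometric mean of the
#' two regions' surface areas, compensating for region size.
#'
#' @param streamline_count nonnegative streamline count.
#' @param area_a,area_b strictly positive surface areas (mm^2).
#' @return `streamline_count / sqrt(area_a * area_b)`.
#' @export
fiber_density <- function(streamline_count, area_a, area_b) {
  if (any(streamline_count < 0)) stop("streamline_count must be nonnegative")
  if (any(area_a <= 0) || any(area_b <= 0))
    stop("surface areas must be strictly positive")
  streamline_count / sqrt(area_a * area_b)
}

#' Normalize connectome weights to unit mean nonzero edge weight
#'
#' Rescales all weights by one constant so that the average of the non-zero
#' edge weights equals one. Zero entries stay zero and weight ratios are
#' preserved; the operation is idempotent.
#'
#' @param sc a [structural_connectome()].
#' @return The rescaled `structural_connectome`.
#' @export
normalize_weights <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  w <- sc$weights
  nz <- w[w > 0]
  if (length(nz) == 0) stop("connectome has no non-zero weights")
  sc$weights <- w / mean(nz)
  sc
}

#' Degree- and strength-preserving surrogate connectome
#'
#' Randomizes the connectome by iterated degree-preserving double-edge swaps
#' on the binary topology, then re-ranks the original weights onto the new
#' edges so that each node's strength (weighted degree) is approximately
#' preserved. Each swapped edge carries its weight together with its fiber
#' length, so the length distribution is unchanged. Candidates are rejected
#' and regenerated until the Pearson correlation between the original and
#' surrogate node-strength sequences exceeds `strength_threshold`.
#'
#' Weight re-ranking follows the positive-weight branch of the standard
#' signed null model for weighted undirected networks: unassigned edges are
#' repeatedly ranked by the product of their endpoints' residual strengths
#' and a randomly drawn edge receives its rank-matched weight. A greedy
#' refinement pass then swaps (weight, length) pairs between edges whenever
#' that lowers the squared deviation of node strengths from their targets.
#'
#' @param sc a [structural_connectome()].
#' @param seed integer seed; the same seed reproduces the same surrogate.
#' @param n_swaps number of attempted double-edge swaps per candidate
#'   (default 10 per edge).
#' @param strength_threshold required correlation between original and
#'   surrogate strength sequences (default 0.95).
#' @param max_attempts candidates generated before giving up (default 1000).
#' @return A `surrogate_connectome` (inherits `structural_connectome`) with
#'   attributes `strength_correlation` and `provenance`.
#' @export
rewire_surrogate <- function(sc, seed, n_swaps = NULL,
                             strength_threshold = 0.95, max_attempts = 1000) {
  stopifnot(inherits(sc, "structural_connectome"))
  n <- nrow(sc$weights)
  ut <- which(upper.tri(sc$weights) & sc$weights > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2) stop("need at least 2 edges to rewire")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  s_orig <- rowSums(sc$weights)
  best_cor <- -Inf
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (attempt in seq_len(max_attempts)) {
    cand <- rewire_once(sc, ut, n_swaps)
    s_new <- rowSums(cand$weights)
    rho <- suppressWarnings(stats::cor(s_orig, s_new))
    if (is.na(rho)) rho <- -Inf
    if (rho > best_cor) best_cor <- rho
    if (rho > strength_threshold) {
      out <- structural_connectome(cand$weights, cand$lengths, sc$node_ids,
                                   sc$system_labels, sc$hemisphere)
      class(out) <- c("surrogate_connectome", class(out))
      attr(out, "strength_correlation") <- rho
      attr(out, "provenance") <- list(seed = seed, n_swaps = n_swaps,
                                      attempts = attempt)
      return(out)
    }
  }
  stop(sprintf(paste0("failed to reach strength correlation > %.2f in %d ",
                      "attempts (best achieved: %.4f)"),
               strength_threshold, max_attempts, best_cor))
}

# one rewiring candidate: double-edge swaps on the binary topology, then
# residual-strength weight re-ranking (weights carry their lengths)
rewire_once <- function(sc, ut, n_swaps) {
  n <- nrow(sc$weights)
  edges <- cpp_edge_swap(ut, n, n_swaps)
  w_orig <- sc$weights[ut]
  l_orig <- sc$lengths[ut]
  ord <- order(w_orig, decreasing = TRUE)
  s0 <- rowSums(sc$weights)
  idx <- cpp_rerank_weights(edges, s0, w_orig[ord])
  idx <- cpp_strength_refine(edges, idx, w_orig[ord], s0,
                             n_iter = 50L * length(w_orig))
  W <- matrix(0, n, n); L <- matrix(0, n, n)
  W[edges] <- w_orig[ord][idx]; L[edges] <- l_orig[ord][idx]
  W[edges[, c(2, 1)]] <- W[edges]; L[edges[, c(2, 1)]] <- L[edges]
  list(weights = W, lengths = L)
}

#' Write / read a connectome as delimited text
#'
#' `write_connectome()` stores the weight and length matrices as
#' tab-separated files with a header row of node ids, plus the label vector,
#' inside `dir`. `read_connectome()` reads them back.
#'
#' @param sc a [structural_connectome()].
#' @param dir directory to create/read.
#' @return `read_connectome()` returns a `structural_connectome`;
#'   `write_connectome()` returns `dir` invisibly.
#' @export
write_connectome <- function(sc, dir) {
  stopifnot(inherits(sc, "structural_connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sc$weights, file.path(dir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  utils::write.table(sc$lengths, file.path(dir, "lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  labels <- data.frame(node_id = sc$node_ids, system = sc$system_labels,
                       hemisphere = if (is.null(sc$hemisphere)) NA
                                    else sc$hemisphere)
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(dir) {
  w <- as.matrix(utils::read.table(file.path(dir, "weights.tsv"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  l <- as.matrix(utils::read.table(file.path(dir, "lengths.tsv"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                           sep = "\t")
  hemi <- if (all(is.na(lab$hemisphere))) NULL else as.character(lab$hemisphere)
  structural_connectome(w, l, lab$node_id, lab$system, hemi)
}
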