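#' Signed modularity of a partition
#'
#' Modularity quality generalized to networks with positive and negative
#' weights: with `w+`/`w-` the positive/negative parts of the weight matrix,
#' `s+-_i` node strengths, `v+-` total weights, and chance densities
#' `e+-_ij = s_i * s_j / v`,
#' `Q = (1/v+) * sum((w+ - e+) * delta) - (1/(v+ + v-)) * sum((w- - e-) * delta)`,
#' summed over all ordered node pairs in the same module (diagonal chance
#' terms included). The positive term alone is the standard Newman-Girvan
#' quality; the negative term rewards placing negative edges between
#' modules.
#'
#' @param weights N x N symmetric signed matrix with zero diagonal (an
#'   `fc_matrix` is accepted; `NA` diagonals are treated as 0).
#' @param membership integer module assignment of each node.
#' @param resolution resolution parameter `gamma` scaling the chance terms
#'   (default 1).
#' @return The scalar quality `Q`.
#' @export
signed_modularity <- function(weights, membership, resolution = 1) {
  w <- signed_weight_matrix(weights)
  if (length(membership) != nrow(w)) stop("one module label per node")
  B <- signed_modularity_matrix(w, resolution)
  same <- outer(membership, membership, `==`)
  sum(B[same])
}

# coerce input to a clean signed weight matrix
signed_weight_matrix <- function(weights) {
  w <- if (inherits(weights, "fc_matrix")) weights$values else as.matrix(weights)
  w[is.na(w)] <- 0
  diag(w) <- 0
  if (max(abs(w - t(w))) > 1e-8 * max(1, max(abs(w))))
    stop("weights must be symmetric")
  (w + t(w)) / 2
}

# B such that Q = sum of B over within-module ordered pairs (incl. diagonal)
signed_modularity_matrix <- function(w, resolution = 1) {
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  if (vp == 0) stop("graph has no positive weights")
  sp <- rowSums(wp); sn <- rowSums(wn)
  B <- (wp - resolution * outer(sp, sp) / vp) / vp
  if (vn > 0)
    B <- B - (wn - resolution * outer(sn, sn) / vn) / (vp + vn)
  B
}

#' Maximize signed modularity with restarted Louvain
#'
#' Runs the Louvain algorithm (random node sweep order, greedy local moves,
#' community aggregation) on the signed modularity matrix `n_restarts` times
#' with random initial sweep orders and returns the best partition by `Q`.
#'
#' @inheritParams signed_modularity
#' @param n_restarts number of independent runs (default 100).
#' @param seed integer seed making the whole set of restarts reproducible.
#' @return A list: `Q` (best quality), `membership` (1-based contiguous
#'   labels), `n_modules`.
#' @export
maximize_modularity <- function(weights, n_restarts = 100, resolution = 1,
                                seed = NULL) {
  w <- signed_weight_matrix(weights)
  B <- signed_modularity_matrix(w, resolution)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- cpp_louvain(B, 1e-10)
    if (is.null(best) || res$Q > best$Q) best <- res
  }
  memb <- as.integer(factor(best$membership, levels = unique(best$membership)))
  list(Q = best$Q, membership = memb, n_modules = max(memb))
}

#' Within-module degree z-score
#'
#' For each node, the weighted degree towards nodes of its own module,
#' standardized by the mean and SD of those within-module degrees over the
#' module: `z_i = (kappa_i - mean(kappa_module)) / sd(kappa_module)`. By
#' default the full signed weights are summed; `positive_only = TRUE`
#' restricts to positive weights. Modules of size 1 or with zero SD give
#' `z = 0`.
#'
#' @inheritParams signed_modularity
#' @param positive_only use only positive weights in the degree (default
#'   FALSE, i.e. signed degrees).
#' @return Numeric vector of per-node z-scores.
#' @export
within_module_zscore <- function(weights, membership, positive_only = FALSE) {
  w <- signed_weight_matrix(weights)
  if (positive_only) w <- pmax(w, 0)
  n <- nrow(w)
  z <- numeric(n)
  for (m in unique(membership)) {
    nodes <- which(membership == m)
    if (length(nodes) < 2) next
    kappa <- rowSums(w[nodes, nodes, drop = FALSE])
    s <- stats::sd(kappa)
    if (is.na(s) || s == 0) next
    z[nodes] <- (kappa - mean(kappa)) / s
  }
  z
}

#' Participation coefficient (positive weights)
#'
#' `P_i = 1 - sum_m (kappa+_im / kappa+_i)^2` where `kappa+_im` is node i's
#' positive strength into module m and `kappa+_i` its total positive
#' strength; `P_i = 0` when the node has no positive strength. High values
#' mark nodes whose positive connectivity spreads across modules
#' (integrative hubs).
#'
#' @inheritParams signed_modularity
#' @return Numeric vector of per-node participation coefficients in `[0, 1]`.
#' @export
participation_coefficient <- function(weights, membership) {
  w <- pmax(signed_weight_matrix(weights), 0)
  ktot <- rowSums(w)
  mods <- sort(unique(membership))
  km <- vapply(mods, function(m)
    rowSums(w[, membership == m, drop = FALSE]), numeric(nrow(w)))
  km <- matrix(km, nrow = nrow(w))
  p <- 1 - rowSums((km / ifelse(ktot > 0, ktot, 1))^2)
  p[ktot == 0] <- 0
  p
}

#' Network cartography of time-resolved FC
#'
#' For every FC window: maximize signed modularity (best of `n_restarts`
#' Louvain runs), then compute the within-module degree z-scores and
#' participation coefficients under the winning partition.
#'
#' @param trfc a [time_resolved_fc()].
#' @param n_restarts Louvain restarts per window (default 100).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed.
#' @param zscore_positive_only passed to [within_module_zscore()].
#' @return A `cartography` object: `modularity` (Q_t, length W), `zscores`
#'   and `participation` (W x N matrices), `partitions` (list of membership
#'   vectors), `n_modules` (per window), `step_seconds`.
#' @export
cartography <- function(trfc, n_restarts = 100, resolution = 1, seed = NULL,
                        zscore_positive_only = FALSE) {
  stopifnot(inherits(trfc, "time_resolved_fc"))
  W <- dim(trfc$matrices)[3]
  n <- dim(trfc$matrices)[1]
  if (!is.null(seed)) set.seed(seed)
  Q <- numeric(W); nm <- integer(W)
  zs <- matrix(0, W, n); pc <- matrix(0, W, n)
  parts <- vector("list", W)
  for (wi in seq_len(W)) {
    m <- trfc$matrices[, , wi]
    fit <- maximize_modularity(m, n_restarts = n_restarts,
                               resolution = resolution)
    Q[wi] <- fit$Q; nm[wi] <- fit$n_modules; parts[[wi]] <- fit$membership
    zs[wi, ] <- within_module_zscore(m, fit$membership,
                                     positive_only = zscore_positive_only)
    pc[wi, ] <- participation_coefficient(m, fit$membership)
  }
  step_s <- if (is.na(trfc$tr_seconds)) NA_real_
            else trfc$spec$step_trs * trfc$tr_seconds
  structure(list(modularity = Q, zscores = zs, participation = pc,
                 partitions = parts, n_modules = nm, step_seconds = step_s),
            class = "cartography")
}

#' @export
print.cartography <- function(x, ...) {
  cat(sprintf(paste0("Cartography: %d windows; mean Q = %.3f (SD %.3f), ",
                     "mean P = %.3f (SD of mean P %.3f)\n"),
              length(x$modularity), mean(x$modularity),
              stats::sd(x$modularity), mean(x$participation),
              stats::sd(rowMeans(x$participation))))
  invisible(x)
}
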