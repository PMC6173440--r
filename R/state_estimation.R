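#' Per-window joint (z, P) histograms
#'
#' Bins each window's nodal within-module degree z-scores and participation
#' coefficients into a 100 x 100 joint histogram over the open ranges
#' `-5 < z < 5` and `0 < P < 1` (100 equal bins per axis, half-open
#' `[lo, hi)` convention); values outside a range are clipped into the
#' nearest edge bin, so each window's counts sum to N.
#'
#' @param profile a [cartography()] object.
#' @param n_bins bins per axis (default 100).
#' @param z_range,p_range axis ranges.
#' @return A `joint_histograms` object: `counts` (W x n_bins^2 matrix of
#'   flattened histograms), `n_bins`, `z_range`, `p_range`.
#' @export
joint_histogram <- function(profile, n_bins = 100, z_range = c(-5, 5),
                            p_range = c(0, 1)) {
  stopifnot(inherits(profile, "cartography"))
  W <- nrow(profile$zscores)
  counts <- matrix(0L, W, n_bins * n_bins)
  for (wi in seq_len(W)) {
    zi <- bin_index(profile$zscores[wi, ], z_range, n_bins)
    pi_ <- bin_index(profile$participation[wi, ], p_range, n_bins)
    idx <- (pi_ - 1L) * n_bins + zi
    tab <- tabulate(idx, nbins = n_bins * n_bins)
    counts[wi, ] <- tab
  }
  structure(list(counts = counts, n_bins = n_bins, z_range = z_range,
                 p_range = p_range),
            class = "joint_histograms")
}

# half-open equal-width binning with edge clipping, 1-based
bin_index <- function(x, range, n_bins) {
  i <- floor((x - range[1]) / (range[2] - range[1]) * n_bins) + 1
  pmin(pmax(as.integer(i), 1L), n_bins)
}

#' Segregated / integrated state estimation
#'
#' Clusters the per-window joint (z, P) histograms into two groups with
#' k-means (Euclidean distance on the count vectors, best within-cluster sum
#' of squares over `restarts` random initializations). The cluster whose
#' member windows have the greater average nodal participation coefficient
#' is labeled *integrated*, the other *segregated*.
#'
#' @param histograms a [joint_histogram()] result.
#' @param mean_participation per-window mean nodal participation (e.g.
#'   `rowMeans(profile$participation)`).
#' @param restarts k-means restarts (default 500).
#' @param seed integer seed.
#' @param normalize divide each histogram by its total before clustering
#'   (default FALSE, i.e. raw counts).
#' @return A `state_sequence`: factor `labels` with levels
#'   `c("segregated", "integrated")` plus attribute `degenerate` when the
#'   windows were indistinguishable.
#' @export
estimate_states <- function(histograms, mean_participation, restarts = 500,
                            seed = NULL, normalize = FALSE) {
  stopifnot(inherits(histograms, "joint_histograms"))
  X <- histograms$counts
  if (nrow(X) < 2) stop("need at least 2 windows")
  if (length(mean_participation) != nrow(X))
    stop("one mean participation value per window")
  if (normalize) X <- X / pmax(rowSums(X), 1)
  keep <- which(colSums(abs(X)) > 0)       # drop empty bins (distance-neutral)
  X <- X[, keep, drop = FALSE]
  degenerate <- nrow(unique(X)) < 2
  if (degenerate) {
    labels <- factor(rep("segregated", nrow(histograms$counts)),
                     levels = c("segregated", "integrated"))
    warning("all windows identical; single-cluster degenerate output")
  } else {
    if (!is.null(seed)) set.seed(seed)
    km <- stats::kmeans(X, centers = 2, nstart = restarts, iter.max = 50)
    p_by_cluster <- tapply(mean_participation, km$cluster, mean)
    integrated <- as.integer(names(which.max(p_by_cluster)))
    labels <- factor(ifelse(km$cluster == integrated, "integrated",
                            "segregated"),
                     levels = c("segregated", "integrated"))
  }
  structure(list(labels = labels), class = "state_sequence",
            degenerate = degenerate)
}

#' Modularity tercile periods
#'
#' Labels each window by comparing its modularity `Q_t` with the per-run
#' terciles: strictly above the upper tercile is `high`, strictly below the
#' lower tercile is `low`, everything else (ties included) `middle`.
#'
#' @param q_series per-window modularity values of one run.
#' @return A `state_sequence` with factor levels `c("high", "middle", "low")`.
#' @export
modularity_periods <- function(q_series) {
  if (length(q_series) < 3) stop("need at least 3 windows")
  terc <- stats::quantile(q_series, c(1 / 3, 2 / 3), names = FALSE)
  labels <- factor(ifelse(q_series > terc[2], "high",
                          ifelse(q_series < terc[1], "low", "middle")),
                   levels = c("high", "middle", "low"))
  structure(list(labels = labels), class = "state_sequence")
}

#' Transition probabilities and mean dwell times
#'
#' Transition matrix `T[i, j] = P(state j at t+1 | state i at t)` over
#' consecutive windows, and mean dwell time (mean length of consecutive
#' same-state runs) per state, in windows and in seconds.
#'
#' @param seq a `state_sequence` (or factor/character vector of labels).
#' @param step_seconds window step in seconds (default 2.16).
#' @return A list: `transition_matrix` (rows of observed states sum to 1;
#'   unobserved states give `NaN` rows), `mean_dwell_windows`,
#'   `mean_dwell_seconds`, `occupancy`.
#' @export
transition_stats <- function(seq, step_seconds = 2.16) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else factor(seq)
  W <- length(labels)
  if (W < 2) stop("need at least 2 windows")
  lv <- levels(labels)
  S <- length(lv)
  counts <- table(factor(labels[-W], levels = lv),
                  factor(labels[-1], levels = lv))
  tm <- counts / pmax(rowSums(counts), 1)
  tm[rowSums(counts) == 0, ] <- NaN
  runs <- rle(as.character(labels))
  dwell <- vapply(lv, function(s) {
    len <- runs$lengths[runs$values == s]
    if (length(len) == 0) NaN else mean(len)
  }, numeric(1))
  occ <- as.numeric(table(labels)) / W
  names(occ) <- lv
  list(transition_matrix = as.matrix(unclass(tm)),
       mean_dwell_windows = dwell,
       mean_dwell_seconds = dwell * step_seconds,
       occupancy = occ)
}

#' State centroids of time-resolved FC
#'
#' Edge-wise median of the Fisher-z FC matrices over the windows assigned to
#' each state.
#'
#' @param trfc a [time_resolved_fc()].
#' @param seq a `state_sequence` (or label vector), one label per window.
#' @return A named list of `fc_matrix` centroids, one per observed state;
#'   states with no windows are `NULL` (with a warning).
#' @export
state_centroids <- function(trfc, seq) {
  stopifnot(inherits(trfc, "time_resolved_fc"))
  labels <- if (inherits(seq, "state_sequence")) seq$labels else factor(seq)
  if (length(labels) != dim(trfc$matrices)[3])
    stop("one state label per window")
  out <- stats::setNames(vector("list", nlevels(labels)), levels(labels))
  for (s in levels(labels)) {
    idx <- which(labels == s)
    if (length(idx) == 0) {
      warning("state '", s, "' has no windows; centroid undefined")
      next
    }
    med <- apply(trfc$matrices[, , idx, drop = FALSE], c(1, 2),
                 stats::median)
    out[[s]] <- structure(list(values = med, scale = "fisher_z"),
                          class = "fc_matrix")
  }
  out
}

#' Between-state contrasts of system-pair connectivity
#'
#' Averages each sample's state-centroid edge weights within every pair of
#' intrinsic systems, takes the paired difference `state_a - state_b` across
#' samples, and reports per-cell paired t-scores masked by
#' Benjamini-Hochberg FDR at `alpha`. Positive t means larger connectivity
#' in `state_a`.
#'
#' @param centroids_a,centroids_b lists (one element per sample) of
#'   `fc_matrix` centroids for the two states.
#' @param system_labels per-node system assignment.
#' @param alpha FDR level (default 0.05).
#' @return A list: `t` (systems x systems), `p`, `p_adjusted`,
#'   `significant` (logical mask), `mean_difference`.
#' @export
between_state_contrast <- function(centroids_a, centroids_b, system_labels,
                                   alpha = 0.05) {
  n_samp <- length(centroids_a)
  if (length(centroids_b) != n_samp)
    stop("need the same number of samples for both states")
  if (n_samp < 3) stop("need at least 3 samples")
  sys <- sort(unique(system_labels))
  S <- length(sys)
  cell_means <- function(fc) {
    v <- fc$values
    out <- matrix(NA_real_, S, S, dimnames = list(sys, sys))
    for (a in seq_len(S)) for (b in seq_len(a)) {
      block <- v[system_labels == sys[a], system_labels == sys[b],
                 drop = FALSE]
      out[a, b] <- out[b, a] <- mean(block, na.rm = TRUE)
    }
    out
  }
  diffs <- array(NA_real_, c(S, S, n_samp))
  for (k in seq_len(n_samp))
    diffs[, , k] <- cell_means(centroids_a[[k]]) - cell_means(centroids_b[[k]])
  tmat <- pmat <- matrix(NA_real_, S, S, dimnames = list(sys, sys))
  for (a in seq_len(S)) for (b in seq_len(a)) {
    d <- diffs[a, b, ]
    tt <- stats::t.test(d)
    tmat[a, b] <- tmat[b, a] <- unname(tt$statistic)
    pmat[a, b] <- pmat[b, a] <- tt$p.value
  }
  lower <- which(lower.tri(pmat, diag = TRUE))
  padj <- matrix(NA_real_, S, S, dimnames = list(sys, sys))
  padj[lower] <- stats::p.adjust(pmat[lower], method = "BH")
  padj[upper.tri(padj)] <- t(padj)[upper.tri(padj)]
  list(t = tmat, p = pmat, p_adjusted = padj,
       significant = !is.na(padj) & padj < alpha,
       mean_difference = apply(diffs, c(1, 2), mean))
}

#' Structure-function similarity
#'
#' Pearson correlation between structural connection weights and FC edge
#' weights over the upper-triangle positions with non-zero structural
#' connections.
#'
#' @param sc a [structural_connectome()].
#' @param fc an `fc_matrix` (or N x N matrix).
#' @return The correlation coefficient.
#' @export
sc_fc_similarity <- function(sc, fc) {
  stopifnot(inherits(sc, "structural_connectome"))
  v <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  up <- upper.tri(sc$weights)
  keep <- up & sc$weights > 0
  if (sum(keep) < 3) stop("need at least 3 non-zero structural edges")
  x <- sc$weights[keep]; y <- v[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant weights; correlation undefined")
  stats::cor(x, y)
}

#' Global absolute functional connectivity per state
#'
#' Mean of `|edge weight|` over all off-diagonal edges and all windows
#' assigned to each state.
#'
#' @inheritParams state_centroids
#' @return Named numeric vector, one value per observed state.
#' @export
global_absolute_fc <- function(trfc, seq) {
  stopifnot(inherits(trfc, "time_resolved_fc"))
  labels <- if (inherits(seq, "state_sequence")) seq$labels else factor(seq)
  up <- upper.tri(trfc$matrices[, , 1])
  vapply(stats::setNames(levels(labels), levels(labels)), function(s) {
    idx <- which(labels == s)
    if (length(idx) == 0) return(NaN)
    mean(abs(apply(trfc$matrices[, , idx, drop = FALSE], 3,
                   function(m) m[up])))
  }, numeric(1))
}
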