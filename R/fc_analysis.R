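#' Fisher z-transform of correlation coefficients
#'
#' `atanh(r)` with `|r| >= 1` clipped to `1 - 1e-15` (a warning is emitted),
#' so degenerate perfectly-correlated toys stay finite.
#'
#' @param r correlations in `[-1, 1]`.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlation magnitude >= 1 clipped before atanh")
    r <- sign(r) * pmin(abs(r), 1 - 1e-15)
  }
  atanh(r)
}

#' Long-timescale functional connectivity
#'
#' Pairwise Pearson correlation between regional BOLD time courses over the
#' whole run, Fisher z-transformed; the diagonal is `NA`.
#'
#' @param bold a [bold_dataset()] (or N x T matrix).
#' @return An `fc_matrix`: `values` (N x N Fisher-z, diag `NA`),
#'   `scale = "fisher_z"`.
#' @export
long_timescale_fc <- function(bold) {
  x <- if (inherits(bold, "bold_dataset")) bold$signal else as.matrix(bold)
  if (ncol(x) < 3) stop("need at least 3 time points")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("constant time series at node(s): ",
         paste(which(sds == 0), collapse = ", "))
  r <- stats::cor(t(x))
  diag(r) <- NA
  z <- fisher_z(r)
  structure(list(values = z, scale = "fisher_z"), class = "fc_matrix")
}

#' Tapered sliding-window specification
#'
#' The taper is the full discrete convolution of a rectangle of
#' `rect_width_trs` TRs with a Gaussian kernel of SD `gauss_sigma_trs` TRs
#' truncated at `kernel_halfwidth_trs` TRs, normalized to sum 1; the window
#' support is `rect_width + 2*kernel_halfwidth` TRs. Defaults (66, 9, 3, 8)
#' correspond, at TR = 0.72 s, to a 47.52-s rectangle, sigma = 6.48 s, and
#' 2.16-s steps.
#'
#' @param rect_width_trs rectangle width in TRs.
#' @param gauss_sigma_trs Gaussian SD in TRs.
#' @param step_trs window step in TRs.
#' @param kernel_halfwidth_trs Gaussian truncation radius in TRs.
#' @return A `window_spec` list.
#' @export
window_spec <- function(rect_width_trs = 66, gauss_sigma_trs = 9,
                        step_trs = 3, kernel_halfwidth_trs = 8) {
  if (rect_width_trs < 1 || step_trs < 1 || kernel_halfwidth_trs < 0 ||
      gauss_sigma_trs < 0)
    stop("window spec values must be positive (halfwidth/sigma nonnegative)")
  structure(list(rect_width_trs = as.integer(rect_width_trs),
                 gauss_sigma_trs = gauss_sigma_trs,
                 step_trs = as.integer(step_trs),
                 kernel_halfwidth_trs = as.integer(kernel_halfwidth_trs)),
            class = "window_spec")
}

#' Build tapered window weight vectors
#'
#' Places every fully contained window along a series of `n_timepoints`
#' samples, advancing by `step_trs`. With the defaults and 1186 usable
#' volumes this yields 369 windows.
#'
#' @param spec a [window_spec()].
#' @param n_timepoints length of the series the windows will be applied to.
#' @return A list: `weights` (support x W matrix, columns sum to 1),
#'   `starts` (1-based start indices), `centers_trs`, `count`, `support`.
#' @export
build_tapered_windows <- function(spec, n_timepoints) {
  stopifnot(inherits(spec, "window_spec"))
  hw <- spec$kernel_halfwidth_trs
  rect <- rep(1, spec$rect_width_trs)
  if (spec$gauss_sigma_trs > 0) {
    kern <- stats::dnorm(-hw:hw, sd = spec$gauss_sigma_trs)
  } else {
    kern <- c(rep(0, hw), 1, rep(0, hw))
  }
  taper <- stats::convolve(rect, rev(kern), type = "open")
  taper <- taper / sum(taper)
  support <- length(taper)                 # rect + 2*hw
  if (n_timepoints < support)
    stop("series shorter than one window")
  starts <- seq(1, n_timepoints - support + 1, by = spec$step_trs)
  list(weights = matrix(rep(taper, length(starts)), ncol = length(starts)),
       starts = starts,
       centers_trs = starts + (support - 1) / 2,
       count = length(starts), support = support)
}

# weighted Pearson correlation of rows of x under nonnegative weights w
weighted_correlation <- function(x, w) {
  w <- w / sum(w)
  mu <- drop(x %*% w)
  xc <- sweep(x, 1, mu) * rep(sqrt(w), each = nrow(x))
  cv <- tcrossprod(xc)
  v <- diag(cv)
  if (any(v <= 0)) stop("zero weighted variance in window")
  cv / sqrt(outer(v, v))
}

#' Time-resolved functional connectivity
#'
#' Per-window weighted Pearson correlation (weighted means and covariances
#' under the taper weights), Fisher z-transformed.
#'
#' @param bold a [bold_dataset()] (or N x T matrix).
#' @param spec a [window_spec()].
#' @return A `time_resolved_fc`: `matrices` (N x N x W Fisher-z array,
#'   diagonals `NA`), `window_centers_trs`, `spec`, `tr_seconds`.
#' @export
time_resolved_fc <- function(bold, spec = window_spec()) {
  x <- if (inherits(bold, "bold_dataset")) bold$signal else as.matrix(bold)
  tr <- if (inherits(bold, "bold_dataset")) bold$tr_seconds else NA_real_
  win <- build_tapered_windows(spec, ncol(x))
  n <- nrow(x)
  mats <- array(NA_real_, c(n, n, win$count))
  for (wi in seq_len(win$count)) {
    idx <- win$starts[wi] + seq_len(win$support) - 1
    r <- weighted_correlation(x[, idx, drop = FALSE], win$weights[, wi])
    diag(r) <- NA
    mats[, , wi] <- suppressWarnings(fisher_z(r))
  }
  structure(list(matrices = mats, window_centers_trs = win$centers_trs,
                 spec = spec, tr_seconds = tr),
            class = "time_resolved_fc")
}

#' @export
print.time_resolved_fc <- function(x, ...) {
  cat(sprintf("Time-resolved FC: %d windows of %d x %d (step %d TRs)\n",
              dim(x$matrices)[3], dim(x$matrices)[1], dim(x$matrices)[2],
              x$spec$step_trs))
  invisible(x)
}

#' Functional connectivity dynamics (FCD) distribution
#'
#' Correlates the upper-triangle Fisher-z vectors of every pair of FC
#' windows and pools the coefficients; pairs whose window-center separation
#' is less than one rectangle width (`rect_width_trs`) are discarded, i.e.
#' only pairs at least `ceiling(rect_width / step)` window steps apart are
#' retained.
#'
#' @param trfc a [time_resolved_fc()].
#' @param source_label label carried along for pooling.
#' @return An `fcd_summary`: `correlations` (vector in `[-1, 1]`),
#'   `source_label`, `exclusion_lag_windows`.
#' @export
fcd_distribution <- function(trfc, source_label = "model") {
  stopifnot(inherits(trfc, "time_resolved_fc"))
  W <- dim(trfc$matrices)[3]
  if (W < 2) stop("need at least 2 windows")
  up <- upper.tri(trfc$matrices[, , 1])
  vecs <- apply(trfc$matrices, 3, function(m) m[up])
  e <- ceiling(trfc$spec$rect_width_trs / trfc$spec$step_trs)
  cc <- stats::cor(vecs)
  keep <- which(outer(seq_len(W), seq_len(W),
                      function(a, b) b - a >= e))
  structure(list(correlations = cc[keep], source_label = source_label,
                 exclusion_lag_windows = e),
            class = "fcd_summary")
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Sup-norm distance between the empirical CDFs (the two-sample KS
#' statistic), used to compare modeled and reference FCD distributions.
#'
#' @param a,b numeric vectors or `fcd_summary` objects.
#' @return The KS distance in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  va <- if (inherits(a, "fcd_summary")) a$correlations else as.numeric(a)
  vb <- if (inherits(b, "fcd_summary")) b$correlations else as.numeric(b)
  if (length(va) == 0 || length(vb) == 0) stop("empty sample")
  unname(suppressWarnings(stats::ks.test(va, vb, exact = FALSE)$statistic))
}
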