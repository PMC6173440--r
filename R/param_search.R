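#' Parameter grid for the model search
#'
#' Defaults reproduce the full search space: coupling 2.5-70 in steps of
#' 2.5 (28 values) by mean delay 2-17 ms in steps of 1 ms (16 values),
#' 448 parameter sets.
#'
#' @param coupling_values strictly increasing coupling constants.
#' @param mean_delay_values_ms strictly increasing mean delays (ms).
#' @return A `parameter_grid`: data frame of all (coupling, mean_delay_ms)
#'   combinations, delay varying fastest.
#' @export
parameter_grid <- function(coupling_values = seq(2.5, 70, by = 2.5),
                           mean_delay_values_ms = seq(2, 17, by = 1)) {
  if (any(diff(coupling_values) <= 0) || any(diff(mean_delay_values_ms) <= 0))
    stop("grid values must be strictly increasing")
  g <- expand.grid(mean_delay_ms = mean_delay_values_ms,
                   coupling = coupling_values)[, c(2, 1)]
  structure(g, class = c("parameter_grid", "data.frame"))
}

#' Simulation / preprocessing options for one modeled BOLD sample
#'
#' Bundles everything [model_bold_sample()] needs. The `"paper"` preset uses
#' the full-scale settings (0.2-ms steps, 1186 volumes at TR 0.72 s,
#' deterministic integration); the `"reduced"` preset is a desk-scale
#' variant (1-ms steps, 360 volumes = ~259 s, stochastic integration with phase noise SD 1.25 rad/s).
#'
#' @param preset `"paper"` or `"reduced"`.
#' @param ... overrides of individual fields (`dt_ms`, `noise_sd_rad_s`,
#'   `natural_frequency_hz`, `tr_seconds`, `run_length_timepoints`,
#'   `transient_discard_s`, `band`, `balloon`, `window`).
#' @return A `model_opts` list.
#' @export
model_opts <- function(preset = c("reduced", "paper"), ...) {
  preset <- match.arg(preset)
  o <- if (preset == "paper")
    list(dt_ms = 0.2, noise_sd_rad_s = 0, natural_frequency_hz = 60,
         tr_seconds = 0.72, run_length_timepoints = 1186,
         transient_discard_s = 20, band = c(1 / (66 * 0.72), 0.1),
         balloon = balloon_params(), window = window_spec())
  else
    list(dt_ms = 1, noise_sd_rad_s = 1.25, natural_frequency_hz = 60,
         tr_seconds = 0.72, run_length_timepoints = 360,
         transient_discard_s = 20, band = c(1 / (66 * 0.72), 0.1),
         balloon = balloon_params(), window = window_spec())
  dots <- list(...)
  o[names(dots)] <- dots
  structure(o, class = "model_opts")
}

#' One modeled BOLD sample
#'
#' Runs the full forward pipeline: delayed-Kuramoto integration, sine
#' transform and 1-kHz decimation, Balloon/Windkessel conversion, band-pass,
#' TR decimation, and global-signal regression.
#'
#' @param sc a normalized [structural_connectome()].
#' @param coupling global coupling constant.
#' @param mean_delay_ms mean interaction delay (ms).
#' @param seed integer seed for this sample.
#' @param opts a [model_opts()].
#' @return A list: `bold` (preprocessed [bold_dataset()]), `order`
#'   (an `order_parameter` for the run).
#' @export
model_bold_sample <- function(sc, coupling, mean_delay_ms, seed,
                              opts = model_opts()) {
  duration <- opts$transient_discard_s +
    opts$run_length_timepoints * opts$tr_seconds + 2
  cfg <- kuramoto_config(coupling = coupling, mean_delay_ms = mean_delay_ms,
                         natural_frequency_hz = opts$natural_frequency_hz,
                         dt_ms = opts$dt_ms,
                         noise_sd_rad_s = opts$noise_sd_rad_s,
                         duration_s = duration,
                         transient_discard_s = opts$transient_discard_s,
                         seed = seed)
  traj <- simulate_kuramoto(sc, cfg)
  op <- order_parameter(traj)
  act <- phases_to_activity(traj)
  raw <- balloon_windkessel(act, opts$balloon)
  bold <- preprocess_bold(raw, band = opts$band,
                          target_tr_s = opts$tr_seconds,
                          run_length_timepoints = opts$run_length_timepoints)
  list(bold = bold, order = op)
}

#' Reference summaries for the parameter search
#'
#' Reduces reference BOLD runs (empirical-like or synthetic) to the
#' quantities the search compares against: the run-averaged long-timescale
#' FC, the pooled FCD distribution, and the run-averaged temporal SDs of
#' mean participation and modularity.
#'
#' @param bold_runs list of [bold_dataset()] runs.
#' @param wspec a [window_spec()].
#' @param cart_restarts Louvain restarts per window.
#' @param seed integer seed (community detection).
#' @return A `reference_summaries` list: `long_fc` (N x N mean Fisher-z),
#'   `fcd` (pooled correlations), `sd_meanP`, `sd_Q`.
#' @export
reference_summaries <- function(bold_runs, wspec = window_spec(),
                                cart_restarts = 100, seed = 1) {
  zsum <- NULL
  fcd_all <- numeric(0)
  sdP <- sdQ <- numeric(length(bold_runs))
  for (i in seq_along(bold_runs)) {
    b <- bold_runs[[i]]
    z <- long_timescale_fc(b)$values
    zsum <- if (is.null(zsum)) z else zsum + z
    trfc <- time_resolved_fc(b, wspec)
    fcd_all <- c(fcd_all, fcd_distribution(trfc, "reference")$correlations)
    prof <- cartography(trfc, n_restarts = cart_restarts, seed = seed + i)
    sdP[i] <- stats::sd(rowMeans(prof$participation))
    sdQ[i] <- stats::sd(prof$modularity)
  }
  structure(list(long_fc = zsum / length(bold_runs), fcd = fcd_all,
                 sd_meanP = mean(sdP), sd_Q = mean(sdQ)),
            class = "reference_summaries")
}

#' Fluctuation-magnitude ratio
#'
#' Ratio of the temporal SD of a modeled per-window metric series to the
#' reference SD of the same metric.
#'
#' @param model_series per-window metric values of one modeled sample.
#' @param empirical_reference_sd positive reference SD.
#' @return `sd(model_series) / empirical_reference_sd`.
#' @export
fluctuation_ratio <- function(model_series, empirical_reference_sd) {
  if (length(model_series) < 2) stop("need at least 2 values")
  if (empirical_reference_sd <= 0) stop("reference SD must be positive")
  stats::sd(model_series) / empirical_reference_sd
}

#' First-stage selection
#'
#' Keeps parameter sets whose model-vs-reference long-timescale FC
#' correlation over structurally connected pairs exceeds `corr_threshold`
#' and whose FCD KS distance is below `ks_threshold` (both strict).
#'
#' @param results data frame with columns `corr_direct` and `ks_fcd`.
#' @param corr_threshold,ks_threshold selection thresholds (defaults 0.33).
#' @return `results` with a logical `selected` column.
#' @export
stage1_select <- function(results, corr_threshold = 0.33,
                          ks_threshold = 0.33) {
  results$selected <- results$corr_direct > corr_threshold &
    results$ks_fcd < ks_threshold
  results
}

#' Second-stage selection
#'
#' Scores each candidate by the mean absolute deviation of its two mean
#' fluctuation ratios from one, `score = (|1 - ratio_meanP| + |1 - ratio_Q|) / 2`,
#' and returns the candidate with the smallest score (ties broken by
#' smaller coupling, then smaller delay).
#'
#' @param results data frame with columns `coupling`, `mean_delay_ms`,
#'   `ratio_meanP`, `ratio_Q`.
#' @return A list: `best` (one-row data frame), `ranking` (full table with
#'   `score`, ordered best-first).
#' @export
stage2_select <- function(results) {
  if (nrow(results) < 1) stop("need at least one candidate")
  results$score <- (abs(1 - results$ratio_meanP) +
                    abs(1 - results$ratio_Q)) / 2
  ord <- order(results$score, results$coupling, results$mean_delay_ms)
  ranking <- results[ord, , drop = FALSE]
  list(best = ranking[1, , drop = FALSE], ranking = ranking)
}

#' Synchrony matching on a surrogate connectome
#'
#' With the mean delay fixed, simulates the model on the surrogate for every
#' coupling in `k_grid` and returns the coupling whose mean order parameter
#' (global synchrony) is closest to `target_synchrony`; ties go to the
#' smallest coupling. A coupling whose simulation diverges is skipped with a
#' warning.
#'
#' @param surrogate a (surrogate) [structural_connectome()].
#' @param target_synchrony synchrony of the original-connectome simulation.
#' @param fixed_mean_delay_ms mean delay used for all simulations.
#' @param k_grid coupling values to try.
#' @param seed integer seed.
#' @param opts a [model_opts()]; only the simulation fields are used.
#' @param duration_s simulation length for the synchrony probe (default
#'   40 s including the transient).
#' @return A list: `coupling` (chosen k), `synchrony` (per-k values).
#' @export
surrogate_synchrony_match <- function(surrogate, target_synchrony,
                                      fixed_mean_delay_ms,
                                      k_grid = seq(2.5, 70, by = 2.5),
                                      seed = 1, opts = model_opts(),
                                      duration_s = 40) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty")
  syn <- rep(NA_real_, length(k_grid))
  for (i in seq_along(k_grid)) {
    cfg <- kuramoto_config(coupling = k_grid[i],
                           mean_delay_ms = fixed_mean_delay_ms,
                           natural_frequency_hz = opts$natural_frequency_hz,
                           dt_ms = opts$dt_ms,
                           noise_sd_rad_s = opts$noise_sd_rad_s,
                           duration_s = duration_s,
                           transient_discard_s = opts$transient_discard_s,
                           seed = seed + i)
    traj <- try(simulate_kuramoto(surrogate, cfg), silent = TRUE)
    if (inherits(traj, "try-error")) {
      warning("simulation diverged at k = ", k_grid[i], "; skipped")
      next
    }
    syn[i] <- order_parameter(traj)$synchrony
  }
  if (all(is.na(syn))) stop("all couplings diverged")
  dev <- abs(syn - target_synchrony)
  best <- which(dev == min(dev, na.rm = TRUE))[1]   # ties -> smallest k
  list(coupling = k_grid[best], synchrony = stats::setNames(syn, k_grid))
}

# per-(set, sample) seed derivation: documented, bounded below 2^31
derive_seed <- function(base, set_index, sample_index) {
  as.integer((base + 7919 * set_index + 131 * sample_index) %% 2147483647L)
}

#' Two-stage grid search over coupling and mean delay
#'
#' Stage 1: for every parameter set, simulate `n_samples_stage1` samples,
#' average their long-timescale FC, correlate it with the reference FC over
#' all node pairs and over structurally connected pairs, pool the samples'
#' FCD distributions and measure the KS distance to the reference FCD;
#' select sets by [stage1_select()]. Stage 2: for the selected sets,
#' simulate `n_samples_stage2` fresh samples, compute per-sample temporal
#' SDs of mean participation and modularity, form fluctuation ratios against
#' the reference SDs, and pick the best set by [stage2_select()].
#'
#' @param sc a normalized [structural_connectome()].
#' @param grid a [parameter_grid()].
#' @param reference a [reference_summaries()].
#' @param n_samples_stage1,n_samples_stage2 simulation samples per set.
#' @param seed base seed; all per-sample seeds derive from it.
#' @param opts a [model_opts()].
#' @param cart_restarts Louvain restarts per window in stage 2.
#' @return A list: `stage1` (per-set table with `selected`), `stage2`
#'   (candidate table with ratios and `score`), `selection` (one-row data
#'   frame or `NULL` when stage 1 selected nothing).
#' @export
run_grid <- function(sc, grid, reference, n_samples_stage1 = 10,
                     n_samples_stage2 = 100, seed = 1,
                     opts = model_opts(), cart_restarts = 100) {
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(reference, "reference_summaries"))
  up <- upper.tri(reference$long_fc)
  direct <- up & sc$weights > 0
  s1 <- cbind(grid, corr_all = NA_real_, corr_direct = NA_real_,
              ks_fcd = NA_real_)
  for (g in seq_len(nrow(grid))) {
    zsum <- NULL
    fcd_pool <- numeric(0)
    for (s in seq_len(n_samples_stage1)) {
      samp <- model_bold_sample(sc, grid$coupling[g], grid$mean_delay_ms[g],
                                seed = derive_seed(seed, g, s), opts = opts)
      z <- long_timescale_fc(samp$bold)$values
      zsum <- if (is.null(zsum)) z else zsum + z
      trfc <- time_resolved_fc(samp$bold, opts$window)
      fcd_pool <- c(fcd_pool, fcd_distribution(trfc)$correlations)
    }
    zbar <- zsum / n_samples_stage1
    s1$corr_all[g] <- stats::cor(zbar[up], reference$long_fc[up])
    s1$corr_direct[g] <- stats::cor(zbar[direct], reference$long_fc[direct])
    s1$ks_fcd[g] <- ks_distance(fcd_pool, reference$fcd)
  }
  s1 <- stage1_select(s1)
  cand <- which(s1$selected)
  if (length(cand) == 0)
    return(list(stage1 = s1, stage2 = NULL, selection = NULL))
  s2 <- cbind(grid[cand, , drop = FALSE], ratio_meanP = NA_real_,
              ratio_Q = NA_real_)
  for (ci in seq_along(cand)) {
    g <- cand[ci]
    rP <- rQ <- numeric(n_samples_stage2)
    for (s in seq_len(n_samples_stage2)) {
      samp <- model_bold_sample(sc, grid$coupling[g], grid$mean_delay_ms[g],
                                seed = derive_seed(seed, g,
                                                   n_samples_stage1 + s),
                                opts = opts)
      trfc <- time_resolved_fc(samp$bold, opts$window)
      prof <- cartography(trfc, n_restarts = cart_restarts,
                          seed = derive_seed(seed, g, 100000 + s))
      rP[s] <- fluctuation_ratio(rowMeans(prof$participation),
                                 reference$sd_meanP)
      rQ[s] <- fluctuation_ratio(prof$modularity, reference$sd_Q)
    }
    s2$ratio_meanP[ci] <- mean(rP)
    s2$ratio_Q[ci] <- mean(rQ)
  }
  sel <- stage2_select(s2)
  list(stage1 = s1, stage2 = sel$ranking, selection = sel$best)
}

#' Fluctuation ratios on surrogate connectomes
#'
#' For each of `n_surrogates` degree/strength-preserving surrogates of `sc`:
#' match the original simulation's synchrony by varying the coupling at
#' fixed mean delay, simulate `n_samples` BOLD samples at the matched
#' coupling, and compute the mean fluctuation ratios of mean participation
#' and modularity against the supplied reference SDs.
#'
#' @param sc the original (normalized) [structural_connectome()].
#' @param coupling,mean_delay_ms operating point of the original model.
#' @param reference a [reference_summaries()] giving `sd_meanP`, `sd_Q`.
#' @param n_surrogates number of surrogates (default 5).
#' @param n_samples BOLD samples per surrogate (default 2).
#' @param k_grid couplings tried during synchrony matching.
#' @param seed base seed.
#' @param opts a [model_opts()].
#' @param cart_restarts Louvain restarts per window.
#' @return A data frame with one row per surrogate: `matched_k`,
#'   `synchrony`, `ratio_meanP`, `ratio_Q`.
#' @export
surrogate_fluctuation_ratios <- function(sc, coupling, mean_delay_ms,
                                         reference, n_surrogates = 5,
                                         n_samples = 2,
                                         k_grid = seq(10, 70, by = 10),
                                         seed = 1, opts = model_opts(),
                                         cart_restarts = 100) {
  cfg <- kuramoto_config(coupling = coupling, mean_delay_ms = mean_delay_ms,
                         natural_frequency_hz = opts$natural_frequency_hz,
                         dt_ms = opts$dt_ms,
                         noise_sd_rad_s = opts$noise_sd_rad_s,
                         duration_s = 40,
                         transient_discard_s = opts$transient_discard_s,
                         seed = seed)
  target <- order_parameter(simulate_kuramoto(sc, cfg))$synchrony
  out <- data.frame(surrogate = seq_len(n_surrogates), matched_k = NA_real_,
                    synchrony = NA_real_, ratio_meanP = NA_real_,
                    ratio_Q = NA_real_)
  for (i in seq_len(n_surrogates)) {
    sur <- rewire_surrogate(sc, seed = derive_seed(seed, i, 0))
    match <- surrogate_synchrony_match(sur, target, mean_delay_ms,
                                       k_grid = k_grid,
                                       seed = derive_seed(seed, i, 1),
                                       opts = opts)
    out$matched_k[i] <- match$coupling
    out$synchrony[i] <- min(match$synchrony[!is.na(match$synchrony)][
      which.min(abs(match$synchrony - target))])
    rP <- rQ <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      samp <- model_bold_sample(sur, match$coupling, mean_delay_ms,
                                seed = derive_seed(seed, i, 10 + s),
                                opts = opts)
      trfc <- time_resolved_fc(samp$bold, opts$window)
      prof <- cartography(trfc, n_restarts = cart_restarts,
                          seed = derive_seed(seed, i, 200 + s))
      rP[s] <- fluctuation_ratio(rowMeans(prof$participation),
                                 reference$sd_meanP)
      rQ[s] <- fluctuation_ratio(prof$modularity, reference$sd_Q)
    }
    out$ratio_meanP[i] <- mean(rP)
    out$ratio_Q[i] <- mean(rQ)
  }
  out
}
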