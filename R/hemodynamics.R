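#' BOLD dataset container
#'
#' @param signal N x T matrix of regional BOLD signal (regions in rows).
#' @param tr_seconds sampling interval of the columns, in seconds.
#' @param run_label free-text label.
#' @return A `bold_dataset` list.
#' @export
bold_dataset <- function(signal, tr_seconds, run_label = "run") {
  signal <- as.matrix(signal)
  if (any(!is.finite(signal))) stop("BOLD signal must be finite")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(list(signal = signal, tr_seconds = tr_seconds,
                 run_label = run_label),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("BOLD dataset '%s': %d regions x %d samples, TR = %g s (%.1f s)\n",
              x$run_label, nrow(x$signal), ncol(x$signal), x$tr_seconds,
              ncol(x$signal) * x$tr_seconds))
  invisible(x)
}

#' Phase trajectory to regional neural activity
#'
#' Transforms phases to activity `r_n(t) = sin(theta_n(t))` and decimates to
#' a 1 kHz sampling rate by keeping every `factor`-th sample starting at the
#' first one; the trajectory sample rate must be an integer multiple of 1 kHz.
#'
#' @param traj a `phase_trajectory`.
#' @param target_rate_hz output rate (default 1000).
#' @return A `neural_activity` list: `activity` (N x T, in `[-1, 1]`),
#'   `sample_rate_hz`.
#' @export
phases_to_activity <- function(traj, target_rate_hz = 1000) {
  stopifnot(inherits(traj, "phase_trajectory"))
  fac <- traj$sample_rate_hz / target_rate_hz
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("trajectory sample rate must be an integer multiple of the target rate")
  fac <- as.integer(round(fac))
  idx <- seq(1, ncol(traj$phases), by = fac)
  structure(list(activity = sin(traj$phases[, idx, drop = FALSE]),
                 sample_rate_hz = target_rate_hz),
            class = "neural_activity")
}

#' Balloon/Windkessel hemodynamic parameters
#'
#' Canonical parameter set of the single-compartment Balloon/Windkessel
#' model: vasodilatory signal decay `kappa`, flow feedback `gamma`, venous
#' transit time `tau0`, vessel stiffness `alpha`, resting oxygen extraction
#' `E0`, resting venous volume fraction `V0`, and the BOLD readout
#' coefficients `k1 = 7*E0`, `k2 = 2`, `k3 = 2*E0 - 0.2`. All values are
#' overridable.
#'
#' @param signal_decay `kappa` (1/s).
#' @param feedback `gamma` (1/s).
#' @param transit_time `tau0` (s).
#' @param stiffness `alpha`, in (0, 1).
#' @param resting_extraction `E0`, in (0, 1).
#' @param resting_volume `V0`.
#' @param bold_coefficients `c(k1, k2, k3)`; `NULL` derives them from `E0`.
#' @param integration_dt_s integration step (default 1 ms).
#' @return A `balloon_params` list.
#' @export
balloon_params <- function(signal_decay = 0.65, feedback = 0.41,
                           transit_time = 0.98, stiffness = 0.32,
                           resting_extraction = 0.34, resting_volume = 0.02,
                           bold_coefficients = NULL,
                           integration_dt_s = 0.001) {
  if (signal_decay <= 0 || feedback <= 0 || transit_time <= 0 ||
      integration_dt_s <= 0)
    stop("rates and times must be positive")
  if (stiffness <= 0 || stiffness >= 1) stop("stiffness must be in (0, 1)")
  if (resting_extraction <= 0 || resting_extraction >= 1)
    stop("resting_extraction must be in (0, 1)")
  if (is.null(bold_coefficients))
    bold_coefficients <- c(7 * resting_extraction, 2,
                           2 * resting_extraction - 0.2)
  structure(list(signal_decay = signal_decay, feedback = feedback,
                 transit_time = transit_time, stiffness = stiffness,
                 resting_extraction = resting_extraction,
                 resting_volume = resting_volume,
                 bold_coefficients = bold_coefficients,
                 integration_dt_s = integration_dt_s),
            class = "balloon_params")
}

#' Balloon/Windkessel conversion of neural activity to raw BOLD
#'
#' Integrates, per node, the hemodynamic states (vasodilatory signal `s`,
#' inflow `f`, venous volume `v`, deoxyhemoglobin `q`) from rest
#' `(0, 1, 1, 1)` with input `z = r_n(t)` using Heun's method, and reads out
#' `y = V0*(k1*(1-q) + k2*(1-q/v) + k3*(1-v))`.
#'
#' @param activity a `neural_activity` (or N x T matrix at 1 kHz).
#' @param params a [balloon_params()].
#' @return A [bold_dataset()] at the activity sampling rate.
#' @export
balloon_windkessel <- function(activity, params = balloon_params()) {
  act <- if (inherits(activity, "neural_activity")) activity$activity
         else as.matrix(activity)
  rate <- if (inherits(activity, "neural_activity")) activity$sample_rate_hz
          else 1000
  if (any(!is.finite(act))) stop("activity must be finite")
  k <- params$bold_coefficients
  y <- cpp_balloon(act, params$integration_dt_s, params$signal_decay,
                   params$feedback, params$transit_time, params$stiffness,
                   params$resting_extraction, params$resting_volume,
                   k[1], k[2], k[3])
  bold_dataset(y, tr_seconds = 1 / rate, run_label = "balloon_raw")
}

#' Preprocess raw modeled BOLD
#'
#' Mirrors the treatment of reference rs-fMRI data: anti-alias decimation to
#' the target TR, zero-phase second-order Butterworth band-pass (defaults
#' 1/(66 TRs) = 0.021 Hz to 0.1 Hz), truncation to the run length, and
#' global-signal regression (per-node residual after regressing the
#' across-node mean signal with intercept).
#'
#' Decimation averages non-overlapping blocks of `round(TR / dt)` raw
#' samples, which low-pass protects the band of interest; the band-pass is
#' then applied at the TR rate where the normalized cutoffs are numerically
#' well-conditioned.
#'
#' @param raw a [bold_dataset()] at a high sampling rate.
#' @param band `c(low_hz, high_hz)` pass band.
#' @param target_tr_s output TR (default 0.72 s).
#' @param run_length_timepoints output volumes; the series is truncated to
#'   this length after filtering.
#' @param global_signal_regression logical (default TRUE).
#' @return A [bold_dataset()] with `run_length_timepoints` volumes at
#'   `target_tr_s`.
#' @export
preprocess_bold <- function(raw, band = c(1 / (66 * 0.72), 0.1),
                            target_tr_s = 0.72, run_length_timepoints,
                            global_signal_regression = TRUE) {
  stopifnot(inherits(raw, "bold_dataset"))
  fs_raw <- 1 / raw$tr_seconds
  if (fs_raw < 2 * band[2])
    stop("raw sampling rate must be at least twice the high cutoff")
  block <- round(target_tr_s / raw$tr_seconds)
  x <- raw$signal
  n_blocks <- floor(ncol(x) / block)
  if (n_blocks < run_length_timepoints)
    stop(sprintf("requested %d volumes but only %d available",
                 run_length_timepoints, n_blocks))
  idx <- rep(seq_len(n_blocks), each = block)
  dec <- t(rowsum(t(x[, seq_len(n_blocks * block), drop = FALSE]), idx,
                  reorder = TRUE)) / block
  filt <- bandpass_filter(dec, fs = 1 / target_tr_s, band = band)
  filt <- filt[, seq_len(run_length_timepoints), drop = FALSE]
  if (global_signal_regression) filt <- regress_global_signal(filt)
  bold_dataset(filt, tr_seconds = target_tr_s, run_label = raw$run_label)
}

# zero-phase 2nd-order Butterworth band-pass, forward-backward, applied
# per row after demeaning (reflection padding to tame edge transients)
bandpass_filter <- function(x, fs, band) {
  wn <- band / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1)) stop("band edges must be inside (0, Nyquist)")
  bf <- signal::butter(2, wn, type = "pass")
  t(apply(x, 1, function(r) {
    r0 <- r - mean(r)
    npad <- min(length(r0) - 1, 3 * ceiling(fs / band[1]))
    padded <- c(rev(r0[seq_len(npad)]), r0, rev(r0[length(r0) - seq_len(npad) + 1]))
    out <- signal::filtfilt(bf, padded)
    out[npad + seq_along(r0)]
  }))
}

#' Global-signal regression
#'
#' Replaces each region's time course with its residual after least-squares
#' regression on the across-region mean signal (with intercept). Residuals
#' are exactly orthogonal to the global mean regressor.
#'
#' @param x N x T signal matrix.
#' @return The N x T residual matrix.
#' @export
regress_global_signal <- function(x) {
  g <- colMeans(x)
  X <- cbind(1, g)
  coefs <- solve(crossprod(X), crossprod(X, t(x)))   # 2 x N
  x - t(X %*% coefs)
}
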