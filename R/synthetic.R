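#' Ground-truth specification for a simulated session
#'
#' Bundles everything the generator needs to produce a session with known
#' truth: the generating HRF, the activation amplitude in percent signal
#' change of the peak-normalized task regressor, AR(1) noise, slow cosine
#' drift (period beyond the 128 s high-pass cutoff, so drift columns
#' remove it by construction) and a motion spike schedule.
#'
#' @param hrf_params generating [hrf_params] (default: tailored dog).
#' @param amplitude peak percent-signal-change of the response (default 1).
#' @param noise_sd stationary SD of the AR(1) noise (default 0.7; see
#'   [snr_preset]).
#' @param ar1_phi lag-1 autocorrelation in `[0, 1)` (default 0.3).
#' @param drift_amplitude,drift_period cosine drift (default 0.5 at 200 s).
#' @param spike_rate per-scan probability of a motion spike (default 0.078).
#' @param spike_magnitude translation jump size in mm (default 1).
#' @param seed RNG seed; the same seed reproduces the session bit for bit.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(hrf_params = hrf_preset("dog_boch2020"),
                            amplitude = 1, noise_sd = 0.7, ar1_phi = 0.3,
                            drift_amplitude = 0.5, drift_period = 200,
                            spike_rate = 0.078, spike_magnitude = 1,
                            seed = NULL) {
  stopifnot(inherits(hrf_params, "hrf_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (ar1_phi < 0 || ar1_phi >= 1)
    stop("ar1_phi must lie in [0, 1)", call. = FALSE)
  if (spike_rate < 0 || spike_rate > 1)
    stop("spike_rate must lie in [0, 1]", call. = FALSE)
  structure(list(hrf_params = hrf_params, amplitude = amplitude,
                 noise_sd = noise_sd, ar1_phi = ar1_phi,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, spike_rate = spike_rate,
                 spike_magnitude = spike_magnitude, seed = seed),
            class = "synthetic_truth")
}

#' Named signal-to-noise presets for the generator
#'
#' `"study_like"` is calibrated once so that single-subject FIR curves
#' from the block paradigm have peak-bin SNR in roughly \[1.5, 4\] and the
#' fit of the generating kernel to a subject's FIR curve lands near
#' R-squared 0.6 — the regime the estimation procedure is expected to work
#' in. `"clean"` is near-noise-free; `"noisy"` doubles the noise.
#'
#' @param name preset name.
#' @param ... overrides passed on to [synthetic_truth].
#' @return A `synthetic_truth`.
#' @export
snr_preset <- function(name = c("study_like", "clean", "noisy"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    study_like = list(amplitude = 1, noise_sd = 0.7),
    clean      = list(amplitude = 1, noise_sd = 1e-6),
    noisy      = list(amplitude = 1, noise_sd = 0.9))
  do.call(synthetic_truth, utils::modifyList(args, list(...)))
}

#' Block-design paradigm: flickering-checkerboard run
#'
#' Six 10 s stimulation blocks alternating with 10 s baseline, starting
#' with baseline; 134 scans at TR = 1 s.
#'
#' @return List with `events` ([event_table], onsets 10, 30, ..., 110 s),
#'   `n_scans` (134) and `tr` (1).
#' @export
make_exp1_paradigm <- function() {
  ev <- event_table(onset = seq(10, 110, by = 20), duration = 10,
                    trial_type = "checkerboard", run_length = 134)
  list(events = ev, n_scans = 134L, tr = 1)
}

#' Event-related paradigm: two jittered face-processing runs
#'
#' 60 trials of 3 s visual stimulation split across two 270-scan runs
#' (TR = 1 s), inter-trial baseline drawn uniformly from \[3, 7\] s, run
#' lead-in of at least 5 s. If a drawn schedule does not fit the run it is
#' re-drawn (up to `max_attempts`, with a warning).
#'
#' @param seed RNG seed.
#' @param n_trials_per_run trials per run (default 30).
#' @param n_scans scans per run (default 270).
#' @param max_attempts re-draw limit per run.
#' @return List of two run lists, each with `events`, `n_scans`, `tr`.
#' @export
make_exp2_paradigm <- function(seed = NULL, n_trials_per_run = 30L,
                               n_scans = 270L, max_attempts = 100L) {
  if (!is.null(seed)) set.seed(seed)
  draw_run <- function() {
    for (att in seq_len(max_attempts)) {
      onsets <- numeric(n_trials_per_run)
      onsets[1] <- stats::runif(1, 5, 7)
      if (n_trials_per_run > 1)
        for (i in 2:n_trials_per_run)
          onsets[i] <- onsets[i - 1] + 3 + stats::runif(1, 3, 7)
      if (onsets[n_trials_per_run] + 3 <= n_scans) {
        if (att > 1) warning("paradigm re-drawn ", att - 1, " time(s)")
        return(event_table(onset = onsets, duration = 3,
                           trial_type = "face", run_length = n_scans))
      }
    }
    stop("could not fit ", n_trials_per_run, " trials into ", n_scans,
         " scans after ", max_attempts, " attempts", call. = FALSE)
  }
  lapply(1:2, function(r)
    list(events = draw_run(), n_scans = as.integer(n_scans), tr = 1))
}

ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive"))
}

# rows = series, columns = time; recursion vectorized over rows
ar1_noise_matrix <- function(nrow, n, sd, phi) {
  if (sd == 0) return(matrix(0, nrow, n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(stats::rnorm(nrow * n, 0, innov_sd), nrow, n)
  e[, 1] <- stats::rnorm(nrow, 0, sd)  # stationary start
  for (t in 2:n) e[, t] <- phi * e[, t - 1] + e[, t]
  e
}

#' Simulate a region-of-interest BOLD time series
#'
#' `signal = amplitude * (stimulus convolved with the truth HRF,
#' peak-normalized) + cosine drift + AR(1) Gaussian noise` with stationary
#' variance `noise_sd^2`. Peak normalization of the regressor makes
#' `amplitude` read directly as peak percent signal change.
#'
#' @param events an [event_table] (see the paradigm generators).
#' @param truth a [synthetic_truth].
#' @param n_scans,tr run geometry.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return Numeric series of length `n_scans`, with attributes
#'   `clean_signal` (noise- and drift-free) and `truth`.
#' @export
simulate_roi_timeseries <- function(events, truth, n_scans, tr = 1,
                                    seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  spec <- sampling_spec(tr)
  k <- sample_double_gamma(truth$hrf_params, spec$dt)
  u <- boxcar_microtime(events, n_scans, spec)
  reg <- convolve_downsample(u, k, spec)
  if (max(abs(reg)) > 0) reg <- reg / max(reg)
  signal <- truth$amplitude * reg
  tt <- (seq_len(n_scans) - 1) * tr
  drift <- truth$drift_amplitude * cos(2 * pi * tt / truth$drift_period)
  y <- signal + drift + ar1_noise(n_scans, truth$noise_sd, truth$ar1_phi)
  attr(y, "clean_signal") <- signal
  attr(y, "truth") <- truth
  y
}

#' Simulate a realignment-parameter trace with motion spikes
#'
#' A smooth random walk (kept well below the scrubbing threshold) plus
#' sustained Bernoulli jumps sized to exceed it, emulating sessions where
#' a known fraction of scans gets scrubbed.
#'
#' @param n_scans number of scans.
#' @param spike_rate per-scan spike probability (scans 2..n).
#' @param spike_magnitude translation jump in mm (must exceed the FD
#'   threshold to be flagged; default 1).
#' @param seed RNG seed.
#' @return Matrix `n_scans` x 6 of class `motion_trace` with attribute
#'   `spike_scans` (the scheduled spike indices).
#' @export
simulate_motion <- function(n_scans, spike_rate = 0.078,
                            spike_magnitude = 1, seed = NULL) {
  if (spike_rate < 0 || spike_rate > 1)
    stop("spike_rate must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_scans)
  steps <- cbind(matrix(stats::rnorm(3 * n, 0, 0.015), n, 3),
                 matrix(stats::rnorm(3 * n, 0, 0.0002), n, 3))
  steps[1, ] <- 0
  spikes <- which(stats::runif(n) < spike_rate)
  spikes <- spikes[spikes > 1]
  if (length(spikes))
    steps[spikes, 1] <- steps[spikes, 1] +
      spike_magnitude * sample(c(-1, 1), length(spikes), replace = TRUE)
  m <- apply(steps, 2, cumsum)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  attr(m, "spike_scans") <- spikes
  class(m) <- c("motion_trace", class(m))
  m
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter; `sigma = fwhm / sqrt(8 log 2)` per axis,
#' expressed in voxels through the voxel size. Provided for the volume
#' simulator only (real-data preprocessing is out of scope).
#'
#' @param vol 3D array.
#' @param fwhm full width at half maximum in mm (0 = no smoothing).
#' @param voxel_size numeric length-3, mm per voxel.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(vol, fwhm, voxel_size = c(1.5, 1.5, 2)) {
  if (fwhm == 0) return(vol)
  sig <- fwhm / sqrt(8 * log(2)) / voxel_size
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    apply_along <- function(v) {
      n <- length(v)
      vp <- c(rep(v[1], r), v, rep(v[n], r))  # replicate-pad edges
      stats::convolve(vp, rev(k), type = "open")[(2 * r + 1):(2 * r + n)]
    }
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    b <- apply(matrix(b, db[1]), 2, apply_along)
    b <- array(b, db)
    aperm(b, order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax, sig[ax])
  vol
}

#' Ellipsoidal ROI mask on a voxel grid
#'
#' @param dims grid dimensions (3 integers).
#' @param center voxel coordinates of the centre.
#' @param radii semi-axes in voxels.
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(dims, center, radii) {
  if (any(center - radii < 1) || any(center + radii > dims))
    stop("ROI ellipsoid extends outside the grid", call. = FALSE)
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  inside <- ((g$x - center[1]) / radii[1])^2 +
            ((g$y - center[2]) / radii[2])^2 +
            ((g$z - center[3]) / radii[3])^2 <= 1
  array(inside, dims)
}

#' Simulate a full 4D session with an active visual-cortex ellipsoid
#'
#' ROI voxels carry the shared task signal from
#' [simulate_roi_timeseries] plus independent per-voxel AR(1) noise;
#' background voxels are noise-only. Optional Gaussian smoothing emulates
#' the preprocessing of real acquisitions.
#'
#' @param paradigm list with `events`, `n_scans`, `tr` (see the paradigm
#'   generators).
#' @param truth a [synthetic_truth].
#' @param dims grid dimensions (default 32 x 32 x 24).
#' @param roi_center,roi_radii ellipsoid specification in voxels
#'   (defaults place a small occipital-like blob).
#' @param fwhm smoothing FWHM in mm (default 0: off).
#' @param voxel_size mm per voxel (default 1.5 x 1.5 x 2).
#' @param seed RNG seed.
#' @return List of class `session`: `data` (4D array), `events`,
#'   `motion` (a `motion_trace`), `roi_mask`, `truth`, `tr`,
#'   `roi_signal` (the noise-free ROI time course).
#' @export
simulate_volume_session <- function(paradigm, truth,
                                    dims = c(32L, 32L, 24L),
                                    roi_center = c(16, 26, 12),
                                    roi_radii = c(4, 3, 3),
                                    fwhm = 0, voxel_size = c(1.5, 1.5, 2),
                                    seed = truth$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_scans <- paradigm$n_scans
  mask <- ellipsoid_mask(dims, roi_center, roi_radii)
  signal <- simulate_roi_timeseries(paradigm$events, truth, n_scans,
                                    paradigm$tr, seed = NULL)
  clean <- attr(signal, "clean_signal")
  nvox <- prod(dims)
  flat <- ar1_noise_matrix(nvox, n_scans, truth$noise_sd, truth$ar1_phi)
  tt <- (seq_len(n_scans) - 1) * paradigm$tr
  drift_series <- truth$drift_amplitude *
    cos(2 * pi * tt / truth$drift_period)
  flat <- sweep(flat, 2, drift_series, `+`)
  roi_idx <- which(mask)
  flat[roi_idx, ] <- sweep(flat[roi_idx, , drop = FALSE], 2, clean, `+`)
  data <- array(t(flat), c(n_scans, dims))
  data <- aperm(data, c(2, 3, 4, 1))
  if (fwhm > 0)
    for (s in seq_len(n_scans))
      data[, , , s] <- gaussian_smooth_3d(data[, , , s], fwhm, voxel_size)
  motion <- simulate_motion(n_scans, truth$spike_rate,
                            truth$spike_magnitude, seed = NULL)
  structure(list(data = data, events = paradigm$events, motion = motion,
                 roi_mask = mask, truth = truth, tr = paradigm$tr,
                 roi_signal = clean),
            class = "session")
}

#' Simulate a cohort of FIR curves through the full extraction pathway
#'
#' For each subject: simulate an ROI series under the paradigm and truth,
#' simulate motion, build nuisance columns (drift, realignment, spikes)
#' and fit the FIR model — i.e. the same path real data would take.
#'
#' @param n_subjects cohort size.
#' @param paradigm list with `events`, `n_scans`, `tr`.
#' @param truth a [synthetic_truth].
#' @param n_bins FIR bins (20 for the block design).
#' @param highpass cutoff (s) for the drift columns.
#' @param seed cohort seed; subject s uses `seed + s`.
#' @return List of [fir_estimate]s (length `n_subjects`).
#' @export
simulate_fir_cohort <- function(n_subjects, paradigm, truth, n_bins = 20,
                                highpass = 128, seed = 1) {
  lapply(seq_len(n_subjects), function(s) {
    set.seed(seed + s)
    y <- simulate_roi_timeseries(paradigm$events, truth, paradigm$n_scans,
                                 paradigm$tr, seed = NULL)
    motion <- simulate_motion(paradigm$n_scans, truth$spike_rate,
                              truth$spike_magnitude, seed = NULL)
    fd <- framewise_displacement(motion)
    sp <- spike_regressors(fd)
    nuis <- cbind(dct_drift(paradigm$n_scans, paradigm$tr, highpass),
                  unclass(motion), sp$columns)
    fit_fir(as.numeric(y), paradigm$events, n_bins, paradigm$tr,
            nuisance = nuis, subject = sprintf("sub-%02d", s))
  })
}
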