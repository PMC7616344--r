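#' First-level GLM for one run under a chosen HRF model
#'
#' Builds the complete first-level design (task regressor(s) from the
#' chosen HRF model, drift columns at the high-pass cutoff, six
#' realignment columns and FD spike regressors) and fits it to an ROI
#' series or a scans-by-voxels data matrix.
#'
#' @param y ROI time series or scans x voxels matrix.
#' @param events an [event_table].
#' @param params an [hrf_params] for the task regressor.
#' @param tr repetition time (s).
#' @param motion optional `n_scans` x 6 realignment matrix.
#' @param derivatives add temporal and dispersion derivative columns
#'   (informed basis set).
#' @param highpass high-pass cutoff in seconds (default 128).
#' @param fd_threshold scrubbing threshold in mm (default 0.5).
#' @param orthogonalize orthogonalize derivative columns (see
#'   [hrf_basis]).
#' @return List with `fit` (a [glm_result][fit_ols]), `design` (the
#'   [design_matrix][assemble_design]), `scrub_fraction`, and for
#'   derivative models `boost` (the combined amplitude H per voxel).
#' @export
first_level_glm <- function(y, events, params, tr = 1, motion = NULL,
                            derivatives = FALSE, highpass = 128,
                            fd_threshold = 0.5, orthogonalize = TRUE) {
  n_scans <- if (is.matrix(y)) nrow(y) else length(y)
  spec <- sampling_spec(tr)
  basis <- hrf_basis(params, spec$dt, derivatives = derivatives,
                     orthogonalize = orthogonalize)
  task <- task_regressors(events, basis, n_scans, spec)
  drift <- dct_drift(n_scans, tr, highpass)
  spikes <- NULL
  scrub_fraction <- 0
  if (!is.null(motion)) {
    fd <- framewise_displacement(motion)
    sp <- spike_regressors(fd, fd_threshold)
    spikes <- sp$columns
    scrub_fraction <- sp$fraction
  }
  X <- assemble_design(task, drift = drift, motion = motion,
                       spikes = spikes, tr = tr, highpass = highpass)
  fit <- fit_ols(y, X)
  out <- list(fit = fit, design = X, scrub_fraction = scrub_fraction)
  if (derivatives) {
    b <- fit$betas
    cn <- colnames(X$matrix)
    i1 <- which(cn == "task")
    i2 <- which(cn == "temporal_derivative")
    i3 <- which(cn == "dispersion_derivative")
    out$boost <- if (is.matrix(b))
      derivative_boost(b[i1, ], b[i2, ], b[i3, ])
    else derivative_boost(b[i1], b[i2], b[i3])
  }
  out
}

#' Compare per-subject model fits of two HRF parametrizations
#'
#' Computes each subject's FIR-fit R-squared under both parameter sets
#' (see [hrf_fit_r2]) and tests the paired difference with the exact
#' Wilcoxon signed-rank test.
#'
#' @param curves subjects' FIR curves (matrix, list of [fir_estimate]s or
#'   list of numeric vectors).
#' @param params_a,params_b the two [hrf_params] sets (e.g. dog vs human).
#' @inheritParams hrf_fit_r2
#' @return List with `r2_a`, `r2_b` (per subject), `mean_a`, `mean_b` and
#'   `wilcoxon` (a [wilcoxon_result][wilcoxon_signed_rank] of a vs b).
#' @export
compare_hrf_fits <- function(curves, params_a, params_b, duration = 10,
                             bin_width = 1, dt = 0.05) {
  r2a <- hrf_fit_r2(curves, params_a, duration, bin_width, dt)
  r2b <- hrf_fit_r2(curves, params_b, duration, bin_width, dt)
  list(r2_a = r2a, r2_b = r2b,
       mean_a = mean(r2a), mean_b = mean(r2b),
       wilcoxon = wilcoxon_signed_rank(r2a, r2b))
}
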