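#' Event table constructor and validation
#'
#' Events follow the BIDS convention: `onset` in seconds from the first
#' retained scan (0-based), `duration` in seconds, `trial_type` label.
#' Intervals are half-open `[onset, onset + duration)`.
#'
#' @param onset,duration numeric vectors (seconds).
#' @param trial_type character vector of condition labels (recycled).
#' @param run_length optional run length in seconds for bounds checking.
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(onset, duration, trial_type = "task",
                        run_length = NULL) {
  n <- max(length(onset), length(duration))
  ev <- data.frame(onset = as.numeric(rep_len(onset, n)),
                   duration = as.numeric(rep_len(duration, n)),
                   trial_type = as.character(rep_len(trial_type, n)),
                   stringsAsFactors = FALSE)
  if (length(onset) == 0L)
    ev <- ev[integer(0), ]
  if (any(!is.finite(ev$onset)) || any(!is.finite(ev$duration)))
    stop("onsets and durations must be finite numbers", call. = FALSE)
  if (any(ev$onset < 0))
    stop("negative onset in row(s) ",
         paste(which(ev$onset < 0), collapse = ", "), call. = FALSE)
  if (any(ev$duration < 0))
    stop("negative duration in row(s) ",
         paste(which(ev$duration < 0), collapse = ", "), call. = FALSE)
  for (ty in unique(ev$trial_type)) {
    o <- ev$onset[ev$trial_type == ty]
    if (length(o) > 1L && any(diff(o) <= 0))
      stop("onsets must be strictly increasing within condition '", ty, "'",
           call. = FALSE)
  }
  if (!is.null(run_length)) {
    over <- which(ev$onset + ev$duration > run_length + 1e-9)
    if (length(over))
      stop("event row(s) ", paste(over, collapse = ", "),
           " extend beyond the run (", run_length, " s)", call. = FALSE)
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Microtime boxcar stimulus function
#'
#' Builds the stimulus indicator on the microtime grid: 1 during
#' stimulation, 0 otherwise. Event edges at fractional bins are rounded to
#' the nearest microtime bin.
#'
#' @param events an [event_table].
#' @param n_scans number of scans in the run.
#' @param spec a [sampling_spec].
#' @return Numeric vector of length `n_scans * microtime_bins`.
#' @export
boxcar_microtime <- function(events, n_scans, spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  n_scans <- as.integer(n_scans)
  run_length <- n_scans * spec$tr
  n <- n_scans * spec$microtime_bins
  u <- numeric(n)
  if (nrow(events) == 0L) return(u)
  for (i in seq_len(nrow(events))) {
    if (events$onset[i] + events$duration[i] > run_length + 1e-9)
      stop("event row ", i, " (onset ", events$onset[i], " s, duration ",
           events$duration[i], " s) lies outside the ", run_length,
           " s run", call. = FALSE)
    from <- round(events$onset[i] / spec$dt)
    to   <- round((events$onset[i] + events$duration[i]) / spec$dt)
    if (to > from) u[(from + 1L):min(to, n)] <- 1
  }
  u
}

#' Convolve a microtime stimulus with an HRF and sample to the scan grid
#'
#' Causal discrete convolution truncated to run length, then read off at
#' the reference microtime bin of each TR.
#'
#' @param stimulus microtime stimulus vector (see [boxcar_microtime]).
#' @param kernel a `sampled_hrf` whose `dt` equals the microtime step.
#' @param spec a [sampling_spec].
#' @return Numeric regressor of length `n_scans`.
#' @export
convolve_downsample <- function(stimulus, kernel, spec) {
  stopifnot(inherits(kernel, "sampled_hrf"), inherits(spec, "sampling_spec"))
  if (abs(kernel$dt - spec$dt) > 1e-12)
    stop("kernel dt (", kernel$dt, ") must equal the microtime step (",
         spec$dt, ")", call. = FALSE)
  n <- length(stimulus)
  full <- stats::convolve(stimulus, rev(kernel$values), type = "open")
  full <- full[seq_len(n)]
  idx <- (seq_len(n %/% spec$microtime_bins) - 1L) * spec$microtime_bins +
    spec$reference_bin
  full[idx]
}

#' Finite impulse response (FIR) design columns
#'
#' One indicator column per peristimulus time bin: column `j`
#' (`j = 0 .. n_bins - 1`) is 1 at scans falling `j` bins after any event
#' onset. Overlapping events sum. Bins extending past the run for the last
#' events are truncated with a warning.
#'
#' @param events an [event_table].
#' @param n_bins number of peristimulus bins (20 for the 10 s block design,
#'   10 for the 3 s event design).
#' @param bin_width bin width in seconds (equal to the TR here).
#' @param n_scans,tr run geometry.
#' @return Matrix (`n_scans` x `n_bins`) with columns `fir_01` ...
#' @export
fir_design <- function(events, n_bins, bin_width, n_scans, tr) {
  n_scans <- as.integer(n_scans)
  if (abs(bin_width - tr) > 1e-9 && bin_width %% tr != 0)
    stop("bin_width must be a multiple of tr", call. = FALSE)
  m <- matrix(0, n_scans, n_bins,
              dimnames = list(NULL, sprintf("fir_%02d", seq_len(n_bins))))
  scans_per_bin <- as.integer(round(bin_width / tr))
  truncated <- FALSE
  for (on in events$onset) {
    s0 <- as.integer(round(on / tr))  # 0-based scan of onset
    for (j in seq_len(n_bins) - 1L) {
      rows <- s0 + j * scans_per_bin + seq_len(scans_per_bin)  # 1-based
      ok <- rows >= 1L & rows <= n_scans
      if (!all(ok)) truncated <- TRUE
      m[rows[ok], j + 1L] <- m[rows[ok], j + 1L] + 1
    }
  }
  if (truncated)
    warning("FIR window extends beyond the run for late events; truncated")
  m
}

#' Discrete-cosine high-pass drift basis
#'
#' DCT basis of order `K = floor(2 * n_scans * tr / cutoff + 1)` with the
#' constant term removed; columns are unit-norm and mutually orthonormal.
#' Drift terms are included as regressors in the GLM rather than applied
#' as a pre-filter (equivalent under OLS).
#'
#' @param n_scans,tr run geometry.
#' @param cutoff high-pass cutoff period in seconds (default 128).
#' @return Matrix (`n_scans` x `K - 1`) with columns `drift_1` ...;
#'   zero-column matrix (with a warning) when `K <= 1`.
#' @export
dct_drift <- function(n_scans, tr, cutoff = 128) {
  if (cutoff <= 2 * tr)
    stop("cutoff must exceed 2 * tr", call. = FALSE)
  n <- as.integer(n_scans)
  K <- floor(2 * n * tr / cutoff + 1)
  if (K <= 1) {
    warning("high-pass cutoff longer than twice the run; no drift columns")
    return(matrix(0, n, 0))
  }
  ks <- seq_len(K - 1)
  m <- vapply(ks, function(k)
    sqrt(2 / n) * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n)),
    numeric(n))
  colnames(m) <- sprintf("drift_%d", ks)
  m
}

#' Framewise displacement from realignment parameters
#'
#' `fd[t] = sum |delta translations| + radius * sum |delta rotations|`,
#' with `fd[1] = 0`. Rotations (radians) are converted to arc length on a
#' sphere of the given radius; the 50 mm default follows the convention of
#' Power-style scrubbing. The paradigm does not pin down a radius for dog
#' heads, so it is configurable.
#'
#' @param motion matrix (`n_scans` x 6): x, y, z translations (mm), then
#'   pitch, roll, yaw rotations (radians).
#' @param radius head radius in mm (default 50).
#' @return Numeric FD series (mm), length `n_scans`, first element 0.
#' @export
framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion must have 6 columns (3 translations mm, 3 rotations rad); ",
         "got ", ncol(motion), call. = FALSE)
  if (nrow(motion) < 2L) stop("need at least 2 scans", call. = FALSE)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Motion-spike (scrubbing) regressors from an FD series
#'
#' One one-hot column per scan whose FD strictly exceeds the threshold
#' ("exceeded" is read as a strict inequality: FD exactly at the threshold
#' is not flagged).
#'
#' @param fd framewise displacement series (mm).
#' @param threshold FD threshold in mm (default 0.5).
#' @return List with `columns` (matrix, possibly 0 columns, named
#'   `spike_<scan>`), `flagged` (scan indices) and `fraction` flagged.
#' @export
spike_regressors <- function(fd, threshold = 0.5) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  flagged <- which(fd > threshold)
  m <- matrix(0, length(fd), length(flagged))
  if (length(flagged)) {
    m[cbind(flagged, seq_along(flagged))] <- 1
    colnames(m) <- sprintf("spike_%03d", flagged)
  }
  list(columns = m, flagged = flagged,
       fraction = length(flagged) / length(fd))
}

#' Assemble a first-level design matrix
#'
#' Concatenates column groups in role order
#' task | derivatives | fir | drift | realignment | spike | constant,
#' attaches role labels, and validates: exactly one constant column, no
#' all-zero task column, unique labels, full rank among task columns,
#' no duplicate one-hot spike columns.
#'
#' @param task matrix of task regressors (convolved or FIR), with column
#'   names; may carry columns named `temporal_derivative` /
#'   `dispersion_derivative`, which get the corresponding roles.
#' @param drift,motion,spikes optional matrices (may be `NULL` or have
#'   zero columns).
#' @param tr repetition time (s).
#' @param highpass high-pass cutoff (s) recorded as metadata.
#' @return An object of class `design_matrix`: list with `matrix`, `roles`
#'   (character per column), `tr`, `highpass`, `rank`.
#' @export
assemble_design <- function(task, drift = NULL, motion = NULL, spikes = NULL,
                            tr, highpass = 128) {
  task <- as.matrix(task)
  if (is.null(colnames(task)))
    colnames(task) <- sprintf("task_%d", seq_len(ncol(task)))
  if (any(colSums(abs(task)) == 0))
    stop("all-zero task column: ",
         paste(colnames(task)[colSums(abs(task)) == 0], collapse = ", "),
         call. = FALSE)
  if (qr(task)$rank < ncol(task))
    stop("task columns are rank deficient", call. = FALSE)
  n <- nrow(task)
  task_roles <- ifelse(grepl("^fir_", colnames(task)), "fir_bin",
                ifelse(colnames(task) == "temporal_derivative",
                       "temporal_derivative",
                ifelse(colnames(task) == "dispersion_derivative",
                       "dispersion_derivative", "task")))
  groups <- list(list(task, task_roles))
  add <- function(groups, m, role) {
    if (is.null(m)) return(groups)
    m <- as.matrix(m)
    if (ncol(m) == 0L) return(groups)
    if (nrow(m) != n)
      stop(role, " columns have ", nrow(m), " rows; expected ", n,
           call. = FALSE)
    c(groups, list(list(m, rep(role, ncol(m)))))
  }
  groups <- add(groups, drift, "drift")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")[
      seq_len(ncol(motion))]
  }
  groups <- add(groups, motion, "realignment")
  if (!is.null(spikes) && is.list(spikes) && !is.matrix(spikes))
    spikes <- spikes$columns
  if (!is.null(spikes) && ncol(as.matrix(spikes)) > 0) {
    sp <- as.matrix(spikes)
    hit <- apply(sp, 2, function(col) which(col != 0))
    if (is.list(hit)) hit <- vapply(hit, `[`, 1L, 1L)
    if (anyDuplicated(hit))
      stop("duplicate spike column(s) for scan(s) ",
           paste(unique(hit[duplicated(hit)]), collapse = ", "),
           call. = FALSE)
  }
  groups <- add(groups, spikes, "spike")
  const <- matrix(1, n, 1, dimnames = list(NULL, "constant"))
  groups <- c(groups, list(list(const, "constant")))
  X <- do.call(cbind, lapply(groups, `[[`, 1L))
  roles <- unlist(lapply(groups, `[[`, 2L))
  if (anyDuplicated(colnames(X)))
    stop("duplicate column labels: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "),
         call. = FALSE)
  structure(list(matrix = X, roles = roles, tr = tr, highpass = highpass,
                 rank = qr(X)$rank),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", nrow(x$matrix), "scans x", ncol(x$matrix),
      "columns (rank", x$rank, ")\n")
  print(table(factor(x$roles,
                     levels = c("task", "temporal_derivative",
                                "dispersion_derivative", "fir_bin", "drift",
                                "realignment", "spike", "constant"))))
  invisible(x)
}

#' Convolved task regressor for an event table
#'
#' Convenience wrapper: microtime boxcar, convolution with each basis
#' kernel, downsampling to the scan grid.
#'
#' @param events an [event_table].
#' @param basis an `hrf_basis` (see [hrf_basis]) sampled at the microtime
#'   step, or a single `sampled_hrf`.
#' @param n_scans,spec run geometry ([sampling_spec]).
#' @return Matrix `n_scans` x `n_kernels`, columns named after the basis.
#' @export
task_regressors <- function(events, basis, n_scans, spec) {
  u <- boxcar_microtime(events, n_scans, spec)
  if (inherits(basis, "sampled_hrf"))
    basis <- structure(list(columns = cbind(task = basis$values),
                            dt = basis$dt, orthogonalized = FALSE),
                       class = "hrf_basis")
  if (abs(basis$dt - spec$dt) > 1e-12)
    stop("basis dt must equal the microtime step", call. = FALSE)
  out <- vapply(seq_len(ncol(basis$columns)), function(k) {
    kern <- structure(list(values = basis$columns[, k], dt = basis$dt),
                      class = "sampled_hrf")
    convolve_downsample(u, kern, spec)
  }, numeric(n_scans))
  colnames(out) <- colnames(basis$columns)
  colnames(out)[colnames(out) == "canonical"] <- "task"
  out
}
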