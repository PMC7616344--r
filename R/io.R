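#' Read a BIDS-style events.tsv
#'
#' Tab-separated with a header containing at least `onset`, `duration`
#' and `trial_type`. Extra columns are preserved as an attribute.
#' Tolerant of CRLF line endings.
#'
#' @param path file path.
#' @return An [event_table].
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("events file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in row(s) ",
           paste(bad, collapse = ", "), " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  ev <- event_table(df$onset, df$duration, df$trial_type)
  extra <- setdiff(names(df), need)
  if (length(extra)) attr(ev, "extra") <- df[extra]
  ev
}

#' @rdname read_events
#' @param events an [event_table].
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[c("onset", "duration",
                                             "trial_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column realignment-parameter text file
#'
#' Plain text, one scan per line, 6 whitespace-separated values:
#' x/y/z translations in mm followed by pitch/roll/yaw rotations in
#' radians (the SPM `rp_*.txt` dialect).
#'
#' @param path file path.
#' @param n_scans optional expected scan count; a mismatch (e.g. a
#'   truncated file) is an error.
#' @return A `motion_trace` matrix (`n_scans` x 6).
#' @export
read_motion <- function(path, n_scans = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                              "\\s+")[[1]]))
    if (length(v) != 6L || any(is.na(v)))
      stop("motion file ", path, ": line ", i,
           " does not contain 6 numeric values", call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  if (!is.null(n_scans) && nrow(m) != n_scans)
    stop("motion file has ", nrow(m), " scans; expected ", n_scans,
         call. = FALSE)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  class(m) <- c("motion_trace", class(m))
  m
}

#' @rdname read_motion
#' @param motion a motion matrix.
#' @export
write_motion <- function(motion, path) {
  m <- unclass(as.matrix(motion))
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.10e", r), collapse = "  ")), path)
  invisible(path)
}

#' Read / write FIR estimates as tidy CSV
#'
#' Columns: `subject`, `bin`, `amplitude`, `se`.
#'
#' @param estimates list of [fir_estimate]s.
#' @param path file path.
#' @return `write_fir_csv` returns `path`; `read_fir_csv` returns a list
#'   of `fir_estimate`s.
#' @export
write_fir_csv <- function(estimates, path) {
  df <- do.call(rbind, lapply(estimates, function(e)
    data.frame(subject = e$subject, bin = seq_len(e$n_bins),
               amplitude = e$amplitudes, se = e$se)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fir_csv
#' @export
read_fir_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "bin", "amplitude")
  if (!all(need %in% names(df)))
    stop("FIR csv needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$subject), function(d) {
    d <- d[order(d$bin), ]
    structure(list(amplitudes = d$amplitude,
                   se = if ("se" %in% names(d)) d$se else
                     rep(NA_real_, nrow(d)),
                   n_bins = nrow(d), bin_width = 1,
                   subject = d$subject[1], r2 = NA_real_),
              class = "fir_estimate")
  })
}

#' Write statistic volumes as NIfTI with a JSON design sidecar
#'
#' @param maps named list of 3D arrays (e.g. `list(beta = ..., t = ...)`).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param voxel_size mm per voxel for the affine.
#' @param design_info list serialized to `<prefix>_design.json`.
#' @return Invisibly, the written file paths.
#' @export
write_stat_maps <- function(maps, dir, prefix = "stat",
                            voxel_size = c(1.5, 1.5, 2),
                            design_info = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps)) {
    img <- RNifti::asNifti(maps[[nm]], pixdim = voxel_size)
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, sprintf("%s_design.json", prefix))
  jsonlite::write_json(design_info, sidecar, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, sidecar))
}

#' Write a simulated session to disk in a BIDS-like layout
#'
#' Emits NIfTI data and mask, `events.tsv`, an rp-dialect motion file and
#' a JSON file with the ground truth and provenance (seed, package
#' version).
#'
#' @param session a `session` from [simulate_volume_session].
#' @param dir output directory.
#' @param subject subject label.
#' @return Invisibly, the output directory.
#' @export
write_session <- function(session, dir, subject = "sub-01") {
  sd_ <- file.path(dir, subject)
  dir.create(sd_, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(session$data),
                     file.path(sd_, "bold.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(session$roi_mask * 1),
                     file.path(sd_, "roi_mask.nii.gz"))
  write_events(session$events, file.path(sd_, "events.tsv"))
  write_motion(session$motion, file.path(sd_, "rp.txt"))
  truth <- session$truth
  jsonlite::write_json(
    list(hrf_params = as.list(truth$hrf_params),
         amplitude = truth$amplitude, noise_sd = truth$noise_sd,
         ar1_phi = truth$ar1_phi, spike_rate = truth$spike_rate,
         seed = truth$seed,
         package_version = as.character(utils::packageVersion("caninehrf"))),
    file.path(sd_, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(sd_)
}
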