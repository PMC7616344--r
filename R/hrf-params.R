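#' Seven-parameter double-gamma HRF specification
#'
#' Constructs a validated parameter set for the double-gamma haemodynamic
#' response function. The seven parameters follow the convention used by
#' SPM-style canonical HRFs:
#'
#' * `p1` — delay of the response relative to onset (s)
#' * `p2` — delay of the undershoot relative to onset (s)
#' * `p3` — dispersion of the response
#' * `p4` — dispersion of the undershoot
#' * `p5` — ratio of the response to the undershoot
#' * `p6` — onset (s)
#' * `p7` — length of the kernel (s)
#'
#' The response component is a gamma density with shape `p1/p3` and scale
#' `p3`, so its mode falls at `p1 - p3` after onset; the undershoot is a
#' gamma density with shape `p2/p4` and scale `p4`, divided by `p5` and
#' subtracted.
#'
#' @param p1,p2,p3,p4,p5,p6,p7 numeric scalars as described above. Defaults
#'   give the canonical human HRF (6, 16, 1, 1, 6, 0, 32).
#' @return An object of class `hrf_params` (named numeric vector).
#' @export
#' @examples
#' hrf_params()                       # canonical human
#' hrf_params(p1 = 4.3, p2 = 6.6, p5 = 3)  # tailored dog estimate
hrf_params <- function(p1 = 6, p2 = 16, p3 = 1, p4 = 1, p5 = 6, p6 = 0,
                       p7 = 32) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6, p7 = p7)
  validate_hrf_params(p)
  structure(p, class = "hrf_params")
}

validate_hrf_params <- function(p) {
  if (length(p) != 7L || any(!is.finite(p)))
    stop("hrf_params requires 7 finite values p1..p7", call. = FALSE)
  if (p[["p3"]] <= 0 || p[["p4"]] <= 0)
    stop("dispersions p3 and p4 must be positive (got p3 = ", p[["p3"]],
         ", p4 = ", p[["p4"]], ")", call. = FALSE)
  if (p[["p1"]] <= 0 || p[["p2"]] <= 0 || p[["p5"]] <= 0 || p[["p7"]] <= 0)
    stop("p1, p2, p5 and p7 must be positive", call. = FALSE)
  if (p[["p6"]] < 0)
    stop("onset p6 must be non-negative", call. = FALSE)
  if (p[["p1"]] >= p[["p2"]])
    stop("response delay p1 (", p[["p1"]], ") must be smaller than ",
         "undershoot delay p2 (", p[["p2"]], ")", call. = FALSE)
  if (p[["p7"]] < p[["p2"]])
    stop("kernel length p7 must be at least the undershoot delay p2",
         call. = FALSE)
  invisible(p)
}

#' Shipped HRF parameter presets
#'
#' `"human_canonical"` is the default double-gamma parametrization
#' (6, 16, 1, 1, 6, 0, 32), peaking near 5 s. `"dog_boch2020"` is the
#' tailored dog estimate for awake-dog visual cortex (p1 = 4.3 s,
#' p2 = 6.6 s, p5 = 3, others at default), peaking roughly 2 s earlier.
#' The dog preset assumes onset p6 = 0.
#'
#' @param name preset name, `"human_canonical"` or `"dog_boch2020"`.
#' @return An `hrf_params` object.
#' @export
hrf_preset <- function(name = c("human_canonical", "dog_boch2020")) {
  name <- match.arg(name)
  switch(name,
    human_canonical = hrf_params(),
    dog_boch2020    = hrf_params(p1 = 4.3, p2 = 6.6, p5 = 3))
}

#' Read / write HRF parameters as a flat key-value config file
#'
#' The on-disk format is one `key = value` pair per line with keys
#' `p1` ... `p7`. Lines beginning with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @param params an `hrf_params` object (for writing).
#' @return `read_hrf_config` returns an `hrf_params` object;
#'   `write_hrf_config` returns `path` invisibly.
#' @export
read_hrf_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  need <- paste0("p", 1:7)
  if (!all(need %in% keys))
    stop("config must define all of ", paste(need, collapse = ", "),
         call. = FALSE)
  v <- vals[match(need, keys)]
  if (any(is.na(v))) stop("non-numeric value in HRF config", call. = FALSE)
  do.call(hrf_params, as.list(stats::setNames(v, need)))
}

#' @rdname read_hrf_config
#' @export
write_hrf_config <- function(params, path) {
  stopifnot(inherits(params, "hrf_params"))
  writeLines(sprintf("%s = %.10g", names(params), as.numeric(params)), path)
  invisible(path)
}

#' @export
print.hrf_params <- function(x, ...) {
  cat("<hrf_params>", paste(sprintf("%s=%g", names(x), x), collapse = " "),
      "\n")
  invisible(x)
}

#' Microtime sampling specification
#'
#' Stimulus functions are built and convolved on a sub-TR ("microtime")
#' grid, then sampled back to the scan grid at a reference bin. The default
#' (16 bins, reference bin 8) corresponds to a mid-TR reference, consistent
#' with slice-timing correction referenced to the middle slice.
#'
#' @param tr repetition time in seconds.
#' @param microtime_bins integer number of subdivisions per TR.
#' @param reference_bin bin (1-based) at which regressors are read off.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(tr, microtime_bins = 16L, reference_bin = 8L) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar", call. = FALSE)
  microtime_bins <- as.integer(microtime_bins)
  reference_bin <- as.integer(reference_bin)
  if (microtime_bins < 1L)
    stop("microtime_bins must be >= 1", call. = FALSE)
  if (reference_bin < 1L || reference_bin > microtime_bins)
    stop("reference_bin must lie in [1, microtime_bins]", call. = FALSE)
  structure(list(tr = tr, microtime_bins = microtime_bins,
                 reference_bin = reference_bin, dt = tr / microtime_bins),
            class = "sampling_spec")
}
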