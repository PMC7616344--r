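#' Sample a double-gamma HRF kernel on a uniform grid
#'
#' Evaluates
#' \deqn{h(t) = G(t - p_6;\, p_1/p_3,\, p_3) - G(t - p_6;\, p_2/p_4,\, p_4)/p_5}
#' where `G(t; shape, scale)` is the gamma probability density, on the grid
#' `t = 0, dt, ..., p7`, sets negative-time values to zero, and divides the
#' kernel by its sum. Unit-sum normalization affects the scale of fitted
#' GLM coefficients but not R-squared or t statistics.
#'
#' @param params an [hrf_params] object.
#' @param dt grid spacing in seconds (e.g. `tr / microtime_bins`).
#' @return An object of class `sampled_hrf`: list with `values`
#'   (length `floor(p7/dt) + 1`, summing to 1), `dt` and `params`.
#' @export
#' @examples
#' h <- sample_double_gamma(hrf_preset("human_canonical"), dt = 0.0625)
#' peak_time(h)  # ~5 s
sample_double_gamma <- function(params, dt) {
  stopifnot(inherits(params, "hrf_params"))
  validate_hrf_params(params)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  v <- double_gamma_values(params, dt)
  s <- sum(v)
  if (s <= 0) stop("degenerate kernel: non-positive sum", call. = FALSE)
  structure(list(values = v / s, dt = dt, params = params),
            class = "sampled_hrf")
}

# Unnormalized closed-form evaluation; shared by derivative helpers.
double_gamma_values <- function(params, dt) {
  p <- as.numeric(params)
  t <- seq(0, p[7], by = dt)
  u <- t - p[6]
  h <- stats::dgamma(u, shape = p[1] / p[3], scale = p[3]) -
       stats::dgamma(u, shape = p[2] / p[4], scale = p[4]) / p[5]
  h[u < 0] <- 0
  h
}

#' Temporal derivative of the double-gamma HRF
#'
#' Finite-difference derivative with respect to onset:
#' `(h(t; p6) - h(t; p6 + shift)) / shift`, where each kernel is the
#' unit-sum-normalized sample. Not renormalized. With the canonical 1 s
#' shift this is the "time derivative" column of the informed basis set.
#'
#' @inheritParams sample_double_gamma
#' @param shift onset perturbation in seconds (default 1).
#' @return A `sampled_hrf` (values do not sum to 1).
#' @export
temporal_derivative <- function(params, dt, shift = 1) {
  stopifnot(inherits(params, "hrf_params"))
  if (shift <= 0) stop("shift must be positive", call. = FALSE)
  h0 <- sample_double_gamma(params, dt)
  p_shift <- params
  p_shift[["p6"]] <- p_shift[["p6"]] + shift
  h1 <- sample_double_gamma(p_shift, dt)
  structure(list(values = (h0$values - h1$values) / shift, dt = dt,
                 params = params),
            class = "sampled_hrf")
}

#' Dispersion derivative of the double-gamma HRF
#'
#' Finite-difference derivative with respect to the response dispersion:
#' `(h(p3) - h(p3 + dp3)) / dp3` on unit-sum-normalized kernels. Because
#' both kernels sum to 1, the derivative column sums to exactly zero.
#'
#' @inheritParams sample_double_gamma
#' @param dp3 dispersion perturbation (default 0.01).
#' @return A `sampled_hrf` (values sum to 0).
#' @export
dispersion_derivative <- function(params, dt, dp3 = 0.01) {
  stopifnot(inherits(params, "hrf_params"))
  if (dp3 <= 0) stop("dp3 must be positive", call. = FALSE)
  h0 <- sample_double_gamma(params, dt)
  p_disp <- params
  p_disp[["p3"]] <- p_disp[["p3"]] + dp3
  h1 <- sample_double_gamma(p_disp, dt)
  structure(list(values = (h0$values - h1$values) / dp3, dt = dt,
                 params = params),
            class = "sampled_hrf")
}

#' Informed basis set: canonical HRF plus temporal and dispersion derivatives
#'
#' @inheritParams sample_double_gamma
#' @param derivatives include the temporal and dispersion derivative columns.
#' @param orthogonalize residualize each derivative column against all
#'   preceding columns (see [orthogonalize_basis]). Whether the original
#'   analyses orthogonalized their basis is not documented, so this is a
#'   switch.
#' @param shift,dp3 finite-difference steps for the derivative columns.
#' @return An object of class `hrf_basis`: list with `columns` (matrix,
#'   samples x kernels, labelled `canonical`, `temporal_derivative`,
#'   `dispersion_derivative`), `dt`, `orthogonalized`.
#' @export
hrf_basis <- function(params, dt, derivatives = TRUE, orthogonalize = TRUE,
                      shift = 1, dp3 = 0.01) {
  can <- sample_double_gamma(params, dt)
  cols <- cbind(canonical = can$values)
  if (derivatives) {
    cols <- cbind(cols,
                  temporal_derivative =
                    temporal_derivative(params, dt, shift)$values,
                  dispersion_derivative =
                    dispersion_derivative(params, dt, dp3)$values)
  }
  b <- structure(list(columns = cols, dt = dt, orthogonalized = FALSE),
                 class = "hrf_basis")
  if (orthogonalize && ncol(cols) > 1L) b <- orthogonalize_basis(b)
  b
}

#' Successive orthogonalization of basis columns
#'
#' Column `k` is replaced by its residual after regressing out columns
#' `1 .. k-1`; the first (canonical) column is unchanged. A column that is
#' linearly dependent on its predecessors becomes all-zero (it carries no
#' additional information), which is reported via an attribute rather than
#' an error.
#'
#' @param basis an `hrf_basis`, or a plain numeric matrix.
#' @return Same type as the input, with derivative columns orthogonal to
#'   all preceding columns (inner products below 1e-8 relative scale).
#' @export
orthogonalize_basis <- function(basis) {
  m <- if (inherits(basis, "hrf_basis")) basis$columns else as.matrix(basis)
  if (ncol(m) < 1L) stop("basis needs at least one column", call. = FALSE)
  for (k in seq_len(ncol(m))[-1]) {
    prev <- m[, seq_len(k - 1L), drop = FALSE]
    keep <- colSums(prev^2) > 0
    if (any(keep)) {
      prev <- prev[, keep, drop = FALSE]
      fit <- qr(prev)
      m[, k] <- m[, k] - prev %*% qr.coef(fit, m[, k])
    }
  }
  if (inherits(basis, "hrf_basis")) {
    basis$columns <- m
    basis$orthogonalized <- TRUE
    basis
  } else m
}

#' Time-to-peak of a sampled HRF kernel
#'
#' Grid time of the global maximum; ties are broken toward the earlier
#' time. For the canonical human parameters this is about 5 s; for the
#' tailored dog parameters about 3 s.
#'
#' @param hrf a `sampled_hrf`.
#' @return Peak time in seconds.
#' @export
peak_time <- function(hrf) {
  stopifnot(inherits(hrf, "sampled_hrf"))
  v <- hrf$values
  if (all(v == v[1]))
    stop("peak_time undefined for a constant kernel", call. = FALSE)
  (which.max(v) - 1L) * hrf$dt
}

#' @export
print.sampled_hrf <- function(x, ...) {
  cat("<sampled_hrf>", length(x$values), "samples, dt =", x$dt,
      "s, sum =", signif(sum(x$values), 4), "\n")
  invisible(x)
}
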