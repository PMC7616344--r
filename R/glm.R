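#' Ordinary least-squares fit of a design matrix
#'
#' Fits `y = X beta + e` by QR-based OLS for a single time series or a
#' scans-by-voxels matrix. R-squared is computed about the mean
#' (`1 - SSE/SST`), matching the usual regression R-squared for models
#' that contain a constant. No autocorrelation pre-whitening is applied.
#'
#' @param y numeric vector (`n_scans`) or matrix (`n_scans` x voxels).
#' @param X a [design_matrix][assemble_design] or plain numeric matrix.
#' @return An object of class `glm_result`: `betas` (columns x voxels, or
#'   named vector for a single series), `residual_variance`, `r2`, `dof`,
#'   plus the fit internals needed by [contrast_t].
#' @export
fit_ols <- function(y, X) {
  Xm <- if (inherits(X, "design_matrix")) X$matrix else as.matrix(X)
  ym <- as.matrix(y)
  if (nrow(ym) != nrow(Xm))
    stop("y has ", nrow(ym), " rows but X has ", nrow(Xm), call. = FALSE)
  qrx <- qr(Xm)
  if (qrx$rank < ncol(Xm)) {
    dep <- colnames(Xm)[qrx$pivot[(qrx$rank + 1):ncol(Xm)]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qrx, ym)
  fitted <- Xm %*% betas
  res <- ym - fitted
  n <- nrow(Xm)
  dof <- n - qrx$rank
  sse <- colSums(res^2)
  sst <- colSums(sweep(ym, 2, colMeans(ym))^2)
  r2 <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse / sst)), 0)
  single <- is.null(dim(y)) || ncol(ym) == 1L
  structure(list(
    betas = if (single) stats::setNames(betas[, 1], colnames(Xm)) else betas,
    residual_variance = if (single) sse[1] / dof else sse / dof,
    r2 = if (single) unname(r2[1]) else unname(r2),
    dof = dof,
    mean_square_total = if (single) sst[1] / max(n - 1, 1) else
      sst / max(n - 1, 1),
    qr = qrx, X = Xm, n = n),
    class = "glm_result")
}

#' Contrast t statistic from an OLS fit
#'
#' `t = c' beta / sqrt(sigma2 * c' (X'X)^-1 c)` with
#' `dof = n - rank(X)`. On noise-free data (zero residual variance) the
#' statistic is undefined and an error is raised.
#'
#' @param result a [glm_result][fit_ols].
#' @param contrast numeric contrast vector (length = number of columns) or
#'   the name of a single design column.
#' @return For a single series, a list with `t`, `effect`, `se`, `dof`;
#'   for multi-voxel fits, `t` is a vector over voxels.
#' @export
contrast_t <- function(result, contrast) {
  stopifnot(inherits(result, "glm_result"))
  Xcols <- colnames(result$X)
  if (is.character(contrast)) {
    if (!contrast %in% Xcols)
      stop("no design column named '", contrast, "'", call. = FALSE)
    contrast <- as.numeric(Xcols == contrast)
  }
  if (length(contrast) != ncol(result$X))
    stop("contrast length ", length(contrast), " != ", ncol(result$X),
         " design columns", call. = FALSE)
  xtxinv <- chol2inv(chol(crossprod(result$X)))
  cvar <- drop(t(contrast) %*% xtxinv %*% contrast)
  b <- result$betas
  # residual variance at numerical zero (noise-free fit) leaves t undefined
  degenerate <- result$residual_variance <=
    1e-12 * pmax(result$mean_square_total, .Machine$double.xmin)
  if (any(degenerate) || any(result$residual_variance * cvar <= 0))
    stop("zero residual variance: t statistic undefined (noise-free fit)",
         call. = FALSE)
  se2 <- result$residual_variance * cvar
  eff <- if (is.matrix(b)) drop(t(contrast) %*% b) else sum(contrast * b)
  list(t = eff / sqrt(se2), effect = eff, se = sqrt(se2),
       dof = result$dof)
}

#' Derivative boost: signed combined amplitude of an informed basis set
#'
#' `H = sgn(beta1) * sqrt(beta1^2 + beta2^2 + beta3^2)`, combining the
#' canonical, temporal-derivative and dispersion-derivative coefficients
#' into one signed amplitude. `sgn(0)` is taken as +1 so the result is
#' deterministic in the degenerate case.
#'
#' @param b1,b2,b3 coefficients of the canonical, temporal-derivative and
#'   dispersion-derivative regressors.
#' @return The signed boost amplitude `H` (numeric scalar or vector).
#' @export
derivative_boost <- function(b1, b2 = 0, b3 = 0) {
  s <- ifelse(b1 >= 0, 1, -1)
  s * sqrt(b1^2 + b2^2 + b3^2)
}

#' Average basis coefficients across runs, then combine
#'
#' Multi-run informed-basis analyses first average each coefficient across
#' runs, then apply the derivative boost to the averages (not the average
#' of per-run boosts). Note the cancellation hazard: coefficients of
#' opposite sign across runs can average to zero.
#'
#' @param betas_per_run list of numeric vectors `(beta1, beta2, beta3)`
#'   (or matrices voxels x 3), identically ordered across runs.
#' @return List with `means` (averaged coefficients) and `boost`.
#' @export
combine_runs <- function(betas_per_run) {
  if (length(betas_per_run) == 0L)
    stop("need at least one run", call. = FALSE)
  first <- betas_per_run[[1]]
  if (is.matrix(first)) {
    means <- Reduce(`+`, betas_per_run) / length(betas_per_run)
    boost <- derivative_boost(means[, 1], means[, 2], means[, 3])
  } else {
    m <- do.call(rbind, betas_per_run)
    means <- colMeans(m)
    boost <- derivative_boost(means[1],
                              if (length(means) > 1) means[2] else 0,
                              if (length(means) > 2) means[3] else 0)
  }
  list(means = means, boost = boost)
}
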