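#' Exact Wilcoxon signed-rank test for paired model fits
#'
#' Computes differences `d = a - b`, drops zero differences, ranks `|d|`
#' with midranks for ties, and reports the positive-rank sum `W+`. For
#' `n <= 25` effective pairs the two-sided p value is exact, computed from
#' the full null distribution of the rank sum (sign assignments
#' equiprobable over all 2^n patterns, evaluated by convolution over the
#' tied rank multiset); above 25 a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b paired numeric vectors (e.g. per-subject R-squared under two
#'   HRF models).
#' @return Object of class `wilcoxon_result`: `w_plus`, `w_minus`,
#'   `n_effective`, `p_two_sided`, `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("a and b must be paired vectors of equal length >= 1",
         call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences zero; W+ = 0, p = 1")
    return(structure(list(w_plus = 0, w_minus = 0, n_effective = 0L,
                          p_two_sided = 1, exact = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  if (n <= 25L) {
    # null distribution over 2*ranks (integers even with midranks)
    r2 <- as.integer(round(2 * r))
    dist <- c(1, rep(0, sum(r2)))          # index = value of 2*W+ + 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- total / 2
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(w_plus = w_plus, w_minus = total - w_plus,
                 n_effective = n, p_two_sided = p, exact = exact),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("<wilcoxon_result> W+ =", x$w_plus, ", n =", x$n_effective,
      ", two-sided p =", signif(x$p_two_sided, 3),
      if (x$exact) "(exact)" else "(normal approx.)", "\n")
  invisible(x)
}

as_subject_matrix <- function(maps) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    m <- do.call(rbind, lapply(maps, as.numeric))
    attr(m, "grid") <- dims
    m
  } else if (length(dim(maps)) == 4L) {
    dd <- dim(maps)
    m <- t(matrix(maps, prod(dd[1:3]), dd[4]))
    attr(m, "grid") <- dd[1:3]
    m
  } else as.matrix(maps)
}

#' Voxelwise one-sample t map
#'
#' `t = mean / (sd / sqrt(n))` per voxel with `dof = n - 1`. Voxels with
#' zero variance across subjects are masked out (`NA`) and counted.
#'
#' @param maps subject maps: matrix (subjects x voxels), list of arrays,
#'   or 4D array (x, y, z, subject).
#' @return List with `t` (vector or array matching the input grid), `dof`,
#'   `n_masked` (zero-variance voxels).
#' @export
one_sample_tmap <- function(maps) {
  m <- as_subject_matrix(maps)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  mu <- colMeans(m)
  sd_ <- sqrt(colSums(sweep(m, 2, mu)^2) / (n - 1))
  t <- ifelse(sd_ > 0, mu / (sd_ / sqrt(n)), NA_real_)
  grid <- attr(m, "grid")
  if (!is.null(grid)) t <- array(t, grid)
  list(t = t, dof = n - 1L, n_masked = sum(sd_ == 0))
}

#' Voxelwise paired t map
#'
#' One-sample t map of per-subject differences `maps_a - maps_b`.
#' Swapping the arguments negates the map.
#'
#' @param maps_a,maps_b subject maps in any form accepted by
#'   [one_sample_tmap], identically shaped.
#' @return As [one_sample_tmap].
#' @export
paired_tmap <- function(maps_a, maps_b) {
  a <- as_subject_matrix(maps_a)
  b <- as_subject_matrix(maps_b)
  if (!all(dim(a) == dim(b)))
    stop("paired map stacks must have identical shape", call. = FALSE)
  d <- a - b
  attr(d, "grid") <- attr(a, "grid")
  one_sample_tmap(d)
}

#' Label connected clusters in a 3D binary map
#'
#' Breadth-first connected-component labelling with 6-, 18- or
#' 26-connectivity (default 26: faces, edges and corners).
#'
#' @param mask logical/0-1 3D array.
#' @param connectivity 6, 18 or 26.
#' @return List with `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per cluster, decreasing).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  dd <- dim(mask)
  if (length(dd) != 3L) stop("mask must be 3D", call. = FALSE)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh >= 1 & manh <= 2,
                 "26" = manh >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  offs <- as.matrix(offs[keep, ])
  lab <- array(0L, dd)
  fg <- which(mask != 0, arr.ind = TRUE)
  lin <- which(mask != 0)
  if (nrow(fg) == 0L) return(list(labels = lab, sizes = integer(0)))
  inmask <- array(FALSE, dd); inmask[lin] <- TRUE
  nextlab <- 0L
  sizes <- integer(0)
  for (i in seq_len(nrow(fg))) {
    if (lab[fg[i, 1], fg[i, 2], fg[i, 3]] != 0L) next
    nextlab <- nextlab + 1L
    queue <- matrix(fg[i, ], 1)
    lab[fg[i, 1], fg[i, 2], fg[i, 3]] <- nextlab
    size <- 1L
    while (nrow(queue) > 0L) {
      v <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      nb <- sweep(offs, 2, v, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dd[1] &
            nb[, 2] >= 1 & nb[, 2] <= dd[2] &
            nb[, 3] >= 1 & nb[, 3] <= dd[3]
      nb <- nb[ok, , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        x <- nb[j, 1]; y <- nb[j, 2]; z <- nb[j, 3]
        if (inmask[x, y, z] && lab[x, y, z] == 0L) {
          lab[x, y, z] <- nextlab
          queue <- rbind(queue, nb[j, ])
          size <- size + 1L
        }
      }
    }
    sizes <- c(sizes, size)
  }
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes)); relabel[ord] <- seq_along(sizes)
  lab[lab != 0L] <- relabel[lab[lab != 0L]]
  list(labels = lab, sizes = sizes[ord])
}

#' Permutation-based cluster-extent thresholding
#'
#' Nonparametric family-wise-error control on cluster size: the group t
#' map is thresholded at the one-sided cluster-defining threshold
#' (`p < cdt_p` on `t(n-1)`), clusters are formed with the chosen
#' connectivity, and each cluster size is referred to the permutation null
#' of the maximum cluster size obtained by random sign-flipping of subject
#' maps. FWE p = `(1 + #{perm max >= k}) / (1 + n_perm)`.
#'
#' @param maps subject maps as a 4D array (x, y, z, subject) or list of 3D
#'   arrays.
#' @param cdt_p cluster-defining (uncorrected, one-sided) threshold.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @param connectivity cluster connectivity (default 26).
#' @return Object of class `cluster_result`: data frame `clusters`
#'   (`id`, `size`, `peak_x/y/z`, `peak_t`, `p_fwe`), `t_threshold`,
#'   `max_null` (permutation distribution of the max cluster size).
#' @export
permutation_cluster_threshold <- function(maps, cdt_p = 0.001,
                                          n_perm = 1000, seed = NULL,
                                          connectivity = 26) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  m <- as_subject_matrix(maps)
  grid <- attr(m, "grid")
  if (is.null(grid))
    stop("maps must carry a 3D grid (4D array or list of 3D arrays)",
         call. = FALSE)
  n <- nrow(m)
  if (n < 8) warning("fewer than 8 subjects; permutation null is coarse")
  if (!is.null(seed)) set.seed(seed)
  tcrit <- stats::qt(1 - cdt_p, df = n - 1)

  tvec <- function(mm) {
    mu <- colMeans(mm)
    sd_ <- sqrt(colSums(sweep(mm, 2, mu)^2) / (n - 1))
    ifelse(sd_ > 0, mu / (sd_ / sqrt(n)), 0)
  }
  max_cluster <- function(tv) {
    supra <- array(tv > tcrit, grid)
    if (!any(supra)) return(0L)
    cl <- label_clusters(supra, connectivity)
    if (length(cl$sizes)) cl$sizes[1] else 0L
  }

  t_obs <- tvec(m)
  supra <- array(t_obs > tcrit, grid)
  obs <- label_clusters(supra, connectivity)

  max_null <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    max_null[p] <- max_cluster(tvec(m * signs))
  }

  if (length(obs$sizes)) {
    t_arr <- array(t_obs, grid)
    peaks <- t(vapply(seq_along(obs$sizes), function(id) {
      idx <- which(obs$labels == id)
      pk <- idx[which.max(t_arr[idx])]
      co <- arrayInd(pk, grid)
      c(co, t_arr[pk])
    }, numeric(4)))
    clusters <- data.frame(
      id = seq_along(obs$sizes), size = obs$sizes,
      peak_x = as.integer(peaks[, 1]), peak_y = as.integer(peaks[, 2]),
      peak_z = as.integer(peaks[, 3]), peak_t = peaks[, 4],
      p_fwe = vapply(obs$sizes, function(k)
        (1 + sum(max_null >= k)) / (1 + n_perm), numeric(1)))
  } else {
    clusters <- data.frame(id = integer(0), size = integer(0),
                           peak_x = integer(0), peak_y = integer(0),
                           peak_z = integer(0), peak_t = numeric(0),
                           p_fwe = numeric(0))
  }
  structure(list(clusters = clusters, t_threshold = tcrit, cdt_p = cdt_p,
                 n_perm = n_perm, max_null = max_null,
                 labels = obs$labels),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$clusters), "cluster(s) at t >",
      signif(x$t_threshold, 4), "(CDT p <", x$cdt_p, ")\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
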