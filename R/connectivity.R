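#' Pearson correlation matrix of ROI time courses
#'
#' @param tc T x R numeric matrix of ROI time courses (T >= 3), columns
#'   named by ROI.
#' @return Symmetric R x R correlation matrix with unit diagonal.
#' @export
pearson_fc <- function(tc) {
  if (!is.matrix(tc) || !is.numeric(tc)) stop("`tc` must be a numeric matrix", call. = FALSE)
  if (nrow(tc) < 3L) stop("need at least 3 time points for Pearson r", call. = FALSE)
  if (anyNA(tc)) stop("time courses contain missing values", call. = FALSE)
  sds <- apply(tc, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(tc)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance ROI time course: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- cor(tc)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Fisher z-transform a correlation matrix
#'
#' Applies `atanh` elementwise after clipping `|r|` at `1 - 1e-7` (so
#' perfect correlations map to a large finite z of about 8.4), and forces
#' the diagonal to zero. The result is the edge-weight matrix used by all
#' graph analyses.
#'
#' @param corr Symmetric correlation matrix with entries in `[-1, 1]`.
#' @return Symmetric Fisher-z matrix with zero diagonal (an `FcMatrix`).
#' @export
fisher_z <- function(corr) {
  if (any(abs(corr) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  clipped <- pmin(pmax(corr, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(clipped)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}

#' Proportional sparsity thresholding of a connectivity matrix
#'
#' Ranks the `E = R(R-1)/2` upper-triangle edges by signed weight
#' (largest first; set `rank_by = "absolute"` to rank by magnitude),
#' keeps the top `round(sparsity * E)` edges (round half away from zero)
#' and zeroes the rest, mirroring to the lower triangle. Ties at the cut
#' are broken by (row, column) lexicographic order.
#'
#' @param fc Symmetric Fisher-z matrix (zero diagonal).
#' @param sparsity Fraction of edges to retain, in `(0, 1]`.
#' @param rank_by `"signed"` (default; the strongest positive
#'   connections) or `"absolute"`.
#' @return A `thresholded_graph`: list with `z_thresholded`, `sparsity`,
#'   `retained_edges`, `retained_index` (upper-triangle positions, column
#'   major) and `rank_by`.
#' @export
proportional_threshold <- function(fc, sparsity, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  check_fc_matrix(fc)
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1) {
    stop("sparsity must lie in (0, 1]", call. = FALSE)
  }
  R <- nrow(fc)
  ut <- upper_tri_index(R)
  vals <- fc[upper.tri(fc)]
  key <- if (rank_by == "signed") vals else abs(vals)
  ord <- order(-key, ut$i, ut$j)
  k <- as.integer(round_half_away(sparsity * ut$n))
  keep <- sort(ord[seq_len(k)])
  zt <- matrix(0, R, R, dimnames = dimnames(fc))
  utm <- upper.tri(zt)
  kept_vals <- numeric(ut$n)
  kept_vals[keep] <- vals[keep]
  zt[utm] <- kept_vals
  zt[lower.tri(zt)] <- t(zt)[lower.tri(zt)]
  structure(
    list(z_thresholded = zt, sparsity = sparsity, retained_edges = k,
         retained_index = keep, rank_by = rank_by),
    class = "thresholded_graph"
  )
}

#' Mean connectivity over retained edges
#'
#' The "FC" summary of a thresholded graph: the average of the retained
#' upper-triangle edge weights (negative edges, if retained, enter
#' as-is).
#'
#' @param g A [proportional_threshold()] result.
#' @return Scalar mean retained connectivity.
#' @export
mean_nonzero_fc <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  if (g$retained_edges < 1L) stop("graph has no retained edges", call. = FALSE)
  vals <- g$z_thresholded[upper.tri(g$z_thresholded)]
  mean(vals[g$retained_index])
}

#' Seed-to-voxel Fisher-z correlation map
#'
#' Correlates a seed time course with every voxel time course and
#' Fisher-z transforms the result. Zero-variance voxels map to z = 0; a
#' warning reports how many.
#'
#' @param seed_tc Length-T numeric seed time course with positive
#'   variance.
#' @param voxel_tcs T x V matrix of voxel time courses.
#' @return Length-V numeric z map with attribute `n_zero_variance`.
#' @export
seed_correlation_map <- function(seed_tc, voxel_tcs) {
  if (!is.matrix(voxel_tcs)) voxel_tcs <- as.matrix(voxel_tcs)
  TT <- length(seed_tc)
  if (nrow(voxel_tcs) != TT) stop("seed and voxel time courses differ in length", call. = FALSE)
  if (sd(seed_tc) == 0) stop("seed time course has zero variance", call. = FALSE)
  sc <- seed_tc - mean(seed_tc)
  vc <- sweep(voxel_tcs, 2L, colMeans(voxel_tcs))
  denom <- sqrt(colSums(vc^2)) * sqrt(sum(sc^2))
  zero <- denom == 0
  denom[zero] <- 1
  r <- as.vector(crossprod(vc, sc)) / denom
  r[zero] <- 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance voxel(s) mapped to z = 0", call. = FALSE)
  }
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  attr(z, "n_zero_variance") <- sum(zero)
  z
}
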