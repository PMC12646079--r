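#' Threshold-free cluster enhancement of a 3D stat map
#'
#' For each voxel, integrates `extent(v, h)^E * h^H` over thresholds h
#' from 0 up to the voxel's height, where `extent(v, h)` is the size (in
#' voxels) of the connected suprathreshold component containing v. This
#' boosts spatially extended signals without committing to a single
#' cluster-forming threshold. The integral is discretized at `nsteps`
#' midpoint thresholds spanning the map's peak (`dh = peak / nsteps`);
#' the negative tail is enhanced by transforming `-values` and negating.
#'
#' @param values 3D numeric array (e.g. a t map).
#' @param mask Logical 3D array; default all TRUE.
#' @param H Height exponent (default 2).
#' @param E Extent exponent (default 0.5).
#' @param nsteps Number of integration steps (default 100).
#' @param connectivity Neighbourhood: 6, 18 or 26 (default 26).
#' @return 3D array of signed TFCE scores (0 outside the mask).
#' @export
tfce <- function(values, mask = NULL, H = 2, E = 0.5, nsteps = 100L,
                 connectivity = 26L) {
  d <- dim(values)
  if (length(d) != 3L) stop("`values` must be a 3D array", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) stop("mask shape mismatch", call. = FALSE)
  if (!sum(mask)) stop("mask is empty", call. = FALSE)
  if (H <= 0 || E <= 0 || nsteps < 1L) stop("H, E, nsteps must be positive", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  if (anyNA(values[mask])) stop("non-finite values inside the mask", call. = FALSE)
  pos <- tfce_positive_cpp(as.numeric(pmax(values, 0)), as.integer(d),
                           as.logical(mask), H, E, as.integer(nsteps),
                           as.integer(connectivity))
  neg <- tfce_positive_cpp(as.numeric(pmax(-values, 0)), as.integer(d),
                           as.logical(mask), H, E, as.integer(nsteps),
                           as.integer(connectivity))
  array(pos - neg, d)
}

#' Voxel-wise permutation test with TFCE and max-statistic FWE correction
#'
#' Computes the observed pooled-variance two-sample t map, enhances it
#' with [tfce()], then builds the null distribution of the maximal
#' absolute TFCE score over the mask by shuffling group labels `n_perm`
#' times. The FWE-corrected p at voxel v is
#' `(1 + #permutation maxima >= |TFCE_obs(v)|) / (1 + n_perm)` — strong
#' family-wise error control by the permutation distribution of the
#' maximum statistic.
#'
#' @param images List of per-subject 3D arrays on a common grid.
#' @param labels Two-level factor of group labels, one per image (>= 2
#'   per group).
#' @param mask Logical 3D array; default all TRUE.
#' @param n_perm Number of label permutations (default 1000; < 100 draws
#'   a warning).
#' @param seed Optional RNG seed, recorded in the result.
#' @param H,E,nsteps,connectivity TFCE parameters, see [tfce()].
#' @return An `fwe_result` list: `p` (corrected-p 3D array, NA outside
#'   the mask), `tfce_obs`, `t_obs`, `null_max`, `n_permutations`,
#'   `seed`.
#' @export
permutation_fwe <- function(images, labels, mask = NULL, n_perm = 1000L,
                            seed = NULL, H = 2, E = 0.5, nsteps = 100L,
                            connectivity = 26L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("`labels` must have exactly 2 levels", call. = FALSE)
  if (any(table(labels) < 2L)) stop("need >= 2 subjects per group", call. = FALSE)
  if (length(images) != length(labels)) stop("one label per image", call. = FALSE)
  if (n_perm < 100L) warning("fewer than 100 permutations", call. = FALSE)
  d <- dim(images[[1L]])
  if (is.null(mask)) mask <- array(TRUE, d)
  midx <- which(mask)
  X <- vapply(images, function(img) {
    if (!identical(dim(img), d)) stop("images differ in shape", call. = FALSE)
    as.numeric(img[midx])
  }, numeric(length(midx)))
  n <- ncol(X)
  nA <- sum(labels == levels(labels)[1L])
  tfce_masked <- function(tvec) {
    tm <- array(0, d)
    tm[midx] <- tvec
    abs(tfce(tm, mask, H = H, E = E, nsteps = nsteps,
             connectivity = connectivity))[midx]
  }
  t_of <- function(idxA) {
    tt <- pooled_t_columns(t(X[, idxA, drop = FALSE]),
                           t(X[, -idxA, drop = FALSE]))
    tt$t
  }
  t_obs <- t_of(which(labels == levels(labels)[1L]))
  enh_obs <- tfce_masked(t_obs)
  tmpl <- array(0, d)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      tmpl[midx] <- t_of(sample.int(n, nA))
      tfce_max_abs_cpp(as.numeric(tmpl), as.integer(d), as.logical(mask),
                       H, E, as.integer(nsteps), as.integer(connectivity))
    }, numeric(1L))
  })
  pvec <- vapply(enh_obs, function(e) (1 + sum(null_max >= e)) / (1 + n_perm),
                 numeric(1L))
  p <- array(NA_real_, d)
  p[midx] <- pvec
  tfce_full <- array(0, d); tfce_full[midx] <- enh_obs
  t_full <- array(0, d); t_full[midx] <- t_obs
  structure(
    list(p = p, tfce_obs = tfce_full, t_obs = t_full, null_max = null_max,
         n_permutations = as.integer(n_perm), seed = seed),
    class = "fwe_result"
  )
}
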