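# Separable Gaussian smoothing of a 3D array (zero-padded borders).
# `norm` attribute gives the interior standard deviation of the smoothed
# field when the input is unit-variance white noise.
smooth_gaussian3d <- function(x, sigma) {
  d <- dim(x)
  if (sigma <= 0) return(structure(x, norm = 1))
  radius <- ceiling(3 * sigma)
  kern <- dnorm(-radius:radius, sd = sigma)
  band <- function(n) {
    M <- matrix(0, n, n)
    for (off in -radius:radius) {
      idx <- seq_len(n)
      keep <- idx + off >= 1L & idx + off <= n
      M[cbind(idx[keep] + off, idx[keep])] <- kern[off + radius + 1L]
    }
    M
  }
  apply_dim <- function(arr, M, dim_i) {
    perm <- c(dim_i, setdiff(1:3, dim_i))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- M %*% matrix(a, da[1L], prod(da[-1L]))
    dim(a) <- da
    aperm(a, order(perm))
  }
  for (i in 1:3) x <- apply_dim(x, band(d[i]), i)
  structure(x, norm = sqrt(sum(kern^2))^3)
}

#' Simulate per-subject 3D stat images with a planted spherical signal
#'
#' Generates smooth Gaussian random fields (white noise convolved with a
#' Gaussian kernel and rescaled to unit interior variance) for every
#' subject in the cohort's adulthood session. Knockout subjects receive an
#' added spherical signal of radius `signal_radius` voxels and height
#' `signal_amplitude` noise-standard-deviations at the image centre; with
#' `signal_amplitude = 0` the two groups are exchangeable and the images
#' form a null dataset for calibrating voxel-wise inference. The analysis
#' mask excludes a one-voxel border (where zero-padded smoothing
#' attenuates the field).
#'
#' @param cfg A [sim_config()]; `image_shape` must be >= 8 in every
#'   dimension.
#' @param cohort Optional cohort table; defaults to `make_cohort(cfg)`.
#' @return List: `images` (named list of 3D arrays, one per subject),
#'   `mask` (logical 3D array), `groups` (genotype factor aligned with
#'   `images`), `signal` (logical 3D array marking planted voxels),
#'   `voxel_size`.
#' @export
simulate_stat_images <- function(cfg, cohort = NULL) {
  if (any(cfg$image_shape < 8L)) stop("image_shape must be >= 8x8x8", call. = FALSE)
  if (is.null(cohort)) cohort <- make_cohort(cfg)
  subjects <- cohort_subjects(cohort)
  d <- cfg$image_shape
  mask <- array(TRUE, d)
  mask[c(1L, d[1L]), , ] <- FALSE
  mask[, c(1L, d[2L]), ] <- FALSE
  mask[, , c(1L, d[3L])] <- FALSE
  centre <- (d + 1) / 2
  gr <- expand.grid(x = seq_len(d[1L]), y = seq_len(d[2L]), z = seq_len(d[3L]))
  dist2 <- (gr$x - centre[1L])^2 + (gr$y - centre[2L])^2 + (gr$z - centre[3L])^2
  signal <- array(dist2 <= cfg$signal_radius^2, d) & mask
  with_seed(cfg$seed + 3L, {
    images <- lapply(seq_len(nrow(subjects)), function(k) {
      noise <- array(rnorm(prod(d)), d)
      sm <- smooth_gaussian3d(noise, cfg$smooth_sigma)
      img <- sm / attr(sm, "norm")
      if (subjects$genotype[k] == "knockout" && cfg$signal_amplitude != 0) {
        img[signal] <- img[signal] + cfg$signal_amplitude
      }
      img
    })
    names(images) <- subjects$subject_id
    list(
      images = images, mask = mask,
      groups = factor(subjects$genotype, levels = c("wildtype", "knockout")),
      signal = signal, voxel_size = cfg$voxel_size
    )
  })
}
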