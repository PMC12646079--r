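#' Default 36-region parcellation names
#'
#' The functional parcellation used throughout the package: 36 unilateral
#' grey-matter regions, 18 per hemisphere, named with an `L_`/`R_`
#' hemisphere prefix.
#'
#' @return Character vector of 36 ROI names (all left-hemisphere names
#'   first, then right).
#' @export
default_roi_names <- function() {
  base <- c(
    "cingulate_cortex", "prefrontal_cortex", "amygdala",
    "pallidum_accumbens", "striatum", "hypothalamus",
    "dorsal_hippocampus", "ventral_hippocampus", "periaqueductal_grey",
    "brain_stem", "colliculus", "sensory_cortex", "motor_cortex",
    "thalamus", "septum", "olfactory_bulb", "insular_cortex",
    "retrosplenial_cortex"
  )
  c(paste0("L_", base), paste0("R_", base))
}

bilateral <- function(regions) c(paste0("L_", regions), paste0("R_", regions))

#' Bundled resting-state network definitions
#'
#' Three canonical mouse networks defined as fixed subsets of the 36-region
#' parcellation: the default mode network (bilateral prefrontal cortex,
#' cingulate cortex and dorsal hippocampus), the salience network
#' (bilateral cingulate cortex, amygdala and striatum), and an
#' anxiety-related network of 20 regions (10 per hemisphere: cingulate and
#' prefrontal cortex, amygdala, pallidum and accumbens, striatum,
#' hypothalamus, dorsal and ventral hippocampus, periaqueductal grey,
#' brain stem).
#'
#' @return Named list of `network_definition` objects (`name`, `rois`).
#' @export
default_networks <- function() {
  list(
    dmn = network_definition("dmn", bilateral(c(
      "prefrontal_cortex", "cingulate_cortex", "dorsal_hippocampus"
    ))),
    salience = network_definition("salience", bilateral(c(
      "cingulate_cortex", "amygdala", "striatum"
    ))),
    anxiety = network_definition("anxiety", bilateral(c(
      "cingulate_cortex", "prefrontal_cortex", "amygdala",
      "pallidum_accumbens", "striatum", "hypothalamus",
      "dorsal_hippocampus", "ventral_hippocampus", "periaqueductal_grey",
      "brain_stem"
    )))
  )
}

#' Seed regions for the a priori node-strength analysis
#'
#' The 20 anxiety- and fear-related regions (10 left + 10 right) whose mean
#' absolute connectivity to all other regions is tested.
#'
#' @return Character vector of 20 ROI names.
#' @export
anxiety_seed_regions <- function() default_networks()$anxiety$rois

#' Define a named ROI network
#'
#' @param name Network name.
#' @param rois Character vector of at least two ROI names.
#' @return A `network_definition` list.
#' @export
network_definition <- function(name, rois) {
  stopifnot(is.character(name), length(name) == 1L)
  rois <- as.character(rois)
  if (length(rois) < 2L) stop("a network needs at least 2 ROIs", call. = FALSE)
  if (anyDuplicated(rois)) stop("duplicated ROI names in network", call. = FALSE)
  structure(list(name = name, rois = rois), class = "network_definition")
}

#' Default white-matter regions for fractional anisotropy tables
#'
#' Eight tract regions; the olfactory tract is the designated
#' early-maturing region whose simulated developmental FA increment is
#' zero.
#'
#' @return Character vector of region names.
#' @export
default_wm_regions <- function() {
  c(
    "corpus_callosum", "olfactory_tract", "internal_capsule",
    "optic_tract", "anterior_commissure", "fimbria",
    "cerebral_peduncle", "hippocampal_commissure"
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators: cohort layout,
#' modular correlation structure of the BOLD time series, genotype and
#' developmental effect sizes, and image geometry. The target correlation
#' matrix is `r_between` everywhere, raised to `r_within` inside each
#' module (overlapping modules keep the larger value), with
#' `genotype_edge_delta` added on `effect_edges` for knockout sessions.
#' Matrices that are not positive definite after these edits are repaired
#' by eigenvalue flooring (see [target_correlation()]).
#'
#' @param n_per_cell Subjects per genotype-by-sex cell (>= 1).
#' @param n_rois Number of ROIs (default 36, 18 per hemisphere).
#' @param n_timepoints_scan Samples per BOLD run (default 500).
#' @param roi_names ROI labels with `L_`/`R_` hemisphere prefixes; half of
#'   each.
#' @param modules Named list of networks used as correlation blocks.
#' @param r_within,r_between Fisher-scale correlations inside/between
#'   modules; `0 <= r_between <= r_within < 1`.
#' @param genotype_edge_delta Additive correlation shift on `effect_edges`
#'   in knockout sessions.
#' @param effect_edges Two-column matrix of ROI-name pairs carrying the
#'   genotype effect; `NULL` means all pairs within the first module.
#' @param developmental_delta_fa FA increment adulthood minus adolescence
#'   (>= 0); applied to every white-matter region except the olfactory
#'   tract.
#' @param fa_noise_sd Residual sd of the FA change.
#' @param fa_subject_sd Between-subject sd of adolescent FA.
#' @param fa_regions White-matter region names.
#' @param ar1_coef Temporal AR(1) coefficient in `[0, 1)`.
#' @param volume_region_count Number of atlas regions in volume tables
#'   (default 72).
#' @param volume_cv Generating coefficient of variation of regional
#'   volumes (default 0.05, the observed 4-5% range).
#' @param volume_sex_effect Multiplicative male-vs-female volume excess in
#'   adolescence (sex differences wash out by adulthood).
#' @param volume_growth Multiplicative adolescence-to-adulthood growth.
#' @param image_shape 3D stat-image dimensions (each >= 8).
#' @param signal_amplitude Planted spherical signal height in units of the
#'   smoothed-noise standard deviation (0 = null images).
#' @param signal_radius Sphere radius in voxels.
#' @param smooth_sigma Gaussian smoothing sigma of the noise field, voxels.
#' @param voxel_size Isotropic voxel edge in mm (default 0.15, in vivo).
#' @param seed RNG seed driving all generators.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_cell = 9L,
                       n_rois = 36L,
                       n_timepoints_scan = 500L,
                       roi_names = default_roi_names(),
                       modules = default_networks(),
                       r_within = 0.35,
                       r_between = 0.10,
                       genotype_edge_delta = 0,
                       effect_edges = NULL,
                       developmental_delta_fa = 0.03,
                       fa_noise_sd = 0.01,
                       fa_subject_sd = 0.02,
                       fa_regions = default_wm_regions(),
                       ar1_coef = 0.3,
                       volume_region_count = 72L,
                       volume_cv = 0.05,
                       volume_sex_effect = 0.04,
                       volume_growth = 0.10,
                       image_shape = c(16L, 16L, 16L),
                       signal_amplitude = 0,
                       signal_radius = 3,
                       smooth_sigma = 1,
                       voxel_size = 0.15,
                       seed = 1L) {
  cfg <- list(
    n_per_cell = as.integer(n_per_cell), n_rois = as.integer(n_rois),
    n_timepoints_scan = as.integer(n_timepoints_scan),
    roi_names = as.character(roi_names), modules = modules,
    r_within = r_within, r_between = r_between,
    genotype_edge_delta = genotype_edge_delta, effect_edges = effect_edges,
    developmental_delta_fa = developmental_delta_fa,
    fa_noise_sd = fa_noise_sd, fa_subject_sd = fa_subject_sd,
    fa_regions = as.character(fa_regions),
    ar1_coef = ar1_coef,
    volume_region_count = as.integer(volume_region_count),
    volume_cv = volume_cv, volume_sex_effect = volume_sex_effect,
    volume_growth = volume_growth,
    image_shape = as.integer(image_shape),
    signal_amplitude = signal_amplitude, signal_radius = signal_radius,
    smooth_sigma = smooth_sigma, voxel_size = voxel_size,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_cell < 1L) stop("n_per_cell must be >= 1", call. = FALSE)
  if (length(cfg$roi_names) != cfg$n_rois) {
    stop("roi_names must have n_rois entries", call. = FALSE)
  }
  left <- startsWith(cfg$roi_names, "L_")
  right <- startsWith(cfg$roi_names, "R_")
  if (!all(left | right) || sum(left) != cfg$n_rois / 2) {
    stop("roi_names must be half 'L_'- and half 'R_'-prefixed", call. = FALSE)
  }
  if (!(cfg$r_between >= 0 && cfg$r_between <= cfg$r_within && cfg$r_within < 1)) {
    stop("need 0 <= r_between <= r_within < 1", call. = FALSE)
  }
  if (cfg$ar1_coef < 0 || cfg$ar1_coef >= 1) {
    stop("ar1_coef must be in [0, 1)", call. = FALSE)
  }
  if (cfg$developmental_delta_fa < 0) {
    stop("developmental_delta_fa must be >= 0", call. = FALSE)
  }
  if (cfg$volume_region_count < 2L) {
    stop("volume_region_count must be >= 2", call. = FALSE)
  }
  if (length(cfg$image_shape) != 3L || any(cfg$image_shape < 8L)) {
    stop("image_shape must be 3 dimensions, each >= 8", call. = FALSE)
  }
  for (net in cfg$modules) {
    missing <- setdiff(net$rois, cfg$roi_names)
    if (length(missing)) {
      stop("module ROI(s) not in parcellation: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# Edge set carrying the genotype effect, as an index matrix into roi_names.
effect_edge_index <- function(cfg) {
  if (is.null(cfg$effect_edges)) {
    rois <- cfg$modules[[1L]]$rois
    pairs <- t(utils::combn(rois, 2L))
  } else {
    pairs <- cfg$effect_edges
  }
  cbind(match(pairs[, 1L], cfg$roi_names), match(pairs[, 2L], cfg$roi_names))
}

#' Repair a correlation matrix to positive definiteness
#'
#' Floors eigenvalues at `floor` and rescales to unit diagonal; a valid
#' multivariate-normal target must be positive definite. The return value
#' records whether a repair was needed.
#'
#' @param C Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor (default 1e-6).
#' @return List with `matrix` (repaired correlation) and `repaired` flag.
#' @export
repair_correlation <- function(C, floor = 1e-6) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  repaired <- any(e$values < floor)
  if (repaired) {
    vals <- pmax(e$values, floor)
    C <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  list(matrix = C, repaired = repaired)
}

#' Model correlation matrix implied by a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @param genotype `"wildtype"` or `"knockout"`; knockouts receive
#'   `genotype_edge_delta` on the designated effect edges.
#' @return List with `matrix` (R x R correlation, ROI dimnames) and
#'   `repaired` flag from [repair_correlation()].
#' @export
target_correlation <- function(cfg, genotype = c("wildtype", "knockout")) {
  genotype <- match.arg(genotype)
  R <- cfg$n_rois
  C <- matrix(cfg$r_between, R, R,
              dimnames = list(cfg$roi_names, cfg$roi_names))
  for (net in cfg$modules) {
    idx <- match(net$rois, cfg$roi_names)
    C[idx, idx] <- pmax(C[idx, idx], cfg$r_within)
  }
  diag(C) <- 1
  if (genotype == "knockout" && cfg$genotype_edge_delta != 0) {
    ee <- effect_edge_index(cfg)
    for (k in seq_len(nrow(ee))) {
      i <- ee[k, 1L]; j <- ee[k, 2L]
      C[i, j] <- C[i, j] + cfg$genotype_edge_delta
      C[j, i] <- C[i, j]
    }
    C[] <- pmin(pmax(C, -0.99), 0.99)
    diag(C) <- 1
  }
  rep <- repair_correlation(C)
  ev <- eigen(rep$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("target correlation not positive definite after repair (min eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  }
  rep
}
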