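#' Jacobian-determinant volume image
#'
#' Container for a subject's Jacobian map: the local volume expansion
#' factor of the registration to the study template. A valid
#' diffeomorphism has positive determinant inside the brain mask.
#'
#' @param values 3D numeric array of Jacobian determinants.
#' @param voxel_volume Voxel volume in mm^3.
#' @param mask Logical 3D array (template brain mask); default all TRUE.
#' @return A `jacobian_volume` list.
#' @export
jacobian_volume <- function(values, voxel_volume, mask = NULL) {
  stopifnot(length(dim(values)) == 3L, voxel_volume > 0)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  structure(list(values = values, voxel_volume = voxel_volume, mask = mask),
            class = "jacobian_volume")
}

#' Atlas label image
#'
#' @param labels 3D integer array; 0 is background.
#' @param lookup Named character vector or data frame mapping label
#'   values to region names; every non-zero label must appear.
#' @return A `label_volume` list.
#' @export
label_volume <- function(labels, lookup) {
  stopifnot(length(dim(labels)) == 3L)
  if (is.data.frame(lookup)) {
    lk <- stats::setNames(as.character(lookup[[2L]]), lookup[[1L]])
  } else {
    lk <- lookup
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, as.integer(names(lk)))
  if (length(missing)) {
    stop("labels without lookup entry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(labels = labels, lookup = lk), class = "label_volume")
}

#' Regional and total brain volume from a Jacobian map
#'
#' Region volume is the sum of Jacobian determinants over the region's
#' labelled voxels times the voxel volume; total brain volume is the sum
#' over the template brain mask; relative volume is region over total
#' (the scale-free quantity reported when global brain size differs).
#'
#' @param jac A [jacobian_volume()].
#' @param atlas A [label_volume()] on the same grid.
#' @param subject_id,timepoint Optional identifiers copied into the
#'   table.
#' @return Data frame with `absolute_mm3` and `relative_fraction` rows
#'   per region; attribute `total_brain_volume` (mm^3).
#' @export
regional_volumes <- function(jac, atlas, subject_id = NA_character_,
                             timepoint = NA_character_) {
  stopifnot(inherits(jac, "jacobian_volume"), inherits(atlas, "label_volume"))
  if (!identical(dim(jac$values), dim(atlas$labels))) {
    stop("Jacobian and atlas grids differ in shape", call. = FALSE)
  }
  bad <- sum(jac$values[jac$mask] <= 0)
  if (bad > 0) {
    warning(bad, " non-positive Jacobian value(s) inside the mask", call. = FALSE)
  }
  total <- sum(jac$values[jac$mask]) * jac$voxel_volume
  lab <- as.vector(atlas$labels)
  sel <- lab != 0L
  sums <- tapply(as.vector(jac$values)[sel], lab[sel], sum) * jac$voxel_volume
  region <- unname(atlas$lookup[names(sums)])
  out <- rbind(
    data.frame(subject_id = subject_id, timepoint = timepoint,
               region = region, value = as.numeric(sums),
               value_kind = "absolute_mm3"),
    data.frame(subject_id = subject_id, timepoint = timepoint,
               region = region, value = as.numeric(sums) / total,
               value_kind = "relative_fraction")
  )
  attr(out, "total_brain_volume") <- total
  out
}

#' Per-region coefficient of variation by group
#'
#' CV = sd / mean (sample sd) per region within each group — the
#' variability audit establishing whether regional volume estimates are
#' precise enough to detect group effects (about 4-5% in well-behaved
#' mouse volumetry).
#'
#' @param table Long-format regional table with columns `region`,
#'   `value`, and the grouping column.
#' @param group_col Grouping column name (default `"genotype"`).
#' @param value_kind Optional filter on the `value_kind` column.
#' @return Data frame `group`, `region`, `cv`.
#' @export
region_cv <- function(table, group_col = "genotype", value_kind = NULL) {
  if (!is.null(value_kind) && "value_kind" %in% names(table)) {
    table <- table[table$value_kind == value_kind, ]
  }
  if (!all(c("region", "value", group_col) %in% names(table))) {
    stop("table needs columns region, value, ", group_col, call. = FALSE)
  }
  groups <- split(table, table[[group_col]])
  rows <- lapply(names(groups), function(g) {
    tb <- groups[[g]]
    n <- tapply(tb$value, tb$region, length)
    if (any(n < 2L)) stop("need >= 2 subjects per group and region", call. = FALSE)
    mu <- tapply(tb$value, tb$region, mean)
    if (any(mu <= 0)) stop("non-positive region mean", call. = FALSE)
    s <- tapply(tb$value, tb$region, sd)
    data.frame(group = g, region = names(mu), cv = as.numeric(s / mu))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-region medians of a 3D image
#'
#' Median voxel value within each atlas region (even counts take the
#' midpoint), as used for regional fractional anisotropy summaries.
#' Regions without labelled voxels get NA and are flagged.
#'
#' @param image 3D numeric array.
#' @param atlas A [label_volume()] on the same grid.
#' @param regions Optional subset of region names.
#' @return Data frame `region`, `value`; attribute `empty_regions`.
#' @export
roi_median <- function(image, atlas, regions = NULL) {
  stopifnot(inherits(atlas, "label_volume"))
  if (!identical(dim(image), dim(atlas$labels))) {
    stop("image and atlas grids differ in shape", call. = FALSE)
  }
  wanted <- if (is.null(regions)) unname(atlas$lookup) else as.character(regions)
  if (!length(wanted)) stop("`regions` must be non-empty", call. = FALSE)
  unknown <- setdiff(wanted, atlas$lookup)
  if (length(unknown)) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lab <- as.vector(atlas$labels)
  vals <- as.vector(image)
  med <- vapply(wanted, function(rg) {
    code <- as.integer(names(atlas$lookup)[atlas$lookup == rg])
    v <- vals[lab %in% code]
    if (!length(v)) NA_real_ else median(v)
  }, numeric(1L))
  out <- data.frame(region = wanted, value = unname(med))
  attr(out, "empty_regions") <- wanted[is.na(med)]
  out
}
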