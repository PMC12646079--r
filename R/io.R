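#' Write / read a participants table as TSV
#'
#' Columns: subject_id, genotype, sex, litter_id, timepoint.
#' @param cohort Cohort table.
#' @param path File path.
#' @return `read_participants` returns the cohort data frame.
#' @export
write_participants <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read one session's ROI time courses as TSV
#'
#' T rows by R columns, header row of ROI names.
#' @param tc T x R time-course matrix.
#' @param path File path.
#' @return `read_timecourse` returns the numeric matrix.
#' @export
write_timecourse <- function(tc, path) {
  write.table(tc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Write / read a connectivity matrix as TSV with ROI-name header
#'
#' @param fc Symmetric matrix with ROI dimnames.
#' @param path File path.
#' @return `read_fc_matrix` returns the matrix with dimnames restored.
#' @export
write_fc_matrix <- function(fc, path) {
  write.table(fc, path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a long-format regional or curve table as TSV
#' @param table Data frame.
#' @param path File path.
#' @export
write_regional_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read network definitions as YAML or JSON
#'
#' The file maps network names to ROI-name lists; format is chosen from
#' the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param networks Named list of [network_definition()]s.
#' @param path File path.
#' @return `read_networks` returns a named list of
#'   [network_definition()]s.
#' @export
write_networks <- function(networks, path) {
  lst <- lapply(networks, `[[`, "rois")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_networks
#' @export
read_networks <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  nets <- lapply(names(lst), function(nm) {
    network_definition(nm, unlist(lst[[nm]]))
  })
  names(nets) <- names(lst)
  nets
}

#' Write / read a simulation configuration as YAML
#' @param cfg A [sim_config()].
#' @param path File path.
#' @return `read_sim_config` returns a validated [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$modules <- lapply(lst$modules, `[[`, "rois")
  if (!is.null(lst$effect_edges)) {
    lst$effect_edges <- apply(lst$effect_edges, 1L, paste, collapse = "|")
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$modules <- lapply(names(lst$modules), function(nm) {
    network_definition(nm, unlist(lst$modules[[nm]]))
  })
  names(lst$modules) <- vapply(lst$modules, `[[`, character(1L), "name")
  if (!is.null(lst$effect_edges)) {
    lst$effect_edges <- do.call(rbind, strsplit(unlist(lst$effect_edges), "|",
                                                fixed = TRUE))
  }
  do.call(sim_config, lst)
}

#' Write / read a 3D image as NIfTI
#'
#' Voxel size (mm) is recorded in the header.
#' @param values 3D numeric array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel edge in mm.
#' @return `read_nifti_image` returns a list with `values` (plain array)
#'   and `voxel_size`.
#' @export
write_nifti_image <- function(values, path, voxel_size = 0.15) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(voxel_size, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)),
       voxel_size = RNifti::pixdim(img)[1L])
}

#' Serialize a test result to JSON with its provenance
#'
#' Records the statistic, p-value, permutation count and seed so that a
#' rerun with the same configuration reproduces the file byte for byte.
#'
#' @param result An `auc_test`, `nbs_result` or `fwe_result`.
#' @param path File path.
#' @export
write_result_json <- function(result, path) {
  payload <- unclass(result)
  payload$null_max_sizes <- NULL
  payload$null_max <- NULL
  payload$p <- NULL
  payload$tfce_obs <- NULL
  payload$t_obs <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
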