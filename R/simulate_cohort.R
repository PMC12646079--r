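#' Generate a littermate-design study cohort
#'
#' Lays out `2 genotypes x 2 sexes x n_per_cell` subjects, each scanned at
#' both timepoints (adolescence and adulthood). Litters are assigned
#' round-robin within genotype so that every litter contains both
#' wild-type and knockout animals whenever `n_per_cell >= 2` — the
#' littermate-control design in which mutants and their wild-type siblings
#' share litter environment.
#'
#' @param cfg A [sim_config()].
#' @param n_litters Number of litters; default targets about 3-4 pups per
#'   litter.
#' @return Data frame with one row per subject-session: `subject_id`,
#'   `genotype` (`wildtype`/`knockout`), `sex` (`F`/`M`), `litter_id`,
#'   `timepoint` (`adolescence`/`adulthood`). `(subject_id, timepoint)` is
#'   unique.
#' @export
make_cohort <- function(cfg, n_litters = NULL) {
  n_subjects <- 4L * cfg$n_per_cell
  if (is.null(n_litters)) n_litters <- max(1L, ceiling(n_subjects / 3.5))
  cells <- expand.grid(
    genotype = c("wildtype", "knockout"),
    sex = c("F", "M"),
    replicate = seq_len(cfg$n_per_cell),
    stringsAsFactors = FALSE
  )
  ord <- order(cells$genotype == "knockout", cells$sex, cells$replicate)
  cells <- cells[ord, ]
  cells$subject_id <- sprintf("sub-%03d", seq_len(n_subjects))
  # round-robin litter assignment within genotype: the i-th wildtype and
  # the i-th knockout land in the same litter cycle, so litters mix
  # genotypes as soon as each genotype has >= n_litters animals
  for (g in c("wildtype", "knockout")) {
    sel <- cells$genotype == g
    cells$litter_id[sel] <- sprintf(
      "litter-%02d", ((seq_len(sum(sel)) - 1L) %% n_litters) + 1L
    )
  }
  records <- merge(
    cells[, c("subject_id", "genotype", "sex", "litter_id")],
    data.frame(timepoint = c("adolescence", "adulthood")),
    by = NULL
  )
  records <- records[order(records$subject_id, records$timepoint), ]
  rownames(records) <- NULL
  records
}

#' Subjects present in a cohort table
#' @param cohort Output of [make_cohort()].
#' @return Data frame with one row per subject.
#' @export
cohort_subjects <- function(cohort) {
  unique(cohort[, c("subject_id", "genotype", "sex", "litter_id")])
}

session_key <- function(subject_id, timepoint) paste(subject_id, timepoint, sep = "_")
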