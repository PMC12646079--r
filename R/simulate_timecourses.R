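#' Simulate ROI BOLD time courses for every subject-session
#'
#' Each session draws `n_timepoints_scan` samples from a zero-mean
#' multivariate normal whose correlation matrix is the configuration's
#' modular target ([target_correlation()]; knockout sessions include the
#' genotype edge effect), then applies stationary AR(1) temporal
#' filtering with coefficient `ar1_coef`. The filter is shared across
#' ROIs, so the zero-lag cross-correlation structure is preserved while
#' successive samples acquire BOLD-like temporal smoothness. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config()]; `n_timepoints_scan` must be >= 50.
#' @param cohort Cohort table from [make_cohort()].
#' @return Named list (one element per subject-session,
#'   `"<subject>_<timepoint>"`) of T x R matrices with ROI column names
#'   and attributes `subject_id`, `timepoint`, `genotype`. The list
#'   carries attribute `correlation_repaired` per genotype.
#' @export
simulate_timecourses <- function(cfg, cohort) {
  if (cfg$n_timepoints_scan < 50L) {
    stop("n_timepoints_scan must be >= 50", call. = FALSE)
  }
  targets <- list(
    wildtype = target_correlation(cfg, "wildtype"),
    knockout = target_correlation(cfg, "knockout")
  )
  chols <- lapply(targets, function(t) chol(t$matrix))
  TT <- cfg$n_timepoints_scan
  R <- cfg$n_rois
  a <- cfg$ar1_coef
  out <- with_seed(cfg$seed, {
    sessions <- vector("list", nrow(cohort))
    names(sessions) <- session_key(cohort$subject_id, cohort$timepoint)
    for (k in seq_len(nrow(cohort))) {
      g <- cohort$genotype[k]
      innov <- matrix(rnorm(TT * R), TT, R) %*% chols[[g]]
      x <- innov
      if (a > 0) {
        s <- sqrt(1 - a^2)
        for (t in 2:TT) x[t, ] <- a * x[t - 1L, ] + s * innov[t, ]
      }
      colnames(x) <- cfg$roi_names
      attr(x, "subject_id") <- cohort$subject_id[k]
      attr(x, "timepoint") <- cohort$timepoint[k]
      attr(x, "genotype") <- g
      sessions[[k]] <- x
    }
    sessions
  })
  attr(out, "correlation_repaired") <- vapply(targets, `[[`, logical(1L), "repaired")
  out
}
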