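#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integration over the sparsity axis expressed in percentage
#' points, giving one threshold-free summary statistic per subject and
#' metric (e.g. a constant mean-FC of 0.5 over 5-50% integrates to 22.5).
#'
#' @param values Metric values, one per sparsity level.
#' @param levels Sparsity levels in percent (default 5-50% by 5%); at
#'   least two.
#' @return Scalar AUC in metric-units x percent.
#' @export
auc <- function(values, levels = seq(5, 50, by = 5)) {
  if (length(values) < 2L) stop("AUC needs at least 2 sparsity levels", call. = FALSE)
  if (length(values) != length(levels)) {
    stop("`values` and `levels` differ in length", call. = FALSE)
  }
  pracma::trapz(as.numeric(levels), as.numeric(values))
}

#' Per-subject AUCs from a set of metric curves
#'
#' @param curves Named list of [metric_curves()] data frames (one per
#'   subject-session).
#' @param metric Metric to extract.
#' @return Named numeric vector of AUCs.
#' @export
curve_aucs <- function(curves, metric) {
  vapply(curves, function(cv) {
    sel <- cv$metric == metric
    auc(cv$value[sel], cv$sparsity[sel])
  }, numeric(1L))
}

#' Two-group permutation test on AUC values
#'
#' The statistic is the difference of group mean AUCs. Group labels are
#' shuffled `n_perm` times and the two-sided p-value uses the add-one
#' estimator `(1 + #permutations with |diff| >= |observed|) / (1 +
#' n_perm)`, so p has resolution `1/(n_perm + 1)` and can never be zero.
#'
#' @param auc_a,auc_b Numeric vectors of per-subject AUCs (>= 2 each).
#' @param n_perm Number of label permutations (default 10000, as used
#'   for the full-scale analyses; < 100 draws a warning).
#' @param seed Optional RNG seed; recorded in the result.
#' @return An `auc_test` list: `group_means`, `observed_diff`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
auc_permutation_test <- function(auc_a, auc_b, n_perm = 10000L, seed = NULL) {
  if (length(auc_a) < 1L || length(auc_b) < 1L) stop("empty group", call. = FALSE)
  if (length(auc_a) < 2L || length(auc_b) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (n_perm < 100L) warning("fewer than 100 permutations", call. = FALSE)
  pooled <- c(auc_a, auc_b)
  nA <- length(auc_a); n <- length(pooled)
  total <- sum(pooled)
  # same arithmetic path as the permuted statistics, so exact ties (e.g.
  # the identity relabelling) compare bit-identically
  sA0 <- sum(auc_a)
  obs <- sA0 / nA - (total - sA0) / (n - nA)
  # exact ties (identity and complement relabellings) must count as
  # "as extreme"; a scaled epsilon absorbs last-bit float differences
  cut <- abs(obs) - sqrt(.Machine$double.eps) * max(abs(pooled), 1)
  p_value <- with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      sA <- sum(pooled[sample.int(n, nA)])
      d <- sA / nA - (total - sA) / (n - nA)
      if (abs(d) >= cut) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + n_perm)
  })
  structure(
    list(group_means = c(sA0 / nA, (total - sA0) / (n - nA)),
         observed_diff = obs,
         p_value = p_value, n_permutations = as.integer(n_perm), seed = seed),
    class = "auc_test"
  )
}
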