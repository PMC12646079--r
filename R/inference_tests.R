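#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure (via
#' [stats::p.adjust()]): adjusted values are monotone in the ordered
#' p-values and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and chi-square p-value (via
#' [stats::kruskal.test()]). Completely tied data (all values identical)
#' return H = 0, p = 1.
#'
#' @param groups List of >= 2 numeric vectors, each non-empty.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1L)) < 1L)) {
    stop("every group needs at least one value", call. = FALSE)
  }
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1L) return(list(H = 0, p = 1))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Per-unit longitudinal change with one-sample t-tests
#'
#' Matches subjects across the two timepoints, computes the per-subject
#' change `t2 - t1` for every unit (region or sparsity level), tests each
#' unit's mean change against zero with a two-sided one-sample t-test,
#' and BH-corrects within the unit family. Unmatched subjects are dropped
#' with a reported count; units with zero change variance get an
#' undefined p (NA) and are flagged.
#'
#' @param values_t1,values_t2 Long-format data frames with columns
#'   `subject_id`, the unit column, and `value`.
#' @param unit_col Name of the unit column (default `"region"`).
#' @return A `change_result` data frame: unit, `n`, `delta_mean`,
#'   `t_stat`, `p`, `q`; attributes `dropped_subjects` and
#'   `zero_variance_units`.
#' @export
longitudinal_change <- function(values_t1, values_t2, unit_col = "region") {
  for (df in list(values_t1, values_t2)) {
    if (!all(c("subject_id", unit_col, "value") %in% names(df))) {
      stop("inputs need columns subject_id, ", unit_col, ", value", call. = FALSE)
    }
  }
  s1 <- unique(values_t1$subject_id)
  s2 <- unique(values_t2$subject_id)
  matched <- intersect(s1, s2)
  dropped <- length(setdiff(union(s1, s2), matched))
  if (length(matched) < 2L) stop("fewer than 2 matched subjects", call. = FALSE)
  t1 <- values_t1[values_t1$subject_id %in% matched, ]
  t2 <- values_t2[values_t2$subject_id %in% matched, ]
  key1 <- paste(t1$subject_id, t1[[unit_col]])
  key2 <- paste(t2$subject_id, t2[[unit_col]])
  if (anyDuplicated(key1) || anyDuplicated(key2)) {
    stop("duplicate subject-unit rows", call. = FALSE)
  }
  t2 <- t2[match(key1, key2), ]
  if (anyNA(t2$value)) stop("unit sets differ across timepoints", call. = FALSE)
  delta <- t2$value - t1$value
  units <- t1[[unit_col]]
  ulev <- unique(units)
  n <- tapply(delta, units, length)[ulev]
  dm <- tapply(delta, units, mean)[ulev]
  dsd <- tapply(delta, units, sd)[ulev]
  tstat <- dm / (dsd / sqrt(n))
  zero <- dsd == 0
  tstat[zero & dm == 0] <- 0
  p <- 2 * pt(-abs(tstat), n - 1)
  p[zero] <- NA_real_
  q <- benjamini_hochberg(p)
  out <- data.frame(
    unit = ulev, n = as.integer(n), delta_mean = as.numeric(dm),
    t_stat = as.numeric(tstat), p = as.numeric(p), q = as.numeric(q)
  )
  names(out)[1L] <- unit_col
  attr(out, "dropped_subjects") <- dropped
  attr(out, "zero_variance_units") <- sum(zero)
  class(out) <- c("change_result", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the repeated measures (double-centred covariance formulation).
gg_epsilon <- function(wide, groups) {
  b <- ncol(wide)
  Ss <- lapply(split(seq_len(nrow(wide)), groups), function(idx) {
    if (length(idx) < 2L) return(NULL)
    (length(idx) - 1L) * stats::cov(wide[idx, , drop = FALSE])
  })
  Ss <- Filter(Negate(is.null), Ss)
  S <- Reduce(`+`, Ss) / (nrow(wide) - length(Ss))
  rm_ <- rowMeans(S); cm <- colMeans(S); gm <- mean(S)
  M <- S - outer(rm_, rep(1, b)) - outer(rep(1, b), cm) + gm
  sum(diag(M))^2 / ((b - 1) * sum(M^2))
}

#' Mixed-design ANOVA (one between factor, one within factor)
#'
#' Classical sums-of-squares mixed ANOVA for a design with one
#' between-subjects factor (e.g. genotype) and one complete
#' within-subjects factor (e.g. region): every subject contributes one
#' value per within level, group sizes may differ. Reports F, degrees of
#' freedom, p and partial eta-squared for the between effect (tested
#' against the between-subject error), the within effect and the
#' interaction (tested against the within-subject error). An optional
#' Greenhouse-Geisser sphericity correction rescales the within-stratum
#' degrees of freedom.
#'
#' @param data Long-format data frame.
#' @param dv,between,within,subject Column names.
#' @param gg Apply the Greenhouse-Geisser correction (default FALSE).
#' @return A `mixed_anova` list with per-effect entries `F`, `df1`,
#'   `df2`, `p`, `pes`, plus the sums-of-squares table.
#' @export
mixed_anova <- function(data, dv = "value", between = "genotype",
                        within = "region", subject = "subject_id",
                        gg = FALSE) {
  y <- data[[dv]]
  A <- factor(data[[between]])
  B <- factor(data[[within]])
  S <- factor(data[[subject]])
  if (anyNA(y)) stop("missing values in the response", call. = FALSE)
  counts <- table(S, B)
  if (any(counts != 1L)) {
    stop("design must be balanced: one value per subject and within level",
         call. = FALSE)
  }
  a <- nlevels(A); b <- nlevels(B)
  subj_group <- tapply(as.character(A), S, unique)
  n_j <- table(factor(subj_group, levels = levels(A)))
  if (any(n_j < 2L)) stop("need >= 2 subjects per group", call. = FALSE)
  N <- sum(n_j)
  GM <- mean(y)
  SS_T <- sum((y - GM)^2)
  A_mean <- tapply(y, A, mean)
  B_mean <- tapply(y, B, mean)
  S_mean <- tapply(y, S, mean)
  cell <- tapply(y, list(A, B), mean)
  SS_A <- b * sum(n_j * (A_mean - GM)^2)
  SS_S <- b * sum((S_mean - A_mean[subj_group])^2)
  SS_B <- N * sum((B_mean - GM)^2)
  SS_AB <- sum(outer(as.numeric(n_j), rep(1, b)) *
                 (cell - outer(A_mean, rep(1, b)) -
                    outer(rep(1, a), B_mean) + GM)^2)
  SS_E <- SS_T - SS_A - SS_S - SS_B - SS_AB
  df_A <- a - 1L; df_S <- N - a
  df_B <- b - 1L; df_AB <- (a - 1L) * (b - 1L); df_E <- (N - a) * (b - 1L)
  eps <- 1
  if (gg) {
    wide <- matrix(NA_real_, N, b, dimnames = list(levels(S), levels(B)))
    wide[cbind(as.integer(S), as.integer(B))] <- y
    eps <- gg_epsilon(wide, subj_group[levels(S)])
  }
  eff <- function(ssn, dfn, sse, dfe, scale = 1) {
    Fv <- (ssn / dfn) / (sse / dfe)
    list(F = Fv, df1 = dfn * scale, df2 = dfe * scale,
         p = stats::pf(Fv, dfn * scale, dfe * scale, lower.tail = FALSE),
         pes = ssn / (ssn + sse))
  }
  structure(
    list(
      between = eff(SS_A, df_A, SS_S, df_S),
      within = eff(SS_B, df_B, SS_E, df_E, eps),
      interaction = eff(SS_AB, df_AB, SS_E, df_E, eps),
      ss = c(between = SS_A, subjects = SS_S, within = SS_B,
             interaction = SS_AB, error = SS_E, total = SS_T),
      gg_epsilon = if (gg) eps else NA_real_
    ),
    class = "mixed_anova"
  )
}

#' Minimum detectable Cohen's d of a two-sample t-test
#'
#' The smallest standardized mean difference for which a two-sided
#' two-sample t-test at level `alpha` attains the target power, computed
#' from the noncentral t distribution (df = n1 + n2 - 2, noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))`) by bisection to 1e-6. At the study's
#' sample size of 34 per group this evaluates to about 0.69, i.e. 80%
#' power for moderate effects of d = 0.7.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (alpha, 1).
#' @return Minimum detectable Cohen's d.
#' @export
min_detectable_d <- function(n1, n2, alpha = 0.05, power = 0.80) {
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= alpha || power >= 1) {
    stop("power must lie in (alpha, 1)", call. = FALSE)
  }
  df <- n1 + n2 - 2
  mult <- sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * mult
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  }
  hi <- 1
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > 1e4) stop("target power unattainable", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pow(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
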