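split_sessions <- function(sessions, what, value) {
  sessions[vapply(sessions, function(s) attr(s, what) == value, logical(1L))]
}

#' End-to-end functional connectivity pipeline
#'
#' Runs the full resting-state analysis graph on a simulated cohort:
#' time courses to Fisher-z matrices, metric-versus-sparsity curves, AUC
#' permutation tests per timepoint (with a Bonferroni report across the
#' three global metrics), one-sample change-over-time tests BH-corrected
#' across the sparsity levels, edge-wise FDR and NBS per timepoint, node
#' strength with mixed ANOVA, and within-network mean FC and weighted
#' efficiency with BH-corrected genotype t-tests. One seed per test
#' family is derived from the configuration's master seed, and every
#' stochastic result records its seed.
#'
#' @param cfg A [sim_config()].
#' @param n_perm Permutations per test family (default 1000 for desk
#'   runs; the full-scale analyses use 10000).
#' @param sparsity_levels Sparsity grid in percent.
#' @param networks Named list of [network_definition()]s.
#' @param nbs_threshold |t| cutoff for the NBS suprathreshold graph.
#' @return A result bundle (list) with elements `cohort`, `fc`,
#'   `curves`, `auc_tests`, `change`, `edge_stats`, `nbs`,
#'   `node_strength`, `networks`, `seeds`.
#' @export
run_fc_pipeline <- function(cfg, n_perm = 1000L,
                            sparsity_levels = seq(5, 50, by = 5),
                            networks = default_networks(),
                            nbs_threshold = 2) {
  cohort <- make_cohort(cfg)
  sessions <- simulate_timecourses(cfg, cohort)
  fc <- lapply(sessions, function(tc) {
    z <- fisher_z(pearson_fc(tc))
    attributes(z)[c("subject_id", "timepoint", "genotype")] <-
      attributes(tc)[c("subject_id", "timepoint", "genotype")]
    z
  })
  curves <- lapply(fc, metric_curves, levels = sparsity_levels)
  for (k in seq_along(curves)) {
    attributes(curves[[k]])[c("subject_id", "timepoint", "genotype")] <-
      attributes(fc[[k]])[c("subject_id", "timepoint", "genotype")]
  }
  seeds <- list(auc = cfg$seed + 101L, nbs = cfg$seed + 202L,
                change = cfg$seed + 303L)
  metrics <- c("mean_fc", "global_efficiency", "clustering_coefficient")
  by_tp <- function(objs, tp) split_sessions(objs, "timepoint", tp)
  by_gt <- function(objs, gt) split_sessions(objs, "genotype", gt)

  auc_tests <- list()
  for (tp in c("adolescence", "adulthood")) {
    cv_tp <- by_tp(curves, tp)
    tests <- lapply(metrics, function(m) {
      a <- curve_aucs(by_gt(cv_tp, "wildtype"), m)
      b <- curve_aucs(by_gt(cv_tp, "knockout"), m)
      auc_permutation_test(a, b, n_perm = n_perm, seed = seeds$auc)
    })
    names(tests) <- metrics
    # Bonferroni across the three global metrics at the reporting layer
    for (m in metrics) {
      tests[[m]]$p_bonferroni <- min(1, tests[[m]]$p_value * length(metrics))
    }
    auc_tests[[tp]] <- tests
  }

  # change over time: per-subject adulthood - adolescence curves
  change <- list()
  change_curves <- list()
  subjects <- cohort_subjects(cohort)
  for (m in metrics) {
    long_tp <- function(tp) {
      cvs <- by_tp(curves, tp)
      do.call(rbind, lapply(cvs, function(cv) {
        sel <- cv$metric == m
        data.frame(subject_id = attr(cv, "subject_id"),
                   sparsity = cv$sparsity[sel], value = cv$value[sel])
      }))
    }
    t1 <- long_tp("adolescence"); t2 <- long_tp("adulthood")
    change[[m]] <- longitudinal_change(t1, t2, unit_col = "sparsity")
    # genotype comparison of the change curves by AUC permutation
    wide <- function(df) {
      m2 <- tapply(df$value, list(df$subject_id, df$sparsity), mean)
      m2[order(rownames(m2)), order(as.numeric(colnames(m2)))]
    }
    w1 <- wide(t1); w2 <- wide(t2)
    delta <- w2 - w1
    aucs <- apply(delta, 1L, auc, levels = sparsity_levels)
    gt <- subjects$genotype[match(rownames(delta), subjects$subject_id)]
    change_curves[[m]] <- auc_permutation_test(
      aucs[gt == "wildtype"], aucs[gt == "knockout"],
      n_perm = n_perm, seed = seeds$change
    )
  }

  edge_stats <- list(); nbs_res <- list(); strength <- list(); net_res <- list()
  for (tp in c("adolescence", "adulthood")) {
    fc_tp <- by_tp(fc, tp)
    ga <- by_gt(fc_tp, "wildtype"); gb <- by_gt(fc_tp, "knockout")
    edge_stats[[tp]] <- edgewise_ttests(ga, gb)
    nbs_res[[tp]] <- nbs(ga, gb, threshold = nbs_threshold,
                         n_perm = n_perm, seed = seeds$nbs)
    ns_long <- do.call(rbind, lapply(fc_tp, function(z) {
      cbind(subject_id = attr(z, "subject_id"),
            genotype = attr(z, "genotype"), node_strength(z))
    }))
    strength[[tp]] <- list(
      table = ns_long,
      anova = mixed_anova(ns_long, between = "genotype", within = "region")
    )
    # within-network analyses: genotype t-tests BH-corrected per outcome
    per_net <- function(fun) {
      vals <- lapply(networks, function(net) {
        va <- vapply(ga, fun, numeric(1L), net = net)
        vb <- vapply(gb, fun, numeric(1L), net = net)
        tt <- stats::t.test(va, vb, var.equal = TRUE)
        data.frame(network = net$name, mean_wildtype = mean(va),
                   mean_knockout = mean(vb), t = unname(tt$statistic),
                   p = tt$p.value)
      })
      out <- do.call(rbind, vals)
      out$q <- benjamini_hochberg(out$p)
      rownames(out) <- NULL
      out
    }
    net_res[[tp]] <- list(
      mean_fc = per_net(network_mean_fc),
      weighted_efficiency = per_net(weighted_efficiency)
    )
  }

  list(cohort = cohort, fc = fc, curves = curves, auc_tests = auc_tests,
       change = change, change_auc_tests = change_curves,
       edge_stats = edge_stats, nbs = nbs_res, node_strength = strength,
       networks = net_res, seeds = seeds,
       config = cfg, n_perm = as.integer(n_perm))
}

#' End-to-end morphometry pipeline
#'
#' Simulates regional volume and FA tables for the cohort, audits
#' regional volume variability with per-genotype coefficients of
#' variation compared by Kruskal-Wallis at each timepoint, and tests the
#' developmental FA change per region with BH-corrected one-sample
#' t-tests plus a genotype-by-region mixed ANOVA on the change.
#'
#' @param cfg A [sim_config()].
#' @return Result bundle: `cohort`, `volumes`, `cv` (per-timepoint CV
#'   tables with Kruskal-Wallis results), `fa`, `fa_change`,
#'   `fa_change_anova`.
#' @export
run_morphometry_pipeline <- function(cfg) {
  cohort <- make_cohort(cfg)
  volumes <- simulate_regional_volumes(cfg, cohort)
  cv <- list()
  for (tp in c("adolescence", "adulthood")) {
    tab <- region_cv(volumes[volumes$timepoint == tp, ],
                     group_col = "genotype", value_kind = "absolute_mm3")
    kw <- kruskal_wallis(split(tab$cv, tab$group))
    cv[[tp]] <- list(table = tab, kruskal_wallis = kw)
  }
  fa <- simulate_fa_table(cfg, cohort)
  fa_change <- longitudinal_change(
    fa[fa$timepoint == "adolescence", ],
    fa[fa$timepoint == "adulthood", ]
  )
  # genotype x region mixed ANOVA on the per-subject FA change
  t1 <- fa[fa$timepoint == "adolescence", ]
  t2 <- fa[fa$timepoint == "adulthood", ]
  key <- paste(t1$subject_id, t1$region)
  t2 <- t2[match(key, paste(t2$subject_id, t2$region)), ]
  delta <- data.frame(subject_id = t1$subject_id, genotype = t1$genotype,
                      region = t1$region, value = t2$value - t1$value)
  list(cohort = cohort, volumes = volumes, cv = cv, fa = fa,
       fa_change = fa_change,
       fa_change_anova = mixed_anova(delta, between = "genotype",
                                     within = "region"),
       config = cfg)
}
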