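test_that("cohort layout crosses genotype, sex and timepoint", {
  cfg <- sim_config(n_per_cell = 9)
  coh <- make_cohort(cfg)
  expect_equal(nrow(coh), 72)
  subj <- cohort_subjects(coh)
  expect_equal(nrow(subj), 36)
  expect_equal(as.vector(table(subj$genotype)), c(18L, 18L))
  expect_equal(as.vector(table(subj$sex)), c(18L, 18L))
  expect_false(anyDuplicated(paste(coh$subject_id, coh$timepoint)) > 0)
  expect_setequal(unique(coh$timepoint), c("adolescence", "adulthood"))

  coh1 <- make_cohort(sim_config(n_per_cell = 1))
  expect_equal(nrow(coh1), 8)
  expect_equal(nrow(cohort_subjects(coh1)), 4)
})

test_that("round-robin litters mix genotypes whenever n_per_cell >= 2", {
  for (npc in 2:6) {
    subj <- cohort_subjects(make_cohort(sim_config(n_per_cell = npc)))
    mix <- tapply(subj$genotype, subj$litter_id,
                  function(g) length(unique(g)))
    expect_true(all(mix == 2), info = paste("n_per_cell =", npc))
  }
})

test_that("simulated time courses are deterministic and well shaped", {
  cfg <- sim_config(n_per_cell = 1, n_timepoints_scan = 80, seed = 11)
  coh <- make_cohort(cfg)
  a <- simulate_timecourses(cfg, coh)
  b <- simulate_timecourses(cfg, coh)
  expect_identical(a, b)
  expect_length(a, nrow(coh))
  expect_equal(dim(a[[1]]), c(80L, 36L))
  expect_equal(colnames(a[[1]]), cfg$roi_names)
})

test_that("empirical correlations converge to the modular target", {
  cfg <- sim_config(n_per_cell = 1, n_timepoints_scan = 10000,
                    r_within = 0.6, r_between = 0.1, ar1_coef = 0.3,
                    seed = 21)
  coh <- make_cohort(cfg)[1, , drop = FALSE]
  tc <- simulate_timecourses(cfg, coh)[[1]]
  r <- pearson_fc(tc)
  within_pairs <- do.call(rbind, lapply(default_networks(), function(net) {
    t(combn(match(net$rois, cfg$roi_names), 2))
  }))
  expect_gt(mean(r[within_pairs]), 0.58)
  expect_lt(mean(r[within_pairs]), 0.62)

  # null structure: identity target, no autocorrelation
  cfg0 <- sim_config(n_per_cell = 1, n_timepoints_scan = 2000,
                     r_within = 0, r_between = 0, ar1_coef = 0, seed = 22)
  tc0 <- simulate_timecourses(cfg0, coh)[[1]]
  r0 <- pearson_fc(tc0)
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.05)
})

test_that("Frobenius distance to the target shrinks with scan length", {
  target <- target_correlation(sim_config(), "wildtype")$matrix
  dists <- vapply(c(200, 2000, 20000), function(TT) {
    cfg <- sim_config(n_per_cell = 1, n_timepoints_scan = TT, ar1_coef = 0,
                      seed = 33)
    coh <- make_cohort(cfg)[1, , drop = FALSE]
    r <- pearson_fc(simulate_timecourses(cfg, coh)[[1]])
    sqrt(sum((r - target)^2))
  }, numeric(1))
  expect_true(all(diff(dists) < 0))
})

test_that("knockout sessions carry the planted edge effect", {
  cfg <- sim_config(n_per_cell = 1, genotype_edge_delta = 0.3)
  tw <- target_correlation(cfg, "wildtype")$matrix
  tk <- target_correlation(cfg, "knockout")$matrix
  dmn <- match(default_networks()$dmn$rois, cfg$roi_names)
  off <- setdiff(seq_len(36), dmn)
  expect_true(all(tk[t(combn(dmn, 2))] > tw[t(combn(dmn, 2))]))
  expect_equal(tk[off, off], tw[off, off], tolerance = 0.05)
})

test_that("correlation repair floors eigenvalues and is flagged", {
  C <- matrix(0.99, 3, 3)
  C[1, 2] <- C[2, 1] <- -0.99
  rep <- repair_correlation(C)
  expect_true(rep$repaired)
  ev <- eigen(rep$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(diag(rep$matrix), rep(1, 3))
  ok <- repair_correlation(diag(3))
  expect_false(ok$repaired)
})

test_that("regional volume generator honours region count and CV", {
  cfg <- sim_config(n_per_cell = 2, volume_region_count = 72, seed = 5)
  coh <- make_cohort(cfg)
  vol <- simulate_regional_volumes(cfg, coh)
  expect_equal(length(unique(vol$region)), 72)
  expect_equal(nrow(vol), nrow(coh) * 72)

  cfg0 <- sim_config(n_per_cell = 2, volume_cv = 0, seed = 5)
  vol0 <- simulate_regional_volumes(cfg0, coh)
  one <- vol0[vol0$timepoint == "adolescence" & vol0$sex == "F", ]
  spread <- tapply(one$value, one$region, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("FA tables are paired, clamped, and spare the olfactory tract", {
  cfg <- sim_config(n_per_cell = 8, developmental_delta_fa = 0.03,
                    fa_noise_sd = 0.01, seed = 6)
  coh <- make_cohort(cfg)
  fa <- simulate_fa_table(cfg, coh)
  expect_true(all(fa$value >= 0 & fa$value <= 1))
  wide <- merge(fa[fa$timepoint == "adolescence", c("subject_id", "region", "value")],
                fa[fa$timepoint == "adulthood", c("subject_id", "region", "value")],
                by = c("subject_id", "region"))
  delta <- tapply(wide$value.y - wide$value.x, wide$region, mean)
  expect_lt(abs(delta[["olfactory_tract"]]), 0.005)
  expect_true(all(delta[setdiff(names(delta), "olfactory_tract")] > 0.02))
})

test_that("stat images mask the border and plant the sphere in knockouts", {
  cfg <- sim_config(n_per_cell = 2, image_shape = c(10, 10, 10),
                    signal_amplitude = 5, signal_radius = 2, seed = 8)
  sim <- simulate_stat_images(cfg)
  d <- dim(sim$mask)
  expect_false(any(sim$mask[1, , ]) || any(sim$mask[d[1], , ]))
  expect_false(any(sim$mask[, 1, ]) || any(sim$mask[, , d[3]]))
  expect_true(sum(sim$signal) > 0)
  ko <- Reduce(`+`, sim$images[sim$groups == "knockout"]) /
    sum(sim$groups == "knockout")
  wt <- Reduce(`+`, sim$images[sim$groups == "wildtype"]) /
    sum(sim$groups == "wildtype")
  expect_gt(mean(ko[sim$signal]) - mean(wt[sim$signal]), 3)
  sim2 <- simulate_stat_images(cfg)
  expect_identical(sim$images, sim2$images)
})
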