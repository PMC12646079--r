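test_that("trapezoidal AUC over the percent grid", {
  expect_equal(auc(rep(0.5, 10)), 22.5)
  expect_equal(auc(seq(0, 1, length.out = 10)), 22.5)
  expect_error(auc(1), "2 sparsity levels")
  # a flat curve near 0.57 lands on the reported FC AUC scale (~25.5)
  expect_equal(auc(rep(0.567, 10)), 25.5, tolerance = 0.02)
})

test_that("AUC permutation test is valid on ties and against enumeration", {
  a <- c(1.2, 1.6, 1.9)
  res <- auc_permutation_test(a, a, n_perm = 300, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_diff, 0)

  set.seed(15)
  for (rep in 1:3) {
    x <- rnorm(3) + 1
    y <- rnorm(3)
    mc <- auc_permutation_test(x, y, n_perm = 20000, seed = rep)$p_value
    exact <- oracle_exhaustive_perm_p(x, y)
    expect_lt(abs(mc - exact), 0.02)
  }
  expect_error(auc_permutation_test(1, c(1, 2)), "2 subjects")
  expect_warning(auc_permutation_test(c(1, 2), c(3, 4), n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("edge-wise t tests cover the 630-edge family with BH", {
  set.seed(16)
  ga <- replicate(5, random_fc_matrix(36), simplify = FALSE)
  res_id <- edgewise_ttests(ga, ga)
  expect_true(all(res_id$t[upper.tri(res_id$t)] == 0))
  expect_true(all(res_id$q[upper.tri(res_id$q)] == 1))
  expect_equal(res_id$n_edges, 630)
  expect_true(all(is.na(diag(res_id$t))))

  # planted single-edge shift of 1.5 pooled sd at n = 30/group
  mk <- function(shift) {
    m <- random_fc_matrix(10)
    m[1, 2] <- m[2, 1] <- m[1, 2] + shift
    m
  }
  ga <- replicate(30, mk(0), simplify = FALSE)
  gb <- replicate(30, mk(1.5), simplify = FALSE)
  res <- edgewise_ttests(ga, gb)
  expect_lt(res$q[1, 2], 0.05)
  expect_equal(res$df, 58)
  # q >= p on the upper triangle
  expect_true(all(res$q[upper.tri(res$q)] >= res$p[upper.tri(res$p)]))
})

test_that("BFS components match the adjacency structure and igraph", {
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  comps <- bfs_components(adj)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$nodes, 1:3)
  expect_equal(comps[[1]]$n_edges, 2)

  adj2 <- matrix(0, 6, 6)
  adj2[1, 2] <- adj2[2, 1] <- 1
  adj2[4, 5] <- adj2[5, 4] <- 1
  comps2 <- bfs_components(adj2)
  expect_length(comps2, 2)
  expect_equal(max(vapply(comps2, `[[`, numeric(1), "n_edges")), 1)

  set.seed(17)
  for (rep in 1:10) {
    A <- matrix(0, 12, 12)
    A[upper.tri(A)] <- rbinom(66, 1, 0.12)
    A <- A + t(A)
    comps <- bfs_components(A)
    ig <- igraph::components(igraph::graph_from_adjacency_matrix(A, "undirected"))
    expect_length(comps, sum(ig$csize >= 2))
    sizes_pkg <- sort(vapply(comps, function(cp) length(cp$nodes), numeric(1)))
    expect_equal(sizes_pkg, sort(ig$csize[ig$csize >= 2]), ignore_attr = TRUE)
  }
})

test_that("NBS finds planted components and stays calm under the null", {
  set.seed(18)
  ga <- replicate(15, random_fc_matrix(15), simplify = FALSE)
  gb <- replicate(15, random_fc_matrix(15, shift = 1.6, planted_nodes = 1:5),
                  simplify = FALSE)
  res <- nbs(ga, gb, threshold = 2, n_perm = 400, seed = 19)
  expect_false(res$empty)
  big <- res$components[[which.max(vapply(res$components, `[[`, numeric(1), "size"))]]
  expect_true(all(1:5 %in% big$nodes))
  expect_lt(big$p_value, 0.05)
  expect_equal(res$max_component_size, max(vapply(res$components, `[[`,
                                                  numeric(1), "size")))
  expect_length(res$null_max_sizes, 400)

  # no suprathreshold edges -> flagged empty result
  bump <- lapply(1:4, function(i) {
    m <- matrix(0, 6, 6); m[1, 2] <- m[2, 1] <- rnorm(1, 0, 1e-4); m
  })
  res0 <- nbs(bump, bump, threshold = 5, n_perm = 120, seed = 1)
  expect_true(res0$empty)
  expect_equal(res0$max_component_size, 0)
})

test_that("longitudinal change drops unmatched subjects and tests each unit", {
  t1 <- expand.grid(subject_id = sprintf("s%02d", 1:12),
                    region = c("a", "b"), stringsAsFactors = FALSE)
  t1$value <- rnorm(nrow(t1), 10)
  t2 <- t1
  t2$value <- t1$value + ifelse(t1$region == "a", 0.5, 0) + rnorm(nrow(t1), 0, 0.05)
  t2 <- rbind(t2, data.frame(subject_id = "s99", region = c("a", "b"), value = 1))
  res <- longitudinal_change(t1, t2)
  expect_equal(attr(res, "dropped_subjects"), 1)
  expect_lt(res$q[res$region == "a"], 0.01)
  expect_gt(res$delta_mean[res$region == "a"], 0.4)

  same <- longitudinal_change(t1, t1)
  expect_true(all(same$delta_mean == 0))
  expect_true(all(same$t_stat == 0))
  expect_equal(attr(same, "zero_variance_units"), 2)
})

test_that("mixed ANOVA agrees with the aov Error-stratum oracle", {
  set.seed(20)
  subs <- sprintf("s%02d", 1:23)
  geno <- rep(c("wt", "ko"), c(12, 11)) # unequal groups, as in the cohort
  regions <- paste0("r", 1:6)
  dat <- expand.grid(subject_id = subs, region = regions,
                     stringsAsFactors = FALSE)
  dat$genotype <- geno[match(dat$subject_id, subs)]
  reg_eff <- stats::setNames(seq(0, 3, length.out = 6), regions)
  dat$value <- rnorm(nrow(dat)) + reg_eff[dat$region]
  res <- mixed_anova(dat)

  fit <- stats::aov(value ~ genotype * region + Error(subject_id),
                    data = dat)
  sm <- summary(fit)
  btw <- sm[["Error: subject_id"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  expect_equal(res$between$F, btw["genotype", "F value"], tolerance = 1e-8)
  expect_equal(res$within$F, wth["region", "F value"], tolerance = 1e-8)
  expect_equal(res$interaction$F, wth["genotype:region", "F value"],
               tolerance = 1e-8)
  expect_equal(res$within$p, wth["region", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(res$between$df2, btw["Residuals", "Df"])

  # strong region effect, null genotype: large region partial eta squared
  expect_lt(res$within$p, 0.001)
  expect_gt(res$between$p, 0.05)
  expect_gt(res$within$pes, 0.3)

  # identical per-region profiles across genotypes -> genotype F ~ 0
  subs2 <- sprintf("t%02d", 1:20)
  dat2 <- expand.grid(subject_id = subs2, region = regions,
                      stringsAsFactors = FALSE)
  dat2$genotype <- rep(c("wt", "ko"), 10)[match(dat2$subject_id, subs2)]
  offsets <- rep(rnorm(10), each = 2) # mirrored across genotypes
  dat2$value <- reg_eff[dat2$region] + offsets[match(dat2$subject_id, subs2)]
  res2 <- mixed_anova(dat2)
  expect_lt(res2$between$F, 1e-6)

  dat3 <- dat[-1, ]
  expect_error(mixed_anova(dat3), "balanced")
})

test_that("BH step-up matches the hand calculation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.3), 0.3)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.4)), "\\[0, 1\\]")
  # order invariance and q >= p
  set.seed(21)
  p <- runif(20)
  q <- benjamini_hochberg(p)
  ord <- sample(20)
  expect_equal(benjamini_hochberg(p[ord]), q[ord])
  expect_true(all(q >= p))
})

test_that("Kruskal-Wallis wraps rank arithmetic with degenerate guards", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$p, 1)
  sep <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  # maximal H for 3+3 distinct values: 12/(6*7) * (6^2/3 + 15^2/3) - 3*7
  expect_equal(sep$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  # no arrangement of ranks 1..6 into two triples beats full separation
  all_H <- apply(combn(6, 3), 2, function(idx) {
    r <- 1:6
    g1 <- sum(r[idx]); g2 <- sum(r[-idx])
    12 / 42 * (g1^2 / 3 + g2^2 / 3) - 21
  })
  expect_equal(max(all_H), sep$H)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("minimum detectable d matches power.t.test and is monotone", {
  d <- min_detectable_d(34, 34, 0.05, 0.80)
  ref <- stats::power.t.test(n = 34, power = 0.80, sig.level = 0.05)$delta
  expect_equal(d, ref, tolerance = 1e-4)
  expect_equal(min_detectable_d(4, 4), 2.38, tolerance = 0.01)
  expect_gt(min_detectable_d(34, 34, power = 0.95), d)
  expect_lt(min_detectable_d(60, 60), d)
  expect_error(min_detectable_d(1, 5), ">= 2")
  expect_error(min_detectable_d(5, 5, power = 0.04), "power")
})
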