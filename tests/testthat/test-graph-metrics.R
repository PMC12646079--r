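adj_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  A
}

test_that("binary global efficiency matches hand-derived graphs", {
  complete <- adj_from_edges(4, combn(4, 2, simplify = FALSE))
  expect_equal(global_efficiency_binary(complete), 1)
  expect_equal(global_efficiency_binary(matrix(0, 5, 5)), 0)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency_binary(path3), (1 + 1 + 0.5) / 3)
  expect_error(global_efficiency_binary(matrix(0, 1, 1)), "2 nodes")
})

test_that("binary clustering matches hand-derived graphs", {
  triangle <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clustering_coefficient_binary(triangle), 1)
  star <- adj_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(clustering_coefficient_binary(star), 0)
  k4_minus <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(clustering_coefficient_binary(k4_minus), (2 / 3 + 2 / 3 + 1 + 1) / 4)
})

test_that("binary metrics agree with enumeration oracles on random graphs", {
  set.seed(10)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    A <- A + t(A)
    expect_equal(global_efficiency_binary(A), oracle_global_efficiency(A))
    expect_equal(clustering_coefficient_binary(A), oracle_clustering(A))
  }
})

test_that("binary metrics are monotone non-decreasing in sparsity", {
  z <- toy_fc(20, seed = 12)
  levels <- seq(5, 50, by = 5)
  ge <- cc <- numeric(length(levels))
  for (k in seq_along(levels)) {
    g <- proportional_threshold(z, levels[k] / 100)
    ge[k] <- global_efficiency_binary(g)
    cc[k] <- clustering_coefficient_binary(g)
  }
  expect_true(all(diff(ge) >= 0))
  expect_true(all(diff(cc) >= 0))
})

test_that("weighted efficiency matches Dijkstra by hand and by enumeration", {
  w2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  net2 <- network_definition("pair", c("a", "b"))
  # a 2-node subnetwork is constant by construction: normalization errors,
  # the pre-normalized weight of 1 gives efficiency 1
  expect_error(weighted_efficiency(w2, net2), "degenerate")
  expect_equal(weighted_efficiency(w2, net2, normalize = FALSE), 1)

  chain <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  net3 <- network_definition("chain", c("a", "b", "c"))
  expect_equal(weighted_efficiency(chain, net3), (1 + 1 + 0.5) / 3)

  expect_error(
    weighted_efficiency(matrix(0.5, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2)),
                        net3),
    "degenerate"
  )

  set.seed(13)
  for (rep in 1:8) {
    nm <- letters[1:5]
    W <- matrix(0, 5, 5, dimnames = list(nm, nm))
    W[upper.tri(W)] <- runif(10)
    W <- W + t(W)
    net <- network_definition("rand", nm)
    # oracle applies the same min-max normalization
    off <- W[upper.tri(W) | lower.tri(W)]
    Wn <- (W - min(off)) / (max(off) - min(off))
    diag(Wn) <- 0
    expect_equal(weighted_efficiency(W, net), oracle_weighted_efficiency(Wn),
                 tolerance = 1e-12)
  }
})

test_that("node strength averages absolute connectivity over 35 peers", {
  z <- matrix(0.4, 36, 36,
              dimnames = list(default_roi_names(), default_roi_names()))
  diag(z) <- 0
  ns <- node_strength(z)
  expect_equal(nrow(ns), 20)
  expect_true(all(ns$value == 0.4))
  # mixed signs collapse to magnitude
  z2 <- z
  z2["L_amygdala", ] <- -0.3; z2[, "L_amygdala"] <- -0.3
  diag(z2) <- 0
  ns2 <- node_strength(z2, "L_amygdala")
  expect_equal(ns2$value, 0.3)
  expect_error(node_strength(z, "not_a_region"), "not_a_region")
})

test_that("within-network mean FC averages the unthresholded pairs", {
  rois <- default_roi_names()
  z <- matrix(0.5, 36, 36, dimnames = list(rois, rois))
  diag(z) <- 0
  net <- default_networks()$dmn
  expect_equal(network_mean_fc(z, net), 0.5)
  z3 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  z3[1, 2] <- z3[2, 1] <- 0.1
  z3[1, 3] <- z3[3, 1] <- 0.3
  z3[2, 3] <- z3[3, 2] <- 0.5
  net3 <- network_definition("t", c("a", "b", "c"))
  expect_equal(network_mean_fc(z3, net3), 0.3)
  shuffled <- network_definition("t", c("c", "a", "b"))
  expect_equal(network_mean_fc(z3, shuffled), 0.3)
})

test_that("metric curves cover the default ten-level grid", {
  z <- toy_fc(36, seed = 14)
  mc <- metric_curves(z)
  expect_equal(nrow(mc), 30)
  expect_equal(sort(unique(mc$sparsity)), seq(5, 50, by = 5))
  fc_curve <- mc$value[mc$metric == "mean_fc"]
  expect_true(all(diff(fc_curve) <= 0)) # adding weaker edges lowers the mean
  expect_identical(mc, metric_curves(z))
  expect_error(metric_curves(z, levels = c(0, 5)), "levels")
})
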