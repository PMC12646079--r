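as_binary_adjacency <- function(g) {
  m <- if (inherits(g, "thresholded_graph")) g$z_thresholded else g
  A <- m != 0
  diag(A) <- FALSE
  A
}

binary_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A * 1, mode = "undirected", diag = FALSE)
}

#' Binary global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs of the
#' binarized graph; disconnected pairs contribute 0 (1/Inf). A proxy for
#' network integration.
#'
#' @param g A `thresholded_graph` or adjacency/weight matrix (nonzero =
#'   edge); at least 2 nodes.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency_binary <- function(g) {
  A <- as_binary_adjacency(g)
  R <- nrow(A)
  if (R < 2L) stop("need at least 2 nodes", call. = FALSE)
  D <- igraph::distances(binary_graph(A))
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (R * (R - 1))
}

#' Binary average clustering coefficient
#'
#' Average over nodes of `C_i = 2 t_i / (k_i (k_i - 1))` where `t_i`
#' counts triangles through node i on the binarized graph; nodes with
#' degree < 2 contribute 0. A proxy for local segregation.
#'
#' @param g A `thresholded_graph` or adjacency/weight matrix; at least 3
#'   nodes.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient_binary <- function(g) {
  A <- as_binary_adjacency(g)
  if (nrow(A) < 3L) stop("need at least 3 nodes", call. = FALSE)
  ci <- igraph::transitivity(binary_graph(A), type = "local", isolates = "zero")
  mean(ci)
}

#' Weighted efficiency of a subnetwork
#'
#' Extracts the subnetwork's connectivity submatrix, min-max normalizes
#' its off-diagonal entries to `[0, 1]` (per subject, so the value is
#' scale-free), sets edge lengths to `1/weight` (absent for weight 0),
#' and averages inverse weighted shortest-path distances over ordered
#' pairs. Used for small a priori networks where proportional
#' thresholding is not meaningful.
#'
#' @param fc Symmetric connectivity matrix with ROI dimnames.
#' @param net A [network_definition()] with >= 2 ROIs present in `fc`.
#' @param normalize Min-max normalize the off-diagonal entries (default).
#'   With `normalize = FALSE` the entries are used as weights directly
#'   and must already lie in `[0, 1]`.
#' @return Scalar weighted efficiency.
#' @export
weighted_efficiency <- function(fc, net, normalize = TRUE) {
  check_fc_matrix(fc)
  sub <- subnetwork_matrix(fc, net)
  if (normalize) {
    off <- sub[upper.tri(sub) | lower.tri(sub)]
    mn <- min(off); mx <- max(off)
    if (mx == mn) stop("degenerate normalization: constant subnetwork matrix", call. = FALSE)
    w <- (sub - mn) / (mx - mn)
  } else {
    if (any(sub[upper.tri(sub)] < 0 | sub[upper.tri(sub)] > 1)) {
      stop("weights must lie in [0, 1] when normalize = FALSE", call. = FALSE)
    }
    w <- sub
  }
  diag(w) <- 0
  n <- nrow(w)
  lengths <- 1 / w
  lengths[w == 0] <- 0 # absent edges dropped below
  gr <- igraph::graph_from_adjacency_matrix(
    lengths, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  D <- igraph::distances(gr, algorithm = "dijkstra")
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

subnetwork_matrix <- function(fc, net) {
  rois <- if (inherits(net, "network_definition")) net$rois else as.character(net)
  missing <- setdiff(rois, rownames(fc))
  if (length(missing)) {
    stop("ROI(s) not in parcellation: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  fc[rois, rois]
}

#' Node strength of seed regions
#'
#' For each seed, the mean absolute connectivity (|z|) to all other
#' regions of the unthresholded matrix. Defaults to the 20 a priori
#' anxiety- and fear-related seeds.
#'
#' @param fc Symmetric Fisher-z matrix with ROI dimnames.
#' @param seeds Character vector of seed ROI names.
#' @return Data frame `region`, `value`, `value_kind = "node_strength"`.
#' @export
node_strength <- function(fc, seeds = anxiety_seed_regions()) {
  check_fc_matrix(fc)
  if (length(seeds) < 1L) stop("`seeds` must be non-empty", call. = FALSE)
  missing <- setdiff(seeds, rownames(fc))
  if (length(missing)) {
    stop("unknown ROI name(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  R <- nrow(fc)
  strength <- rowSums(abs(fc))[seeds] / (R - 1) # diagonal is zero
  data.frame(region = seeds, value = unname(strength),
             value_kind = "node_strength")
}

#' Mean within-network connectivity
#'
#' Average of all pairwise (upper-triangle) connections between the
#' network's nodes, without thresholding.
#'
#' @inheritParams weighted_efficiency
#' @return Scalar mean connectivity.
#' @export
network_mean_fc <- function(fc, net) {
  check_fc_matrix(fc)
  sub <- subnetwork_matrix(fc, net)
  mean(sub[upper.tri(sub)])
}

#' Metric-versus-sparsity curves for one subject
#'
#' Thresholds the connectivity matrix at each sparsity level (default 5%
#' to 50% in 5% steps, ten graphs) and evaluates mean retained
#' connectivity, binary global efficiency and binary clustering
#' coefficient on each.
#'
#' @param fc Symmetric Fisher-z matrix.
#' @param levels Sparsity levels in percent, strictly increasing, in
#'   `(0, 100]`.
#' @param rank_by Edge ranking passed to [proportional_threshold()].
#' @return Data frame `metric` (`mean_fc`, `global_efficiency`,
#'   `clustering_coefficient`), `sparsity` (percent), `value`.
#' @export
metric_curves <- function(fc, levels = seq(5, 50, by = 5),
                          rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  if (any(levels <= 0 | levels > 100)) stop("levels must lie in (0, 100]", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly increasing", call. = FALSE)
  }
  rows <- lapply(levels, function(lev) {
    g <- proportional_threshold(fc, lev / 100, rank_by = rank_by)
    data.frame(
      metric = c("mean_fc", "global_efficiency", "clustering_coefficient"),
      sparsity = lev,
      value = c(mean_nonzero_fc(g), global_efficiency_binary(g),
                clustering_coefficient_binary(g))
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$sparsity), ]
  rownames(out) <- NULL
  out
}
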