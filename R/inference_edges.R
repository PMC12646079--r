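# Stack a list of symmetric R x R matrices into an n x E matrix of
# upper-triangle edge values (column-major edge order).
stack_edges <- function(matrices) {
  t(vapply(matrices, function(m) m[upper.tri(m)],
           numeric(sum(upper.tri(matrices[[1L]])))))
}

#' Edge-wise two-sample t-tests with BH-FDR correction
#'
#' A pooled-variance (Student) t-test per upper-triangle edge of the
#' connectivity matrices, Benjamini-Hochberg corrected over the whole
#' upper-triangle family (630 tests for 36 ROIs). Edges with zero pooled
#' variance get t = 0 and are counted in `zero_variance_edges`.
#'
#' @param group_a,group_b Lists of symmetric connectivity matrices (>= 2
#'   subjects per group, common ROI order).
#' @return An `edge_stats` list: symmetric `t`, `p`, `q` matrices (NA
#'   diagonal), `df`, `n_edges`, `zero_variance_edges`.
#' @export
edgewise_ttests <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  R <- nrow(group_a[[1L]])
  XA <- stack_edges(group_a)
  XB <- stack_edges(group_b)
  tt <- pooled_t_columns(XA, XB)
  p <- 2 * pt(-abs(tt$t), tt$df)
  q <- p.adjust(p, method = "BH")
  dn <- dimnames(group_a[[1L]])
  structure(
    list(
      t = ut_matrix(tt$t, R, dimnames = dn),
      p = ut_matrix(p, R, dimnames = dn),
      q = ut_matrix(q, R, dimnames = dn),
      df = tt$df, n_edges = length(tt$t),
      zero_variance_edges = sum(tt$zero_variance)
    ),
    class = "edge_stats"
  )
}

#' Breadth-first-search connected components of an adjacency matrix
#'
#' Explores all neighbours of a node before moving deeper, returning the
#' connected components among nodes with at least one edge.
#'
#' @param adj Logical/numeric symmetric adjacency matrix.
#' @return List of components, each a list with `nodes` (integer vector)
#'   and `n_edges`.
#' @export
bfs_components <- function(adj) {
  A <- adj != 0
  diag(A) <- FALSE
  n <- nrow(A)
  visited <- rep(FALSE, n)
  deg <- rowSums(A)
  comps <- list()
  for (start in seq_len(n)) {
    if (visited[start] || deg[start] == 0) next
    queue <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      members <- c(members, v)
      nbr <- which(A[v, ] & !visited)
      visited[nbr] <- TRUE
      queue <- c(queue, nbr)
    }
    members <- sort(members)
    comps[[length(comps) + 1L]] <- list(
      nodes = members,
      n_edges = sum(A[members, members]) / 2
    )
  }
  comps
}

# Max component sizes across permutations: given an n x E edge-data
# matrix, draw label shuffles in chunks, recompute pooled t for every
# edge by matrix algebra, threshold, and measure the maximal connected
# component (in edges or nodes) with the compiled union-find.
nbs_null_max <- function(X, nA, threshold, n_perm, ut, size = "edges",
                         chunk = 250L) {
  n <- nrow(X); nB <- n - nA
  df <- n - 2L
  X2 <- X * X
  tot <- colSums(X); tot2 <- colSums(X2)
  out <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    IA <- matrix(0, m, n)
    for (b in seq_len(m)) IA[b, sample.int(n, nA)] <- 1
    SA <- IA %*% X
    SA2 <- IA %*% X2
    mA <- SA / nA
    mB <- sweep(-SA, 2L, tot, `+`) / nB
    vA <- (SA2 - nA * mA^2) / (nA - 1L)
    vB <- (sweep(-SA2, 2L, tot2, `+`) - nB * mB^2) / (nB - 1L)
    se <- sqrt(((nA - 1L) * vA + (nB - 1L) * vB) / df * (1 / nA + 1 / nB))
    tmat <- (mA - mB) / se
    tmat[se == 0] <- 0
    for (b in seq_len(m)) {
      sel <- which(abs(tmat[b, ]) >= threshold)
      out[done + b] <- max_component_size_cpp(
        length(ut$i), ut$i[sel], ut$j[sel], size == "edges"
      )
    }
    done <- done + m
  }
  out
}

#' Network-based statistic (NBS)
#'
#' Thresholds the edge-wise |t| matrix at `threshold`, finds connected
#' components of suprathreshold edges by breadth-first search, retains
#' components spanning more than one ROI, and compares each component's
#' size against a permutation null of the maximal component size obtained
#' by shuffling group labels and recomputing the t matrix. Component size
#' is measured in edges by default (`size = "nodes"` available). P-values
#' use the add-one estimator with ties counting against the observed
#' component.
#'
#' @param group_a,group_b Lists of symmetric connectivity matrices.
#' @param threshold |t| cutoff forming the suprathreshold graph (> 0;
#'   default 2).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional RNG seed, recorded in the result.
#' @param size `"edges"` (default) or `"nodes"` component-size measure.
#' @return An `nbs_result` list: `threshold`, `components` (each with
#'   `nodes`, `n_edges`, `size`, `p_value`), `max_component_size`,
#'   `null_max_sizes`, `n_permutations`, `seed`, `empty` flag.
#' @export
nbs <- function(group_a, group_b, threshold = 2, n_perm = 10000L,
                seed = NULL, size = c("edges", "nodes")) {
  size <- match.arg(size)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  R <- nrow(group_a[[1L]])
  ut <- upper_tri_index(R)
  XA <- stack_edges(group_a)
  XB <- stack_edges(group_b)
  tt <- pooled_t_columns(XA, XB)
  supra <- abs(tt$t) >= threshold
  adj <- matrix(FALSE, R, R)
  adj[cbind(ut$i[supra], ut$j[supra])] <- TRUE
  adj <- adj | t(adj)
  comps <- bfs_components(adj)
  comps <- Filter(function(cp) length(cp$nodes) >= 2L, comps)
  if (!length(comps)) {
    return(structure(
      list(threshold = threshold, components = list(),
           max_component_size = 0L, null_max_sizes = NULL,
           n_permutations = as.integer(n_perm), seed = seed, empty = TRUE),
      class = "nbs_result"
    ))
  }
  sizes <- vapply(comps, function(cp) {
    if (size == "edges") cp$n_edges else length(cp$nodes)
  }, numeric(1L))
  null_max <- with_seed(seed, {
    nbs_null_max(rbind(XA, XB), nrow(XA), threshold, n_perm, ut, size)
  })
  for (k in seq_along(comps)) {
    comps[[k]]$size <- sizes[k]
    comps[[k]]$p_value <- (1 + sum(null_max >= sizes[k])) / (1 + n_perm)
  }
  structure(
    list(threshold = threshold, components = comps,
         max_component_size = max(sizes), null_max_sizes = null_max,
         n_permutations = as.integer(n_perm), seed = seed, empty = FALSE),
    class = "nbs_result"
  )
}
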