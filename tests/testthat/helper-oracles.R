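# Independent oracles used to validate the package's graph, permutation
# and image statistics. These deliberately re-derive each quantity by
# brute force (matrix-power shortest paths, path enumeration, exhaustive
# label splits, per-threshold relabelling) rather than calling the code
# paths under test.

# Unweighted all-pairs shortest paths by Floyd-Warshall.
oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_shortest_paths(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Average binary clustering via triangle counts from A^3.
oracle_clustering <- function(A) {
  A <- (A != 0) * 1
  diag(A) <- 0
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  mean(ci)
}

# Weighted efficiency by exhaustive simple-path enumeration (small n).
oracle_weighted_efficiency <- function(W) {
  n <- nrow(W)
  L <- 1 / W
  L[W == 0] <- Inf
  diag(L) <- 0
  best <- function(i, j, visited, acc) {
    if (i == j) return(acc)
    out <- Inf
    for (k in seq_len(n)) {
      if (!visited[k] && is.finite(L[i, k])) {
        visited[k] <- TRUE
        out <- min(out, best(k, j, visited, acc + L[i, k]))
        visited[k] <- FALSE
      }
    }
    out
  }
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    visited <- rep(FALSE, n)
    visited[i] <- TRUE
    d <- best(i, j, visited, 0)
    tot <- tot + if (is.finite(d)) 1 / d else 0
  }
  tot / (n * (n - 1))
}

# Exhaustive two-sided permutation p for a difference of group means.
oracle_exhaustive_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  obs <- abs(mean(a) - mean(b))
  splits <- combn(n, length(a))
  ps <- apply(splits, 2L, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(ps >= obs - 1e-12)
}

# TFCE by explicit per-threshold connected-component labelling (own BFS
# over the voxel grid), on the same midpoint discretization.
oracle_tfce <- function(values, mask, H = 2, E = 0.5, nsteps = 20,
                        connectivity = 26) {
  d <- dim(values)
  peak <- max(values[mask], 0)
  out <- array(0, d)
  if (peak <= 0) return(out)
  dh <- peak / nsteps
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  for (k in seq_len(nsteps)) {
    h <- (k - 0.5) * dh
    supra <- values >= h & mask
    labels <- array(0L, d)
    nextlab <- 0L
    for (v in which(supra)) {
      if (labels[v] != 0L) next
      nextlab <- nextlab + 1L
      queue <- v
      labels[v] <- nextlab
      while (length(queue)) {
        cur <- queue[1L]; queue <- queue[-1L]
        z <- (cur - 1L) %/% (d[1L] * d[2L])
        rem <- (cur - 1L) - z * d[1L] * d[2L]
        y <- rem %/% d[1L]; x <- rem %% d[1L]
        for (o in seq_len(nrow(offs))) {
          nx <- x + offs$dx[o]; ny <- y + offs$dy[o]; nz <- z + offs$dz[o]
          if (nx < 0 || nx >= d[1L] || ny < 0 || ny >= d[2L] ||
              nz < 0 || nz >= d[3L]) next
          w <- 1L + nx + d[1L] * (ny + d[2L] * nz)
          if (supra[w] && labels[w] == 0L) {
            labels[w] <- nextlab
            queue <- c(queue, w)
          }
        }
      }
    }
    if (nextlab > 0L) {
      sizes <- tabulate(labels[labels > 0L], nextlab)
      act <- which(supra)
      out[act] <- out[act] + sizes[labels[act]]^E * h^H * dh
    }
  }
  out
}

# Random symmetric zero-diagonal matrix, optional planted edge shift on
# the clique over `planted_nodes` for matrices in the "shifted" group.
random_fc_matrix <- function(R, shift = 0, planted_nodes = integer(0)) {
  m <- matrix(0, R, R)
  m[upper.tri(m)] <- rnorm(R * (R - 1) / 2)
  if (shift != 0 && length(planted_nodes) >= 2L) {
    pairs <- t(combn(planted_nodes, 2L))
    m[pairs] <- m[pairs] + shift
  }
  m <- m + t(m)
  diag(m) <- 0
  m
}

# Small deterministic Fisher-z matrix with ROI names for metric tests.
toy_fc <- function(R = 36, seed = 1) {
  set.seed(seed)
  rois <- if (R == 36) default_roi_names() else sprintf("roi%02d", seq_len(R))
  m <- random_fc_matrix(R) * 0.3
  dimnames(m) <- list(rois, rois)
  m
}
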