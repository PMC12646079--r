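# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed runs `expr` as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row/column indices of the strict upper triangle of an R x R matrix, in
# column-major order (the order `m[upper.tri(m)]` uses). All edge-wise
# statistics index the 630 edges of a 36-node graph this way.
upper_tri_index <- function(R) {
  idx <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L], n = nrow(idx))
}

# Extract the strict upper triangle as a vector.
ut_values <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (diagonal `diag_value`) from upper-triangle
# values in column-major order.
ut_matrix <- function(values, R, diag_value = NA_real_, dimnames = NULL) {
  m <- matrix(diag_value, R, R, dimnames = dimnames)
  m[upper.tri(m)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# round() half-away-from-zero, the proportional-threshold edge-count rule.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Symmetry check used by FcMatrix validators.
is_symmetric_matrix <- function(m, tol = 1e-12) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

check_fc_matrix <- function(z, arg = "fc") {
  if (!is.matrix(z) || !is.numeric(z)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(z) != ncol(z)) stop(sprintf("`%s` must be square", arg), call. = FALSE)
  if (any(!is.finite(z))) stop(sprintf("`%s` has non-finite entries", arg), call. = FALSE)
  if (!is_symmetric_matrix(z)) stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  invisible(z)
}

# Pooled-variance two-sample t statistics for column-stacked data.
# Returns t = 0 (flagged) where the pooled variance is zero.
pooled_t_columns <- function(XA, XB) {
  nA <- nrow(XA); nB <- nrow(XB)
  df <- nA + nB - 2L
  mA <- colMeans(XA); mB <- colMeans(XB)
  vA <- (colSums(XA^2) - nA * mA^2) / (nA - 1L)
  vB <- (colSums(XB^2) - nB * mB^2) / (nB - 1L)
  vA[vA < 0] <- 0; vB[vB < 0] <- 0
  sp <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
  se <- sqrt(sp * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  zero <- se == 0
  t[zero] <- 0
  list(t = t, df = df, zero_variance = zero)
}
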