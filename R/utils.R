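# Small numerical helpers shared across the package.

#' Moore-Penrose pseudoinverse via singular value decomposition
#'
#' Singular values below `tol * max(singular value)` are treated as zero,
#' so rank-deficient generalized least squares systems (e.g. after design
#' detachment) are solved in the minimum-norm sense.
#'
#' @param A numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return matrix of the same transposed dimension.
#' @keywords internal
#' @noRd
pinv <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (length(A) == 0L) return(t(A))
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Numerical rank under the same cutoff convention as pinv().
mat_rank <- function(A, tol = 1e-10) {
  if (length(A) == 0L) return(0L)
  d <- svd(as.matrix(A))$d
  sum(d > tol * max(d, 0))
}

# Block-diagonal assembly of a list of square matrices.
block_diag <- function(blocks) {
  dims <- vapply(blocks, nrow, integer(1))
  n <- sum(dims)
  out <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

# Symmetric positive-definite solve with a fallback to the pseudoinverse.
solve_spd <- function(A) {
  if (length(A) == 1L) {
    a <- A[1L]
    return(matrix(if (a > 0) 1 / a else 0, 1L, 1L))
  }
  A <- (A + t(A)) / 2
  out <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(out)) out <- pinv(A)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
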