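#' Fit an affine subspace to a cloud of LPC coefficient vectors
#'
#' One cognitive group's LPC vectors (one per training subject) define an
#' affine subspace: the bias vector is the column-wise mean, and the
#' orthonormal basis is the first `n` right-singular vectors of the centered
#' matrix scaled by `1 / sqrt(S - 1)` (the scaling affects singular values
#' only, not the basis, and is kept for fidelity to the estimator's
#' definition), ordered by descending singular value.
#'
#' @param vectors numeric matrix, `S` rows (subjects) by `K` columns
#'   (coefficient dimensions), `S >= 2`.
#' @param n subspace dimension, `1 <= n < K` and `n <= S - 1`. If the numeric
#'   rank of the centered cloud is below `n` (singular values below
#'   `1e-12` of the largest), the dimension is truncated with a warning.
#' @return object of class `affine_subspace`: list with `bias` (length `K`),
#'   `basis` (`K x n`, orthonormal columns), `dim`, `n_train`.
#' @export
fit_affine_subspace <- function(vectors, n) {
  vectors <- as.matrix(vectors)
  S <- nrow(vectors); K <- ncol(vectors)
  n <- as.integer(n)
  if (S < 2) stop("need at least 2 training vectors")
  if (n < 1 || n >= K) stop(sprintf("subspace dimension must satisfy 1 <= n < K = %d", K))
  if (n > S - 1) stop(sprintf("subspace dimension %d exceeds S - 1 = %d", n, S - 1))
  m <- colMeans(vectors)
  W <- sweep(vectors, 2, m) / sqrt(S - 1)
  sv <- svd(W, nu = 0, nv = min(S, K))
  rank <- sum(sv$d > 1e-12 * max(sv$d, .Machine$double.eps))
  if (rank < n) {
    warning(sprintf("numeric rank %d below requested dimension %d; truncating",
                    rank, n))
    n <- max(rank, 1L)
  }
  structure(
    list(bias = m, basis = sv$v[, seq_len(n), drop = FALSE],
         dim = n, n_train = S),
    class = "affine_subspace")
}

#' @export
print.affine_subspace <- function(x, ...) {
  cat(sprintf("affine subspace: dim %d in R^%d (fitted from %d vectors)\n",
              x$dim, length(x$bias), x$n_train))
  invisible(x)
}

#' Distance from a point to an affine subspace
#'
#' Euclidean norm of the component of `a - bias` orthogonal to the basis
#' span: the residual after subtracting the projection onto each basis
#' vector (with the `p^T p` normalization written out, a no-op for an
#' orthonormal basis).
#'
#' @param a numeric vector of length `K`.
#' @param sub an `affine_subspace` in the same `K`-dimensional space.
#' @return nonnegative scalar distance.
#' @export
subspace_distance <- function(a, sub) {
  if (length(a) != length(sub$bias))
    stop(sprintf("dimension mismatch: point has length %d, subspace lives in R^%d",
                 length(a), length(sub$bias)))
  d <- a - sub$bias
  P <- sub$basis
  coef <- as.numeric(crossprod(P, d)) / colSums(P^2)
  resid <- d - as.numeric(P %*% coef)
  sqrt(sum(resid^2))
}

#' Pair of group subspaces
#'
#' Bundles the cognitively impaired and cognitively normal subspaces fitted
#' in the same LPC-coefficient space.
#'
#' @param impaired,normal `affine_subspace` objects of equal ambient
#'   dimension.
#' @return object of class `subspace_pair`.
#' @export
subspace_pair <- function(impaired, normal) {
  if (length(impaired$bias) != length(normal$bias))
    stop("subspaces must share the ambient dimension K")
  structure(list(impaired = impaired, normal = normal),
            class = "subspace_pair")
}

#' Single-electrode LEAPD index
#'
#' The normalized distance ratio `rho = D_imp / (D_imp + D_norm)` where
#' `D_imp` and `D_norm` are the distances from the LPC vector to the
#' impaired and normal subspaces. `rho` lies in `[0, 1]`: 0 means the point
#' sits on the impaired subspace, 1 on the normal subspace, and values below
#' 0.5 mean the point is closer to the impaired subspace (impaired-like).
#' If both distances are zero the index is defined as 0.5 with a warning.
#'
#' @param a numeric LPC coefficient vector.
#' @param pair a [subspace_pair()].
#' @return scalar in `[0, 1]`.
#' @export
leapd_index <- function(a, pair) {
  d_imp <- subspace_distance(a, pair$impaired)
  d_norm <- subspace_distance(a, pair$normal)
  if (d_imp + d_norm == 0) {
    warning("point lies in both subspaces; index defined as 0.5")
    return(0.5)
  }
  d_imp / (d_imp + d_norm)
}

#' Combine single-electrode indices
#'
#' Geometric mean of `L` single-electrode LEAPD indices, giving the combined
#' LEAPD index.
#'
#' @param rho numeric vector of indices in `[0, 1]`, length `L >= 1`.
#' @return scalar geometric mean in `[0, 1]`.
#' @export
combine_indices <- function(rho) {
  if (!length(rho)) stop("cannot combine an empty index list")
  if (any(rho < 0 | rho > 1)) stop("indices must lie in [0, 1]")
  if (any(rho == 0)) return(0)
  exp(mean(log(rho)))
}
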