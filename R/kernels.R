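#' Tanimoto (Jaccard) similarity kernel from binary fingerprints
#'
#' Computes the Tanimoto coefficient between every pair of rows of a binary
#' feature matrix: the number of shared on-bits divided by the number of bits
#' set in either fingerprint. This is the standard similarity measure for
#' chemical fingerprints (MACCS, Morgan and the like).
#'
#' @param F binary matrix, one row per entity, one column per feature bit.
#'   Entries must be exactly 0 or 1.
#' @param ids optional character vector of entity identifiers; defaults to
#'   `rownames(F)`.
#' @return A square symmetric similarity matrix with unit diagonal and
#'   entries in \[0, 1\], with `ids` as dimnames. The similarity of two
#'   all-zero fingerprints is defined as 0 (off-diagonal); the diagonal is
#'   always 1.
#' @examples
#' F <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 0, 1))
#' tanimoto_kernel(F)
#' @export
tanimoto_kernel <- function(F, ids = rownames(F)) {
  F <- as.matrix(F)
  if (!all(F %in% c(0, 1))) {
    stop("tanimoto_kernel: feature matrix must be binary (0/1)")
  }
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(F)))
  storage.mode(F) <- "double"
  inter <- tcrossprod(F)
  sz <- rowSums(F)
  union <- outer(sz, sz, "+") - inter
  S <- ifelse(union > 0, inter / union, 0)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  validate_kernel(S)
}

#' Gaussian RBF similarity kernel from real-valued features
#'
#' @param F numeric feature matrix, one row per entity.
#' @param bandwidth positive length-scale; similarity is
#'   `exp(-||F_i - F_k||^2 / (2 * bandwidth^2))`.
#' @param ids optional identifiers, defaulting to `rownames(F)`.
#' @return Square symmetric kernel matrix with unit diagonal, entries in
#'   (0, 1\].
#' @export
rbf_kernel <- function(F, bandwidth, ids = rownames(F)) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0) {
    stop("rbf_kernel: bandwidth must be a positive scalar")
  }
  F <- as.matrix(F)
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(F)))
  sq <- rowSums(F^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(F)
  d2[d2 < 0] <- 0  # numerical noise
  S <- exp(-d2 / (2 * bandwidth^2))
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  validate_kernel(S)
}

#' Keep only the nearest neighbours of each entity in a similarity kernel
#'
#' For every row, similarities outside the `n` largest off-diagonal entries
#' are set to zero; ties are broken deterministically by ascending index.
#' The result is symmetrized by the element-wise maximum, so an edge is kept
#' if either endpoint selected it, and the retained graph is undirected.
#' The diagonal is always retained. Truncation with the same `n` is
#' idempotent.
#'
#' @param K square symmetric similarity matrix.
#' @param n number of neighbours to keep per entity (at least 1). If
#'   `n >= nrow(K) - 1` the kernel is returned unchanged.
#' @return The truncated kernel matrix.
#' @export
truncate_neighbors <- function(K, n) {
  K <- validate_kernel(K)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("truncate_neighbors: n must be a positive integer")
  }
  I <- nrow(K)
  if (n >= I - 1L) return(K)
  keep <- matrix(FALSE, I, I)
  for (i in seq_len(I)) {
    off <- setdiff(seq_len(I), i)
    # stable: order() breaks ties by ascending index
    nb <- off[order(K[i, off], decreasing = TRUE)][seq_len(n)]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)  # element-wise max symmetrization of the mask
  Kt <- ifelse(keep, K, 0)
  diag(Kt) <- diag(K)
  dimnames(Kt) <- dimnames(K)
  Kt
}

#' Graph-Laplacian prior precision per latent dimension
#'
#' Builds the precision matrix of the Gaussian prior on each latent
#' dimension implied by the combined Laplacian regularizer: summing the
#' per-pair penalty `gamma_n * K_n[i,k] * ||u_i - u_k||^2` over all ordered
#' pairs (i, k) and adding the ridge `alpha * ||u_i||^2` gives
#' `Q = 2 * sum_n weights[n] * (D_n - K_n) + alpha * I`,
#' where `D_n` is the diagonal matrix of row sums of kernel `n`.
#' The Laplacians are positive semidefinite and the ridge makes the total
#' positive definite.
#'
#' @param kernels list of square symmetric kernel matrices sharing dimnames.
#' @param weights nonnegative kernel weights, one per kernel.
#' @param alpha positive ridge precision.
#' @return Symmetric positive-definite matrix of the same dimension as the
#'   kernels.
#' @export
graph_precision <- function(kernels, weights, alpha) {
  if (!is.list(kernels) || length(kernels) == 0L) {
    stop("graph_precision: kernels must be a non-empty list")
  }
  if (length(weights) != length(kernels)) {
    stop("graph_precision: need one weight per kernel")
  }
  if (any(weights < 0)) stop("graph_precision: weights must be nonnegative")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("graph_precision: alpha must be a positive scalar")
  }
  I <- nrow(kernels[[1L]])
  Q <- diag(alpha, I)
  for (n in seq_along(kernels)) {
    K <- validate_kernel(kernels[[n]])
    if (nrow(K) != I) stop("graph_precision: kernels differ in size")
    Q <- Q + 2 * weights[n] * (diag(rowSums(K)) - K)
  }
  dimnames(Q) <- dimnames(kernels[[1L]])
  Q
}

#' @keywords internal
validate_kernel <- function(S, tol = 1e-8, check_psd = FALSE) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("kernel must be square")
  if (!all(is.finite(S))) stop("kernel has non-finite entries")
  asym <- max(abs(S - t(S)))
  if (asym > tol) stop("kernel asymmetric beyond tolerance (", signif(asym, 3), ")")
  S <- (S + t(S)) / 2
  ids <- rownames(S)
  if (!is.null(ids) && anyDuplicated(ids)) stop("kernel identifiers must be unique")
  if (check_psd) {
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      # PSD is not required for the Laplacian construction; flag it anyway
      message("kernel has negative eigenvalues (min ", signif(ev_min, 3), ")")
    }
  }
  S
}

#' @keywords internal
check_kernel_list <- function(kernels, ids, side) {
  if (is.matrix(kernels)) kernels <- list(kernels)
  if (!is.list(kernels) || length(kernels) == 0L) {
    stop("need a non-empty list of ", side, " kernels")
  }
  if (is.null(names(kernels)) || any(names(kernels) == "")) {
    names(kernels) <- paste0(side, "_kernel_", seq_along(kernels))
  }
  lapply(kernels, function(K) {
    K <- validate_kernel(K, check_psd = TRUE)
    if (nrow(K) != length(ids)) {
      stop(side, " kernel size ", nrow(K), " does not match ", length(ids), " ids")
    }
    kid <- rownames(K)
    if (!is.null(kid)) {
      if (!setequal(kid, ids)) {
        stop(side, " kernel ids do not match interaction ids: missing ",
             paste(setdiff(ids, kid), collapse = ", "))
      }
      K <- K[ids, ids, drop = FALSE]
    } else {
      dimnames(K) <- list(ids, ids)
    }
    K
  })
}

#' Identity kernel (no side information)
#'
#' Convenience constructor for the "no kernel" ablation: the Laplacian of
#' the identity kernel vanishes, leaving only the ridge prior.
#'
#' @param ids entity identifiers.
#' @return Identity matrix with `ids` as dimnames.
#' @export
identity_kernel <- function(ids) {
  S <- diag(length(ids))
  dimnames(S) <- list(ids, ids)
  S
}
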