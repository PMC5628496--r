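#' Row and column observation masks
#'
#' A drug row (target column) of the training matrix that contains no known
#' interaction is treated as unobserved: its zeros carry no likelihood and
#' its latent factors are driven by the prior (side information) alone.
#'
#' @param R binary interaction matrix (drugs in rows, targets in columns).
#' @return list with `m_u` (length-I 0/1 vector, 1 iff row has a positive)
#'   and `m_v` (length-J analogue for columns).
#' @export
derive_masks <- function(R) {
  R <- check_interactions(R)
  list(m_u = as.numeric(rowSums(R) >= 1),
       m_v = as.numeric(colSums(R) >= 1))
}

#' Jaakkola bound curvature coefficient
#'
#' The quadratic lower bound on the log-sigmoid,
#' `ln sigma(z) >= ln sigma(xi) + (z - xi)/2 + lambda(xi) (z^2 - xi^2)`,
#' has curvature `lambda(xi) = -(sigma(xi) - 1/2) / (2 xi)`, with analytic
#' limit -1/8 at `xi = 0`. The coefficient lies in \[-1/8, 0) and tends to
#' zero from below as `xi` grows; the bound is tight at `|z| = xi`.
#'
#' @param xi nonnegative local variational parameter(s); vectorized.
#' @return coefficient(s) in \[-1/8, 0).
#' @export
jaakkola_coefficient <- function(xi) {
  if (any(xi < 0)) stop("jaakkola_coefficient: xi must be nonnegative")
  out <- rep(-0.125, length(xi))
  nz <- xi > 1e-8
  out[nz] <- -(stats::plogis(xi[nz]) - 0.5) / (2 * xi[nz])
  if (is.matrix(xi)) out <- matrix(out, nrow(xi), ncol(xi))
  out
}

#' @keywords internal
#' Jaakkola lower bound on sigma(z) itself (used by tests and the ELBO).
jaakkola_bound <- function(z, xi) {
  lam <- jaakkola_coefficient(xi)
  stats::plogis(xi) * exp((z - xi) / 2 + lam * (z^2 - xi^2))
}

# Likelihood auxiliaries shared by the factor updates and the ELBO.
# R_hat_ij = m_i m_j ((c-1) R_ij + 1): the multiplicity of the Jaakkola
#   bound at cell (i,j) -- c for positives, 1 for usable negatives, 0 masked.
# R_prime_ij = m_i m_j (c R_ij - R_hat_ij / 2): coefficient of the linear
#   term of the bounded log-likelihood in z_ij = u_i' v_j, i.e. +c/2 at
#   positives and -1/2 at negatives.
likelihood_aux <- function(R, m_u, m_v, c) {
  if (!is.numeric(c) || length(c) != 1L || c < 1) {
    stop("importance weight c must be a scalar >= 1")
  }
  M <- outer(m_u, m_v)
  R_hat <- M * ((c - 1) * R + 1)
  R_prime <- M * (c * R - ((c - 1) * R + 1) / 2)
  list(R_hat = R_hat, R_prime = R_prime)
}

#' @keywords internal
check_interactions <- function(R) {
  R <- as.matrix(R)
  bad <- which(!(R %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(R))
    stop("interaction matrix must be binary; first offending cell at row ",
         ij[1], ", column ", ij[2], " (value ", R[bad[1L]], ")")
  }
  storage.mode(R) <- "double"
  if (is.null(rownames(R))) rownames(R) <- paste0("d", seq_len(nrow(R)))
  if (is.null(colnames(R))) colnames(R) <- paste0("t", seq_len(ncol(R)))
  if (anyDuplicated(rownames(R))) stop("duplicate drug identifiers")
  if (anyDuplicated(colnames(R))) stop("duplicate target identifiers")
  R
}

#' @keywords internal
check_hyper <- function(L, c, alpha_u, alpha_v, a, b, neighbors, iterations) {
  stopifnot(
    "latent dimension L must be a positive integer" = L >= 1,
    "importance weight c must be >= 1" = c >= 1,
    "alpha_u must be positive" = alpha_u > 0,
    "alpha_v must be positive" = alpha_v > 0,
    "Gamma shape a must be positive" = a > 0,
    "Gamma rate b must be positive" = b > 0,
    "neighbors must be >= 1" = neighbors >= 1,
    "iterations must be >= 1" = iterations >= 1
  )
  invisible(TRUE)
}
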