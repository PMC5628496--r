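# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: brute-force enumeration for ranking metrics,
# a generic numerical optimizer for the Gaussian update, and direct
# first-principles evaluation of the bounded objective.

# AUROC by exhaustive pair counting: P(random positive outscores random
# negative), ties counting one half.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Step-wise average precision by explicit rank walking (ties broken by
# original index, matching the documented contract).
oracle_auprc <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  hits <- 0
  precs <- c()
  for (k in seq_along(lab)) {
    if (lab[k] == 1) {
      hits <- hits + 1
      precs <- c(precs, hits / k)
    }
  }
  mean(precs)
}

# First-principles bounded objective in U for fixed xi and fixed moments of
# V: sum_ij [ R'_ij u_i'Ev_j + Rhat_ij lambda(xi_ij) u_i' E[v_j v_j'] u_i ]
#  - (1/2) sum_ik Q_ik u_i'u_k.
# `Svv` is a list of J L x L matrices, `Ev` an L x J matrix.
oracle_bounded_objective <- function(uvec, L, Q, R_hat, R_prime, xi, Ev, Svv) {
  I <- nrow(R_hat); J <- ncol(R_hat)
  U <- matrix(uvec, L, I)
  lam <- -(plogis(xi) - 0.5) / (2 * xi)
  lam[xi < 1e-12] <- -0.125
  val <- 0
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      val <- val + R_prime[i, j] * sum(U[, i] * Ev[, j]) +
        R_hat[i, j] * lam[i, j] * drop(crossprod(U[, i], Svv[[j]] %*% U[, i]))
    }
  }
  for (i in seq_len(I)) for (k in seq_len(I)) {
    val <- val - 0.5 * Q[i, k] * sum(U[, i] * U[, k])
  }
  val
}

# Maximize the bounded objective with a generic optimizer (independent of
# the closed-form update).
oracle_factor_argmax <- function(L, Q, R_hat, R_prime, xi, Ev, Svv) {
  I <- nrow(R_hat)
  opt <- optim(rep(0, L * I),
               fn = function(u) -oracle_bounded_objective(u, L, Q, R_hat,
                                                          R_prime, xi, Ev, Svv),
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  matrix(opt$par, L, I)
}

# Draw a random small fixed-moment instance for the update oracle tests.
random_update_instance <- function(seed, I_max = 3, J_max = 2, L_max = 2) {
  set.seed(seed)
  I <- sample(2:I_max, 1); J <- sample(1:J_max, 1); L <- sample(1:L_max, 1)
  R <- matrix(rbinom(I * J, 1, 0.5), I, J)
  Ks <- list(k1 = {
    # similarities must be nonnegative for the Laplacian to be PSD
    Z <- matrix(runif(I * I), I, I); S <- (Z + t(Z)) / 2; diag(S) <- 1; S
  })
  Q <- graph_precision(Ks, weights = runif(1, 0.1, 1), alpha = runif(1, 0.2, 1))
  Ev <- matrix(rnorm(L * J), L, J)
  Svv <- lapply(seq_len(J), function(j) {
    A <- matrix(rnorm(L * L), L, L)
    tcrossprod(A) / L + tcrossprod(Ev[, j])
  })
  xi <- matrix(runif(I * J, 0.1, 3), I, J)
  cmass <- sample(c(1, 5, 10), 1)
  m_u <- rep(1, I); m_v <- rep(1, J)
  aux <- vbmklmf:::likelihood_aux(R, m_u, m_v, cmass)
  list(I = I, J = J, L = L, R = R, Q = Q, Ev = Ev, Svv = Svv, xi = xi,
       c = cmass, R_hat = aux$R_hat, R_prime = aux$R_prime)
}

# Shared small synthetic fit used by several test files.
tiny_fit <- function(seed = 1, I = 12, J = 9, L = 3, iterations = 6, ...) {
  sc <- simulate_dti(I = I, J = J, L = L, seed = seed)
  fit <- suppressMessages(
    vbmklmf(sc$R, sc$drug_kernels, sc$target_kernels, L = L,
            iterations = iterations, seed = seed, ...))
  list(sc = sc, fit = fit)
}
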