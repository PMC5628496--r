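# Mean-field variational inference for multiple-kernel logistic matrix
# factorization. Latent factors U (L x I, drugs) and V (L x J, targets) get
# full Gaussian posteriors over their column-stacked vectorizations; kernel
# weights get conjugate Gamma posteriors. The Bernoulli likelihood is made
# conjugate by the Jaakkola quadratic bound with local parameters xi_ij.

#' Fit a variational Bayesian multiple-kernel logistic matrix factorization
#'
#' Models a binary drug-target interaction matrix `R` through
#' `P(R_ij = 1) = sigma(u_i' v_j)` with L-dimensional latent factors.
#' Observed positives receive importance weight `c >= 1`; zeros in rows or
#' columns with no positive at all are treated as unobserved (masked), so
#' those entities are predicted from side information alone. The prior on
#' each side's factors is a zero-mean Gaussian whose precision per latent
#' dimension is `2 * sum_n gamma_n * Laplacian(K_n) + alpha * I`, built from
#' neighbour-truncated similarity kernels; the kernel weights `gamma_n`
#' carry Gamma(a, b) hyperpriors and are learned.
#'
#' Inference is deterministic coordinate ascent on the Jaakkola-bounded
#' evidence lower bound: each sweep updates the local parameters, the
#' Gaussian posterior of each side (closed form via blocked Cholesky), and
#' the Gamma posteriors of the kernel weights. The bound is recorded and is
#' non-decreasing across updates.
#'
#' @param R binary interaction matrix, drugs in rows, targets in columns,
#'   with identifier dimnames.
#' @param drug_kernels,target_kernels a square symmetric similarity matrix
#'   or a named list of them, aligned with the rows (columns) of `R`.
#'   `NULL` uses the identity kernel, i.e. a pure ridge prior.
#' @param L latent dimension (default 10).
#' @param c importance weight of observed positives (default 10).
#' @param alpha_u,alpha_v ridge precisions of the factor priors (default 0.1).
#' @param a,b Gamma hyperprior shape and rate for the kernel weights
#'   (defaults 1 and 1000).
#' @param neighbors kernel truncation: number of nearest neighbours kept per
#'   entity in each kernel (default 3). Use `Inf` to disable truncation.
#' @param iterations number of full variational sweeps (default 20).
#' @param seed integer seed for the factor-mean initialization.
#' @param tol optional early-stopping threshold on the relative change of
#'   the bound between sweeps; 0 (default) runs all `iterations` sweeps.
#' @param elbo_every record the bound once per `"sweep"` (default) or after
#'   every coordinate `"update"`.
#' @param verbose print per-sweep progress.
#' @return An object of class `"vbmklmf"`: posterior means (`mean_u`,
#'   `mean_v`), full covariances over the vectorized factors (`cov_u`,
#'   `cov_v`), Gamma posteriors (`gamma_u`, `gamma_v`), local parameters
#'   `xi`, the bound trace `elbo`, the training data, masks, truncated
#'   kernels and hyperparameters. Use [predict.vbmklmf()] for interaction
#'   probabilities.
#' @seealso [predict.vbmklmf()], [cross_validate()], [simulate_dti()]
#' @examples
#' sc <- simulate_dti(I = 15, J = 10, L = 3, seed = 1)
#' fit <- vbmklmf(sc$R, sc$drug_kernels, sc$target_kernels,
#'                L = 3, iterations = 5, seed = 1)
#' fit
#' @export
vbmklmf <- function(R, drug_kernels = NULL, target_kernels = NULL,
                    L = 10, c = 10, alpha_u = 0.1, alpha_v = 0.1,
                    a = 1, b = 1000, neighbors = 3, iterations = 20,
                    seed = 1L, tol = 0,
                    elbo_every = c("sweep", "update"), verbose = FALSE) {
  elbo_every <- match.arg(elbo_every)
  R <- check_interactions(R)
  check_hyper(L, c, alpha_u, alpha_v, a, b, neighbors, iterations)
  I <- nrow(R); J <- ncol(R)
  drug_ids <- rownames(R); target_ids <- colnames(R)
  if (is.null(drug_kernels)) drug_kernels <- list(ridge = identity_kernel(drug_ids))
  if (is.null(target_kernels)) target_kernels <- list(ridge = identity_kernel(target_ids))
  Ku <- check_kernel_list(drug_kernels, drug_ids, "drug")
  Kv <- check_kernel_list(target_kernels, target_ids, "target")
  if (is.finite(neighbors)) {
    Ku <- lapply(Ku, truncate_neighbors, n = neighbors)
    Kv <- lapply(Kv, truncate_neighbors, n = neighbors)
  }

  masks <- derive_masks(R)
  aux <- likelihood_aux(R, masks$m_u, masks$m_v, c)
  hyper <- list(L = L, c = c, alpha_u = alpha_u, alpha_v = alpha_v,
                a = a, b = b, neighbors = neighbors, iterations = iterations)

  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  set.seed(seed)

  # Initialization: means ~ N(0, 1/L) keep initial inner products O(1);
  # covariances start at the prior; gamma at its prior mean a/b.
  Mu <- matrix(stats::rnorm(L * I, sd = 1 / sqrt(L)), L, I)
  Mv <- matrix(stats::rnorm(L * J, sd = 1 / sqrt(L)), L, J)
  gu <- list(shape = rep(a, length(Ku)), rate = rep(b, length(Ku)))
  gv <- list(shape = rep(a, length(Kv)), rate = rep(b, length(Kv)))
  pu <- prior_gaussian(Ku, gu, alpha_u, L)
  pv <- prior_gaussian(Kv, gv, alpha_v, L)
  Cu <- pu$cov; ldu <- pu$logdet; Cv <- pv$cov; ldv <- pv$logdet
  Su <- second_moment_mat(Mu, Cu, L)
  Sv <- second_moment_mat(Mv, Cv, L)
  xi <- xi_from_moments(Su, Sv)

  st <- function() list(Mu = Mu, Cu = Cu, ldu = ldu, Mv = Mv, Cv = Cv,
                        ldv = ldv, gu = gu, gv = gv, xi = xi)
  trace_sweep <- integer(0); trace_step <- character(0); trace_val <- numeric(0)
  note <- function(sw, step) {
    if (elbo_every == "update" || step %in% c("init", "sweep")) {
      trace_sweep <<- c(trace_sweep, sw)
      trace_step <<- c(trace_step, step)
      trace_val <<- c(trace_val, vb_elbo(st(), aux, Ku, Kv, hyper))
    }
  }
  note(0L, "init")

  for (d in seq_len(iterations)) {
    lam <- jaakkola_coefficient(xi)
    Qu <- graph_precision(Ku, gu$shape / gu$rate, alpha_u)
    up <- factor_update(Qu, aux$R_hat * lam, aux$R_prime, Mv, Sv, L)
    Mu <- up$mean; Cu <- up$cov; ldu <- up$logdet
    Su <- second_moment_mat(Mu, Cu, L)
    note(d, "q(U)")

    xi <- xi_from_moments(Su, Sv)
    note(d, "xi")

    lam <- jaakkola_coefficient(xi)
    Qv <- graph_precision(Kv, gv$shape / gv$rate, alpha_v)
    vp <- factor_update(Qv, t(aux$R_hat * lam), t(aux$R_prime), Mu, Su, L)
    Mv <- vp$mean; Cv <- vp$cov; ldv <- vp$logdet
    Sv <- second_moment_mat(Mv, Cv, L)
    note(d, "q(V)")

    xi <- xi_from_moments(Su, Sv)
    note(d, "xi2")

    gu <- gamma_update(cross_trace_mat(Mu, Cu, L), Ku, a, b)
    note(d, "q(gamma_u)")
    gv <- gamma_update(cross_trace_mat(Mv, Cv, L), Kv, a, b)
    note(d, "q(gamma_v)")

    if (elbo_every == "sweep") note(d, "sweep")
    if (verbose) {
      message(sprintf("sweep %2d  elbo %.4f  E[gamma_u] %s", d,
                      trace_val[length(trace_val)],
                      paste(signif(gu$shape / gu$rate, 3), collapse = " ")))
    }
    if (tol > 0 && d > 1) {
      nv <- length(trace_val)
      rel <- abs(trace_val[nv] - last_sweep_val) /
        (abs(last_sweep_val) + .Machine$double.eps)
      if (rel < tol) break
    }
    last_sweep_val <- trace_val[length(trace_val)]
  }

  structure(list(
    mean_u = Mu, cov_u = Cu, logdet_cov_u = ldu,
    mean_v = Mv, cov_v = Cv, logdet_cov_v = ldv,
    gamma_u = gu, gamma_v = gv, xi = xi,
    elbo = data.frame(sweep = trace_sweep, step = trace_step,
                      elbo = trace_val, stringsAsFactors = FALSE),
    R = R, m_u = masks$m_u, m_v = masks$m_v,
    drug_ids = drug_ids, target_ids = target_ids,
    drug_kernels = Ku, target_kernels = Kv,
    hyper = hyper, seed = as.integer(seed),
    sweeps_run = d
  ), class = "vbmklmf")
}

# ---- update primitives -----------------------------------------------------

#' @keywords internal
#' Gaussian update for one side by completing the square:
#' Lambda = Q (x) I_L - 2 blkdiag_i(sum_j W_ij E[v_j v_j']),  W = R_hat * lambda(xi)
#' phi    = Lambda^{-1} vec_i(sum_j R'_ij E[v_j])
#' `W` and `Rp` are oriented rows = this side, columns = other side.
factor_update <- function(Q, W, Rp, other_mean, other_smat, L) {
  I <- nrow(W)
  A <- other_smat %*% t(W)                 # L^2 x I, col i = vec(sum_j W_ij S_j)
  Lam <- kronecker(Q, diag(L))
  for (i in seq_len(I)) {
    idx <- ((i - 1L) * L + 1L):(i * L)
    Lam[idx, idx] <- Lam[idx, idx] - 2 * matrix(A[, i], L, L)
  }
  bvec <- as.vector(other_mean %*% t(Rp))  # vec of L x I matrix
  ch <- safe_chol(Lam)
  cov <- chol2inv(ch)
  cov <- (cov + t(cov)) / 2
  list(mean = matrix(cov %*% bvec, L, I),
       cov = cov,
       logdet = -2 * sum(log(diag(ch))))
}

#' @keywords internal
#' Optimal local parameters: xi_ij^2 = E[(u_i' v_j)^2] = tr(E[u u']E[v v']),
#' the exact second moment under independent Gaussian posteriors.
xi_from_moments <- function(Su, Sv) {
  e2 <- crossprod(Su, Sv)
  if (any(e2 < -1e-10)) warning("negative second moment clamped to 0")
  sqrt(pmax(e2, 0))
}

#' @keywords internal
#' Conjugate Gamma update for the kernel weights of one side:
#' shape' = a + I^2/2;  rate' = b + (1/2) sum_ik K_ik E||u_i - u_k||^2,
#' with E[u_i' u_k] read off the cross-trace matrix M.
gamma_update <- function(M, kernels, a, b) {
  I <- nrow(M)
  d2 <- outer(diag(M), diag(M), "+") - 2 * M
  rate <- vapply(kernels, function(K) b + 0.5 * sum(K * d2), numeric(1))
  if (any(rate <= 0)) {
    stop("Gamma rate became nonpositive; posterior covariance is corrupted")
  }
  list(shape = rep(a + I^2 / 2, length(kernels)), rate = unname(rate))
}

# ---- moment helpers --------------------------------------------------------

#' @keywords internal
#' Columns are vec(E[u_i u_i']) = vec(Cov(u_i) + mu_i mu_i').
second_moment_mat <- function(mean, cov, L) {
  I <- ncol(mean)
  out <- matrix(0, L * L, I)
  for (i in seq_len(I)) {
    idx <- ((i - 1L) * L + 1L):(i * L)
    out[, i] <- as.vector(cov[idx, idx, drop = FALSE] + tcrossprod(mean[, i]))
  }
  out
}

#' @keywords internal
#' I x I matrix of E[u_i' u_k] = tr(Cov(u_i, u_k)) + mu_i' mu_k. The trace of
#' cross block (i,k) is the sum over latent dims l of cov[(i-1)L+l, (k-1)L+l],
#' collected with strided index sets.
cross_trace_mat <- function(mean, cov, L) {
  I <- ncol(mean)
  M <- crossprod(mean)
  for (l in seq_len(L)) {
    ix <- seq(l, by = L, length.out = I)
    M <- M + cov[ix, ix, drop = FALSE]
  }
  M
}

#' @keywords internal
#' Prior Gaussian over vec(U): precision Q0 (x) I_L, so the covariance is
#' Q0^{-1} (x) I_L and log|cov| = -L log|Q0|.
prior_gaussian <- function(kernels, g, alpha, L) {
  Q0 <- graph_precision(kernels, g$shape / g$rate, alpha)
  ch <- safe_chol(Q0)
  list(cov = kronecker(chol2inv(ch), diag(L)),
       logdet = -2 * L * sum(log(diag(ch))))
}

#' @keywords internal
safe_chol <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  # Fall back to a symmetric eigendecomposition with a floor on eigenvalues.
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  bad <- min(ev$values)
  warning("precision not positive definite (min eigenvalue ", signif(bad, 3),
          "); flooring spectrum at 1e-10")
  vals <- pmax(ev$values, 1e-10)
  chol(ev$vectors %*% (vals * t(ev$vectors)))
}

# ---- bounded evidence lower bound ------------------------------------------

#' @keywords internal
#' Closed-form value of the Jaakkola-bounded ELBO for the current state:
#' expected bounded log-likelihood + expected log prior (factors, with the
#' I^2/2 log-gamma pseudo-normalizer matching the conjugate update) +
#' expected log Gamma hyperprior + Gaussian and Gamma entropies. Additive
#' constants that no update can change are dropped. Coordinate ascent makes
#' this non-decreasing after every single update.
vb_elbo <- function(st, aux, Ku, Kv, hyper) {
  L <- nrow(st$Mu); I <- ncol(st$Mu); J <- ncol(st$Mv)
  Su <- second_moment_mat(st$Mu, st$Cu, L)
  Sv <- second_moment_mat(st$Mv, st$Cv, L)
  mu_z <- crossprod(st$Mu, st$Mv)
  Ez2 <- crossprod(Su, Sv)
  lam <- jaakkola_coefficient(st$xi)
  lik <- sum(aux$R_hat * (stats::plogis(st$xi, log.p = TRUE) - st$xi / 2 -
                            lam * st$xi^2 + lam * Ez2)) +
    sum(aux$R_prime * mu_z)

  Eg_u <- st$gu$shape / st$gu$rate
  Eg_v <- st$gv$shape / st$gv$rate
  Elg_u <- digamma(st$gu$shape) - log(st$gu$rate)
  Elg_v <- digamma(st$gv$shape) - log(st$gv$rate)
  Qu <- graph_precision(Ku, Eg_u, hyper$alpha_u)
  Qv <- graph_precision(Kv, Eg_v, hyper$alpha_v)
  prior_u <- (I^2 / 2) * sum(Elg_u) - 0.5 * sum(Qu * cross_trace_mat(st$Mu, st$Cu, L))
  prior_v <- (J^2 / 2) * sum(Elg_v) - 0.5 * sum(Qv * cross_trace_mat(st$Mv, st$Cv, L))
  hyp <- sum((hyper$a - 1) * Elg_u - hyper$b * Eg_u) +
    sum((hyper$a - 1) * Elg_v - hyper$b * Eg_v)

  ent <- 0.5 * (st$ldu + st$ldv) +
    gamma_entropy(st$gu) + gamma_entropy(st$gv)
  lik + prior_u + prior_v + hyp + ent
}

#' @keywords internal
gamma_entropy <- function(g) {
  sum(g$shape - log(g$rate) + lgamma(g$shape) +
        (1 - g$shape) * digamma(g$shape))
}
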