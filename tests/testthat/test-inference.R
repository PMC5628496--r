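test_that("scalar Gaussian update matches completing the square by hand", {
  # 1 drug x 1 target, L = 1, E[v] = 1, E[v^2] = 1, R = 1, c = 1, xi = 1,
  # Q = alpha: Lambda = alpha - 2*lambda(1), phi = (1/2) / Lambda.
  alpha <- 0.7
  lam1 <- jaakkola_coefficient(1)
  up <- vbmklmf:::factor_update(
    Q = matrix(alpha, 1, 1),
    W = matrix(1 * lam1, 1, 1),          # R_hat * lambda(xi)
    Rp = matrix(0.5, 1, 1),              # R' = cR - Rhat/2 = 1/2
    other_mean = matrix(1, 1, 1),
    other_smat = matrix(1, 1, 1),        # E[v v'] = 1
    L = 1)
  Lam <- alpha - 2 * lam1
  expect_equal(drop(up$mean), 0.5 / Lam, tolerance = 1e-12)
  expect_equal(drop(up$cov), 1 / Lam, tolerance = 1e-12)
})

test_that("Gaussian update equals a generic numerical maximizer of the bound", {
  for (seed in 1:6) {
    inst <- random_update_instance(seed)
    lam <- jaakkola_coefficient(inst$xi)
    Smat <- vapply(inst$Svv, as.vector, numeric(inst$L^2))
    Smat <- matrix(Smat, inst$L^2, inst$J)
    up <- vbmklmf:::factor_update(inst$Q, inst$R_hat * lam, inst$R_prime,
                                  inst$Ev, Smat, inst$L)
    ref <- oracle_factor_argmax(inst$L, inst$Q, inst$R_hat, inst$R_prime,
                                inst$xi, inst$Ev, inst$Svv)
    expect_equal(up$mean, ref, tolerance = 1e-6)
  }
})

test_that("with no usable observations the posterior equals the prior", {
  ids <- paste0("d", 1:4)
  K <- list(k = random_pd_kernel(4, seed = 5, ids = ids))
  Q <- graph_precision(K, 0.5, alpha = 0.3)
  L <- 2
  up <- vbmklmf:::factor_update(Q, matrix(0, 4, 3), matrix(0, 4, 3),
                                matrix(rnorm(6), 2, 3),
                                matrix(rnorm(12), 4, 3), L)
  expect_equal(up$mean, matrix(0, L, 4))
  expect_equal(up$cov, kronecker(chol2inv(chol(Q)), diag(L)), tolerance = 1e-10)
})

test_that("xi update: closed forms and the Monte-Carlo oracle", {
  # zero covariance: xi = |E[u]' E[v]|
  L <- 2
  mu_u <- matrix(c(1, -2), L, 1); mu_v <- matrix(c(0.5, 1), L, 1)
  Su <- matrix(as.vector(tcrossprod(mu_u)), L^2, 1)
  Sv <- matrix(as.vector(tcrossprod(mu_v)), L^2, 1)
  expect_equal(drop(vbmklmf:::xi_from_moments(Su, Sv)),
               abs(sum(mu_u * mu_v)), tolerance = 1e-12)
  # zero means, unit variances, L = 2: xi^2 = 2
  Su0 <- matrix(as.vector(diag(L)), L^2, 1)
  expect_equal(drop(vbmklmf:::xi_from_moments(Su0, Su0)), sqrt(2))
  # Monte-Carlo: E[(u'v)^2] for diagonal-covariance Gaussians
  set.seed(7)
  mu_u <- c(0.4, -1); su2 <- c(0.5, 1.5)
  mu_v <- c(1, 0.3); sv2 <- c(2, 0.25)
  n <- 1e5
  u <- cbind(rnorm(n, mu_u[1], sqrt(su2[1])), rnorm(n, mu_u[2], sqrt(su2[2])))
  v <- cbind(rnorm(n, mu_v[1], sqrt(sv2[1])), rnorm(n, mu_v[2], sqrt(sv2[2])))
  z2 <- (rowSums(u * v))^2
  Su <- matrix(as.vector(diag(su2) + tcrossprod(mu_u)), 4, 1)
  Sv <- matrix(as.vector(diag(sv2) + tcrossprod(mu_v)), 4, 1)
  xi2 <- drop(vbmklmf:::xi_from_moments(Su, Sv))^2
  expect_lt(abs(mean(z2) - xi2), 3 * sd(z2) / sqrt(n))
})

test_that("Gamma update: shape from matrix size, rate from pairwise distances", {
  # a = 1, I = 4: shape = 1 + 16/2 = 9
  M <- diag(4)
  g <- vbmklmf:::gamma_update(M, list(k = diag(4)), a = 1, b = 10)
  expect_equal(g$shape, 9)
  # all u identical, zero covariance, all-ones kernel: rate = b
  u <- matrix(c(1, 2), 2, 3)  # three identical columns
  M2 <- crossprod(u)
  g2 <- vbmklmf:::gamma_update(M2, list(k = matrix(1, 3, 3)), a = 1, b = 5)
  expect_equal(g2$rate, 5)
  # I = 2, L = 1, u = (0, 2), K all ones: rate = b + 4
  u3 <- matrix(c(0, 2), 1, 2)
  g3 <- vbmklmf:::gamma_update(crossprod(u3), list(k = matrix(1, 2, 2)),
                               a = 1, b = 3)
  expect_equal(g3$rate, 7)
  expect_equal(g3$shape, 1 + 4 / 2)
})

test_that("Gamma rate matches a Monte-Carlo expectation under the posterior", {
  set.seed(11)
  I <- 4; L <- 2; d <- L * I
  A <- matrix(rnorm(d * d), d, d)
  cov <- tcrossprod(A) / d + diag(d) * 0.1
  mean_u <- matrix(rnorm(d, sd = 0.5), L, I)
  K <- random_pd_kernel(I, seed = 3)
  b <- 2
  M <- vbmklmf:::cross_trace_mat(mean_u, cov, L)
  g <- vbmklmf:::gamma_update(M, list(k = unname(K)), a = 1, b = b)
  n <- 1e5
  ch <- chol(cov)
  draws <- matrix(rnorm(n * d), n, d) %*% ch
  draws <- sweep(draws, 2, as.vector(mean_u), "+")
  qf <- numeric(n)
  for (i in seq_len(I)) for (k in seq_len(I)) {
    di <- ((i - 1) * L + 1):(i * L); dk <- ((k - 1) * L + 1):(k * L)
    qf <- qf + K[i, k] * rowSums((draws[, di] - draws[, dk])^2)
  }
  mc <- b + 0.5 * qf
  expect_lt(abs(mean(mc) - g$rate), 3 * sd(mc) / sqrt(n))
})

test_that("bounded ELBO never decreases across any single update", {
  for (seed in 1:4) {
    run <- tiny_fit(seed = seed, I = 10, J = 8, L = 2, iterations = 6,
                    elbo_every = "update")
    e <- run$fit$elbo$elbo
    rel_drop <- diff(e) / pmax(abs(e[-length(e)]), 1)
    expect_true(all(rel_drop >= -1e-6),
                info = paste("seed", seed, "min", min(rel_drop)))
  }
})

test_that("prior-only ELBO equals the analytic value when everything is masked", {
  ids <- paste0("d", 1:4); tds <- paste0("t", 1:3)
  R <- matrix(0, 4, 3, dimnames = list(ids, tds))
  K_u <- list(k = random_pd_kernel(4, seed = 2, ids = ids))
  K_v <- list(k = random_pd_kernel(3, seed = 4, ids = tds))
  a <- 1; b <- 10; alpha <- 0.5; L <- 2
  Qu <- graph_precision(K_u, a / b, alpha)
  Qv <- graph_precision(K_v, a / b, alpha)
  st <- list(
    Mu = matrix(0, L, 4), Cu = kronecker(chol2inv(chol(Qu)), diag(L)),
    ldu = -L * determinant(Qu)$modulus[1],
    Mv = matrix(0, L, 3), Cv = kronecker(chol2inv(chol(Qv)), diag(L)),
    ldv = -L * determinant(Qv)$modulus[1],
    gu = list(shape = a, rate = b), gv = list(shape = a, rate = b),
    xi = matrix(0, 4, 3))
  aux <- vbmklmf:::likelihood_aux(R, rep(0, 4), rep(0, 3), c = 10)
  hyper <- list(alpha_u = alpha, alpha_v = alpha, a = a, b = b)
  got <- vbmklmf:::vb_elbo(st, aux, K_u, K_v, hyper)
  elg <- digamma(a) - log(b)
  # likelihood zero; tr(Q %*% Q^{-1}) = I per side; Gamma cross terms written
  # out directly from the densities and entropies
  want <- (16 / 2) * elg - 0.5 * L * 4 +
    (9 / 2) * elg - 0.5 * L * 3 +
    2 * ((a - 1) * elg - b * (a / b)) +
    0.5 * (st$ldu + st$ldv) +
    2 * (a - log(b) + lgamma(a) + (1 - a) * digamma(a))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("fitting is deterministic given the seed", {
  sc <- simulate_dti(I = 10, J = 8, L = 2, seed = 9)
  f1 <- suppressMessages(vbmklmf(sc$R, sc$drug_kernels, sc$target_kernels,
                                 L = 2, iterations = 4, seed = 42))
  f2 <- suppressMessages(vbmklmf(sc$R, sc$drug_kernels, sc$target_kernels,
                                 L = 2, iterations = 4, seed = 42))
  expect_identical(f1$mean_u, f2$mean_u)
  expect_identical(f1$mean_v, f2$mean_v)
  expect_identical(f1$elbo$elbo, f2$elbo$elbo)
})

test_that("held-in discrimination on informative synthetic data is strong", {
  sc <- simulate_dti(I = 30, J = 20, L = 4, seed = 5)
  fit <- suppressMessages(vbmklmf(sc$R, sc$drug_kernels, sc$target_kernels,
                                  L = 4, iterations = 20, seed = 1))
  P <- predict(fit)
  expect_gt(auroc(as.vector(P), as.vector(sc$R)), 0.95)
})

test_that("prior-dominated limit pushes probabilities to one half", {
  set.seed(2)
  R <- matrix(rbinom(30, 1, 0.3), 6, 5)
  R[rowSums(R) == 0, 1] <- 1  # keep masks active
  fit <- suppressMessages(vbmklmf(R, NULL, NULL, L = 2, c = 1,
                                  alpha_u = 1e3, alpha_v = 1e3,
                                  iterations = 10, seed = 1))
  P <- predict(fit)
  expect_true(all(abs(P - 0.5) < 0.01))
  expect_true(all(abs(fit$mean_u) < 0.05))
})

test_that("increasing the importance weight raises fitted probability at positives", {
  sc <- simulate_dti(I = 10, J = 8, L = 2, seed = 13)
  mean_pos <- vapply(c(1, 5, 20), function(cc) {
    fit <- suppressMessages(vbmklmf(sc$R, sc$drug_kernels, sc$target_kernels,
                                    L = 2, c = cc, iterations = 10, seed = 1))
    mean(predict(fit)[sc$R == 1])
  }, numeric(1))
  expect_true(all(diff(mean_pos) > 0))
})

test_that("masked entities are fitted from the prior alone", {
  sc <- simulate_dti(I = 10, J = 8, L = 2, seed = 21)
  R <- sc$R
  R[3, ] <- 0  # blind drug 3 entirely
  fit <- suppressMessages(vbmklmf(R, sc$drug_kernels, sc$target_kernels,
                                  L = 2, iterations = 6, seed = 1))
  expect_equal(fit$m_u[3], 0)
  # the masked drug's factors must be finite and shrunk relative to active ones
  expect_true(all(is.finite(fit$mean_u[, 3])))
  norm3 <- sum(fit$mean_u[, 3]^2)
  active <- setdiff(which(fit$m_u == 1), 3)
  expect_lt(norm3, max(colSums(fit$mean_u[, active]^2)))
})
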