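# S3 methods for fitted vbmklmf objects.

#' @export
print.vbmklmf <- function(x, ...) {
  cat("Variational Bayesian multiple-kernel logistic matrix factorization\n")
  cat(sprintf("  %d drugs x %d targets, %d latent dimensions, %d sweeps\n",
              ncol(x$mean_u), ncol(x$mean_v), x$hyper$L, x$sweeps_run))
  cat(sprintf("  positives: %d (density %.3f), importance weight c = %g\n",
              sum(x$R), mean(x$R), x$hyper$c))
  cat(sprintf("  final bound: %.4f\n", x$elbo$elbo[nrow(x$elbo)]))
  wu <- x$gamma_u$shape / x$gamma_u$rate
  wv <- x$gamma_v$shape / x$gamma_v$rate
  cat("  E[gamma] drug kernels:  ",
      paste(sprintf("%s=%.3g", names(x$drug_kernels), wu), collapse = ", "), "\n")
  cat("  E[gamma] target kernels:",
      paste(sprintf("%s=%.3g", names(x$target_kernels), wv), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.vbmklmf <- function(object, ...) {
  P <- predict(object)
  out <- list(
    dims = c(drugs = ncol(object$mean_u), targets = ncol(object$mean_v),
             latent = object$hyper$L),
    n_positive = sum(object$R),
    density = mean(object$R),
    sweeps = object$sweeps_run,
    elbo_final = object$elbo$elbo[nrow(object$elbo)],
    elbo_monotone = all(diff(object$elbo$elbo) >=
                          -1e-6 * pmax(abs(object$elbo$elbo[-nrow(object$elbo)]), 1)),
    kernel_weights_u = stats::setNames(object$gamma_u$shape / object$gamma_u$rate,
                                       names(object$drug_kernels)),
    kernel_weights_v = stats::setNames(object$gamma_v$shape / object$gamma_v$rate,
                                       names(object$target_kernels)),
    mean_p_at_positives = mean(P[object$R == 1]),
    mean_p_at_zeros = mean(P[object$R == 0]),
    hyper = object$hyper
  )
  class(out) <- "summary.vbmklmf"
  out
}

#' @export
print.summary.vbmklmf <- function(x, ...) {
  cat(sprintf("vbmklmf fit: %d drugs x %d targets, L = %d, %d sweeps\n",
              x$dims["drugs"], x$dims["targets"], x$dims["latent"], x$sweeps))
  cat(sprintf("  %d positives (density %.3f)\n", x$n_positive, x$density))
  cat(sprintf("  final bound %.4f (monotone trace: %s)\n",
              x$elbo_final, x$elbo_monotone))
  cat(sprintf("  mean P at positives %.3f, at zeros %.3f\n",
              x$mean_p_at_positives, x$mean_p_at_zeros))
  cat("  drug kernel weights:  ",
      paste(sprintf("%s=%.3g", names(x$kernel_weights_u), x$kernel_weights_u),
            collapse = ", "), "\n")
  cat("  target kernel weights:",
      paste(sprintf("%s=%.3g", names(x$kernel_weights_v), x$kernel_weights_v),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.vbmklmf <- function(object, ...) {
  list(U = object$mean_u, V = object$mean_v,
       kernel_weights_u = stats::setNames(object$gamma_u$shape / object$gamma_u$rate,
                                          names(object$drug_kernels)),
       kernel_weights_v = stats::setNames(object$gamma_v$shape / object$gamma_v$rate,
                                          names(object$target_kernels)))
}

#' Posterior interaction probabilities
#'
#' @param object fitted [vbmklmf()] model.
#' @param mode `"plugin"` (default) evaluates `sigma(E[u_i]' E[v_j])`;
#'   `"moment"` applies the probit-style correction
#'   `sigma(mu / sqrt(1 + pi s^2 / 8))` with `mu` and `s^2` the posterior
#'   mean and variance of the latent inner product, shrinking uncertain
#'   predictions toward 1/2.
#' @param type `"response"` (probabilities) or `"link"` (the latent mean
#'   `E[u_i]' E[v_j]`).
#' @param ... unused.
#' @return I x J matrix with drug/target dimnames; probabilities carry the
#'   attribute `link_mode`.
#' @export
predict.vbmklmf <- function(object, mode = c("plugin", "moment"),
                            type = c("response", "link"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  mu <- crossprod(object$mean_u, object$mean_v)
  dimnames(mu) <- list(object$drug_ids, object$target_ids)
  if (type == "link") return(mu)
  if (mode == "plugin") {
    P <- stats::plogis(mu)
  } else {
    L <- object$hyper$L
    Su <- second_moment_mat(object$mean_u, object$cov_u, L)
    Sv <- second_moment_mat(object$mean_v, object$cov_v, L)
    s2 <- pmax(crossprod(Su, Sv) - mu^2, 0)  # Var(u'v) = E[(u'v)^2] - mu^2
    P <- stats::plogis(mu / sqrt(1 + pi * s2 / 8))
  }
  attr(P, "link_mode") <- mode
  P
}

#' @export
fitted.vbmklmf <- function(object, ...) predict(object)

#' @export
residuals.vbmklmf <- function(object, ...) {
  object$R - predict(object)
}

#' Simulate interaction matrices from the fitted probabilities
#'
#' Draws independent Bernoulli matrices from the posterior plug-in
#' probabilities, the generative reading of the fitted model.
#'
#' @param object fitted model.
#' @param nsim number of matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` binary matrices.
#' @export
simulate.vbmklmf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  P <- predict(object)
  lapply(seq_len(nsim), function(k) {
    S <- matrix(stats::rbinom(length(P), 1, P), nrow(P), ncol(P))
    dimnames(S) <- dimnames(P)
    S
  })
}

#' Plot a fitted model: bound trace or latent map
#'
#' @param x fitted model.
#' @param type `"elbo"` plots the bound trace; `"latent"` scatters the first
#'   two posterior-mean latent coordinates of drugs and targets in the
#'   shared pharmacological space.
#' @param ... passed to the underlying plot call.
#' @export
plot.vbmklmf <- function(x, type = c("elbo", "latent"), ...) {
  type <- match.arg(type)
  if (type == "elbo") {
    graphics::plot(seq_len(nrow(x$elbo)), x$elbo$elbo, type = "b", pch = 16,
                   xlab = "update", ylab = "bounded ELBO", ...)
  } else {
    if (x$hyper$L < 2) stop("latent plot needs L >= 2")
    U <- t(x$mean_u[1:2, , drop = FALSE])
    V <- t(x$mean_v[1:2, , drop = FALSE])
    lim <- range(c(U, V))
    graphics::plot(U, col = "steelblue", pch = 16, xlim = lim, ylim = lim,
                   xlab = "latent dim 1", ylab = "latent dim 2", ...)
    graphics::points(V, col = "firebrick", pch = 17)
    graphics::legend("topright", legend = c("drugs", "targets"),
                     col = c("steelblue", "firebrick"), pch = c(16, 17))
  }
  invisible(x)
}
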