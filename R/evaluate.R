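# Cross-validation machinery (CVS1/CVS2/CVS3), ranking metrics and the
# prior-fading learning-curve experiment.

#' Build a repeated cross-validation fold plan
#'
#' Three blinding schemes are supported: `"cvs1"` partitions all I*J cells
#' (pair prediction), `"cvs2"` partitions drug rows (new-drug prediction),
#' `"cvs3"` partitions target columns (new-target prediction). Within each
#' repeat the folds are disjoint and cover everything; the plan is fully
#' reproducible from its seed.
#'
#' @param R binary interaction matrix (only its dimensions are used).
#' @param setting `"cvs1"`, `"cvs2"` or `"cvs3"`.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats number of repeats (default 5).
#' @param seed integer seed.
#' @return object of class `"fold_plan"`: a list of repeats, each a list of
#'   integer index vectors (cell indices for CVS1, row indices for CVS2,
#'   column indices for CVS3), with the setting, dimensions and seed as
#'   attributes.
#' @export
make_folds <- function(R, setting = c("cvs1", "cvs2", "cvs3"),
                       n_folds = 10, n_repeats = 5, seed = 1L) {
  setting <- match.arg(setting)
  if (n_folds < 2) stop("n_folds must be at least 2")
  I <- nrow(R); J <- ncol(R)
  n_items <- switch(setting, cvs1 = I * J, cvs2 = I, cvs3 = J)
  if (n_folds > n_items) {
    stop("n_folds (", n_folds, ") exceeds the number of ",
         switch(setting, cvs1 = "cells", cvs2 = "drug rows", cvs3 = "target columns"),
         " (", n_items, ")")
  }
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  plan <- lapply(seq_len(n_repeats), function(r) {
    perm <- sample.int(n_items)
    fold_of <- rep(seq_len(n_folds), length.out = n_items)
    lapply(seq_len(n_folds), function(f) sort(perm[fold_of == f]))
  })
  structure(plan, class = "fold_plan", setting = setting,
            dims = c(I, J), n_folds = n_folds, n_repeats = n_repeats,
            seed = as.integer(seed))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: %s, %d repeats x %d folds on a %d x %d matrix (seed %d)\n",
              toupper(attr(x, "setting")), attr(x, "n_repeats"),
              attr(x, "n_folds"), attr(x, "dims")[1], attr(x, "dims")[2],
              attr(x, "seed")))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counting one half — computed from rank sums
#' (Mann-Whitney).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1) of the same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUROC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step-wise average precision)
#'
#' Average precision: precision evaluated at the rank of each positive and
#' averaged over positives, i.e. the step-function (not trapezoidal) PR
#' area. Ties in the scores are broken deterministically by original index.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPRC undefined: no positive labels")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  cum_pos <- cumsum(lab)
  prec_at_pos <- cum_pos[lab == 1] / which(lab == 1)
  mean(prec_at_pos)
}

#' Cross-validated AUROC and AUPRC
#'
#' For each fold the test cells (CVS1), rows (CVS2) or columns (CVS3) are
#' blinded to zero, masks are recomputed on the blinded matrix (so blinded
#' rows/columns become prior-only entities — no leakage), the model is
#' refitted from scratch, and the test cells are scored against their true
#' values. Folds whose test set lacks a positive or a negative are skipped
#' with a warning.
#'
#' @param R binary interaction matrix.
#' @param drug_kernels,target_kernels as in [vbmklmf()].
#' @param plan a [make_folds()] plan.
#' @param mode prediction mode passed to [predict.vbmklmf()].
#' @param ... further arguments to [vbmklmf()] (L, c, iterations, ...). The
#'   refit seed is derived from the plan seed plus the fold counter.
#' @return object of class `"dti_cv"`: data.frame of per-fold metrics plus a
#'   summary (mean and 95% normal-approximation confidence half-width).
#' @export
cross_validate <- function(R, drug_kernels = NULL, target_kernels = NULL,
                           plan, mode = "plugin", ...) {
  stopifnot(inherits(plan, "fold_plan"))
  R <- check_interactions(R)
  setting <- attr(plan, "setting")
  stopifnot(all(attr(plan, "dims") == dim(R)))
  rows <- list()
  skipped <- 0L
  fold_counter <- 0L
  for (r in seq_along(plan)) {
    for (f in seq_along(plan[[r]])) {
      fold_counter <- fold_counter + 1L
      idx <- plan[[r]][[f]]
      R_train <- R
      test_cells <- switch(setting,
        cvs1 = idx,
        cvs2 = as.vector(outer(idx, (seq_len(ncol(R)) - 1L) * nrow(R), "+")),
        cvs3 = as.vector(outer(seq_len(nrow(R)), (idx - 1L) * nrow(R), "+"))
      )
      if (setting == "cvs1") R_train[idx] <- 0
      if (setting == "cvs2") R_train[idx, ] <- 0
      if (setting == "cvs3") R_train[, idx] <- 0
      truth <- R[test_cells]
      if (sum(truth == 1) == 0 || sum(truth == 0) == 0) {
        warning("fold ", fold_counter, " has a degenerate test set; skipped")
        skipped <- skipped + 1L
        next
      }
      fit <- vbmklmf(R_train, drug_kernels, target_kernels,
                     seed = attr(plan, "seed") + fold_counter, ...)
      # leakage guard: blinded rows/columns must be masked during training
      if (setting == "cvs2") stopifnot(all(fit$m_u[idx] == 0))
      if (setting == "cvs3") stopifnot(all(fit$m_v[idx] == 0))
      P <- predict(fit, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f,
        auroc = auroc(P[test_cells], truth),
        auprc = auprc(P[test_cells], truth),
        n_test = length(test_cells), n_test_pos = sum(truth)
      )
    }
  }
  folds <- do.call(rbind, rows)
  ci <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  structure(list(
    folds = folds,
    summary = data.frame(
      metric = c("auroc", "auprc"),
      mean = c(mean(folds$auroc), mean(folds$auprc)),
      ci95 = c(ci(folds$auroc), ci(folds$auprc))
    ),
    setting = setting, skipped = skipped,
    auprc_definition = "step-wise average precision"
  ), class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation over %d folds%s\n", toupper(x$setting),
              nrow(x$folds),
              if (x$skipped) sprintf(" (%d skipped)", x$skipped) else ""))
  with(x$summary, cat(sprintf("  %s: %.4f +/- %.4f\n", metric, mean, ci95),
                      sep = ""))
  invisible(x)
}

#' Prior-fading learning curve
#'
#' Quantifies how the benefit of kernel side information fades as training
#' data grows: for each training fraction and seed, a random subset of cells
#' is kept (the rest blinded to zero), the model is fitted once with the
#' supplied kernels (`condition = "kernels"`) and once with identity kernels
#' (`condition = "ridge"`), and the held-out cells are scored.
#'
#' @param R binary interaction matrix.
#' @param drug_kernels,target_kernels side-information kernels.
#' @param train_fractions fractions of the training pool used, in (0, 1].
#' @param seeds integer vector, one replicate per seed.
#' @param eval_fraction fraction of all cells held out as the fixed
#'   evaluation set of a replicate (default 0.25). Keeping the test set
#'   fixed across fractions pairs the comparison and sharply reduces the
#'   variance of the on/off gap estimate.
#' @param ... further arguments to [vbmklmf()].
#' @return data.frame with columns `fraction`, `seed`, `condition`, `auroc`,
#'   `auprc`; replicates whose held-out set lacks a positive are skipped
#'   with a warning.
#' @export
learning_curve <- function(R, drug_kernels, target_kernels,
                           train_fractions = c(0.1, 0.5, 1),
                           seeds = 1:5, eval_fraction = 0.25, ...) {
  R <- check_interactions(R)
  stopifnot(all(train_fractions > 0), all(train_fractions <= 1),
            eval_fraction > 0, eval_fraction < 1)
  n <- length(R)
  out <- list()
  for (s in seeds) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(s)
    perm <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    n_eval <- max(1L, floor(eval_fraction * n))
    eval_cells <- perm[seq_len(n_eval)]
    pool <- perm[(n_eval + 1L):n]
    truth <- R[eval_cells]
    if (sum(truth == 1) == 0 || sum(truth == 0) == 0) {
      warning("seed ", s, ": degenerate evaluation set skipped")
      next
    }
    for (f in train_fractions) {
      n_train <- max(1L, floor(f * length(pool)))
      train_cells <- pool[seq_len(n_train)]
      if (sum(R[train_cells]) == 0) {
        warning("fraction ", f, ", seed ", s, ": no positives in training; skipped")
        next
      }
      R_train <- R
      R_train[setdiff(seq_len(n), train_cells)] <- 0
      for (cond in c("kernels", "ridge")) {
        fit <- if (cond == "kernels") {
          vbmklmf(R_train, drug_kernels, target_kernels, seed = s, ...)
        } else {
          vbmklmf(R_train, NULL, NULL, seed = s, ...)
        }
        P <- predict(fit)
        out[[length(out) + 1L]] <- data.frame(
          fraction = f, seed = s, condition = cond,
          auroc = auroc(P[eval_cells], truth),
          auprc = auprc(P[eval_cells], truth)
        )
      }
    }
  }
  do.call(rbind, out)
}
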