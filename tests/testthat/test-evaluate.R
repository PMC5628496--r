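test_that("fold plans partition cells, rows or columns exactly", {
  R <- matrix(0, 4, 5)
  p1 <- make_folds(R, "cvs1", n_folds = 10, n_repeats = 2, seed = 1)
  for (r in seq_along(p1)) {
    sizes <- lengths(p1[[r]])
    expect_equal(sum(sizes), 20)
    expect_equal(sort(unlist(p1[[r]])), 1:20)    # disjoint cover
    expect_true(all(sizes == 2))
  }
  R2 <- matrix(0, 10, 3)
  p2 <- make_folds(R2, "cvs2", n_folds = 10, n_repeats = 1, seed = 1)
  expect_true(all(lengths(p2[[1]]) == 1))
  expect_equal(sort(unlist(p2[[1]])), 1:10)
  p3 <- make_folds(R2, "cvs3", n_folds = 3, n_repeats = 1, seed = 1)
  expect_equal(sort(unlist(p3[[1]])), 1:3)
  expect_error(make_folds(R2, "cvs3", n_folds = 4), "exceeds")
  expect_identical(make_folds(R, "cvs1", 10, 2, seed = 7),
                   make_folds(R, "cvs1", 10, 2, seed = 7))
})

test_that("AUROC matches hand-counted pairs and handles ties", {
  expect_equal(auroc(c(.9, .8, .1), c(1, 0, 1)), 0.5)
  expect_equal(auroc(c(.9, .8, .7), c(1, 1, 0)), 1)
  expect_equal(auroc(c(.5, .5), c(1, 0)), 0.5)       # tie counts one half
  expect_error(auroc(c(.1, .2), c(1, 1)), "undefined")
})

test_that("AUPRC matches step-wise average precision by hand", {
  expect_equal(auprc(c(.9, .8, .1), c(1, 0, 1)), (1 + 2 / 3) / 2)
  expect_equal(auprc(c(.9, .8, .7), c(1, 1, 0)), 1)
  expect_equal(auprc(c(.1, .9), c(1, 0)), 0.5)
  expect_error(auprc(c(.1, .2), c(0, 0)), "no positive")
})

test_that("ranking metrics equal exhaustive oracles on short vectors", {
  set.seed(123)
  grid <- c(0.1, 0.3, 0.3, 0.7, 0.9)
  for (n in 2:6) {
    for (labs in 0:(2^n - 1)) {
      labels <- as.integer(intToBits(labs))[1:n]
      if (sum(labels) == 0 || sum(labels) == n) next
      scores <- sample(grid, n, replace = TRUE)
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
      expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
    }
  }
})

test_that("CVS1 cross-validation beats chance on informative synthetic data", {
  sc <- simulate_dti(I = 24, J = 16, L = 3, seed = 31)
  plan <- make_folds(sc$R, "cvs1", n_folds = 5, n_repeats = 1, seed = 2)
  cv <- suppressMessages(
    cross_validate(sc$R, sc$drug_kernels, sc$target_kernels, plan,
                   L = 3, iterations = 12))
  au <- cv$summary[cv$summary$metric == "auroc", ]
  expect_gt(au$mean - au$ci95, 0.6)
  # re-running with the same plan reproduces the summary exactly
  cv2 <- suppressMessages(
    cross_validate(sc$R, sc$drug_kernels, sc$target_kernels, plan,
                   L = 3, iterations = 12))
  expect_identical(cv$folds, cv2$folds)
})

test_that("shuffled labels drive cross-validated AUROC to chance", {
  sc <- simulate_dti(I = 24, J = 18, L = 3, seed = 37)
  set.seed(5)
  Rshuf <- matrix(sample(as.vector(sc$R)), nrow(sc$R), ncol(sc$R),
                  dimnames = dimnames(sc$R))
  plan <- make_folds(Rshuf, "cvs1", n_folds = 8, n_repeats = 1, seed = 3)
  cv <- suppressWarnings(suppressMessages(
    cross_validate(Rshuf, sc$drug_kernels, sc$target_kernels, plan,
                   L = 3, iterations = 8)))
  expect_lt(abs(cv$summary$mean[cv$summary$metric == "auroc"] - 0.5), 0.1)
})

test_that("CVS2 blinds whole rows without leakage and scores them", {
  sc <- simulate_dti(I = 12, J = 10, L = 2, seed = 41)
  plan <- make_folds(sc$R, "cvs2", n_folds = 4, n_repeats = 1, seed = 4)
  # the leakage assertion (test rows masked during training) runs inside
  cv <- suppressWarnings(suppressMessages(
    cross_validate(sc$R, sc$drug_kernels, sc$target_kernels, plan,
                   L = 2, iterations = 6)))
  expect_true(all(cv$folds$auroc >= 0 & cv$folds$auroc <= 1))
  expect_true(all(cv$folds$n_test == 10 * lengths(plan[[1]])[cv$folds$fold]))
})

test_that("learning curves are reproducible and well-formed", {
  sc <- simulate_dti(I = 14, J = 10, L = 2, seed = 43)
  lc1 <- suppressMessages(
    learning_curve(sc$R, sc$drug_kernels, sc$target_kernels,
                   train_fractions = c(0.3, 0.8), seeds = 1:2,
                   L = 2, iterations = 5))
  lc2 <- suppressMessages(
    learning_curve(sc$R, sc$drug_kernels, sc$target_kernels,
                   train_fractions = c(0.3, 0.8), seeds = 1:2,
                   L = 2, iterations = 5))
  expect_identical(lc1, lc2)
  expect_setequal(unique(lc1$condition), c("kernels", "ridge"))
  expect_equal(nrow(lc1), 8)
  expect_true(all(lc1$auroc >= 0 & lc1$auroc <= 1))
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (k in 1:5) {
    labels <- c(rbinom(30, 1, 0.4), 0, 1)
    scores <- runif(32)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  }
})
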