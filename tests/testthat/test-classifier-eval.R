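test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c("s", "h", "s", "h"),
                                 c("s", "h", "s", "h")), 1)
  truth <- rep(c("heavy", "safe"), c(80, 20))
  expect_equal(balanced_accuracy(truth, rep("heavy", 100)), 0.5)
  expect_equal(balanced_accuracy(c("s", "s", "h", "h"),
                                 c("s", "h", "h", "h")), 0.75)
  expect_error(balanced_accuracy(rep("s", 4), rep("s", 4)), "absent")
  expect_error(balanced_accuracy(c("s", "h"), c("s")), "aligned")
})

test_that("well-separated classes reach near-perfect MBA", {
  set.seed(5)
  n <- 200
  y <- factor(rep(c("safe", "heavy"), each = n / 2))
  X <- matrix(rnorm(n * 10), n, 10)
  X[y == "heavy", ] <- X[y == "heavy", ] + 6 / sqrt(10)  # centroid distance 6 sd
  res <- train_eval_mba(X, y, model = fast_model(),
                        cv = cv_spec(outer_folds = 5, repetitions = 2,
                                     seed = 8))
  expect_gte(res$mba, 0.95)
  expect_true(all(res$fold_ba >= 0 & res$fold_ba <= 1))
  expect_gte(res$sd, 0)
})

test_that("pure-noise features stay near chance", {
  set.seed(6)
  n <- 200
  y <- factor(rep(c("safe", "heavy"), each = n / 2))
  X <- matrix(rnorm(n * 10), n, 10)
  res <- train_eval_mba(X, y, model = fast_model(),
                        cv = cv_spec(outer_folds = 5, repetitions = 2,
                                     seed = 8))
  expect_lt(abs(res$mba - 0.5), 0.12)
})

test_that("MBA is invariant to pre-pipeline affine feature scaling", {
  set.seed(9)
  n <- 120
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 8), n, 8)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 1
  cv <- cv_spec(outer_folds = 4, repetitions = 2, seed = 2)
  r1 <- train_eval_mba(X, y, model = fast_model(), cv = cv)
  Xs <- sweep(sweep(X, 2, runif(8, 0.2, 5), "*"), 2, rnorm(8, 0, 10), "+")
  r2 <- train_eval_mba(Xs, y, model = fast_model(), cv = cv)
  expect_equal(r1$mba, r2$mba)
})

test_that("counterbalancing a balanced stratum is a no-op for MBA", {
  set.seed(10)
  n <- 80
  y <- factor(rep(c("a", "b"), n / 2))
  strata <- factor(rep(c("p", "q"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5)
  X[y == "b", 1] <- X[y == "b", 1] + 2
  cv <- cv_spec(outer_folds = 4, repetitions = 1, seed = 3)
  # identical fold seeds; balanced cells make the plan the identity
  r0 <- train_eval_mba(X, y, controls = NULL, model = fast_model(), cv = cv)
  ctrl <- compose_controls(site = strata)
  # only exactly balanced within fold if strata cells stay balanced; use a
  # single stratum so every training fold is trivially balanced-checkable
  one <- compose_controls(site = factor(rep("all", n)))
  r1 <- train_eval_mba(X, y, controls = one, model = fast_model(), cv = cv)
  # single stratum: plan only rebalances class sizes; folds stratified by y
  # keep classes equal, so the plan is the identity and MBA matches exactly
  expect_identical(r0$fold_ba, r1$fold_ba)
  expect_s3_class(ctrl, "factor")
})

test_that("duplicating every training subject leaves predictions unchanged", {
  set.seed(11)
  n <- 80
  y <- factor(rep(c("a", "b"), n / 2))
  X <- matrix(rnorm(n * 5), n, 5)
  X[y == "b", 1:2] <- X[y == "b", 1:2] + 3
  tr <- 1:60
  te <- 61:80
  sc <- cbconfound:::standardize_fold(X[tr, ], X[te, ])
  p1 <- cbconfound:::fit_svm_predict(sc$train, y[tr], sc$test, 1, 0.1)
  dup <- rep(tr, each = 2)
  sc2 <- cbconfound:::standardize_fold(X[dup, ], X[te, ])
  p2 <- cbconfound:::fit_svm_predict(sc2$train, y[dup], sc2$test, 1, 0.1)
  expect_identical(as.character(p1), as.character(p2))
})

test_that("label permutation test is rank-based and never zero", {
  set.seed(12)
  n <- 60
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5)
  X[y == "b", ] <- X[y == "b", ] + 2
  cv <- cv_spec(outer_folds = 3, repetitions = 1, seed = 5)
  p <- permutation_test_model(X, y, model = fast_model(), cv = cv,
                              n_perm = 19, seed = 7)
  # a strongly separated model beats every permutation: p = 1/(1+19)
  expect_equal(as.numeric(p), 1 / 20)
  expect_length(attr(p, "permuted"), 19L)
  expect_error(permutation_test_model(X, y, model = fast_model(), cv = cv,
                                      n_perm = 5), "n_perm")
})

test_that("cross-validation guards its preconditions", {
  y <- factor(rep(c("a", "b"), c(3, 57)))
  X <- matrix(rnorm(60 * 4), 60, 4)
  expect_error(train_eval_mba(X, y, model = fast_model(),
                              cv = cv_spec(outer_folds = 5)),
               "smallest class")
})

test_that("inner grid selection runs nested and deterministically", {
  set.seed(13)
  n <- 72
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * 6), n, 6)
  X[y == "b", 1:3] <- X[y == "b", 1:3] + 2
  ctrl <- compose_controls(sex = factor(rep(c("f", "m"), n / 2)))
  m <- model_spec(cost = c(0.5, 2), gamma = c(0.1, 1), inner_folds = 2)
  cv <- cv_spec(outer_folds = 3, repetitions = 1, seed = 6)
  r1 <- train_eval_mba(X, y, controls = ctrl, model = m, cv = cv)
  r2 <- train_eval_mba(X, y, controls = ctrl, model = m, cv = cv)
  expect_identical(r1$fold_ba, r2$fold_ba)
  expect_gte(r1$mba, 0.8)
})
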