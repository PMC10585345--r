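# Classifier evaluation: mean balanced accuracy (MBA) of a radial-kernel
# SVM under repeated, stratified cross-validation. Counterbalancing is
# applied to training folds only; test folds are never resampled, and
# balanced accuracy absorbs any test-fold class imbalance.

#' Specify the classification model
#'
#' A radial-basis-function SVM with an optional hyperparameter grid. When
#' the grid has a single combination the model is fit directly; otherwise
#' the combination maximizing inner cross-validated balanced accuracy on
#' the training multiset is selected per outer fold.
#'
#' @param kernel Only `"rbf"` is supported.
#' @param cost Positive regularization values (grid).
#' @param gamma Positive kernel-width multipliers, relative to the `1/p`
#'   heuristic for `p` features (grid).
#' @param inner_folds Folds for inner grid selection.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(kernel = "rbf", cost = c(0.1, 1, 10),
                       gamma = c(0.1, 1, 10), inner_folds = 3L) {
  stopifnot(identical(kernel, "rbf"),
            length(cost) >= 1L, all(cost > 0),
            length(gamma) >= 1L, all(gamma > 0),
            inner_folds >= 2L)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 inner_folds = as.integer(inner_folds)),
            class = "model_spec")
}

#' Specify the cross-validation scheme
#'
#' @param outer_folds Number of outer folds (must not exceed the smallest
#'   class count).
#' @param repetitions Number of repetitions with re-drawn fold assignments.
#' @param stratify_by `"y"` (default) or `"y_site"`.
#' @param seed Integer seed; fold assignments, fold-level counterbalancing
#'   plans and inner selection all derive substreams from it.
#' @return An object of class `"cv_spec"`.
#' @export
cv_spec <- function(outer_folds = 5L, repetitions = 10L,
                    stratify_by = c("y", "y_site"), seed = 1L) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(outer_folds >= 2L, repetitions >= 1L)
  structure(list(outer_folds = as.integer(outer_folds),
                 repetitions = as.integer(repetitions),
                 stratify_by = stratify_by, seed = as.integer(seed)),
            class = "cv_spec")
}

#' Balanced accuracy
#'
#' Mean of per-class recalls. For a binary problem this is
#' `(recall_safe + recall_heavy) / 2`; any constant predictor scores
#' exactly 0.5 on a fold containing both classes.
#'
#' @param truth True labels (binary factor or coercible).
#' @param predicted Predicted labels aligned with `truth`.
#' @return A number in `[0, 1]`.
#' @examples
#' balanced_accuracy(c("s", "s", "h", "h"), c("s", "h", "h", "h"))
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- droplevels(factor(truth))
  if (nlevels(truth) < 2L)
    stop("a true class is absent from the evaluation set")
  if (length(truth) != length(predicted))
    stop("truth and predicted must be aligned")
  predicted <- factor(as.character(predicted), levels = levels(truth))
  recalls <- vapply(levels(truth), function(l)
    mean(predicted[truth == l] == l, na.rm = FALSE), numeric(1L))
  mean(recalls)
}

# Stratified fold assignment: within each stratum, members are shuffled and
# dealt to folds cyclically, keeping class proportions near-equal per fold.
make_folds <- function(y, k, seed, site = NULL) {
  strat <- if (is.null(site)) factor(y) else interaction(y, site, drop = TRUE)
  fold <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (s in levels(strat)) {
      idx <- which(strat == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- 1L + (offset + seq_along(idx) - 1L) %% k
      offset <- offset + length(idx)
    }
  })
  fold
}

# Standardize train (multiset) and test blocks with train statistics.
standardize_fold <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(Xte, 2L, mu), 2L, sdv, "/"))
}

# Fit the rbf SVM with fixed hyperparameters and predict the test block.
fit_svm_predict <- function(Xtr, ytr, Xte, cost, gamma_rel) {
  fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = cost,
                    gamma = gamma_rel / ncol(Xtr), scale = FALSE)
  predict(fit, Xte)
}

# Counterbalance a training index set and return the resampled positions.
resample_training <- function(y, controls, tr, seed) {
  if (is.null(controls)) return(tr)
  plan <- counterbalance_oversample(y[tr], droplevels(factor(controls[tr])),
                                    seed = seed)
  tr[plan$indices]
}

# Inner grid selection, nested the same way as the outer loop: inner folds
# are drawn over the ORIGINAL training subjects, the inner-training part is
# counterbalanced, and each combination is scored by balanced accuracy on
# the untouched inner-validation part. Splitting the oversampled multiset
# instead would place copies of one subject on both sides of the split and
# bias selection toward memorizing models.
select_hyperparams <- function(X, y, controls, tr, model, seed) {
  grid <- expand.grid(cost = model$cost, gamma_rel = model$gamma)
  if (nrow(grid) == 1L) return(grid[1L, ])
  k <- min(model$inner_folds, min(table(y[tr])))
  if (k < 2L) return(grid[1L, ])
  fold <- make_folds(y[tr], k, derive_seed(seed, "inner_folds"))
  scores <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    itr <- tr[fold != f]
    iva <- tr[fold == f]
    if (nlevels(droplevels(y[iva])) < 2L) next
    idx <- tryCatch(
      resample_training(y, controls, itr,
                        seed = derive_seed(seed, "inner_plan", f)),
      uncounterbalanceable = function(e) NULL)
    if (is.null(idx)) next
    sc <- standardize_fold(X[idx, , drop = FALSE], X[iva, , drop = FALSE])
    for (g in seq_len(nrow(grid))) {
      pred <- fit_svm_predict(sc$train, y[idx], sc$test,
                              grid$cost[g], grid$gamma_rel[g])
      scores[g, f] <- balanced_accuracy(y[iva], pred)
    }
  }
  means <- rowMeans(scores, na.rm = TRUE)
  if (all(is.nan(means))) return(grid[1L, ])
  grid[which.max(means), ]
}

#' Mean balanced accuracy under counterbalanced cross-validation
#'
#' For each repetition and outer fold: counterbalance the training fold by
#' oversampling over the control strata (when `controls` is given), fit a
#' feature scaler and the SVM on the counterbalanced training multiset
#' only, and score balanced accuracy on the untouched test fold. MBA is the
#' grand mean; the reported SD is taken over repetition-level means.
#' Deterministic given `cv$seed`.
#'
#' @param X Numeric feature matrix (subjects x features).
#' @param y Binary outcome aligned with rows of `X`.
#' @param controls Optional control strata factor from [compose_controls()];
#'   `NULL` disables counterbalancing.
#' @param model A [model_spec()].
#' @param cv A [cv_spec()].
#' @param site Optional site factor, used only when
#'   `cv$stratify_by == "y_site"`.
#' @return An object of class `"mba_result"`: list with `mba`, `sd`,
#'   `rep_means`, `fold_ba` (repetitions x folds matrix), `controlled`,
#'   `n_effective` and `seed`.
#' @export
train_eval_mba <- function(X, y, controls = NULL, model = model_spec(),
                           cv = cv_spec(), site = NULL) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  stopifnot(nlevels(y) == 2L, nrow(X) == length(y))
  if (!is.null(controls)) stopifnot(length(controls) == length(y))
  if (cv$outer_folds > min(table(y)))
    stop("outer_folds exceeds the smallest class count")

  R <- cv$repetitions
  K <- cv$outer_folds
  fold_ba <- matrix(NA_real_, R, K)
  for (r in seq_len(R)) {
    fold <- make_folds(y, K, derive_seed(cv$seed, "folds", r),
                       site = if (cv$stratify_by == "y_site") site else NULL)
    for (f in seq_len(K)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      params <- select_hyperparams(X, y, controls, tr, model,
                                   seed = derive_seed(cv$seed, "inner", r, f))
      idx <- resample_training(y, controls, tr,
                               seed = derive_seed(cv$seed, "plan", r, f))
      sc <- standardize_fold(X[idx, , drop = FALSE], X[te, , drop = FALSE])
      pred <- fit_svm_predict(sc$train, y[idx], sc$test,
                              params$cost, params$gamma_rel)
      fold_ba[r, f] <- balanced_accuracy(y[te], pred)
    }
  }
  rep_means <- rowMeans(fold_ba)
  structure(
    list(mba = mean(rep_means),
         sd = if (R > 1L) stats::sd(rep_means) else 0,
         rep_means = rep_means,
         fold_ba = fold_ba,
         controlled = if (is.null(controls)) character(0)
                      else attr(controls, "controls"),
         n_effective = length(y),
         seed = cv$seed,
         model = model, cv = cv),
    class = "mba_result"
  )
}

#' @export
print.mba_result <- function(x, ...) {
  cat(sprintf("MBA = %.2f%% (SD = %.2f%%) over %d folds x %d repetitions\n",
              100 * x$mba, 100 * x$sd, ncol(x$fold_ba), nrow(x$fold_ba)))
  if (length(x$controlled))
    cat("  controlled:", paste(x$controlled, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an MBA result to JSON
#'
#' @param result An `"mba_result"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
mba_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "mba_result"))
  payload <- list(mba = result$mba, sd = result$sd,
                  rep_means = result$rep_means,
                  controlled = result$controlled,
                  n_effective = result$n_effective,
                  seed = result$seed,
                  model = unclass(result$model),
                  cv = unclass(result$cv))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Permutation test of overall model significance
#'
#' Permutes the outcome labels, recomputes MBA with fresh cross-validation
#' per permutation, and reports `p = (1 + b) / (1 + n_perm)` where `b`
#' counts permuted MBA values at or above the observed MBA. The `+1`
#' convention means p-values are never zero.
#'
#' @param X,y,controls,model,cv,site As in [train_eval_mba()].
#' @param n_perm Number of permutations (at least 19).
#' @param seed Integer seed for the permutation stream.
#' @return The p-value, with attributes `observed` (the observed
#'   `"mba_result"`) and `permuted` (vector of permuted MBA values).
#' @export
permutation_test_model <- function(X, y, controls = NULL,
                                   model = model_spec(), cv = cv_spec(),
                                   n_perm = 1000L, seed = 1L, site = NULL) {
  stopifnot(n_perm >= 19L)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("y must be binary")
  obs <- train_eval_mba(X, y, controls, model, cv, site = site)
  permuted <- vapply(seq_len(n_perm), function(b) {
    yb <- with_seed(derive_seed(seed, "permute_y", b), sample(y))
    cv_b <- cv
    cv_b$seed <- derive_seed(seed, "perm_cv", b)
    train_eval_mba(X, yb, controls, model, cv_b, site = site)$mba
  }, numeric(1L))
  p <- (1 + sum(permuted >= obs$mba)) / (1 + n_perm)
  structure(p, observed = obs, permuted = permuted)
}
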