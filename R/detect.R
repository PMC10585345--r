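# Confound detection: per-variable change in mean balanced accuracy when a
# candidate variable joins the sex-by-site control strata, the exploration
# screen over the lowest ~10% of changes, a permutation null for the
# accuracy drop, and Benjamini-Hochberg correction.

empty_confound_report <- function() {
  data.frame(variable = character(0), category = character(0),
             wave = character(0), mba_pre = numeric(0),
             mba_post = numeric(0), mba_post_pre = numeric(0),
             sd_post_pre = numeric(0), stage = character(0),
             p_perm = numeric(0), q_bh = numeric(0),
             significant = logical(0), reason = character(0),
             stringsAsFactors = FALSE)
}

# sex/site baseline control strata, or NULL when neither is supplied
baseline_controls <- function(sex, site) {
  if (is.null(sex) && is.null(site)) return(NULL)
  compose_controls(sex = sex, site = site)
}

confound_report_row <- function(variable, stage, mba_pre = NA_real_,
                                mba_post = NA_real_,
                                sd_post_pre = NA_real_,
                                p_perm = NA_real_, q_bh = NA_real_,
                                significant = NA, reason = "ok") {
  data.frame(variable = variable$name,
             category = variable$category,
             wave = variable$wave,
             mba_pre = mba_pre, mba_post = mba_post,
             mba_post_pre = mba_post - mba_pre,
             sd_post_pre = sd_post_pre, stage = stage,
             p_perm = p_perm, q_bh = q_bh, significant = significant,
             reason = reason, stringsAsFactors = FALSE)
}

#' Accuracy change from controlling one psychometric variable
#'
#' Recomputes MBA with the variable's binarized labels added to the
#' sex-by-site control strata, under the identical cross-validation scheme
#' and seed as the baseline, and reports the signed difference
#' `MBA_post - MBA_pre` (negative when the variable partially explains the
#' prediction). The SD of the difference is taken over paired
#' repetition-level means.
#'
#' @param X,y Feature matrix and binary outcome for the analysis sample.
#' @param variable One element of a [prepare_panel()] result (must be
#'   retained).
#' @param baseline The baseline `"mba_result"` computed with the same
#'   `model`/`cv` and controls `sex` by `site`.
#' @param sex,site Control factors aligned with `y`.
#' @param model,cv As in [train_eval_mba()].
#' @return A one-row data.frame (ConfoundReport fields). If the variable
#'   cannot be counterbalanced (an empty class-by-stratum cell), the row
#'   carries `NA` values and the reason.
#' @export
mba_post_pre <- function(X, y, variable, baseline, sex = NULL, site = NULL,
                         model = model_spec(), cv = cv_spec()) {
  stopifnot(inherits(baseline, "mba_result"))
  if (!isTRUE(variable$retained))
    stop("variable '", variable$name, "' is not retained")
  if (!identical(baseline$cv, cv))
    stop("baseline must be computed with the identical cv specification")
  controls_post <- compose_controls(sex = sex, site = site,
                                    variable = variable$binary)
  post <- tryCatch(
    train_eval_mba(X, y, controls_post, model, cv),
    uncounterbalanceable = function(e) e
  )
  if (inherits(post, "condition")) {
    return(confound_report_row(variable, stage = "explored",
                               mba_pre = baseline$mba,
                               reason = conditionMessage(post)))
  }
  confound_report_row(
    variable, stage = "explored",
    mba_pre = baseline$mba, mba_post = post$mba,
    sd_post_pre = if (length(post$rep_means) > 1L)
      stats::sd(post$rep_means - baseline$rep_means) else 0
  )
}

#' Exploration screen: lowest fraction of accuracy changes
#'
#' Sorts the per-variable `MBA_post - MBA_pre` values ascending and selects
#' the `ceiling(selection_fraction * K)` lowest, extending the selection
#' for exact ties at the boundary.
#'
#' @param reports Data.frame of confound reports (rows from
#'   [mba_post_pre()]).
#' @param selection_fraction Fraction of variables to select (default 0.10).
#' @return List with `selected` (variable names, ascending by change),
#'   `threshold` (the boundary change value) and `k` (the nominal count
#'   before tie extension).
#' @export
exploration_stage <- function(reports, selection_fraction = 0.10) {
  stopifnot(is.data.frame(reports), selection_fraction > 0,
            selection_fraction <= 1)
  finite <- is.finite(reports$mba_post_pre)
  if (!any(finite)) stop("no finite accuracy changes to screen")
  vals <- reports$mba_post_pre[finite]
  nms <- reports$variable[finite]
  K <- length(vals)
  k <- ceiling(selection_fraction * K)
  o <- order(vals)
  threshold <- vals[o][k]
  sel <- o[vals[o] <= threshold]
  list(selected = nms[sel], threshold = threshold, k = k,
       selection_fraction = selection_fraction)
}

#' Permutation null for the accuracy drop of one variable
#'
#' Permutes the candidate variable's binarized labels across subjects,
#' which breaks its ties to both the features and the outcome while leaving
#' the sex-by-site baseline control and the X-y relation intact, and
#' recomputes the accuracy change per permutation. The one-sided p-value in
#' the direction of accuracy reduction is
#' `(1 + #(permuted change <= observed change)) / (1 + n_perm)`.
#' Permutations that produce an uncounterbalanceable table are redrawn (a
#' redraw counter is returned).
#'
#' @param X,y,variable,sex,site,model,cv As in [mba_post_pre()].
#' @param n_perm Number of permutations (at least 19).
#' @param seed Integer seed for the permutation stream.
#' @param baseline Optional precomputed baseline `"mba_result"`; computed
#'   from `sex`/`site` controls when `NULL`.
#' @param max_redraws Redraw budget per permutation.
#' @return The p-value, with attributes `observed_change`,
#'   `permuted_changes`, `n_redraws`, `mba_pre` and `mba_post`.
#' @export
permutation_null_post_pre <- function(X, y, variable, sex = NULL,
                                      site = NULL, model = model_spec(),
                                      cv = cv_spec(), n_perm = 1000L,
                                      seed = 1L, baseline = NULL,
                                      max_redraws = 100L) {
  stopifnot(n_perm >= 19L)
  if (!isTRUE(variable$retained))
    stop("variable '", variable$name, "' is not retained")
  if (is.null(baseline))
    baseline <- train_eval_mba(X, y, baseline_controls(sex, site),
                               model, cv)
  obs <- mba_post_pre(X, y, variable, baseline, sex = sex, site = site,
                      model = model, cv = cv)
  if (!is.finite(obs$mba_post_pre))
    stop("observed configuration is uncounterbalanceable: ", obs$reason)

  n_redraws <- 0L
  permuted <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    attempt <- 0L
    repeat {
      cb <- with_seed(derive_seed(seed, "permute_c", b, attempt),
                      sample(variable$binary))
      controls_b <- compose_controls(sex = sex, site = site, variable = cb)
      post_b <- tryCatch(
        train_eval_mba(X, y, controls_b, model, cv),
        uncounterbalanceable = function(e) e
      )
      if (!inherits(post_b, "condition")) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (attempt > max_redraws)
        stop("exceeded redraw budget for permutation ", b)
    }
    permuted[b] <- post_b$mba - baseline$mba
  }
  p <- (1 + sum(permuted <= obs$mba_post_pre)) / (1 + n_perm)
  structure(p, observed_change = obs$mba_post_pre, permuted_changes = permuted,
            n_redraws = n_redraws, mba_pre = baseline$mba,
            mba_post = obs$mba_post, sd_post_pre = obs$sd_post_pre)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Computes `q_i = min over {j : p_(j) >= p_(i)} of m * p_(j) / j`, clipped
#' at 1 and mapped back to the input order (the classic non-negative
#' step-up construction).
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_correct <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(is.numeric(p), all(is.finite(p)), all(p > 0), all(p <= 1))
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(q_sorted, 1)
  out
}

#' Generalization stage on an independent holdout
#'
#' Recomputes the baseline MBA, each selected variable's accuracy change
#' and its permutation p-value on the holdout sample only (model refit on
#' the holdout), applies Benjamini-Hochberg correction across the selected
#' set, and flags variables with `q <= alpha` as significant.
#'
#' @param selected Variable names from [exploration_stage()].
#' @param X,y Holdout feature matrix and outcome.
#' @param panel Holdout [prepare_panel()] result (variables binarized
#'   within the holdout).
#' @param sex,site Holdout control factors.
#' @param model,cv As in [train_eval_mba()].
#' @param n_perm Permutations per variable.
#' @param alpha Significance level on the BH-adjusted q-values.
#' @param seed Integer seed.
#' @param exploratory_ids,holdout_ids Optional id sets; when both are given
#'   they must be disjoint (hard error otherwise).
#' @return A data.frame of confound reports with `stage = "generalized"`,
#'   `p_perm`, `q_bh` and `significant` filled in.
#' @export
generalization_stage <- function(selected, X, y, panel, sex = NULL,
                                 site = NULL, model = model_spec(),
                                 cv = cv_spec(), n_perm = 1000L,
                                 alpha = 0.05, seed = 1L,
                                 exploratory_ids = NULL,
                                 holdout_ids = NULL) {
  if (!is.null(exploratory_ids) && !is.null(holdout_ids)) {
    overlap <- intersect(exploratory_ids, holdout_ids)
    if (length(overlap))
      stop("holdout overlaps the exploratory set: ",
           paste(head(overlap, 5L), collapse = ", "))
  }
  if (!length(selected)) return(empty_confound_report())
  stopifnot(inherits(panel, "psych_panel"),
            all(selected %in% names(panel)))

  baseline <- train_eval_mba(X, y, baseline_controls(sex, site), model, cv)
  rows <- lapply(selected, function(v) {
    variable <- panel[[v]]
    if (!isTRUE(variable$retained)) {
      row <- confound_report_row(variable, stage = "generalized",
                                 mba_pre = baseline$mba,
                                 reason = paste0("not retained on holdout (",
                                                 variable$reason, ")"))
      return(row)
    }
    pv <- tryCatch(
      permutation_null_post_pre(X, y, variable, sex = sex, site = site,
                                model = model, cv = cv, n_perm = n_perm,
                                seed = derive_seed(seed, "gen", v),
                                baseline = baseline),
      error = function(e) e
    )
    if (inherits(pv, "condition")) {
      return(confound_report_row(variable, stage = "generalized",
                                 mba_pre = baseline$mba,
                                 reason = conditionMessage(pv)))
    }
    confound_report_row(
      variable, stage = "generalized",
      mba_pre = attr(pv, "mba_pre"), mba_post = attr(pv, "mba_post"),
      sd_post_pre = attr(pv, "sd_post_pre"),
      p_perm = as.numeric(pv)
    )
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$p_perm)
  if (any(ok)) {
    out$q_bh[ok] <- bh_correct(out$p_perm[ok])
    out$significant[ok] <- out$q_bh[ok] <= alpha
  }
  out
}
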