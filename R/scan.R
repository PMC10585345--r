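# Top-level driver: the full two-stage confound scan on one cohort, in the
# classic modelling idiom - one call returning a classed object with print,
# summary and plot methods.

#' Two-stage confound scan of a cohort
#'
#' Runs the complete analysis on a cohort: sample assembly (binge-naive
#' filter, outcome categorization, exploratory/holdout split), psychometric
#' panel preparation, the baseline sex-by-site controlled MBA, per-variable
#' accuracy changes on the exploratory set, the exploration screen, and the
#' generalization stage with permutation significance and
#' Benjamini-Hochberg correction on the holdout.
#'
#' @param cohort A `"cohort"` object (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param max_baseline_bde Baseline BDE filter threshold (0 = binge-naive).
#' @param holdout_per_class Holdout subjects per outcome class.
#' @param prep A [prep_config()].
#' @param model A [model_spec()].
#' @param cv A [cv_spec()] (its seed is re-derived from `seed`).
#' @param selection_fraction Exploration screen fraction.
#' @param n_perm Permutations per variable in the generalization stage.
#' @param alpha Significance level on BH-adjusted q-values.
#' @param seed Master seed; all stage seeds are derived substreams.
#' @return An object of class `"confound_scan"`: list with `exploration`
#'   and `generalization` report data.frames, `selected`, `threshold`,
#'   `mba_pre_exploratory` and `mba_pre_holdout` (`"mba_result"` objects),
#'   `assembly`, `panel_report`, and the configuration used.
#' @export
confound_scan <- function(cohort, max_baseline_bde = 0L,
                          holdout_per_class = 39L,
                          prep = prep_config(), model = model_spec(),
                          cv = cv_spec(), selection_fraction = 0.10,
                          n_perm = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  assembly <- assemble_cohort(cohort, max_baseline_bde = max_baseline_bde,
                              holdout_per_class = holdout_per_class,
                              seed = derive_seed(seed, "assembly"))
  expl_ids <- assembly$split$exploratory_ids
  hold_ids <- assembly$split$holdout_ids

  get_block <- function(ids) {
    rows <- match(ids, cohort$phenotype$subject_id)
    list(X = cohort$features[rows, , drop = FALSE],
         y = assembly$labels[ids],
         sex = cohort$phenotype$sex[rows],
         site = droplevels(cohort$phenotype$site[rows]))
  }
  ex <- get_block(expl_ids)

  panel_ex <- prepare_panel(cohort, prep, ids = expl_ids)
  vars <- retained_variables(panel_ex)
  if (!length(vars)) stop("no psychometric variable survives preparation")

  cv_ex <- cv
  cv_ex$seed <- derive_seed(seed, "cv_exploration")
  baseline_ex <- train_eval_mba(ex$X, ex$y,
                                compose_controls(sex = ex$sex,
                                                 site = ex$site),
                                model, cv_ex)
  exploration <- do.call(rbind, lapply(vars, function(v)
    mba_post_pre(ex$X, ex$y, panel_ex[[v]], baseline_ex,
                 sex = ex$sex, site = ex$site, model = model, cv = cv_ex)))

  screen <- exploration_stage(exploration, selection_fraction)
  exploration$stage[exploration$variable %in% screen$selected] <- "selected"

  generalization <- empty_confound_report()
  mba_pre_holdout <- NULL
  if (length(hold_ids) && length(screen$selected)) {
    ho <- get_block(hold_ids)
    panel_ho <- prepare_panel(cohort, prep, ids = hold_ids)
    cv_ho <- cv
    cv_ho$seed <- derive_seed(seed, "cv_holdout")
    generalization <- generalization_stage(
      screen$selected, ho$X, ho$y, panel_ho, sex = ho$sex, site = ho$site,
      model = model, cv = cv_ho, n_perm = n_perm, alpha = alpha,
      seed = derive_seed(seed, "generalization"),
      exploratory_ids = expl_ids, holdout_ids = hold_ids)
    mba_pre_holdout <- train_eval_mba(
      ho$X, ho$y, compose_controls(sex = ho$sex, site = ho$site),
      model, cv_ho)
  }

  structure(
    list(exploration = exploration,
         generalization = generalization,
         selected = screen$selected,
         threshold = screen$threshold,
         mba_pre_exploratory = baseline_ex,
         mba_pre_holdout = mba_pre_holdout,
         assembly = assembly,
         panel_report = as.data.frame(panel_ex),
         config = list(max_baseline_bde = max_baseline_bde,
                       holdout_per_class = holdout_per_class,
                       prep = prep, model = model, cv = cv,
                       selection_fraction = selection_fraction,
                       n_perm = n_perm, alpha = alpha, seed = seed)),
    class = "confound_scan"
  )
}

#' @export
print.confound_scan <- function(x, ...) {
  cat("Two-stage confound scan\n")
  cat(sprintf("  exploratory n = %d, holdout n = %d\n",
              length(x$assembly$split$exploratory_ids),
              length(x$assembly$split$holdout_ids)))
  cat(sprintf("  baseline MBA (exploratory) = %.2f%% (SD = %.2f%%)\n",
              100 * x$mba_pre_exploratory$mba,
              100 * x$mba_pre_exploratory$sd))
  if (!is.null(x$mba_pre_holdout))
    cat(sprintf("  baseline MBA (holdout)     = %.2f%% (SD = %.2f%%)\n",
                100 * x$mba_pre_holdout$mba, 100 * x$mba_pre_holdout$sd))
  cat(sprintf("  screened %d of %d variables (change <= %.2f%%)\n",
              length(x$selected), nrow(x$exploration),
              100 * x$threshold))
  sig <- x$generalization$variable[isTRUE_vec(x$generalization$significant)]
  cat("  significant after BH:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
summary.confound_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.confound_scan")
}

#' @export
print.summary.confound_scan <- function(x, ...) {
  print(x$scan)
  cat("\nExploration stage (ascending accuracy change):\n")
  ex <- x$scan$exploration
  ex <- ex[order(ex$mba_post_pre), c("variable", "category", "wave",
                                     "mba_pre", "mba_post", "mba_post_pre",
                                     "stage")]
  print(ex, row.names = FALSE, digits = 3)
  if (nrow(x$scan$generalization)) {
    cat("\nGeneralization stage:\n")
    print(x$scan$generalization[, c("variable", "mba_pre", "mba_post",
                                    "mba_post_pre", "p_perm", "q_bh",
                                    "significant")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Dot plot of per-variable accuracy changes
#'
#' One marker per variable, grouped by category, with a vertical line at
#' the exploration screen threshold.
#'
#' @param x A `"confound_scan"` object.
#' @param stage `"exploration"` (default) or `"generalization"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the data.frame that was plotted.
#' @export
plot.confound_scan <- function(x, stage = c("exploration", "generalization"),
                               ...) {
  stage <- match.arg(stage)
  rep <- if (stage == "exploration") x$exploration else x$generalization
  plot_postpre(rep, threshold = if (stage == "exploration") x$threshold
                                else NULL, ...)
}

#' Dot plot of accuracy changes for a report table
#'
#' @param reports Confound report data.frame with finite `mba_post_pre`
#'   values.
#' @param threshold Optional screen threshold; drawn as a vertical line.
#' @param file Optional output figure path (`.svg` or `.png` by
#'   extension); plotted to the active device when `NULL`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data.frame (ordered as drawn).
#' @export
plot_postpre <- function(reports, threshold = NULL, file = NULL, ...) {
  stopifnot(is.data.frame(reports))
  rep <- reports[is.finite(reports$mba_post_pre), , drop = FALSE]
  if (!nrow(rep)) stop("no finite accuracy changes to plot")
  cat_f <- factor(ifelse(is.na(rep$category), "uncategorized",
                         rep$category))
  o <- order(cat_f, rep$mba_post_pre)
  rep <- rep[o, ]
  cat_f <- cat_f[o]

  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "svg" && capabilities("cairo")) {
      grDevices::svg(file, width = 7, height = max(3, nrow(rep) * 0.18))
    } else {
      if (ext == "svg") file <- sub("\\.svg$", ".png", file)
      grDevices::png(file, width = 900,
                     height = max(300, nrow(rep) * 18))
    }
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4.5, 10, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  cols <- grDevices::hcl.colors(nlevels(cat_f), "Dark 2")
  graphics::plot(100 * rep$mba_post_pre, seq_len(nrow(rep)),
                 pch = 16, col = cols[as.integer(cat_f)],
                 cex = 0.6 + 1.6 * abs(rep$mba_post_pre) /
                   max(abs(rep$mba_post_pre)),
                 xlab = "MBA change after controlling (percentage points)",
                 ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(rep)), labels = rep$variable,
                 las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, col = "grey70")
  if (!is.null(threshold))
    graphics::abline(v = 100 * threshold, lty = 2)
  invisible(rep)
}
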