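# Sample selection: outcome categorization from the 0-6 lifetime BDE scale,
# the binge-naive baseline filter, and the exploratory/holdout split.

#' Categorize a lifetime BDE score into outcome classes
#'
#' Scores below 4 are safe users, scores above 5 are heavy binge drinkers,
#' and the intermediate scores 4-5 are excluded from analysis.
#'
#' @param score Integer vector with values in 0-6 (NA allowed; propagated).
#' @return A factor with levels `safe`, `heavy`, `excluded`.
#' @examples
#' categorize_bde(0:6)
#' @export
categorize_bde <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 6 & score == round(score))
  if (!all(ok))
    stop("BDE scores must be integers in 0-6; offending values: ",
         paste(unique(score[!ok]), collapse = ", "))
  out <- ifelse(is.na(score), NA_character_,
                ifelse(score < 4, "safe",
                       ifelse(score > 5, "heavy", "excluded")))
  factor(out, levels = c("safe", "heavy", "excluded"))
}

#' Select binge-naive subjects by baseline BDE score
#'
#' @param cohort A `"cohort"` object.
#' @param max_baseline_bde Retain subjects with baseline BDE score at or
#'   below this value. The default 0 is the binge-naive design; 1 gives the
#'   more permissive at-most-one-episode robustness variant.
#' @return A list with `ids` (retained subject ids) and `report`, a
#'   data.frame listing excluded subjects and the reason
#'   (`baseline_above_threshold` or `missing_baseline`; missing scores are
#'   reported, never silently dropped).
#' @export
filter_naive <- function(cohort, max_baseline_bde = 0L) {
  stopifnot(inherits(cohort, "cohort"),
            max_baseline_bde >= 0L, max_baseline_bde <= 6L)
  ph <- cohort$phenotype
  miss <- is.na(ph$bde_baseline)
  keep <- !miss & ph$bde_baseline <= max_baseline_bde
  report <- data.frame(
    subject_id = ph$subject_id[!keep],
    reason = ifelse(miss[!keep], "missing_baseline",
                    "baseline_above_threshold"),
    stringsAsFactors = FALSE
  )
  list(ids = ph$subject_id[keep], report = report)
}

# Largest-remainder allocation of `h` holdout slots over strata with the
# given sizes; never exceeds a stratum's size. Deterministic.
allocate_largest_remainder <- function(sizes, h) {
  stopifnot(h <= sum(sizes))
  quota <- h * sizes / sum(sizes)
  alloc <- pmin(floor(quota), sizes)
  need <- h - sum(alloc)
  rem <- quota - floor(quota)
  ord <- order(-rem, names(sizes))
  while (need > 0) {
    progressed <- FALSE
    for (i in ord) {
      if (need == 0) break
      if (alloc[i] < sizes[i]) {
        alloc[i] <- alloc[i] + 1
        need <- need - 1
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cannot allocate holdout slots")  # unreachable
  }
  alloc
}

#' Split an assembled sample into exploratory and holdout sets
#'
#' Draws a class-balanced holdout (`holdout_per_class` subjects from each
#' outcome class), stratified over sex and site by largest-remainder
#' allocation as far as counts allow; the remainder forms the exploratory
#' set. Deterministic given `seed`.
#'
#' @param ids Subject identifiers.
#' @param labels Outcome factor aligned with `ids`; levels `safe`/`heavy`.
#' @param holdout_per_class Holdout size per class (default 39).
#' @param sex,site Optional stratifiers aligned with `ids`.
#' @param seed Integer seed.
#' @return An object of class `"split_result"`: list with `exploratory_ids`
#'   and `holdout_ids` (disjoint character vectors).
#' @export
split_exploratory_holdout <- function(ids, labels, holdout_per_class = 39L,
                                      sex = NULL, site = NULL, seed = 1L) {
  labels <- factor(labels, levels = c("safe", "heavy"))
  stopifnot(length(ids) == length(labels), !anyNA(labels),
            holdout_per_class >= 0L)
  if (is.null(sex)) sex <- rep("all", length(ids))
  if (is.null(site)) site <- rep("all", length(ids))
  stopifnot(length(sex) == length(ids), length(site) == length(ids))
  strat <- paste(as.character(sex), as.character(site), sep = ":")

  holdout <- character(0)
  for (cl in levels(labels)) {
    in_cl <- labels == cl
    n_cl <- sum(in_cl)
    if (n_cl < holdout_per_class)
      stop("class '", cl, "' has ", n_cl,
           " members, fewer than holdout_per_class = ", holdout_per_class)
    if (holdout_per_class == 0L) next
    sizes <- table(strat[in_cl])
    alloc <- allocate_largest_remainder(
      stats::setNames(as.integer(sizes), names(sizes)), holdout_per_class)
    for (k in names(alloc)) {
      if (alloc[[k]] == 0L) next
      members <- ids[in_cl & strat == k]
      pick <- with_seed(derive_seed(seed, "holdout", cl, k), {
        members[sample.int(length(members), alloc[[k]])]
      })
      holdout <- c(holdout, pick)
    }
  }
  structure(
    list(exploratory_ids = setdiff(ids, holdout), holdout_ids = holdout),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("Exploratory/holdout split:", length(x$exploratory_ids),
      "exploratory,", length(x$holdout_ids), "holdout subjects\n")
  invisible(x)
}

#' Assemble the analysis sample from a cohort
#'
#' Applies, in order: exclusion of subjects with a missing followup BDE
#' score, the binge-naive baseline filter, outcome categorization (dropping
#' scores 4-5), and the exploratory/holdout split. Produces a per-subject
#' disposition report mirroring a sample-selection flow chart.
#'
#' @param cohort A `"cohort"` object.
#' @param max_baseline_bde Passed to [filter_naive()].
#' @param holdout_per_class Passed to [split_exploratory_holdout()].
#' @param seed Integer seed for the split.
#' @return An object of class `"cohort_assembly"`: list with `labels`
#'   (named factor safe/heavy over analysis subjects), `split`
#'   (`"split_result"`), and `report` (per-subject disposition with reason
#'   codes).
#' @export
assemble_cohort <- function(cohort, max_baseline_bde = 0L,
                            holdout_per_class = 39L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  ph <- cohort$phenotype
  disposition <- rep("retained", nrow(ph))
  reason <- rep("", nrow(ph))

  miss_fu <- is.na(ph$bde_followup)
  disposition[miss_fu] <- "dropped"
  reason[miss_fu] <- "missing_followup_bde"

  fn <- filter_naive(cohort, max_baseline_bde)
  not_naive <- !(ph$subject_id %in% fn$ids) & !miss_fu
  disposition[not_naive] <- "dropped"
  reason[not_naive] <- fn$report$reason[match(ph$subject_id[not_naive],
                                              fn$report$subject_id)]

  cand <- !miss_fu & !not_naive
  lab <- categorize_bde(ph$bde_followup)
  excl <- cand & lab == "excluded"
  disposition[excl] <- "dropped"
  reason[excl] <- "bde_score_4_to_5"

  keep <- cand & !excl
  ids <- ph$subject_id[keep]
  labels <- factor(as.character(lab[keep]), levels = c("safe", "heavy"))
  names(labels) <- ids

  split <- split_exploratory_holdout(
    ids, labels, holdout_per_class = holdout_per_class,
    sex = ph$sex[keep], site = ph$site[keep],
    seed = derive_seed(seed, "split"))
  reason[keep] <- ifelse(ids %in% split$holdout_ids, "holdout",
                         "exploratory")

  report <- data.frame(subject_id = ph$subject_id,
                       disposition = disposition, reason = reason,
                       stringsAsFactors = FALSE)
  structure(list(labels = labels, split = split, report = report),
            class = "cohort_assembly")
}

#' @export
print.cohort_assembly <- function(x, ...) {
  cat("Assembled analysis sample:", length(x$labels), "subjects (",
      paste(table(x$labels), collapse = " safe / "), " heavy )\n")
  print(x$split)
  drops <- table(x$report$reason[x$report$disposition == "dropped"])
  if (length(drops)) {
    cat("Dropped:\n")
    for (r in names(drops)) cat("  ", r, ":", drops[[r]], "\n")
  }
  invisible(x)
}

#' Write the per-subject selection report
#'
#' @param assembly A `"cohort_assembly"` object.
#' @param path Output TSV path.
#' @return Invisibly, the report data.frame.
#' @export
write_selection_report <- function(assembly, path) {
  stopifnot(inherits(assembly, "cohort_assembly"))
  utils::write.table(assembly$report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(assembly$report)
}
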