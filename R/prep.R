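# Psychometric preparation: binarize each candidate variable at its mean
# (counterbalancing needs categorical controls) and apply the minimum
# minority-group retention rule.

#' Configuration for psychometric preparation
#'
#' @param min_group_fraction Minimum share of non-missing cases that the
#'   smaller binarized group must reach for the variable to be retained
#'   (default 0.15).
#' @param center `"mean"` (default) or `"median"` split point.
#' @param tie_policy Values exactly at the split point go to the low group;
#'   fixed, deterministic and order-independent.
#' @param missing_policy Missing raw values exclude the subject for that
#'   variable only (pairwise deletion).
#' @return An object of class `"prep_config"`.
#' @export
prep_config <- function(min_group_fraction = 0.15,
                        center = c("mean", "median"),
                        tie_policy = "at-or-below-center-is-low",
                        missing_policy = "exclude-subject-for-this-variable") {
  center <- match.arg(center)
  stopifnot(min_group_fraction > 0, min_group_fraction < 0.5)
  structure(list(min_group_fraction = min_group_fraction, center = center,
                 tie_policy = tie_policy, missing_policy = missing_policy),
            class = "prep_config")
}

#' Binarize a psychometric variable at its mean
#'
#' The split point is the mean (or median) over non-missing values; values
#' at or below it are `low`, above it `high`. The variable is retained only
#' if the smaller group holds at least `min_group_fraction` of non-missing
#' cases; a constant variable (one empty group) is flagged degenerate.
#'
#' @param x Numeric vector (missing values allowed).
#' @param config A [prep_config()].
#' @return List with `binary` (factor `low`/`high`, NA where `x` is
#'   missing), `minority_fraction`, `retained`, `reason` and `center`.
#' @examples
#' binarize_at_mean(c(1, 2, 3, 4, 10))
#' @export
binarize_at_mean <- function(x, config = prep_config()) {
  stopifnot(is.numeric(x), inherits(config, "prep_config"))
  obs <- !is.na(x)
  if (sum(obs) < 2L)
    stop("need at least 2 non-missing values to binarize")
  ctr <- if (config$center == "mean") mean(x[obs]) else stats::median(x[obs])
  binary <- factor(ifelse(is.na(x), NA_character_,
                          ifelse(x <= ctr, "low", "high")),
                   levels = c("low", "high"))
  counts <- table(binary)
  if (any(counts == 0L)) {
    return(list(binary = binary, minority_fraction = 0,
                retained = FALSE, reason = "degenerate", center = ctr))
  }
  mf <- min(counts) / sum(counts)
  retained <- mf >= config$min_group_fraction
  list(binary = binary, minority_fraction = as.numeric(mf),
       retained = retained,
       reason = if (retained) "ok" else "minority_below_threshold",
       center = ctr)
}

#' Prepare the full psychometric panel
#'
#' Binarizes every variable in the panel and applies the retention rule.
#' All variables are returned with their retention flag; downstream stages
#' iterate over the retained subset.
#'
#' @param x A `"cohort"` object (its `psychometrics` block is used, with
#'   wave/category metadata from the generator) or a plain data.frame whose
#'   columns are numeric psychometric variables (an optional `subject_id`
#'   column is used for alignment).
#' @param config A [prep_config()].
#' @param ids Optional subject ids: restrict and order the panel to these
#'   subjects (the split point is then computed within that subset, i.e.
#'   within the dataset being analyzed).
#' @return An object of class `"psych_panel"`: a list of variables, each
#'   with `name`, `wave`, `category`, `raw`, `binary`, `minority_fraction`,
#'   `retained`, `reason`. Has an `as.data.frame` method producing the
#'   panel report.
#' @export
prepare_panel <- function(x, config = prep_config(), ids = NULL) {
  info <- NULL
  if (inherits(x, "cohort")) {
    info <- x$meta$variable_info
    df <- x$psychometrics
  } else {
    df <- as.data.frame(x)
  }
  stopifnot(is.data.frame(df))
  subject_id <- df[["subject_id"]]
  vars <- colnames(df)
  vars <- vars[vars != "subject_id"]
  if (!length(vars)) stop("psychometric panel is empty")
  if (anyDuplicated(vars))
    stop("duplicate variable names: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  rows <- seq_len(nrow(df))
  if (!is.null(ids)) {
    if (is.null(subject_id)) stop("ids given but panel has no subject_id")
    rows <- match(ids, subject_id)
    if (anyNA(rows)) stop("ids absent from the panel: ",
                          paste(ids[is.na(rows)][1:5], collapse = ", "))
  }

  out <- lapply(vars, function(v) {
    raw <- df[[v]][rows]
    meta <- if (!is.null(info) && v %in% info$name)
      info[info$name == v, ] else NULL
    bz <- tryCatch(binarize_at_mean(raw, config), error = function(e) {
      list(binary = factor(rep(NA_character_, length(raw)),
                           levels = c("low", "high")),
           minority_fraction = NA_real_, retained = FALSE,
           reason = "all_missing", center = NA_real_)
    })
    list(name = v,
         wave = if (is.null(meta)) NA_character_ else meta$wave,
         category = if (is.null(meta)) NA_character_ else meta$category,
         raw = raw, binary = bz$binary,
         minority_fraction = bz$minority_fraction,
         retained = bz$retained, reason = bz$reason, center = bz$center)
  })
  names(out) <- vars
  structure(out, class = "psych_panel",
            subject_id = if (is.null(subject_id)) NULL else subject_id[rows])
}

#' @export
as.data.frame.psych_panel <- function(x, ...) {
  data.frame(
    name = vapply(x, `[[`, character(1L), "name"),
    category = vapply(x, `[[`, character(1L), "category"),
    wave = vapply(x, `[[`, character(1L), "wave"),
    minority_fraction = vapply(x, `[[`, numeric(1L), "minority_fraction"),
    retained = vapply(x, `[[`, logical(1L), "retained"),
    reason = vapply(x, `[[`, character(1L), "reason"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.psych_panel <- function(x, ...) {
  rep <- as.data.frame(x)
  cat("Psychometric panel:", nrow(rep), "variables,",
      sum(rep$retained), "retained\n")
  invisible(x)
}

#' Names of the variables retained for counterbalancing
#'
#' @param panel A `"psych_panel"`.
#' @return Character vector of retained variable names.
#' @export
retained_variables <- function(panel) {
  stopifnot(inherits(panel, "psych_panel"))
  names(panel)[vapply(panel, `[[`, logical(1L), "retained")]
}

#' Write the panel report
#'
#' @param panel A `"psych_panel"`.
#' @param path Output TSV path.
#' @return Invisibly, the report data.frame.
#' @export
write_panel_report <- function(panel, path) {
  rep <- as.data.frame(panel)
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rep)
}
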