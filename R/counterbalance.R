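# Counterbalancing with oversampling. Subjects are resampled with
# replacement until the control strata are identically distributed across
# the two outcome classes, which severs the c -> y arm of a confounding
# pathway X <- c -> y without discarding any subject.

#' Compose control strata from sex, site and an optional variable
#'
#' Builds the categorical strata that counterbalancing equalizes across
#' outcome classes: the cross-product of sex, recruitment site and, when
#' present, one binarized psychometric variable. A missing value in any
#' component yields a missing stratum (the subject is then dropped from a
#' resampling plan and reported).
#'
#' @param sex,site,variable Aligned factors (any may be `NULL`; at least
#'   one must be given).
#' @return A factor of stratum labels with a `"controls"` attribute naming
#'   the composed components.
#' @examples
#' compose_controls(sex = c("f", "m"), site = c("s1", "s1"))
#' @export
compose_controls <- function(sex = NULL, site = NULL, variable = NULL) {
  parts <- list(sex = sex, site = site, variable = variable)
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (!length(parts)) stop("at least one control component required")
  n <- unique(lengths(parts))
  if (length(n) != 1L) stop("control components have unequal lengths")
  chr <- lapply(parts, as.character)
  lab <- do.call(paste, c(chr, sep = ":"))
  lab[Reduce(`|`, lapply(chr, is.na))] <- NA_character_
  structure(factor(lab), controls = names(parts))
}

#' Counterbalance a sample by oversampling
#'
#' For each control stratum `k`, let `m_k` be the largest cell count over
#' the two outcome classes; every cell `(class j, stratum k)` is filled up
#' to exactly `m_k` by drawing additional members uniformly with
#' replacement from that cell's original subjects. Afterwards each
#' stratum's count is equal across classes (the class-by-stratum
#' chi-square statistic of the resampled table is exactly zero), the
#' classes are equal in total size, and every original subject with
#' complete control values appears at least once. Deterministic given
#' `seed`.
#'
#' @param y Binary outcome (factor or coercible).
#' @param strata Control stratum labels aligned with `y` (e.g. from
#'   [compose_controls()]); subjects with a missing stratum or outcome are
#'   dropped from the plan and listed in the result.
#' @param seed Integer seed.
#' @return An object of class `"resampling_plan"`: list with `indices`
#'   (multiset of positions into the input vectors), `cell_table_before`,
#'   `cell_table_after`, `control_variables`, `dropped` (positions with
#'   missing controls) and `seed`.
#' @examples
#' y <- rep(c("a", "b"), c(40, 40))
#' s <- rep(c("low", "high", "low", "high"), c(30, 10, 10, 30))
#' plan <- counterbalance_oversample(y, s, seed = 1)
#' plan$cell_table_after
#' @export
counterbalance_oversample <- function(y, strata, seed = 1L) {
  y <- droplevels(factor(y))
  strata_in <- factor(strata)
  if (length(y) != length(strata_in))
    stop("y and strata must be aligned")
  keep <- !is.na(y) & !is.na(strata_in)
  dropped <- which(!keep)
  ys <- droplevels(y[keep])
  if (nlevels(ys) != 2L)
    stop("y must be binary with both classes present")
  ss <- droplevels(strata_in[keep])
  orig <- which(keep)

  tab <- table(y = ys, stratum = ss)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(errorCondition(
      paste0("uncounterbalanceable: empty cell (y = ",
             rownames(tab)[bad[1L]], ", stratum = ",
             colnames(tab)[bad[2L]], ")"),
      class = "uncounterbalanceable"))
  }

  extra <- with_seed(derive_seed(seed, "counterbalance"), {
    add <- list()
    for (k in colnames(tab)) {
      m_k <- max(tab[, k])
      for (j in rownames(tab)) {
        need <- m_k - tab[j, k]
        if (need > 0L) {
          cell <- orig[ys == j & ss == k]
          add[[paste(j, k)]] <-
            cell[sample.int(length(cell), need, replace = TRUE)]
        }
      }
    }
    unlist(add, use.names = FALSE)
  })
  indices <- c(orig, extra)
  after <- table(y = y[indices], stratum = factor(strata_in[indices],
                                                  levels = levels(ss)))
  structure(
    list(indices = as.integer(indices),
         cell_table_before = tab,
         cell_table_after = after,
         control_variables = attr(strata, "controls"),
         dropped = as.integer(dropped),
         seed = as.integer(seed),
         n_original = length(orig)),
    class = "resampling_plan"
  )
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat("Counterbalancing plan:", x$n_original, "original subjects ->",
      length(x$indices), "resampled (", length(x$dropped),
      "dropped for missing controls )\n")
  cat("Cell table after resampling:\n")
  print(x$cell_table_after)
  invisible(x)
}

#' Serialize a resampling plan to JSON
#'
#' Writes indices, both cell tables and the seed, so a plan can be rerun or
#' audited exactly.
#'
#' @param plan A `"resampling_plan"`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "resampling_plan"))
  payload <- list(
    indices = plan$indices,
    cell_table_before = as.data.frame(plan$cell_table_before),
    cell_table_after = as.data.frame(plan$cell_table_after),
    control_variables = plan$control_variables,
    dropped = plan$dropped,
    seed = plan$seed,
    n_original = plan$n_original
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
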