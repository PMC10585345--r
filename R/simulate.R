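# Synthetic cohort generator. Emulates the layout of a longitudinal
# neuroimaging cohort: a structural-feature matrix (T1-weighted + DTI
# derived columns), a phenotype table with ESPAD-coded lifetime binge
# drinking episode (BDE) scores at two waves, sex and recruitment site, and
# a panel of psychometric variables with a known causal role. Every
# variable's relation to features X and outcome y is controlled, so
# downstream confound-detection stages can be tested against ground truth.

PSYCH_CATEGORIES <- c(
  "alcohol-related", "binge-and-addiction-related",
  "mental-health-comorbidity", "general-health", "personality",
  "social", "biographic", "familial-risk"
)

#' Specify one synthetic psychometric variable
#'
#' Defines a candidate explanatory variable `c` and its causal role. A
#' variable with `loading_on_X > 0` and `effect_on_y != 0` is a true
#' confound realizing the pathway `X <- c -> y`; with both zero it is a
#' pure null.
#'
#' @param name Variable name (unique within a cohort specification).
#' @param wave Assessment wave, `"baseline"` or `"followup"`.
#' @param loading_on_X Non-negative strength with which `c` shifts a random
#'   subset of feature columns (in feature-noise SD units per unit of `c`).
#' @param effect_on_y Log-odds contribution of `c` to the outcome liability.
#' @param distribution `"gaussian"` (standard normal) or `"bernoulli"`.
#' @param p Success probability when `distribution = "bernoulli"`.
#' @param n_affected_features Number of randomly chosen feature columns that
#'   receive the loading.
#' @param category One of the eight psychometric categories; metadata only.
#' @param driver Optional label of a shared latent driver. Variables with
#'   the same label draw their underlying latent as
#'   `driver_weight * z_driver + sqrt(1 - driver_weight^2) * z_own`, making
#'   them correlated - the typical situation for psychometric scales that
#'   tap one underlying trait. `NULL` (default) means independent.
#' @param driver_weight Loading on the shared driver, in `[0, 1)`.
#' @return An object of class `"confound_spec"`.
#' @examples
#' confound_spec("sensation_seeking", wave = "baseline",
#'               loading_on_X = 1, effect_on_y = 1.5,
#'               distribution = "bernoulli")
#' @export
confound_spec <- function(name,
                          wave = c("baseline", "followup"),
                          loading_on_X = 0,
                          effect_on_y = 0,
                          distribution = c("gaussian", "bernoulli"),
                          p = 0.5,
                          n_affected_features = 50L,
                          category = "general-health",
                          driver = NULL,
                          driver_weight = 0.8) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  wave <- match.arg(wave)
  distribution <- match.arg(distribution)
  stopifnot(
    is.numeric(loading_on_X), length(loading_on_X) == 1L, loading_on_X >= 0,
    is.numeric(effect_on_y), length(effect_on_y) == 1L,
    is.numeric(p), p > 0, p < 1,
    n_affected_features >= 1L,
    category %in% PSYCH_CATEGORIES,
    is.null(driver) || (is.character(driver) && length(driver) == 1L),
    driver_weight >= 0, driver_weight < 1
  )
  structure(
    list(name = name, wave = wave, loading_on_X = loading_on_X,
         effect_on_y = effect_on_y, distribution = distribution, p = p,
         n_affected_features = as.integer(n_affected_features),
         category = category, driver = driver,
         driver_weight = driver_weight),
    class = "confound_spec"
  )
}

#' Specify a synthetic cohort
#'
#' Collects the dimensions, nuisance structure, signal strengths and
#' candidate-variable panel of a synthetic cohort. Defaults mirror the
#' layout of the motivating study: 656 T1-weighted plus 63 DTI features,
#' 8 recruitment sites, two sexes, and lifetime BDE scores coded 0-6 whose
#' default marginal yields roughly a 53/47 safe/heavy split after dropping
#' the intermediate categories 4-5.
#'
#' @param n_subjects Number of subjects.
#' @param n_t1_features,n_dti_features Feature-block widths.
#' @param n_sites Number of recruitment sites.
#' @param sex_ratio Probability of `"female"`.
#' @param direct_signal_strength Log-odds effect of the latent brain factor
#'   `b` on the outcome liability (the direct `X -> y` signal).
#' @param confound_specs List of [confound_spec()] objects; names unique.
#' @param noise_sd SD of independent feature noise.
#' @param baseline_bde_max Maximum baseline BDE score generated (default 0:
#'   the binge-naive design).
#' @param bde_probs Length-7 marginal distribution of the followup BDE
#'   score over categories 0-6 (normalized internally).
#' @param n_signal_features Number of feature columns carrying the latent
#'   factor `b` (capped at the total feature count).
#' @param signal_loading_sd SD of the sparse loadings of `b` on features.
#' @param site_sd SD of per-site additive feature offsets.
#' @param sex_shift SD of the additive male-vs-female feature offset.
#' @param seed Master seed; all draw steps use named substreams of it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects,
                        n_t1_features = 656L,
                        n_dti_features = 63L,
                        n_sites = 8L,
                        sex_ratio = 0.5,
                        direct_signal_strength = 1,
                        confound_specs = list(),
                        noise_sd = 1,
                        baseline_bde_max = 0L,
                        bde_probs = c(0.200, 0.120, 0.090, 0.078,
                                      0.040, 0.035, 0.437),
                        n_signal_features = 100L,
                        signal_loading_sd = 0.5,
                        site_sd = 0.5,
                        sex_shift = 0.3,
                        seed = 1L) {
  stopifnot(
    n_subjects >= 1L, n_t1_features >= 0L, n_dti_features >= 0L,
    n_t1_features + n_dti_features >= 1L,
    n_sites >= 1L, sex_ratio > 0, sex_ratio < 1,
    direct_signal_strength >= 0, noise_sd > 0,
    baseline_bde_max >= 0L, baseline_bde_max <= 6L,
    length(bde_probs) == 7L, all(bde_probs >= 0), sum(bde_probs) > 0,
    n_signal_features >= 1L, signal_loading_sd >= 0,
    site_sd >= 0, sex_shift >= 0
  )
  if (length(confound_specs)) {
    stopifnot(all(vapply(confound_specs, inherits, logical(1L),
                         "confound_spec")))
    nms <- vapply(confound_specs, `[[`, character(1L), "name")
    if (anyDuplicated(nms))
      stop("confound_specs names must be unique: ",
           paste(unique(nms[duplicated(nms)]), collapse = ", "))
    p_total <- n_t1_features + n_dti_features
    bad <- vapply(confound_specs, function(cs)
      cs$loading_on_X > 0 && cs$n_affected_features > p_total, logical(1L))
    if (any(bad))
      stop("n_affected_features exceeds the feature count for: ",
           paste(nms[bad], collapse = ", "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_t1_features = as.integer(n_t1_features),
         n_dti_features = as.integer(n_dti_features),
         n_sites = as.integer(n_sites),
         sex_ratio = sex_ratio,
         direct_signal_strength = direct_signal_strength,
         confound_specs = confound_specs,
         noise_sd = noise_sd,
         baseline_bde_max = as.integer(baseline_bde_max),
         bde_probs = bde_probs / sum(bde_probs),
         n_signal_features = as.integer(n_signal_features),
         signal_loading_sd = signal_loading_sd,
         site_sd = site_sd,
         sex_shift = sex_shift,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the generative model, in order: (1) sex, site and
#' each psychometric variable `c` from its distribution; (2) a latent brain
#' factor `b ~ N(0,1)` per subject; (3) features as site offset + sex
#' offset + `b` times a sparse loading vector + each confound's loading on
#' its affected columns (random signs) + independent Gaussian noise;
#' (4) a continuous outcome liability `direct_signal_strength * b +
#' sum(effect_on_y * c) + logistic noise`, whose empirical quantiles are
#' cut at the cumulative `bde_probs` to yield the 0-6 followup BDE score;
#' (5) baseline BDE scores bounded by `baseline_bde_max`. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `"cohort"`: a list with a numeric `features`
#'   matrix (subjects x features), a `phenotype` data.frame
#'   (`subject_id`, `bde_baseline`, `bde_followup`, `sex`, `site`), a
#'   `psychometrics` data.frame (one column per variable), and `meta`
#'   (spec echo, variable info, generator internals such as the latent
#'   liability, useful for diagnostics).
#' @examples
#' sp <- cohort_spec(40, n_t1_features = 5, n_dti_features = 2, seed = 7)
#' coh <- generate_cohort(sp)
#' dim(coh$features)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_t1_features + spec$n_dti_features
  seed <- spec$seed

  sex <- with_seed(derive_seed(seed, "sex"),
                   factor(ifelse(runif(n) < spec$sex_ratio, "female", "male"),
                          levels = c("female", "male")))
  site <- with_seed(derive_seed(seed, "site"),
                    factor(paste0("site", sample.int(spec$n_sites, n,
                                                     replace = TRUE)),
                           levels = paste0("site", seq_len(spec$n_sites))))

  cvals <- lapply(spec$confound_specs, function(cs) {
    z <- with_seed(derive_seed(seed, "confound", cs$name), rnorm(n))
    if (!is.null(cs$driver)) {
      zd <- with_seed(derive_seed(seed, "driver", cs$driver), rnorm(n))
      z <- cs$driver_weight * zd + sqrt(1 - cs$driver_weight^2) * z
    }
    if (cs$distribution == "gaussian") z
    else as.numeric(z > stats::qnorm(1 - cs$p))
  })
  names(cvals) <- vapply(spec$confound_specs, `[[`, character(1L), "name")

  b <- with_seed(derive_seed(seed, "latent"), rnorm(n))

  n_sig <- min(spec$n_signal_features, p)
  sig <- with_seed(derive_seed(seed, "signal_loadings"), {
    cols <- sample.int(p, n_sig)
    list(cols = cols, load = rnorm(n_sig, 0, spec$signal_loading_sd))
  })
  site_off <- with_seed(derive_seed(seed, "site_offsets"),
                        matrix(rnorm(spec$n_sites * p, 0, spec$site_sd),
                               spec$n_sites, p))
  sex_off <- with_seed(derive_seed(seed, "sex_offsets"),
                       rnorm(p, 0, spec$sex_shift))

  X <- site_off[as.integer(site), , drop = FALSE]
  X <- X + tcrossprod(as.numeric(sex == "male"), sex_off)
  X[, sig$cols] <- X[, sig$cols] + tcrossprod(b, sig$load)
  for (cs in spec$confound_specs) {
    if (cs$loading_on_X > 0) {
      w <- with_seed(derive_seed(seed, "confound_loading", cs$name), {
        cols <- sample.int(p, cs$n_affected_features)
        signs <- sample(c(-1, 1), cs$n_affected_features, replace = TRUE)
        list(cols = cols, signs = signs)
      })
      X[, w$cols] <- X[, w$cols] +
        tcrossprod(cvals[[cs$name]], cs$loading_on_X * w$signs)
    }
  }
  X <- X + with_seed(derive_seed(seed, "noise"),
                     matrix(rnorm(n * p, 0, spec$noise_sd), n, p))

  liability <- spec$direct_signal_strength * b
  for (cs in spec$confound_specs)
    liability <- liability + cs$effect_on_y * cvals[[cs$name]]
  liability <- liability + with_seed(derive_seed(seed, "liability"),
                                     rlogis(n))
  cuts <- quantile(liability, probs = cumsum(spec$bde_probs)[1:6],
                   names = FALSE)
  bde_followup <- as.integer(cut(liability, breaks = c(-Inf, cuts, Inf),
                                 labels = FALSE)) - 1L

  bde_baseline <- if (spec$baseline_bde_max == 0L) {
    rep(0L, n)
  } else {
    with_seed(derive_seed(seed, "baseline_bde"),
              sample(0:spec$baseline_bde_max, n, replace = TRUE,
                     prob = 0.7^(0:spec$baseline_bde_max)))
  }

  ids <- sprintf("S%05d", seq_len(n))
  colnames(X) <- c(sprintf("t1_%03d", seq_len(spec$n_t1_features)),
                   sprintf("dti_%03d", seq_len(spec$n_dti_features)))
  rownames(X) <- ids

  phenotype <- data.frame(subject_id = ids,
                          bde_baseline = bde_baseline,
                          bde_followup = bde_followup,
                          sex = sex, site = site,
                          stringsAsFactors = FALSE)
  psychometrics <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (nm in names(cvals)) psychometrics[[nm]] <- cvals[[nm]]

  variable_info <- if (length(spec$confound_specs)) {
    data.frame(
      name = names(cvals),
      wave = vapply(spec$confound_specs, `[[`, character(1L), "wave"),
      category = vapply(spec$confound_specs, `[[`, character(1L), "category"),
      distribution = vapply(spec$confound_specs, `[[`, character(1L),
                            "distribution"),
      loading_on_X = vapply(spec$confound_specs, `[[`, numeric(1L),
                            "loading_on_X"),
      effect_on_y = vapply(spec$confound_specs, `[[`, numeric(1L),
                           "effect_on_y"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(name = character(0), wave = character(0),
               category = character(0), distribution = character(0),
               loading_on_X = numeric(0), effect_on_y = numeric(0))
  }

  structure(
    list(features = X, phenotype = phenotype, psychometrics = psychometrics,
         meta = list(spec = spec, variable_info = variable_info,
                     liability = liability, latent_b = b)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$features), "subjects,",
      ncol(x$features), "features\n")
  cat("  sites:", nlevels(x$phenotype$site),
      " sex split:", paste(table(x$phenotype$sex), collapse = "/"), "\n")
  cat("  followup BDE distribution (0-6):",
      paste(tabulate(x$phenotype$bde_followup + 1L, 7L), collapse = " "),
      "\n")
  nv <- ncol(x$psychometrics) - 1L
  cat("  psychometric variables:", nv, "\n")
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes `features.csv`, `phenotype.csv`, `psychometrics.csv` and a
#' `manifest.json` (spec echo, seed, column roles). Numeric values are
#' written with full round-trip precision, so [read_cohort()] reproduces
#' the feature matrix exactly.
#'
#' @param cohort A `"cohort"` object.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  # doubles are serialized with 17 significant digits so that reading the
  # files back reproduces every value bit for bit
  g17 <- function(df) {
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df
  }
  feat <- data.frame(subject_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  data.table::fwrite(g17(feat), file.path(directory, "features.csv"),
                     quote = FALSE)
  data.table::fwrite(cohort$phenotype, file.path(directory, "phenotype.csv"))
  data.table::fwrite(g17(cohort$psychometrics),
                     file.path(directory, "psychometrics.csv"), quote = FALSE)

  spec <- cohort$meta$spec
  manifest <- list(
    format = "cbconfound-cohort",
    package_version = as.character(utils::packageVersion("cbconfound")),
    n_subjects = nrow(cohort$features),
    n_t1_features = spec$n_t1_features,
    n_dti_features = spec$n_dti_features,
    feature_columns = colnames(cohort$features),
    sex_levels = levels(cohort$phenotype$sex),
    site_levels = levels(cohort$phenotype$site),
    column_roles = list(features = "X", bde_followup = "y source",
                        psychometrics = "candidate variables c"),
    seed = spec$seed,
    spec = spec[setdiff(names(spec), "confound_specs")],
    confound_specs = lapply(spec$confound_specs, function(cs)
      Filter(Negate(is.null), unclass(cs))),
    variable_info = cohort$meta$variable_info
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing the cohort files.
#' @return A `"cohort"` object. The generator-internal diagnostics
#'   (liability, latent factor) are not persisted and come back as `NULL`.
#' @export
read_cohort <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path)) stop("missing manifest.json in ", directory)
  for (f in c("features.csv", "phenotype.csv", "psychometrics.csv"))
    if (!file.exists(file.path(directory, f))) stop("missing file: ", f)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)

  feat <- data.table::fread(file.path(directory, "features.csv"),
                            data.table = FALSE)
  phen <- data.table::fread(file.path(directory, "phenotype.csv"),
                            data.table = FALSE)
  psy <- data.table::fread(file.path(directory, "psychometrics.csv"),
                           data.table = FALSE)

  if (!identical(setdiff(colnames(feat), "subject_id"),
                 manifest$feature_columns))
    stop("feature columns do not match the manifest")
  if (!identical(feat$subject_id, phen$subject_id) ||
      !identical(feat$subject_id, psy$subject_id))
    stop("subject alignment error: the three tables do not share one ",
         "subject ordering")

  X <- as.matrix(feat[, manifest$feature_columns, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- feat$subject_id
  for (j in setdiff(colnames(psy), "subject_id"))
    psy[[j]] <- as.double(psy[[j]])
  phen$sex <- factor(phen$sex, levels = manifest$sex_levels)
  phen$site <- factor(phen$site, levels = manifest$site_levels)
  phen$bde_baseline <- as.integer(phen$bde_baseline)
  phen$bde_followup <- as.integer(phen$bde_followup)

  spec_fields <- manifest$spec
  spec <- do.call(cohort_spec, c(
    spec_fields[setdiff(names(spec_fields), character(0))],
    list(confound_specs = lapply(manifest$confound_specs, function(cs)
      do.call(confound_spec, cs)))
  ))

  vi <- manifest$variable_info
  if (is.null(vi) || length(vi) == 0) {
    vi <- data.frame(name = character(0), wave = character(0),
                     category = character(0), distribution = character(0),
                     loading_on_X = numeric(0), effect_on_y = numeric(0))
  } else {
    vi <- do.call(rbind, lapply(vi, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }

  structure(
    list(features = X, phenotype = phen, psychometrics = psy,
         meta = list(spec = spec, variable_info = vi,
                     liability = NULL, latent_b = NULL)),
    class = "cohort"
  )
}
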