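test_that("generation is deterministic given the seed", {
  sp <- cohort_spec(60, n_t1_features = 8, n_dti_features = 2, n_sites = 3,
                    confound_specs = list(confound_spec("v1"),
                                          confound_spec("v2",
                                                        distribution = "bernoulli")),
                    seed = 42)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$features, b$features)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$psychometrics, b$psychometrics)
})

test_that("changing one confound's effect leaves unrelated draws untouched", {
  base <- function(e) cohort_spec(
    100, n_t1_features = 5, n_dti_features = 2,
    confound_specs = list(confound_spec("v1", effect_on_y = e),
                          confound_spec("v2")), seed = 3)
  a <- generate_cohort(base(0))
  b <- generate_cohort(base(2))
  expect_identical(a$psychometrics$v1, b$psychometrics$v1)
  expect_identical(a$psychometrics$v2, b$psychometrics$v2)
  expect_identical(a$phenotype$sex, b$phenotype$sex)
  expect_identical(a$phenotype$site, b$phenotype$site)
})

test_that("default layout has 719 features, 8 sites and both sexes", {
  coh <- generate_cohort(cohort_spec(10, seed = 1))
  expect_identical(ncol(coh$features), 656L + 63L)
  coh500 <- generate_cohort(cohort_spec(500, n_t1_features = 5,
                                        n_dti_features = 2, seed = 2))
  expect_identical(length(unique(coh500$phenotype$site)), 8L)
  expect_setequal(as.character(unique(coh500$phenotype$sex)),
                  c("female", "male"))
  expect_true(all(coh500$phenotype$bde_followup %in% 0:6))
  expect_true(all(coh500$phenotype$bde_baseline == 0L))
})

test_that("a pure-null variable is uncorrelated with the binary outcome", {
  sp <- cohort_spec(2000, n_t1_features = 4, n_dti_features = 1,
                    confound_specs = list(confound_spec("nullv")),
                    seed = 7)
  coh <- generate_cohort(sp)
  lab <- categorize_bde(coh$phenotype$bde_followup)
  keep <- lab != "excluded"
  r <- cor(coh$psychometrics$nullv[keep],
           as.numeric(lab[keep] == "heavy"))
  # analytic null sampling band: |r| < z_{0.995} / sqrt(n - 1)
  expect_lt(abs(r), qnorm(0.995) / sqrt(sum(keep) - 1))
})

test_that("outcome-liability correlation is monotone in effect_on_y", {
  specs <- lapply(c(0, 0.5, 1, 2, 4), function(e)
    cohort_spec(2000, n_t1_features = 4, n_dti_features = 1,
                confound_specs = list(confound_spec("v", effect_on_y = e)),
                seed = 11))
  cors <- vapply(specs, function(sp) {
    coh <- generate_cohort(sp)
    abs(cor(coh$psychometrics$v, coh$meta$liability))
  }, numeric(1L))
  expect_true(all(diff(cors) >= 0))
})

test_that("shared-driver variables are correlated, independent ones are not", {
  sp <- cohort_spec(3000, n_t1_features = 2, n_dti_features = 1,
                    confound_specs = list(
                      confound_spec("a", driver = "d", driver_weight = 0.9),
                      confound_spec("b", driver = "d", driver_weight = 0.9),
                      confound_spec("c")),
                    seed = 5)
  coh <- generate_cohort(sp)
  expect_gt(cor(coh$psychometrics$a, coh$psychometrics$b), 0.6)
  expect_lt(abs(cor(coh$psychometrics$a, coh$psychometrics$c)), 0.08)
})

test_that("write/read round-trips a cohort exactly", {
  sp <- cohort_spec(10, n_t1_features = 656, n_dti_features = 63,
                    confound_specs = list(confound_spec("v1"),
                                          confound_spec("v2",
                                                        distribution = "bernoulli")),
                    seed = 9)
  coh <- generate_cohort(sp)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)

  feat_lines <- readLines(file.path(dir, "features.csv"))
  expect_identical(length(feat_lines) - 1L, 10L)
  expect_identical(length(strsplit(feat_lines[1L], ",")[[1L]]) - 1L, 719L)

  back <- read_cohort(dir)
  expect_identical(back$features, coh$features)
  expect_equal(back$phenotype, coh$phenotype, ignore_attr = TRUE)
  expect_identical(back$psychometrics$v1, coh$psychometrics$v1)
  expect_identical(back$psychometrics$v2, coh$psychometrics$v2)
})

test_that("misaligned tables are rejected on read", {
  coh <- generate_cohort(cohort_spec(8, n_t1_features = 3,
                                     n_dti_features = 1, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ph <- data.table::fread(file.path(dir, "phenotype.csv"))
  data.table::fwrite(ph[-2L, ], file.path(dir, "phenotype.csv"))
  expect_error(read_cohort(dir), "alignment")
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(10, n_t1_features = 0, n_dti_features = 0))
  expect_error(cohort_spec(10, confound_specs = list(
    confound_spec("a"), confound_spec("a"))), "unique")
  expect_error(cohort_spec(10, n_t1_features = 3, n_dti_features = 1,
                           confound_specs = list(
                             confound_spec("a", loading_on_X = 1,
                                           n_affected_features = 10))),
               "exceeds")
})
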