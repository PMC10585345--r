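test_that("BH step-up matches the textbook cases", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_correct(0.37), 0.37)
  expect_equal(bh_correct(c(1, 1)), c(1, 1))
  expect_identical(bh_correct(numeric(0)), numeric(0))
  expect_error(bh_correct(c(0.1, 0)), "p > 0")
})

test_that("BH agrees with the brute-force oracle and stats::p.adjust", {
  set.seed(14)
  for (i in 1:200) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    p[p == 0] <- 1e-12
    q <- bh_correct(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("the exploration screen takes the lowest fraction with ties", {
  mk <- function(vals) data.frame(variable = sprintf("v%02d", seq_along(vals)),
                                  mba_post_pre = vals)
  r <- exploration_stage(mk(c(-0.3, 0.1, -0.1, 0, 0.2, 0.05, -0.05,
                              0.15, 0.01, 0.02)), 0.10)
  expect_identical(r$selected, "v01")
  expect_identical(r$k, 1)

  # exact tie at the selection boundary extends the selection
  tie <- exploration_stage(mk(c(-0.2, -0.1, -0.1, 0, 0.1, 0.2, 0.3, 0.4,
                                0.5, 0.6)), 0.20)
  expect_setequal(tie$selected, c("v01", "v02", "v03"))

  set.seed(15)
  big <- exploration_stage(mk(rnorm(113)), 13 / 113)
  expect_identical(length(big$selected), 13L)

  expect_error(exploration_stage(mk(rep(NA_real_, 3))), "finite")
})

test_that("controlling a single-level variable changes nothing", {
  set.seed(16)
  n <- 120
  y <- factor(rep(c("safe", "heavy"), each = n / 2))
  X <- matrix(rnorm(n * 6), n, 6)
  X[y == "heavy", 1:2] <- X[y == "heavy", 1:2] + 1.5
  sex <- factor(rep(c("f", "m"), n / 2))
  cv <- cv_spec(outer_folds = 4, repetitions = 2, seed = 3)
  baseline <- train_eval_mba(X, y, compose_controls(sex = sex),
                             fast_model(), cv)
  noop <- make_variable("noop", factor(rep("low", n),
                                       levels = c("low", "high")))
  row <- mba_post_pre(X, y, noop, baseline, sex = sex,
                      model = fast_model(), cv = cv)
  expect_identical(row$mba_post, row$mba_pre)
  expect_identical(row$mba_post_pre, 0)
  expect_identical(row$sd_post_pre, 0)
})

test_that("an uncounterbalanceable variable yields an NA report row", {
  set.seed(17)
  n <- 60
  y <- factor(rep(c("safe", "heavy"), each = n / 2))
  X <- matrix(rnorm(n * 4), n, 4)
  cv <- cv_spec(outer_folds = 3, repetitions = 1, seed = 1)
  baseline <- train_eval_mba(X, y, NULL, fast_model(), cv)
  aligned <- make_variable("same_as_y",
                           factor(ifelse(y == "safe", "low", "high"),
                                  levels = c("low", "high")))
  row <- mba_post_pre(X, y, aligned, baseline, model = fast_model(), cv = cv)
  expect_true(is.na(row$mba_post))
  expect_match(row$reason, "uncounterbalanceable")
})

test_that("the variable constructed to drive the outcome screens lowest", {
  sp <- cohort_spec(300, n_t1_features = 25, n_dti_features = 5,
                    n_sites = 1, direct_signal_strength = 0,
                    confound_specs = c(
                      list(confound_spec("alcohol_proxy", loading_on_X = 1,
                                         effect_on_y = 2,
                                         distribution = "bernoulli",
                                         n_affected_features = 15,
                                         category = "alcohol-related")),
                      lapply(1:3, function(i)
                        confound_spec(paste0("null_", i)))),
                    seed = 23)
  coh <- generate_cohort(sp)
  blk <- analysis_block(coh, holdout_per_class = 0, seed = 23)
  cv <- cv_spec(outer_folds = 5, repetitions = 1, seed = 4)
  baseline <- train_eval_mba(blk$X, blk$y,
                             compose_controls(sex = blk$sex,
                                              site = blk$site),
                             fast_model(), cv)
  reports <- do.call(rbind, lapply(retained_variables(blk$panel),
                                   function(v)
    mba_post_pre(blk$X, blk$y, blk$panel[[v]], baseline, sex = blk$sex,
                 site = blk$site, model = fast_model(), cv = cv)))
  expect_identical(reports$variable[which.min(reports$mba_post_pre)],
                   "alcohol_proxy")
  expect_lt(min(reports$mba_post_pre), -0.05)
})

test_that("permutation p-values are granular ranks and never zero", {
  set.seed(18)
  n <- 80
  y <- factor(rep(c("safe", "heavy"), each = n / 2))
  X <- matrix(rnorm(n * 4), n, 4)
  v <- make_variable("v", factor(rep(c("low", "high"), n / 2),
                                 levels = c("low", "high")))
  cv <- cv_spec(outer_folds = 4, repetitions = 1, seed = 2)
  p <- permutation_null_post_pre(X, y, v, model = fast_model(), cv = cv,
                                 n_perm = 19, seed = 3)
  expect_true(as.numeric(p) %in% ((1:20) / 20))
  expect_gt(as.numeric(p), 0)
  expect_length(attr(p, "permuted_changes"), 19L)
})

test_that("generalization enforces holdout disjointness and alpha", {
  set.seed(19)
  n <- 80
  y <- factor(rep(c("safe", "heavy"), each = n / 2))
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == "heavy", 1] <- X[y == "heavy", 1] + 1
  panel <- prepare_panel(data.frame(v1 = rnorm(n)))
  expect_error(
    generalization_stage("v1", X, y, panel,
                         model = fast_model(),
                         cv = cv_spec(outer_folds = 3, repetitions = 1,
                                      seed = 1),
                         n_perm = 19,
                         exploratory_ids = c("a", "b", "c"),
                         holdout_ids = c("c", "d")),
    "overlaps")

  empty <- generalization_stage(character(0), X, y, panel)
  expect_identical(nrow(empty), 0L)

  res <- generalization_stage("v1", X, y, panel, model = fast_model(),
                              cv = cv_spec(outer_folds = 3,
                                           repetitions = 1, seed = 1),
                              n_perm = 19, alpha = 1.0, seed = 5)
  expect_identical(nrow(res), 1L)
  expect_true(res$significant)
  expect_gte(res$q_bh, res$p_perm)
})
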