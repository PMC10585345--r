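# Shared scenario builders. The three simulation studies below define the
# package's reference conditions: a realistic null cohort for calibration,
# a single strong confound for recovery, and a 30-variable panel with two
# correlated true confounds for the end-to-end two-stage design. Problem
# sizes (features, sites, CV repetitions, permutations) are the scaled-down
# study sizes documented in the methods vignette.

# operating point for scaled simulations: fixed hyperparameters at the
# smooth end of the kernel-width heuristic (see vignette)
fast_model <- function() model_spec(cost = 1, gamma = 0.1)

# null-calibration cohort: real brain signal, one pure-null variable,
# 100 features, 600 subjects
null_calibration_spec <- function(seed) {
  cohort_spec(600, n_t1_features = 90, n_dti_features = 10, n_sites = 2,
              direct_signal_strength = 1,
              confound_specs = list(confound_spec("nullv")),
              seed = seed)
}

# confound-recovery cohort: no direct signal; one strong binary confound
# (loading 1.0 on 50 of 100 features, log-odds effect 1.5) plus one null
confound_recovery_spec <- function(seed) {
  cohort_spec(600, n_t1_features = 80, n_dti_features = 20, n_sites = 2,
              direct_signal_strength = 0,
              confound_specs = list(
                confound_spec("conf", loading_on_X = 1, effect_on_y = 1.5,
                              distribution = "bernoulli",
                              n_affected_features = 50,
                              category = "alcohol-related"),
                confound_spec("nullv")),
              seed = seed)
}

# two-stage panel cohort: 2 correlated true confounds (tapping one latent
# trait) + 28 nulls, single site, 40 features
panel_recovery_spec <- function(seed) {
  confs <- c(
    list(confound_spec("conf_a", loading_on_X = 1, effect_on_y = 1,
                       distribution = "bernoulli",
                       n_affected_features = 20,
                       category = "alcohol-related",
                       driver = "binge_latent", driver_weight = 0.95),
         confound_spec("conf_b", wave = "followup", loading_on_X = 1,
                       effect_on_y = 1, distribution = "bernoulli",
                       n_affected_features = 20,
                       category = "binge-and-addiction-related",
                       driver = "binge_latent", driver_weight = 0.95)),
    lapply(1:28, function(i) confound_spec(sprintf("null_%02d", i))))
  cohort_spec(640, n_t1_features = 30, n_dti_features = 10, n_sites = 1,
              direct_signal_strength = 0, confound_specs = confs,
              seed = seed)
}

# assemble a cohort and pull out the aligned analysis blocks
analysis_block <- function(cohort, holdout_per_class = 0L, seed = 1L) {
  asm <- assemble_cohort(cohort, holdout_per_class = holdout_per_class,
                         seed = seed)
  ids <- asm$split$exploratory_ids
  rows <- match(ids, cohort$phenotype$subject_id)
  list(X = cohort$features[rows, , drop = FALSE],
       y = asm$labels[ids],
       sex = cohort$phenotype$sex[rows],
       site = droplevels(cohort$phenotype$site[rows]),
       ids = ids, assembly = asm,
       panel = prepare_panel(cohort, ids = ids))
}

# minimal panel-variable stub for detection-level tests
make_variable <- function(name, binary, retained = TRUE,
                          category = NA_character_, wave = NA_character_) {
  list(name = name, category = category, wave = wave,
       raw = as.numeric(binary == levels(binary)[2L]),
       binary = binary, minority_fraction = NA_real_,
       retained = retained, reason = "ok", center = NA_real_)
}

# independent brute-force step-up oracle for Benjamini-Hochberg
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j)
      if (ps[j] >= ps[i]) m * ps[j] / j else Inf, numeric(1L))
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- q
  out
}
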