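---
title: "Detecting variables that explain a predictive model: counterbalancing with oversampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variables that explain a predictive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A machine-learning model `f: X -> y` that predicts future binge drinking
from adolescent structural brain features is accurate, but accuracy alone
does not say *why*. A psychometric characteristic `c` (a personality
trait, an eating-behavior score, a social variable) may influence both the
brain features and the drinking outcome — a confounding pathway
`X <- c -> y`. If the model's accuracy drops substantially once `c` is
controlled, then `c` partially explains the prediction.

`cbconfound` implements this confound-detection analysis as a reusable,
tested pipeline:

1. **Sample assembly.** Lifetime binge-drinking episodes (BDE) are coded
   on the ESPAD 0–6 categorical scale. Followup scores below 4 define
   *safe users*, above 5 *heavy binge drinkers*; the intermediate scores
   4–5 are dropped. Only subjects who are binge-naive at baseline
   (baseline score 0; configurable to at most 1) enter the analysis, and
   the sample is split into an exploratory set and a class-balanced
   holdout (39 per class by default), stratified over sex and site by
   largest-remainder allocation.
2. **Panel preparation.** Every psychometric variable is binarized at its
   mean (counterbalancing needs categorical controls). A variable whose
   smaller group holds less than 15% of non-missing cases is excluded.
3. **Counterbalancing with oversampling.** For one candidate variable,
   control strata are the cross-product sex × site × binarized `c`.
   Within each stratum, every outcome-class cell is filled up to the
   stratum's largest cell by resampling that cell's own subjects with
   replacement. Afterwards the class-by-stratum table balances *exactly*
   (chi-square statistic identically zero) and no subject is discarded.
4. **Classification.** A radial-kernel SVM is evaluated by repeated,
   stratified cross-validation. Counterbalancing is applied to training
   folds only; test folds are never resampled, and mean balanced accuracy
   (MBA — the mean of per-class recalls) absorbs test-fold imbalance.
   The per-variable statistic is `MBA_post − MBA_pre`: the accuracy change
   when `c` joins the sex × site baseline controls.
5. **Two-stage inference.** The exploration stage screens the lowest
   ~10% of accuracy changes (ceiling rule, ties at the boundary
   included). The generalization stage re-evaluates the screened
   variables on the disjoint holdout with a permutation test and
   Benjamini–Hochberg correction.

## The permutation null

The null distribution for one variable's accuracy drop is built by
permuting the variable's binarized labels across subjects. This severs
`c`'s ties to both `X` and `y` while leaving the sex × site baseline
control and the X–y relation intact; each permutation re-runs the full
counterbalanced cross-validation. The one-sided p-value in the direction
of accuracy *reduction* is `(1 + #[permuted change <= observed change]) /
(1 + n_perm)` — never zero by construction. Permutations that produce an
uncounterbalanceable table (an empty class-by-stratum cell) are redrawn
and counted. Testing is one-sided because only accuracy reductions are
interpreted as explanation.

Model-level significance (`permutation_test_model`) instead permutes the
outcome labels and recomputes MBA with fresh fold assignments.

## The synthetic cohort generator

Real multi-site neuroimaging cohorts are access-restricted, so the
package ships a generator (`cohort_spec()`, `generate_cohort()`) that
emulates the data layout — by default 656 T1-weighted plus 63 DTI feature
columns, 8 recruitment sites, two sexes, ESPAD-coded BDE scores at two
waves — with a *known* causal structure:

* a latent brain factor `b ~ N(0,1)` loads sparsely on features and
  contributes `direct_signal_strength * b` to the outcome liability
  (the direct, non-confounded signal);
* each candidate variable `c` is gaussian or bernoulli, optionally
  correlated with other variables through a shared latent driver (as
  psychometric scales tapping one trait are), shifts a random subset of
  feature columns with random signs (`loading_on_X`), and adds
  `effect_on_y * c` to the liability — a variable with both parameters
  non-zero is a true confound `X <- c -> y`, with both zero a pure null;
* sex and site enter the features as additive offsets, so the baseline
  sex/site control is a genuine nuisance correction;
* the liability (plus standard-logistic noise) is cut at its empirical
  quantiles to produce the 0–6 BDE marginal. The default marginal yields
  roughly a 53/47 safe/heavy split after dropping scores 4–5, matching
  the reference cohort's class sizes — the published study reports class
  sizes, not a generative law, so the marginal is a configurable choice.

All randomness flows from one seed through named substreams (one per
draw step), so changing one specification field never perturbs unrelated
draws; this is what makes the monotonicity and null-calibration
properties testable.

What the generator does **not** emulate: feature covariance (features are
independent given the latent factors — real morphometric features are
strongly dependent), the inter-correlation structure of a real
questionnaire battery, site-specific scanner artefacts beyond additive
offsets, and missingness mechanisms. Passing tests therefore demonstrate
the *method's* statistical behavior under a known causal model, not
performance on real data.

## Numerical and design choices

* **Binarization tie policy.** Values exactly at the mean go to the low
  group — deterministic and order-independent. A median split is
  available (`prep_config(center = "median")`) but the mean is the
  default. Binarization uses the mean *within the dataset being
  analyzed* (exploratory and holdout separately); this is a sensitivity
  knob, not a settled convention.
* **Counterbalancing nested in training.** Duplicated subjects never
  span a train/test boundary; whole-sample resampling before the split
  would leak duplicates into test folds and inflate accuracy.
  `counterbalance_oversample()` is exposed directly for users who want
  to study that failure mode.
* **Fill-to-max rule.** Each stratum's cells are raised to the stratum
  maximum, realizing "equally distributed across outcome classes" by
  oversampling only; matching a pooled marginal would require removals
  and shrink the sample.
* **Kernel width.** The SVM uses `gamma = gamma_rel / p` for `p`
  standardized features. With independent standardized features, squared
  distances concentrate around `2p`, so `gamma_rel = 1` gives typical
  kernel values near `exp(-2)` — already fairly local — and large
  `gamma_rel` approaches a memorizing, nearest-neighbor-like regime. That
  regime defeats counterbalancing: the model can key on the *identities*
  of duplicated minority subjects instead of the count-balanced signal,
  so accuracy changes shrink toward zero. The scaled simulation studies
  therefore run at the smooth operating point `cost = 1, gamma_rel =
  0.1` (typical kernel values near `exp(-0.2)`), where the SVM relies on
  the multiplicity-weighted signal that counterbalancing actually
  controls. The default `model_spec()` keeps the conventional log-spaced
  grids (`cost`, `gamma_rel` in {0.1, 1, 10}) with inner 3-fold
  selection.
* **Nested inner selection.** Hyperparameter selection splits the
  *original* training subjects, counterbalances the inner-training part,
  and scores balanced accuracy on the untouched inner-validation part.
  Splitting the oversampled multiset would place copies of one subject
  on both sides and bias selection toward the memorizing corner of the
  grid.
* **Dispersion.** The reported MBA "SD" is the standard deviation over
  repetition-level means, and the SD of `MBA_post − MBA_pre` pairs
  repetitions (both runs share fold assignments via the common seed), so
  it reflects resampling variability of the *difference*, not two
  independent noises.
* **Screen rule.** `ceiling(fraction * K)` lowest values, extended for
  exact boundary ties; the fraction is a parameter because "~10%" is a
  screen, not a sharp test.
* **p-value convention.** `(b + 1) / (n + 1)` throughout.
* **Degenerate inputs.** Constant variables are flagged `degenerate`
  and never counterbalanced; a variable perfectly aligned with the
  outcome raises a classed `uncounterbalanceable` error naming the empty
  cell; subjects with a missing stratum value are dropped from the plan
  and listed, never silently.

## Simulation study sizes

The packaged tests run three simulation studies, scaled to desk-top
sizes (the published headline numbers come from an access-restricted
cohort and are not reproducible here):

* **Null calibration:** 60 cohorts of 600 subjects, 100 features, a real
  brain-to-outcome signal and one pure-null variable; 5-fold
  cross-validation, 19 permutations. The rejection rate of the
  accuracy-drop permutation test at alpha = 0.05 must lie inside the
  binomial 95% band around 0.05.
* **Single-confound recovery:** 20 cohorts of 600 subjects with no
  direct signal and one strong binary confound (loading 1.0 on 50 of 100
  features, log-odds effect 1.5): the baseline MBA must be at least
  0.60 and controlling the confound must push it to at most 0.55 in at
  least 90% of cohorts, while a null variable moves MBA by at most
  0.03.
* **Two-stage recovery:** 20 cohorts of 640 subjects with two
  correlated true confounds (shared latent driver, weight 0.95) among 28
  nulls; exploration screen at 10% then generalization on a disjoint
  160-subject holdout with 99 permutations and BH correction at
  alpha = 0.05. Both true confounds must come out significant with at
  most one false positive in at least 80% of cohorts.

The two true confounds are *correlated* by design: candidate variables
that tap one underlying trait each produce a large accuracy drop when
controlled, because controlling either removes the shared pathway. Two
*independent* equally-strong confounds would each show only a small
marginal drop (controlling one leaves the other's signal in place) —
worth remembering when interpreting per-variable accuracy changes on
real data.

## Limitations

* Binarization loses information; a continuous confound keeps a residual
  within-group association with the outcome that counterbalancing on the
  binary split cannot remove, so accuracy drops for coarsely binarized
  continuous confounds are conservative.
* Counterbalancing needs every class-by-stratum cell occupied in every
  training fold; small holdouts with many sites can make fine strata
  infeasible (the error says which cell is empty).
* Per-variable tests are marginal; correlated candidates flag together,
  and the method does not attribute shared signal (no causal mediation).
* The permutation scheme for a variable's drop keeps `X` and `y` fixed
  and permutes `c`; it tests "this variable explains part of the
  prediction", not "the model is significant" (use
  `permutation_test_model` for the latter).

## A worked run

```{r}
library(cbconfound)

spec <- cohort_spec(
  n_subjects = 640, n_t1_features = 30, n_dti_features = 10, n_sites = 1,
  direct_signal_strength = 0,
  confound_specs = c(
    list(confound_spec("sensation_seeking", loading_on_X = 1,
                       effect_on_y = 1, distribution = "bernoulli",
                       n_affected_features = 20, category = "personality",
                       driver = "trait", driver_weight = 0.95),
         confound_spec("uncontrolled_eating", wave = "followup",
                       loading_on_X = 1, effect_on_y = 1,
                       distribution = "bernoulli",
                       n_affected_features = 20,
                       category = "binge-and-addiction-related",
                       driver = "trait", driver_weight = 0.95)),
    lapply(1:28, function(i) confound_spec(sprintf("null_%02d", i)))),
  seed = 1)

cohort <- generate_cohort(spec)
scan <- confound_scan(cohort, holdout_per_class = 80,
                      model = model_spec(cost = 1, gamma = 0.1),
                      cv = cv_spec(outer_folds = 5, repetitions = 1),
                      n_perm = 99, seed = 1)
print(scan)
summary(scan)
plot(scan)
```
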