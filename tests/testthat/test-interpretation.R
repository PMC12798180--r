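fitted_tree_model <- function(n = 200, seed = 21) {
  fx <- separable_profiles(n = n, seed = seed)
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = seed)
  tune_and_train("tree_ensemble", data, split,
                 data.frame(nrounds = 20, eta = 0.3, max_depth = 3,
                            alpha = 0, lambda = 1), seed = seed)
}

test_that("tree attributions are locally additive to the model margin", {
  m <- fitted_tree_model()
  eff <- compute_feature_effects(m)
  contrib <- attr(eff, "shap")
  x <- m$parts$test$x
  margin <- predict(m$classifier$fit, xgboost::xgb.DMatrix(x),
                    outputmargin = TRUE)
  expect_lt(max(abs(rowSums(contrib) - margin)), 1e-6)
  expect_equal(nrow(eff), 65)
})

test_that("the planted driving feature carries the largest mean effect", {
  m <- fitted_tree_model(n = 300, seed = 23)
  eff <- compute_feature_effects(m)
  expect_identical(eff$feature[which.max(abs(eff$mean_shap))], "Sad")
  expect_gt(eff$mean_shap[eff$feature == "Sad"], 0)
})

test_that("features constant in training get zero attribution", {
  fx <- separable_profiles(n = 150, seed = 25)
  fx$profiles$Bright <- 2.5  # constant column
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = 25)
  m <- tune_and_train("tree_ensemble", data, split,
                      data.frame(nrounds = 15, eta = 0.3, max_depth = 3,
                                 alpha = 0, lambda = 1), seed = 25)
  eff <- compute_feature_effects(m)
  expect_equal(eff$mean_shap[eff$feature == "Bright"], 0)
  expect_error(compute_feature_effects(
    tune_and_train("ridge", data, split, data.frame(lambda = 0.1))),
    "tree-ensemble")
})

test_that("bootstrap runs have exact cardinality and determinism", {
  fx <- separable_profiles(n = 150, seed = 27)
  b1 <- bootstrap_run(fx$profiles, fx$subjects, n_runs = 10, seed = 6)
  expect_equal(nrow(b1$summary), 10)
  expect_equal(length(unique(b1$effects$run)), 10)
  expect_equal(nrow(b1$effects), 10 * 65)
  expect_true(all(b1$summary$status == "ok"))
  b2 <- bootstrap_run(fx$profiles, fx$subjects, n_runs = 10, seed = 6)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$effects, b2$effects)
  g <- glance(b1)
  expect_equal(g$n_runs, 10)
  s <- summarize_effects(b1)
  expect_equal(nrow(s), 65)
  expect_true(all(s$q2.5 <= s$median_shap & s$median_shap <= s$q97.5))
  # summaries reflect the stored per-run distributions, not a collapsed scalar
  sad_runs <- b1$effects$mean_shap[b1$effects$feature == "Sad"]
  expect_equal(s$mean_shap[s$feature == "Sad"], mean(sad_runs))
  expect_equal(s$sd_shap[s$feature == "Sad"], sd(sad_runs))
  expect_equal(s$q2.5[s$feature == "Sad"],
               unname(quantile(sad_runs, 0.025)))
  expect_true(any(s$sd_shap > 0))
})

test_that("failed bootstrap runs are recorded, not dropped", {
  fx <- separable_profiles(n = 60, seed = 29)
  # sabotage: a language that disappears under resplitting cannot occur here,
  # so force failure through an impossible stratum by dropping depression
  subj <- fx$subjects
  subj$group[subj$group == "depression"][1] <- "control"
  subj$language[1] <- "Chinese"  # lone subject, lone language -> empty stratum
  b <- bootstrap_run(fx$profiles, subj, n_runs = 2, seed = 2)
  expect_equal(nrow(b$summary), 2)
  expect_true(all(b$summary$status %in% c("ok", "failed")))
})

test_that("rank correlations behave on self, negation and planted pairs", {
  tb <- tibble::tibble(feature = binder_feature_names(),
                       mean_shap = rnorm(65))
  expect_equal(correlate_effects(tb, tb), 1)
  neg <- tb; neg$mean_shap <- -neg$mean_shap
  expect_equal(correlate_effects(tb, neg), -1)
  flat <- tb; flat$mean_shap <- 0
  expect_true(is.na(correlate_effects(tb, flat)))
  expect_error(correlate_effects(tb, tb[1:30, ]), "feature set")

  # two independently simulated cohorts sharing the planted effect
  # template yield positively rank-correlated effect tables
  effects_of_cohort <- function(key, seed) {
    study <- cached_cohort(key, function() {
      synthetic_spec(n_subjects = 400, seed = seed)
    })
    prof <- profiles_of(study)
    data <- classification_data(prof, study$subjects)
    subj <- study$subjects[match(data$ids, study$subjects$subject_id), ]
    m <- tune_and_train("tree_ensemble", data, make_split(subj, seed = seed),
                        data.frame(nrounds = 20, eta = 0.3, max_depth = 3,
                                   alpha = 0, lambda = 1), seed = seed)
    compute_feature_effects(m)
  }
  e1 <- effects_of_cohort("corr_a", 131)
  e2 <- effects_of_cohort("corr_b", 137)
  expect_gt(correlate_effects(e1, e2), 0)

  cm <- effects_correlation_matrix(list(a = e1, b = e2, self = e1))
  expect_equal(diag(cm), c(a = 1, b = 1, self = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["a", "self"], 1)
})

test_that("feature clustering separates opposite-sign blocks", {
  feats <- paste0("f", 1:6)
  block <- tibble::tibble(feature = feats,
                          mean_shap = c(1, 1.1, 0.9, -1, -1.1, -0.9))
  other <- tibble::tibble(feature = feats,
                          mean_shap = c(0.8, 1.2, 1.0, -0.7, -1.2, -1.1))
  cl <- cluster_features(list(s1 = block, s2 = other))
  cut2 <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(cut2[feats[1:3]])), 1)
  expect_equal(length(unique(cut2[feats[4:6]])), 1)
  expect_false(cut2[["f1"]] == cut2[["f4"]])

  # identical effects sit adjacent in leaf order
  twin <- tibble::tibble(feature = feats,
                         mean_shap = c(1, 1, 0.2, -1, -0.5, 0.7))
  cl2 <- cluster_features(list(a = twin, b = twin))
  pos <- match(c("f1", "f2"), cl2$order)
  expect_equal(abs(diff(pos)), 1)

  single <- tibble::tibble(feature = "f1", mean_shap = 1)
  cl3 <- cluster_features(list(a = single, b = single))
  expect_identical(cl3$order, "f1")
  expect_null(cl3$hclust)
})

test_that("bootstrap F1 spread shrinks with cohort size", {
  small <- cached_cohort("sdtest300", function() {
    synthetic_spec(n_subjects = 300, seed = 71)
  })
  large <- planted_cohort()
  p_small <- profiles_of(small)
  p_large <- profiles_of(large)
  b_small <- bootstrap_run(p_small, small$subjects, n_runs = 40, seed = 8)
  b_large <- bootstrap_run(p_large, large$subjects, n_runs = 40, seed = 8)
  expect_lt(sd(b_large$summary$f1), sd(b_small$summary$f1))
})

test_that("plot builders return ggplot objects", {
  fx <- separable_profiles(n = 150, seed = 41)
  grids <- lapply(default_grids(), function(g) g[1, , drop = FALSE])
  cmp <- compare_models(fx$profiles, fx$subjects,
                        candidates = c("ridge", "tree_ensemble"),
                        grids = grids, seed = 41)
  expect_s3_class(plot_model_comparison(cmp), "ggplot")
  eff <- compute_feature_effects(cmp$models$tree_ensemble)
  expect_s3_class(plot_feature_effects(eff), "ggplot")
  expect_s3_class(autoplot(eff), "ggplot")
  b <- bootstrap_run(fx$profiles, fx$subjects, n_runs = 3, seed = 2)
  expect_s3_class(plot_bootstrap(b), "ggplot")
  cl <- cluster_features(list(a = eff, b = eff))
  expect_s3_class(plot_effect_heatmap(cl), "ggplot")
})
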