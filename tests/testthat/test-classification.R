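single_stratum_subjects <- function(n = 100) {
  tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)),
                 language = "German", system_terms = 2L, age = 30,
                 gender = "female",
                 group = factor("control", levels = c("control", "depression")))
}

test_that("split fractions follow the 70/30 and 80/20-of-train nesting", {
  split <- make_split(single_stratum_subjects(100), seed = 1)
  expect_length(split$test, 30)
  expect_length(split$train, 70)
  expect_length(split$val, 14)
  expect_length(split$fit, 56)
  expect_setequal(c(split$fit, split$val), split$train)
  expect_length(intersect(split$train, split$test), 0)
})

test_that("splits are stratified, seeded and sensitive to the seed", {
  set.seed(1)
  subj <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:200),
    language = rep(c("German", "Italian"), each = 100),
    group = factor(rep(rep(c("control", "depression"), each = 50), 2),
                   levels = c("control", "depression")))
  s1 <- make_split(subj, seed = 5)
  for (lang in c("German", "Italian")) {
    for (g in c("control", "depression")) {
      ids <- subj$subject_id[subj$language == lang & subj$group == g]
      share <- length(intersect(ids, s1$test)) / length(ids)
      expect_lte(abs(share - 0.30), 1 / length(ids))
    }
  }
  s2 <- make_split(subj, seed = 5)
  expect_setequal(s1$test, s2$test)
  expect_setequal(s1$val, s2$val)
  s3 <- make_split(subj, seed = 6)
  expect_false(setequal(s1$test, s3$test))

  missing_stratum <- subj[!(subj$language == "Italian" &
                              subj$group == "depression"), ]
  expect_error(make_split(missing_stratum), "depression.Italian")
})

test_that("downsampling balances classes and anchors chance at 0.5", {
  ids <- sprintf("s%03d", 1:100)
  groups <- rep(c("control", "depression"), c(60, 40))
  bal <- balance_by_downsampling(ids, groups, seed = 3)
  expect_length(bal, 80)
  tab <- table(groups[match(bal, ids)])
  expect_equal(unname(tab["control"]), 40)
  expect_equal(unname(tab["depression"]), 40)
  expect_true(all(ids[groups == "depression"] %in% bal))  # minority untouched

  already <- balance_by_downsampling(ids[21:100], groups[21:100], seed = 3)
  expect_setequal(already, ids[21:100])

  # majority-class prediction on the balanced set scores 0.5 accuracy
  y <- as.integer(groups[match(bal, ids)] == "depression")
  expect_equal(mean(rep(0L, 80) == y), 0.5)
  expect_error(balance_by_downsampling(ids[1:60], groups[1:60], 1),
               "both classes")
})

test_that("metrics agree with a hand-computed confusion matrix", {
  truth <- rep(c(1, 1, 0, 0), c(8, 4, 4, 14))
  prob <- rep(c(0.9, 0.1, 0.9, 0.1), c(8, 4, 4, 14))  # TP FN FP TN
  m <- eval_metrics(truth, prob)
  expect_equal(m$precision, 8 / 12, tolerance = 1e-12)
  expect_equal(m$recall, 8 / 12, tolerance = 1e-12)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 22 / 30, tolerance = 1e-12)

  perfect <- eval_metrics(c(1, 0, 1, 0), c(0.99, 0.01, 0.98, 0.02))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$roc_auc, 1)

  onecls <- eval_metrics(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(onecls$roc_auc))
})

test_that("metrics match an independent tally on random predictions", {
  set.seed(61)
  for (rep in 1:5) {
    truth <- rbinom(60, 1, 0.5)
    prob <- runif(60)
    m <- eval_metrics(truth, prob)
    pred <- as.integer(prob > 0.5)
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
    rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    expect_equal(m$f1, ifelse(prec + rec == 0, 0,
                              2 * prec * rec / (prec + rec)))
    # AUC equals the Mann-Whitney probability of correct ranking
    pos <- prob[truth == 1]; neg <- prob[truth == 0]
    mw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(m$roc_auc, mw, tolerance = 1e-12)
  }
})

test_that("a singleton grid is always the chosen configuration", {
  fx <- separable_profiles(n = 120)
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = 2)
  grid <- data.frame(nrounds = 15, eta = 0.3, max_depth = 3, alpha = 0,
                     lambda = 1)
  m <- tune_and_train("tree_ensemble", data, split, grid, seed = 2)
  expect_equal(m$params$nrounds, 15)
  expect_equal(nrow(m$val_scores), 1)
  audit_no_leakage(m)
})

test_that("a separable signal is learned almost perfectly by the ensemble", {
  fx <- separable_profiles(n = 300)
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = 4)
  m <- tune_and_train("tree_ensemble", data, split,
                      default_grids()$tree_ensemble[1:4, ], seed = 4)
  met <- evaluate_per_language(m, languages = character())
  expect_gte(met$f1[met$subset == "full_test"], 0.95)
})

test_that("every candidate trains, predicts probabilities and evaluates", {
  fx <- separable_profiles(n = 160)
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = 7)
  grids <- list(ridge = data.frame(lambda = 0.1),
                ridge_ls = data.frame(lambda = 0.1),
                knn = data.frame(k = 5, leaf_size = 30, weights = "distance",
                                 stringsAsFactors = FALSE),
                tree_ensemble = data.frame(nrounds = 10, eta = 0.3,
                                           max_depth = 3, alpha = 0,
                                           lambda = 1),
                nn2 = data.frame(batch_size = 32, epochs = 20),
                nn3 = data.frame(batch_size = 32, epochs = 20))
  for (cand in c(classifier_candidates(), "ridge_ls")) {
    m <- tune_and_train(cand, data, split, grids[[cand]], seed = 7)
    prob <- predict(m$classifier, m$parts$test$x)
    expect_true(all(prob >= 0 & prob <= 1), info = cand)
    met <- evaluate_per_language(m, languages = character())
    expect_true(all(met$f1 >= 0 & met$f1 <= 1), info = cand)
    # strong separable signal: everything should beat coin flipping
    expect_gt(met$f1[met$subset == "full_test"], 0.6)
  }
})

test_that("the label-shuffled baseline sits at chance and leaves test labels alone", {
  fx <- separable_profiles(n = 200, seed = 11)
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = 11)
  accs <- vapply(1:15, function(i) {
    b <- shuffled_label_baseline("tree_ensemble", data, split, seed = i)
    # audit: the shuffled copy never touches test labels
    expect_identical(b$model$parts$test$y,
                     data$y[match(split$test, data$ids)])
    b$metrics$accuracy[b$metrics$subset == "full_test_balanced"]
  }, numeric(1))
  expect_gt(median(accs), 0.35)
  expect_lt(median(accs), 0.65)
  b1 <- shuffled_label_baseline("tree_ensemble", data, split, seed = 5)
  b2 <- shuffled_label_baseline("tree_ensemble", data, split, seed = 5)
  expect_equal(b1$metrics, b2$metrics)
})

test_that("per-language evaluation flags absent languages", {
  fx <- separable_profiles(n = 120, seed = 13)
  data <- classification_data(fx$profiles, fx$subjects)
  split <- make_split(fx$subjects, seed = 13)
  m <- tune_and_train("ridge", data, split, data.frame(lambda = 0.1),
                      seed = 13)
  met <- evaluate_per_language(m, languages = c("English", "Chinese"))
  expect_false(met$absent[met$subset == "English"])
  expect_true(met$absent[met$subset == "Chinese"])
  expect_true(is.na(met$f1[met$subset == "Chinese"]))
})

test_that("compare_models evaluates every candidate on the identical split", {
  fx <- separable_profiles(n = 150, seed = 17)
  grids <- lapply(default_grids(), function(g) g[1, , drop = FALSE])
  cmp <- compare_models(fx$profiles, fx$subjects,
                        candidates = c("ridge", "knn", "tree_ensemble"),
                        grids = grids, seed = 17)
  expect_setequal(unique(cmp$metrics$candidate),
                  c("ridge", "knn", "tree_ensemble"))
  for (m in cmp$models) {
    expect_identical(m$split$test, cmp$split$test)
    audit_no_leakage(m)
  }
  g <- glance(cmp)
  expect_equal(nrow(g), 3)
  td <- tidy(cmp)
  expect_true(all(c("candidate", "subset", "f1") %in% names(td)))
})
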