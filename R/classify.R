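#' Stratified train/validation/test split
#'
#' Splits subjects 70/30 into training and hold-out test sets, then sets
#' aside 20% of the training set for hyperparameter validation, with both
#' splits stratified by outcome group crossed with language so that every
#' (group, language) stratum keeps its proportions within rounding.
#'
#' @param subjects Subject tibble with `subject_id`, `group`, `language`.
#' @param seed Seed.
#' @param test_frac,val_of_train Split fractions; defaults 0.30 and 0.20.
#' @return List with class `dct_split`: character vectors `train` (all
#'   training ids), `fit` (training minus validation), `val`, `test`, and
#'   a tibble `assignment`.
#' @export
make_split <- function(subjects, seed = 1L, test_frac = 0.30,
                       val_of_train = 0.20) {
  assert_cols(subjects, c("subject_id", "group", "language"), "subjects")
  key <- paste(subjects$group, subjects$language, sep = ".")
  wanted <- as.vector(outer(unique(as.character(subjects$group)),
                            unique(subjects$language), paste, sep = "."))
  empty <- setdiff(wanted, unique(key))
  if (length(empty)) {
    abort(sprintf("make_split: empty stratum %s", empty[1]))
  }
  strata <- split(subjects$subject_id, key)
  with_seed(child_seed(seed, "split"), {
    parts <- lapply(strata, function(ids) {
      n <- length(ids)
      ids <- sample(ids)
      n_test <- round(test_frac * n)
      test <- ids[seq_len(n_test)] %theni% character()
      train <- setdiff(ids, test)
      n_val <- round(val_of_train * length(train))
      val <- train[seq_len(n_val)] %theni% character()
      list(test = test, train = train, val = val,
           fit = setdiff(train, val))
    })
  })
  out <- list(
    train = unlist(lapply(parts, `[[`, "train"), use.names = FALSE),
    fit = unlist(lapply(parts, `[[`, "fit"), use.names = FALSE),
    val = unlist(lapply(parts, `[[`, "val"), use.names = FALSE),
    test = unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  out$assignment <- tibble::tibble(
    subject_id = c(out$fit, out$val, out$test),
    partition = rep(c("fit", "val", "test"),
                    c(length(out$fit), length(out$val), length(out$test))))
  structure(out, class = "dct_split")
}

#' Downsample the majority class to balance prevalence
#'
#' Removes randomly chosen majority-class subjects until both classes
#' have equal counts, leaving the minority class untouched. On a balanced
#' set a majority-class (or random) classifier has chance accuracy 0.5.
#'
#' @param ids Character vector of subject ids.
#' @param groups Factor/vector of group labels aligned with `ids`.
#' @param seed Seed.
#' @return Subset of `ids` with equal class counts.
#' @export
balance_by_downsampling <- function(ids, groups, seed = 1L) {
  stopifnot(length(ids) == length(groups))
  tab <- table(as.character(groups))
  if (length(tab) < 2 || any(tab == 0)) {
    abort("balance_by_downsampling: both classes must be present")
  }
  n_min <- min(tab)
  with_seed(child_seed(seed, "downsample"), {
    keep <- unlist(lapply(names(tab), function(g) {
      g_ids <- ids[groups == g]
      if (length(g_ids) > n_min) sample(g_ids, n_min) else g_ids
    }), use.names = FALSE)
  })
  ids[ids %in% keep]
}

#' Assemble a classification dataset from profiles and subjects
#'
#' @param profiles Semantic-profile tibble (raw scale; scaling happens
#'   per split inside the pipeline).
#' @param subjects Subject tibble.
#' @return List: predictor matrix `x` (rows named by subject), 0/1
#'   outcome `y`, `language`, `ids`.
#' @export
classification_data <- function(profiles, subjects) {
  ids <- intersect(profiles$subject_id, subjects$subject_id)
  profiles <- profiles[match(ids, profiles$subject_id), ]
  subj <- subjects[match(ids, subjects$subject_id), ]
  list(x = profile_matrix(profiles), y = group_code(subj$group),
       language = subj$language, ids = ids)
}

#' The five classifier candidates
#' @return Character vector of candidate names.
#' @export
classifier_candidates <- function() {
  c("ridge", "knn", "tree_ensemble", "nn2", "nn3")
}

#' Default hyperparameter grids
#'
#' One tibble of configurations per candidate: penalty strength for the
#' ridge model; neighbor count, leaf size and weighting for k-NN;
#' boosting rounds, learning rate, tree depth and both regularization
#' strengths (L2 `alpha`-style ridge and L1 lasso) for the tree ensemble;
#' batch size and epoch count for the two networks (hidden widths fixed
#' at 128/64 and 128/64/32).
#'
#' @return Named list of data frames.
#' @export
default_grids <- function() {
  list(
    ridge = expand.grid(lambda = c(0.01, 0.1, 1)),
    ridge_ls = expand.grid(lambda = c(0.01, 0.1, 1)),
    knn = expand.grid(k = c(5, 15, 25), leaf_size = 30,
                      weights = c("uniform", "distance"),
                      stringsAsFactors = FALSE),
    tree_ensemble = expand.grid(nrounds = c(20, 50), eta = c(0.1, 0.3),
                                max_depth = c(3, 6), alpha = 0.01,
                                lambda = c(0.001, 1)),
    nn2 = expand.grid(batch_size = c(32, 64), epochs = c(30, 60)),
    nn3 = expand.grid(batch_size = c(32, 64), epochs = c(30, 60)))
}

knn_predict <- function(train_x, train_y, test_x, k, weights = "uniform") {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * test_x %*% t(train_x)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(k)]
    if (weights == "distance") {
      w <- 1 / pmax(sqrt(row[nb]), 1e-12)
      sum(w * train_y[nb]) / sum(w)
    } else {
      mean(train_y[nb])
    }
  })
}

fit_candidate <- function(candidate, x, y, params, seed = 1L) {
  fit <- switch(
    candidate,
    ridge = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                           lambda = params$lambda),
    ridge_ls = glmnet::glmnet(x, y, family = "gaussian", alpha = 0,
                              lambda = params$lambda),
    knn = list(x = x, y = y, k = params$k,
               weights = params$weights %||% "uniform"),
    tree_ensemble = {
      dm <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta, max_depth = params$max_depth,
                      alpha = params$alpha %||% 0,
                      lambda = params$lambda %||% 1,
                      nthread = 1, seed = seed),
        data = dm, nrounds = params$nrounds, verbose = 0)
    },
    nn2 = mlp_fit(x, y, hidden = c(128, 64), task = "binary",
                  epochs = params$epochs, batch_size = params$batch_size,
                  seed = seed),
    nn3 = mlp_fit(x, y, hidden = c(128, 64, 32), task = "binary",
                  epochs = params$epochs, batch_size = params$batch_size,
                  seed = seed),
    abort(sprintf("unknown candidate '%s'", candidate)))
  structure(list(candidate = candidate, fit = fit, params = params),
            class = "dct_classifier")
}

#' Predicted probability of depression
#'
#' @param object A fitted `dct_classifier`.
#' @param newdata Predictor matrix.
#' @param ... Unused.
#' @return Probability vector (for the least-squares ridge variant, the
#'   clipped linear score).
#' @export
predict.dct_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  switch(
    object$candidate,
    ridge = as.vector(predict(object$fit, x, type = "response")),
    ridge_ls = pmin(pmax(as.vector(predict(object$fit, x)), 0), 1),
    knn = knn_predict(object$fit$x, object$fit$y, x, object$fit$k,
                      object$fit$weights),
    tree_ensemble = predict(object$fit, xgboost::xgb.DMatrix(x)),
    nn2 = predict(object$fit, x),
    nn3 = predict(object$fit, x))
}

#' Classification metrics from labels and scores
#'
#' Computes accuracy, precision, recall, F1 (positive class = depression)
#' and ROC-AUC from an independent confusion-matrix tally; AUC comes from
#' the trapezoidal ROC (pROC). Degenerate cases (single-class truth)
#' yield NA AUC rather than an error.
#'
#' @param truth 0/1 vector of true groups.
#' @param prob Predicted depression probabilities.
#' @param threshold Classification threshold, default 0.5.
#' @param subset Label for the evaluation subset.
#' @return One-row tibble: subset, n, f1, roc_auc, precision, recall,
#'   accuracy.
#' @export
eval_metrics <- function(truth, prob, threshold = 0.5, subset = "full") {
  stopifnot(length(truth) == length(prob))
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- if (length(unique(truth)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  tibble::tibble(subset = subset, n = length(truth), f1 = f1, roc_auc = auc,
                 precision = precision, recall = recall,
                 accuracy = (tp + tn) / length(truth))
}

prepare_pipeline_data <- function(data, split, seed,
                                  downsample = c("train_only", "before_split")) {
  downsample <- match.arg(downsample)
  pick <- function(ids) {
    i <- match(ids, data$ids)
    list(x = data$x[i, , drop = FALSE], y = data$y[i],
         language = data$language[i], ids = ids)
  }
  if (downsample == "before_split") {
    keep <- balance_by_downsampling(data$ids, data$y, child_seed(seed, "pre"))
    split <- lapply(split[c("train", "fit", "val", "test")],
                    function(ids) intersect(ids, keep))
  }
  fit_ids <- balance_by_downsampling(
    split$fit, data$y[match(split$fit, data$ids)], child_seed(seed, "fit"))
  val_ids <- if (length(split$val)) {
    balance_by_downsampling(split$val, data$y[match(split$val, data$ids)],
                            child_seed(seed, "val"))
  } else character()
  train_ids <- balance_by_downsampling(
    split$train, data$y[match(split$train, data$ids)],
    child_seed(seed, "train"))
  test_bal_ids <- balance_by_downsampling(
    split$test, data$y[match(split$test, data$ids)], child_seed(seed, "test"))

  train <- pick(train_ids)
  mu <- colMeans(train$x)
  sdv <- apply(train$x, 2, sd)
  sdv[is.na(sdv) | sdv == 0] <- 1
  zs <- function(part) {
    part$x <- sweep(sweep(part$x, 2, mu, "-"), 2, sdv, "/")
    part
  }
  list(fit = zs(pick(fit_ids)), val = zs(pick(val_ids)), train = zs(train),
       test = zs(pick(split$test)), test_balanced = zs(pick(test_bal_ids)),
       scaling = list(mean = mu, sd = sdv))
}

#' Tune hyperparameters and train a candidate
#'
#' Grid search: each configuration is fit on the balanced fit partition
#' and scored on the validation partition; the configuration maximizing
#' validation F1 (earliest grid row on ties) is refit on the full
#' balanced training set. Profiles are z-scored with training-set
#' statistics throughout, so no test information enters fitting.
#'
#' @param candidate Candidate name; see [classifier_candidates()].
#' @param data From [classification_data()].
#' @param split A [make_split()].
#' @param grid Data frame of configurations; default from
#'   [default_grids()].
#' @param seed Seed.
#' @param tune_metric `"f1"` (default) or `"roc_auc"`.
#' @param downsample Balance the training partition only (default) or
#'   the whole sample before splitting.
#' @return List with class `dct_model`: the fitted classifier, chosen
#'   `params`, `val_scores` tibble, `scaling` statistics, and the
#'   prepared evaluation partitions.
#' @export
tune_and_train <- function(candidate, data, split, grid = NULL, seed = 1L,
                           tune_metric = c("f1", "roc_auc"),
                           downsample = "train_only") {
  tune_metric <- match.arg(tune_metric)
  grid <- grid %||% default_grids()[[candidate]]
  stopifnot(nrow(grid) >= 1)
  parts <- prepare_pipeline_data(data, split, seed, downsample)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    if (!length(parts$val$ids)) return(0)
    f <- fit_candidate(candidate, parts$fit$x, parts$fit$y, params,
                       seed = child_seed(seed, paste0("tune", i)))
    prob <- predict(f, parts$val$x)
    if (any(!is.finite(prob))) abort("non-finite validation score")
    m <- eval_metrics(parts$val$y, prob)
    v <- m[[tune_metric]]
    if (is.na(v)) 0 else v
  }, numeric(1))
  best <- which.max(scores)  # earliest max wins ties
  params <- as.list(grid[best, , drop = FALSE])
  final <- fit_candidate(candidate, parts$train$x, parts$train$y, params,
                         seed = child_seed(seed, "final"))
  structure(list(candidate = candidate, classifier = final, params = params,
                 val_scores = dplyr::bind_cols(tibble::as_tibble(grid),
                                               tibble::tibble(score = scores)),
                 scaling = parts$scaling, parts = parts, split = split,
                 seed = seed),
            class = "dct_model")
}

#' @export
print.dct_model <- function(x, ...) {
  cat(sprintf("DCT classifier: %s\n", x$candidate))
  cat("  chosen:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a tuned model on the test set and per language
#'
#' Reports metrics on the full hold-out test set (raw and class-balanced
#' views) and on each language-specific subset. Languages absent from the
#' test set yield a flagged-absent row (NA metrics) rather than a
#' fabricated one.
#'
#' @param model A `dct_model` from [tune_and_train()].
#' @param languages Languages to evaluate; default all present in the
#'   model's data.
#' @return Tibble of [eval_metrics()] rows with an `absent` flag.
#' @export
evaluate_per_language <- function(model, languages = NULL) {
  test <- model$parts$test
  prob <- predict(model$classifier, test$x)
  rows <- list(eval_metrics(test$y, prob, subset = "full_test"))
  bal <- model$parts$test_balanced
  rows <- c(rows, list(eval_metrics(bal$y, predict(model$classifier, bal$x),
                                    subset = "full_test_balanced")))
  languages <- languages %||% sort(unique(test$language))
  for (lang in languages) {
    sel <- test$language == lang
    if (!any(sel)) {
      rows <- c(rows, list(tibble::tibble(subset = lang, n = 0L,
                                          f1 = NA_real_, roc_auc = NA_real_,
                                          precision = NA_real_,
                                          recall = NA_real_,
                                          accuracy = NA_real_)))
    } else {
      rows <- c(rows, list(eval_metrics(test$y[sel], prob[sel], subset = lang)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$absent <- out$n == 0L
  out
}

#' Label-shuffled baseline
#'
#' Runs the identical pipeline after permuting the outcome labels within
#' the training data only (fit, validation and refit all see shuffled
#' labels; test labels are untouched), yielding an empirical null for
#' classification performance.
#'
#' @param candidate Candidate name.
#' @param data,split,grid,seed As in [tune_and_train()].
#' @param tune If `FALSE` (default) the singleton first grid row is used,
#'   which keeps repeated null draws cheap; `TRUE` reruns the full grid
#'   search on the shuffled labels.
#' @return List: `model` (a `dct_model`) and `metrics` (test and balanced
#'   test rows from [evaluate_per_language()]).
#' @export
shuffled_label_baseline <- function(candidate, data, split, grid = NULL,
                                    seed = 1L, tune = FALSE) {
  grid <- grid %||% default_grids()[[candidate]]
  if (!tune) grid <- grid[1, , drop = FALSE]
  shuffled <- data
  train_idx <- match(split$train, data$ids)
  with_seed(child_seed(seed, "shuffle"), {
    shuffled$y[train_idx] <- sample(shuffled$y[train_idx])
  })
  model <- tune_and_train(candidate, shuffled, split, grid, seed)
  metrics <- evaluate_per_language(model, languages = character())
  list(model = model, metrics = metrics)
}

#' Audit a split and pipeline for test-set leakage
#'
#' Asserts that the fit/val/test partitions are disjoint, that together
#' with `fit`+`val` = `train`, and that the model's scaling statistics
#' and balanced fitting ids never include test subjects.
#'
#' @param model A `dct_model`.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
audit_no_leakage <- function(model) {
  s <- model$split
  if (length(intersect(s$train, s$test))) abort("train and test overlap")
  if (length(intersect(s$fit, s$val))) abort("fit and val overlap")
  if (!setequal(union(s$fit, s$val), s$train)) abort("fit+val != train")
  if (length(intersect(model$parts$train$ids, s$test))) {
    abort("test ids entered the fitting set")
  }
  invisible(TRUE)
}

#' Compare the five classifier candidates on one split
#'
#' Tunes and trains every candidate on the identical stratified split and
#' evaluates each on the identical hold-out test set.
#'
#' @param profiles Raw semantic-profile tibble.
#' @param subjects Subject tibble.
#' @param candidates Candidate names; default all five.
#' @param grids Named list of grids; default [default_grids()].
#' @param seed Seed.
#' @return List with class `dct_comparison`: `models` (named list) and
#'   `metrics` (tibble, one row per candidate x subset).
#' @export
compare_models <- function(profiles, subjects,
                           candidates = classifier_candidates(),
                           grids = default_grids(), seed = 1L) {
  data <- classification_data(profiles, subjects)
  subj <- subjects[match(data$ids, subjects$subject_id), ]
  split <- make_split(subj, seed = seed)
  models <- list()
  metrics <- list()
  for (cand in candidates) {
    m <- tune_and_train(cand, data, split, grids[[cand]],
                        seed = child_seed(seed, cand))
    train_prob <- predict(m$classifier, m$parts$train$x)
    met <- dplyr::bind_rows(
      eval_metrics(m$parts$train$y, train_prob, subset = "full_train"),
      evaluate_per_language(m))
    met$candidate <- cand
    models[[cand]] <- m
    metrics[[cand]] <- met
  }
  structure(list(models = models,
                 metrics = dplyr::bind_rows(metrics), split = split,
                 seed = seed),
            class = "dct_comparison")
}
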