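#' Per-feature Shapley effects of a fitted tree ensemble
#'
#' Computes exact per-sample tree-path attributions (TreeSHAP, via the
#' boosted-tree backend) on the hold-out test profiles. The headline
#' summary `mean_shap` is the signed mean attribution among samples
#' scoring above the feature's median, which is exactly the directional
#' reading of effect plots: positive means that *higher* scores on the
#' feature (relatively more proximal choices on items high in it) push
#' predictions toward depression. The unconditioned signed mean over all
#' samples (`mean_shap_all`) is also emitted, but note that for a
#' discriminative feature it mostly reflects the class mix of the
#' evaluation set -- on an imbalanced test set the majority class's
#' negative attributions dominate it even when high scores clearly
#' indicate depression -- so it is not the directional summary. The mean
#' absolute attribution serves as unsigned importance.
#'
#' @param model A `dct_model` whose candidate is `tree_ensemble` (the
#'   attributions are exact for trees; other candidates fail).
#' @param x Optional predictor matrix (scaled as the model expects);
#'   default the model's test partition.
#' @return Tibble with class `dct_effects`: `feature`, `mean_shap`,
#'   `mean_shap_all`, `mean_abs_shap`, `sign`; attribute `shap` holds the
#'   per-sample matrix (with bias column) for additivity checks.
#' @export
compute_feature_effects <- function(model, x = NULL) {
  stopifnot(inherits(model, "dct_model"))
  if (model$candidate != "tree_ensemble") {
    abort("feature effects are defined for the tree-ensemble model only")
  }
  x <- x %||% model$parts$test$x
  if (!nrow(x)) abort("compute_feature_effects: empty test set")
  x <- as.matrix(x)
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- predict(model$classifier$fit, dm, predcontrib = TRUE)
  feat_cols <- setdiff(colnames(contrib), c("(Intercept)", "BIAS"))
  shap_f <- contrib[, feat_cols, drop = FALSE]
  high_mean <- vapply(feat_cols, function(f) {
    hi <- x[, f] > median(x[, f])
    if (!any(hi)) return(mean(shap_f[, f]))  # constant feature
    mean(shap_f[hi, f])
  }, numeric(1))
  out <- tibble::tibble(
    feature = feat_cols,
    mean_shap = unname(high_mean),
    mean_shap_all = unname(colMeans(shap_f)),
    mean_abs_shap = unname(colMeans(abs(shap_f))),
    sign = sign(unname(high_mean)))
  attr(out, "shap") <- contrib
  class(out) <- c("dct_effects", class(out))
  out
}

#' Bootstrapped robustness test
#'
#' Re-runs the classification pipeline `n_runs` times, each run redrawing
#' the stratified 70/30 train/test split (no case resampling), rebalancing
#' by downsampling, retraining the tuned configuration, evaluating on the
#' new test set, and recording per-feature signed mean Shapley effects.
#' Failed runs are recorded with their error, never silently dropped.
#'
#' @param profiles,subjects Study tables (profiles raw).
#' @param params Tuned tree-ensemble configuration (named list); default
#'   the first row of the default grid.
#' @param n_runs Number of bootstrap runs (>= 2).
#' @param seed Master seed; each run's child seed is recorded.
#' @param candidate Candidate to retrain; effects are recorded only for
#'   `tree_ensemble`.
#' @param scope Label stored with the result (e.g. "crosslinguistic" or a
#'   language name).
#' @return List with class `dct_bootstrap`: `summary` (one row per run:
#'   seed, f1 and roc_auc on the raw test set, f1 and accuracy on the
#'   class-balanced test view, status), `effects` (long tibble run x
#'   feature), `scope`, `n_runs`.
#' @export
bootstrap_run <- function(profiles, subjects, params = NULL, n_runs = 100,
                          seed = 1L, candidate = "tree_ensemble",
                          scope = "crosslinguistic") {
  stopifnot(n_runs >= 2)
  params <- params %||% as.list(default_grids()[[candidate]][1, , drop = FALSE])
  data <- classification_data(profiles, subjects)
  subj <- subjects[match(data$ids, subjects$subject_id), ]
  grid <- as.data.frame(params)
  rows <- vector("list", n_runs)
  effs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- child_seed(seed, paste0("boot", r))
    res <- tryCatch({
      split <- make_split(subj, seed = run_seed)
      m <- tune_and_train(candidate, data, split, grid, seed = run_seed)
      met <- evaluate_per_language(m, languages = character())
      bal <- met[met$subset == "full_test_balanced", ]
      raw <- met[met$subset == "full_test", ]
      e <- if (candidate == "tree_ensemble") {
        fe <- compute_feature_effects(m)
        tibble::tibble(run = r, feature = fe$feature,
                       mean_shap = fe$mean_shap)
      } else NULL
      list(row = tibble::tibble(run = r, seed = run_seed, f1 = raw$f1,
                                roc_auc = raw$roc_auc,
                                f1_balanced = bal$f1,
                                accuracy_balanced = bal$accuracy,
                                status = "ok", error = NA_character_),
           eff = e)
    }, error = function(e) {
      list(row = tibble::tibble(run = r, seed = run_seed, f1 = NA_real_,
                                roc_auc = NA_real_, f1_balanced = NA_real_,
                                accuracy_balanced = NA_real_,
                                status = "failed",
                                error = conditionMessage(e)),
           eff = NULL)
    })
    rows[[r]] <- res$row
    effs[[r]] <- res$eff
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 effects = dplyr::bind_rows(effs),
                 scope = scope, n_runs = n_runs, seed = seed,
                 params = params),
            class = "dct_bootstrap")
}

#' Aggregate bootstrapped feature effects
#'
#' @param boot A `dct_bootstrap`.
#' @return Tibble with class `dct_effects`: per feature the mean, median,
#'   SD and central 95% interval of the signed mean Shapley values across
#'   runs, plus the sign of the mean.
#' @export
summarize_effects <- function(boot) {
  stopifnot(inherits(boot, "dct_bootstrap"))
  out <- boot$effects |>
    dplyr::group_by(.data$feature) |>
    # mean_shap is assigned last: naming it first would shadow the input
    # column for the quantile summaries
    dplyr::summarise(median_shap = median(.data$mean_shap),
                     sd_shap = sd(.data$mean_shap),
                     q2.5 = unname(quantile(.data$mean_shap, 0.025)),
                     q97.5 = unname(quantile(.data$mean_shap, 0.975)),
                     mean_shap = mean(.data$mean_shap),
                     .groups = "drop") |>
    dplyr::mutate(sign = sign(.data$mean_shap), scope = boot$scope) |>
    dplyr::relocate("feature", "mean_shap")
  class(out) <- c("dct_effects", class(out))
  out
}

#' Rank correlation between two feature-effect tables
#'
#' Spearman (default) or Kendall correlation of the per-feature signed
#' mean Shapley effects of two model scopes, joined by feature name.
#' Zero-variance ranks make the coefficient undefined; NA is returned.
#'
#' @param table_a,table_b Tibbles with `feature` and `mean_shap`.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return A single correlation (or NA).
#' @export
correlate_effects <- function(table_a, table_b, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  merged <- dplyr::inner_join(
    table_a[c("feature", "mean_shap")], table_b[c("feature", "mean_shap")],
    by = "feature", suffix = c("_a", "_b"))
  if (nrow(merged) != nrow(table_a) || nrow(merged) != nrow(table_b)) {
    abort("effect tables do not share the same feature set")
  }
  if (sd(merged$mean_shap_a) == 0 || sd(merged$mean_shap_b) == 0) {
    return(NA_real_)
  }
  stats::cor(merged$mean_shap_a, merged$mean_shap_b, method = method)
}

#' Pairwise rank-correlation matrix across model scopes
#'
#' @param effect_tables Named list of effect tables (one per scope).
#' @param method Passed to [correlate_effects()].
#' @return Symmetric matrix with unit diagonal (NA where undefined).
#' @export
effects_correlation_matrix <- function(effect_tables,
                                       method = "spearman") {
  k <- length(effect_tables)
  stopifnot(k >= 2, !is.null(names(effect_tables)))
  out <- matrix(NA_real_, k, k,
                dimnames = list(names(effect_tables), names(effect_tables)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- if (i == j) 1 else
        correlate_effects(effect_tables[[i]], effect_tables[[j]], method)
    }
  }
  out
}

#' Hierarchically cluster features across model scopes
#'
#' Builds the scopes-by-features matrix of signed mean effects and
#' clusters the features agglomeratively (average linkage on Euclidean
#' distances), giving the deterministic leaf order used for effect
#' heatmaps.
#'
#' @param effect_tables Named list (length >= 2) of effect tables.
#' @return List with class `dct_feature_clustering`: `order` (feature
#'   names in leaf order), `hclust` (the tree, NULL for a single
#'   feature), `matrix` (scopes x features, leaf-ordered).
#' @export
cluster_features <- function(effect_tables) {
  stopifnot(length(effect_tables) >= 2)
  feats <- effect_tables[[1]]$feature
  m <- vapply(effect_tables, function(tb) {
    tb$mean_shap[match(feats, tb$feature)]
  }, numeric(length(feats)))
  m <- matrix(m, nrow = length(feats),
              dimnames = list(feats, names(effect_tables)))
  m <- t(m)  # scopes x features
  if (length(feats) == 1) {
    return(structure(list(order = feats, hclust = NULL, matrix = m),
                     class = "dct_feature_clustering"))
  }
  hc <- stats::hclust(stats::dist(t(m)), method = "average")
  structure(list(order = feats[hc$order], hclust = hc,
                 matrix = m[, hc$order, drop = FALSE]),
            class = "dct_feature_clustering")
}
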