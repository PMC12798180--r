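#' Plot classifier comparison metrics
#'
#' Test-set F1 and ROC-AUC per candidate as bars, with training-set
#' values overlaid as horizontal ticks (the gap reads as overfitting).
#'
#' @param comparison A `dct_comparison`.
#' @return A ggplot.
#' @export
plot_model_comparison <- function(comparison) {
  met <- comparison$metrics |>
    dplyr::filter(.data$subset %in% c("full_train", "full_test")) |>
    tidyr::pivot_longer(c("f1", "roc_auc"), names_to = "metric")
  ggplot2::ggplot(met, ggplot2::aes(x = .data$candidate, y = .data$value)) +
    ggplot2::geom_col(data = ~dplyr::filter(.x, .data$subset == "full_test"),
                      ggplot2::aes(fill = .data$candidate), width = 0.7,
                      show.legend = FALSE) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$subset == "full_train"),
                        shape = 95, size = 8) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Hold-out performance (bars) vs training (ticks)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot signed per-feature Shapley effects
#'
#' @param effects A `dct_effects` tibble (single fit or bootstrap
#'   summary); bootstrap summaries show the central 95% interval.
#' @param top_n Number of features by absolute effect. Default 20.
#' @return A ggplot.
#' @export
plot_feature_effects <- function(effects, top_n = 20) {
  eff <- effects |>
    dplyr::arrange(dplyr::desc(abs(.data$mean_shap))) |>
    utils::head(top_n) |>
    dplyr::mutate(feature = stats::reorder(.data$feature, .data$mean_shap),
                  direction = ifelse(.data$mean_shap > 0,
                                     "toward depression", "toward control"))
  p <- ggplot2::ggplot(eff, ggplot2::aes(x = .data$mean_shap,
                                         y = .data$feature,
                                         fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean SHAP value", y = NULL, fill = NULL,
                  title = "Semantic feature effects") +
    ggplot2::theme_minimal()
  if (all(c("q2.5", "q97.5") %in% names(effects))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$q2.5, xmax = .data$q97.5), height = 0.3)
  }
  p
}

#' Plot the bootstrap F1 distribution
#'
#' @param boot A `dct_bootstrap` (or list of them for several scopes).
#' @return A ggplot with the chance level marked.
#' @export
plot_bootstrap <- function(boot) {
  if (inherits(boot, "dct_bootstrap")) boot <- list(boot)
  df <- purrr::map_dfr(boot, function(b) {
    dplyr::mutate(b$summary[b$summary$status == "ok", ], scope = b$scope)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$f1)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "red") +
    ggplot2::labs(x = NULL, y = "F1 across bootstraps",
                  title = "Bootstrapped robustness") +
    ggplot2::theme_minimal()
}

#' Heatmap of clustered feature effects across scopes
#'
#' @param clustering A `dct_feature_clustering` from [cluster_features()].
#' @return A ggplot tile map, features in leaf order.
#' @export
plot_effect_heatmap <- function(clustering) {
  m <- clustering$matrix
  df <- tibble::tibble(
    scope = rep(rownames(m), times = ncol(m)),
    feature = factor(rep(colnames(m), each = nrow(m)),
                     levels = clustering$order),
    effect = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$scope,
                                   fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkorange", mid = "white",
                                  high = "darkgreen", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean SHAP") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' @export
autoplot.dct_comparison <- function(object, ...) plot_model_comparison(object)

#' @export
autoplot.dct_effects <- function(object, ...) plot_feature_effects(object, ...)

#' @export
autoplot.dct_bootstrap <- function(object, ...) plot_bootstrap(object)

#' @export
autoplot.dct_feature_clustering <- function(object, ...) {
  plot_effect_heatmap(object)
}
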