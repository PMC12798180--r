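#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model comparison
#' @param x A `dct_comparison`.
#' @param ... Unused.
#' @return Tibble, one row per candidate x evaluation subset.
#' @export
tidy.dct_comparison <- function(x, ...) {
  dplyr::relocate(x$metrics, "candidate")
}

#' One-row-per-candidate summary of a model comparison
#' @param x A `dct_comparison`.
#' @param ... Unused.
#' @return Tibble: candidate, chosen hyperparameters (collapsed), test F1
#'   and ROC-AUC.
#' @export
glance.dct_comparison <- function(x, ...) {
  test <- x$metrics[x$metrics$subset == "full_test", ]
  params <- vapply(x$models, function(m) {
    paste(names(m$params), unlist(m$params), sep = "=", collapse = ", ")
  }, character(1))
  tibble::tibble(candidate = test$candidate,
                 params = unname(params[test$candidate]),
                 f1 = test$f1, roc_auc = test$roc_auc)
}

#' Tidy a bootstrap robustness run
#' @param x A `dct_bootstrap`.
#' @param ... Unused.
#' @return The per-run summary tibble.
#' @export
tidy.dct_bootstrap <- function(x, ...) x$summary

#' Summarize a bootstrap robustness run
#' @param x A `dct_bootstrap`.
#' @param ... Unused.
#' @return One-row tibble: scope, runs, failures, median/SD F1, central
#'   95% F1 interval.
#' @export
glance.dct_bootstrap <- function(x, ...) {
  ok <- x$summary[x$summary$status == "ok", ]
  tibble::tibble(scope = x$scope, n_runs = x$n_runs,
                 n_failed = sum(x$summary$status != "ok"),
                 median_f1 = median(ok$f1), sd_f1 = sd(ok$f1),
                 f1_q2.5 = quantile(ok$f1, 0.025),
                 f1_q97.5 = quantile(ok$f1, 0.975))
}

#' Tidy a replication-arm fit
#' @param x A `dct_replication`.
#' @param ... Unused.
#' @return Per-variant bootstrap accuracy summary tibble.
#' @export
tidy.dct_replication <- function(x, ...) x$metrics

#' One-row summary of the replication arm
#' @param x A `dct_replication`.
#' @param ... Unused.
#' @return Tibble with one column per variant's mean accuracy.
#' @export
glance.dct_replication <- function(x, ...) {
  wide <- setNames(as.list(x$metrics$mean_accuracy), x$metrics$variant)
  dplyr::bind_cols(tibble::tibble(n_boot = x$n_boot), tibble::as_tibble(wide))
}

#' Tidy a response-matrix PCA
#' @param x A `dct_pca`.
#' @param ... Unused.
#' @return Tibble: component, explained variance ratio, cumulative.
#' @export
tidy.dct_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 explained_variance = x$explained_variance,
                 cumulative = cumsum(x$explained_variance))
}
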