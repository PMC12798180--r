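#' Principal components of the raw word-level response matrix
#'
#' Centered PCA of the subjects-by-words coded response matrix, retaining
#' either a fixed number of components or the smallest number reaching a
#' cumulative explained-variance target (default 90%). Reduces the
#' dimensionality and multicollinearity of the 290 word-level predictors
#' before logistic classification.
#'
#' @param responses Wide response tibble from [recode_responses()].
#' @param n_components Fixed component count, or `NULL` (default) to use
#'   the variance target.
#' @param variance Cumulative explained-variance target in (0, 1].
#' @return List with class `dct_pca`: `loadings` (words x components,
#'   orthonormal), `scores` (subjects x components), `explained_variance`
#'   (ratios, non-increasing), `center`, `n_components`, `words`,
#'   `subject_id`.
#' @export
fit_pca <- function(responses, n_components = NULL, variance = 0.9) {
  words <- setdiff(names(responses), "subject_id")
  x <- as.matrix(responses[words])
  if (nrow(x) < 2 || length(words) < 2) {
    abort("fit_pca: need at least 2 subjects and 2 words")
  }
  max_rank <- min(nrow(x), ncol(x))
  if (!is.null(n_components) && n_components > max_rank) {
    abort(sprintf("n_components (%d) exceeds matrix rank bound (%d)",
                  n_components, max_rank))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- n_components %||% max(1L, which(cumsum(evr) >= variance)[1])
  if (is.na(k)) k <- length(evr)
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance = evr[seq_len(k)],
                 explained_variance_all = evr,
                 center = pc$center, n_components = as.integer(k),
                 words = words, subject_id = responses$subject_id),
            class = "dct_pca")
}

#' @export
print.dct_pca <- function(x, ...) {
  cat(sprintf("PCA of DCT responses: %d subjects x %d words, %d components (%.1f%% variance)\n",
              length(x$subject_id), length(x$words), x$n_components,
              100 * sum(x$explained_variance)))
  invisible(x)
}

replication_variants <- function() {
  c("mDCT", "mDCT+GenderAge", "mGenderAge", "mRandomBaseline")
}

variant_design <- function(variant, pc_x, age_z, gender_oh) {
  switch(variant,
         "mDCT" = pc_x,
         "mDCT+GenderAge" = cbind(pc_x, age_z = age_z, gender_oh),
         "mGenderAge" = cbind(age_z = age_z, gender_oh),
         "mRandomBaseline" = pc_x,
         abort(sprintf("unknown variant '%s'", variant)))
}

logistic_fit <- function(x, y) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("degenerate predictor column: %s",
                  colnames(x)[which(sds == 0)[1]]))
  }
  suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                   family = stats::binomial()))
}

logistic_prob <- function(fit, x) {
  as.vector(stats::plogis(cbind(1, x) %*% fit$coefficients))
}

#' Fit the four replication model variants with bootstrapped accuracy
#'
#' The replication arm of the analysis: logistic regression on principal
#' components of raw DCT responses (`mDCT`), on components plus gender
#' and age (`mDCT+GenderAge`), on gender and age alone (`mGenderAge`),
#' and on components with training labels shuffled (`mRandomBaseline`).
#' Each bootstrap redraws a stratified 70/30 split, downsamples the
#' training set to balance classes, fits each variant, and records
#' accuracy on the balanced test set; summaries are the bootstrap mean,
#' SD and central 95% interval. Gender enters one-hot with the largest
#' category as reference; age is z-scored with training statistics.
#'
#' @param pca A [fit_pca()] result.
#' @param subjects Subject tibble covering the PCA's subjects.
#' @param n_boot Number of bootstrap re-splits. Default 100.
#' @param seed Seed.
#' @return List with class `dct_replication`: `metrics` (per variant:
#'   mean/sd/ci of accuracy), `boot` (long tibble), `coefficients`
#'   (PC-space coefficients of the DCT variants fit on the canonical
#'   split), `pca`.
#' @export
fit_variants <- function(pca, subjects, n_boot = 100, seed = 1L) {
  stopifnot(inherits(pca, "dct_pca"))
  subj <- subjects[match(pca$subject_id, subjects$subject_id), ]
  if (anyNA(subj$subject_id)) abort("subjects table does not cover all PCA subjects")
  y <- group_code(subj$group)
  pc_x <- pca$scores
  colnames(pc_x) <- paste0("PC", seq_len(ncol(pc_x)))
  gender <- factor(subj$gender)
  ref <- names(sort(table(gender), decreasing = TRUE))[1]
  gender <- stats::relevel(gender, ref = ref)
  gl <- levels(gender)[-1]
  gender_oh <- vapply(gl, function(g) as.numeric(gender == g),
                      numeric(length(gender)))
  if (length(gl)) colnames(gender_oh) <- paste0("gender_", gl)

  run_one <- function(b) {
    run_seed <- child_seed(seed, paste0("rep", b))
    split <- make_split(subj, seed = run_seed)
    tr_ids <- balance_by_downsampling(
      split$train, y[match(split$train, subj$subject_id)],
      child_seed(run_seed, "train"))
    te_ids <- balance_by_downsampling(
      split$test, y[match(split$test, subj$subject_id)],
      child_seed(run_seed, "test"))
    tr <- match(tr_ids, subj$subject_id)
    te <- match(te_ids, subj$subject_id)
    mu <- mean(subj$age[tr]); s <- sd(subj$age[tr]); if (s == 0) s <- 1
    age_z <- (subj$age - mu) / s
    y_tr <- y[tr]
    y_sh <- with_seed(child_seed(run_seed, "shuffle"), sample(y_tr))
    purrr::map_dfr(replication_variants(), function(v) {
      x <- variant_design(v, pc_x, age_z, gender_oh)
      lab <- if (v == "mRandomBaseline") y_sh else y_tr
      fit <- logistic_fit(x[tr, , drop = FALSE], lab)
      prob <- logistic_prob(fit, x[te, , drop = FALSE])
      tibble::tibble(run = b, variant = v,
                     accuracy = mean((prob > 0.5) == y[te]))
    })
  }
  boot <- purrr::map_dfr(seq_len(n_boot), run_one)
  metrics <- boot |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = sd(.data$accuracy),
                     ci_low = quantile(.data$accuracy, 0.025),
                     ci_high = quantile(.data$accuracy, 0.975),
                     .groups = "drop")

  # canonical fit (seed-derived split) for coefficient back-projection
  split0 <- make_split(subj, seed = child_seed(seed, "canonical"))
  tr0_ids <- balance_by_downsampling(
    split0$train, y[match(split0$train, subj$subject_id)],
    child_seed(seed, "canonical_train"))
  tr0 <- match(tr0_ids, subj$subject_id)
  mu0 <- mean(subj$age[tr0]); s0 <- sd(subj$age[tr0]); if (s0 == 0) s0 <- 1
  age_z0 <- (subj$age - mu0) / s0
  coefs <- lapply(c("mDCT", "mDCT+GenderAge"), function(v) {
    x <- variant_design(v, pc_x, age_z0, gender_oh)
    fit <- logistic_fit(x[tr0, , drop = FALSE], y[tr0])
    fit$coefficients
  })
  names(coefs) <- c("mDCT", "mDCT+GenderAge")
  structure(list(metrics = metrics, boot = boot, coefficients = coefs,
                 pca = pca, seed = seed, n_boot = n_boot),
            class = "dct_replication")
}

#' Most predictive words by back-projected coefficients
#'
#' Projects PC-space logistic coefficients back into word space
#' (`loadings %*% beta`), so that each word carries a signed weight whose
#' inner product with a subject's centered responses reproduces the
#' PC-space linear predictor exactly. Returns the top-k words in each
#' direction.
#'
#' @param pca A `dct_pca`.
#' @param coefficients Named coefficient vector from a DCT variant fit
#'   (intercept plus PC terms; non-PC terms are ignored).
#' @param k Words per direction.
#' @return List: `toward_depression` and `toward_control` tibbles
#'   (word, weight) and the full `weights` tibble.
#' @export
top_predictive_words <- function(pca, coefficients, k = 10) {
  stopifnot(inherits(pca, "dct_pca"))
  if (k > length(pca$words)) {
    abort(sprintf("k (%d) exceeds vocabulary size (%d)", k, length(pca$words)))
  }
  pc_names <- paste0("PC", seq_len(pca$n_components))
  beta <- coefficients[pc_names]
  beta[is.na(beta)] <- 0
  w <- as.vector(pca$loadings %*% beta)
  weights <- tibble::tibble(word = pca$words, weight = w)
  up <- weights |> dplyr::arrange(dplyr::desc(.data$weight)) |>
    utils::head(k)
  down <- weights |> dplyr::arrange(.data$weight) |> utils::head(k)
  list(toward_depression = up, toward_control = down, weights = weights)
}
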