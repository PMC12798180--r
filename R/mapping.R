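#' Read word-embedding vectors from text
#'
#' Reads the common pretrained-vector text dialect: one word per line
#' followed by its whitespace-separated vector components.
#'
#' @param path File path.
#' @return Numeric matrix, one row per word (rownames = words).
#' @export
read_embeddings <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    abort("embedding file has inconsistent vector dimensionality")
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[1])))
  rownames(m) <- words
  m
}

#' Synthetic embedding/norm fixture with a planted linear map
#'
#' Generates seeded Gaussian word vectors and Binder-style norms that are
#' an exact (optionally noisy) linear function of the embeddings, so that
#' mapping-recovery tests have a closed-form truth.
#'
#' @param n_words Number of words.
#' @param dim Embedding dimensionality. Default 50.
#' @param noise_sd SD of additive noise on the norms. Default 0 (exact).
#' @param seed Seed.
#' @return List: `embeddings` (matrix), `norms` (tibble item_id + 65
#'   features), `true_map` (dim x 65 matrix), `intercept` (65-vector).
#' @export
generate_embedding_fixture <- function(n_words = 200, dim = 50,
                                       noise_sd = 0, seed = 1L) {
  feats <- binder_feature_names()
  with_seed(child_seed(seed, "embed_fixture"), {
    words <- sprintf("word%04d", seq_len(n_words))
    emb <- matrix(rnorm(n_words * dim), n_words, dim,
                  dimnames = list(words, paste0("d", seq_len(dim))))
    W <- matrix(rnorm(dim * 65, sd = 0.3), dim, 65)
    a <- rnorm(65, 3, 0.5)
    Y <- sweep(emb %*% W, 2, a, "+") +
      matrix(rnorm(n_words * 65, sd = noise_sd), n_words, 65)
    colnames(Y) <- feats
    norms <- dplyr::bind_cols(tibble::tibble(item_id = words),
                              tibble::as_tibble(as.data.frame(Y)))
    list(embeddings = emb, norms = norms, true_map = W, intercept = a)
  })
}

#' The default mapping-candidate roster
#' @return Character vector of six candidate names.
#' @export
mapping_candidates <- function() {
  c("linear", "ridge", "knn", "boosted_tree", "nn2", "nn3")
}

knn_reg_multi <- function(train_x, train_y, test_x, k) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * test_x %*% t(train_x)
  t(apply(d2, 1, function(row) {
    colMeans(train_y[order(row)[seq_len(k)], , drop = FALSE])
  }))
}

fit_map_one <- function(candidate, x, y, seed = 1L) {
  fit <- switch(
    candidate,
    linear = {
      X <- cbind(1, x)
      list(coef = qr.solve(X, y))
    },
    ridge = glmnet::glmnet(x, y, family = "mgaussian", alpha = 0,
                           lambda = 0.1),
    knn = list(x = x, y = y, k = 5),
    boosted_tree = lapply(seq_len(ncol(y)), function(j) {
      dm <- xgboost::xgb.DMatrix(x, label = y[, j])
      xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                       eta = 0.2, max_depth = 3,
                                       nthread = 1, seed = seed),
                         data = dm, nrounds = 40, verbose = 0)
    }),
    nn2 = mlp_fit(x, y, hidden = c(128, 64), task = "regression",
                  epochs = 200, batch_size = 32, lr = 3e-3, seed = seed),
    nn3 = mlp_fit(x, y, hidden = c(128, 64, 32), task = "regression",
                  epochs = 200, batch_size = 32, lr = 3e-3, seed = seed),
    abort(sprintf("unknown mapping candidate '%s'", candidate)))
  structure(list(candidate = candidate, fit = fit,
                 features = colnames(y)), class = "dct_mapping")
}

#' Predict norms from a fitted mapping
#' @param object A `dct_mapping`.
#' @param newdata Embedding matrix.
#' @param ... Unused.
#' @return Numeric matrix (words x 65).
#' @export
predict.dct_mapping <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  out <- switch(
    object$candidate,
    linear = cbind(1, x) %*% object$fit$coef,
    ridge = {
      p <- predict(object$fit, x)
      matrix(p, nrow(x), dim(p)[2], dimnames = list(NULL, dimnames(p)[[2]]))
    },
    knn = knn_reg_multi(object$fit$x, object$fit$y, x, object$fit$k),
    boosted_tree = vapply(object$fit, function(m) {
      predict(m, xgboost::xgb.DMatrix(x))
    }, numeric(nrow(x))),
    nn2 = predict(object$fit, x),
    nn3 = predict(object$fit, x))
  out <- as.matrix(out)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- object$features
  rownames(out) <- rownames(x)
  out
}

mean_r2 <- function(truth, pred) {
  r2 <- vapply(seq_len(ncol(truth)), function(j) {
    sst <- sum((truth[, j] - mean(truth[, j]))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((truth[, j] - pred[, j])^2) / sst
  }, numeric(1))
  mean(r2, na.rm = TRUE)
}

#' Fit and select embedding-to-norm mapping candidates
#'
#' Trains each roster candidate to predict all 65 Binder dimensions from
#' word embeddings, using only norm words outside the task item set
#' (`exclude_items` is removed before any fitting), scores each by mean
#' R-squared across the 65 dimensions on a seeded 80/20 held-out split of
#' the training words, and selects the best (earliest on ties). The
#' winner is refit on all training words.
#'
#' @param embeddings Matrix with rownames = words.
#' @param norm_table Tibble: `item_id` plus 65 feature columns of known
#'   norms.
#' @param exclude_items Words to exclude from training (the task items).
#' @param roster Candidate names; default [mapping_candidates()].
#' @param seed Seed.
#' @param holdout_frac Held-out fraction for the R-squared comparison.
#' @return List with class `dct_mapping_result`: `scores` tibble
#'   (candidate, mean_r2), `selected`, `mapping` (refit winner),
#'   `training_words`.
#' @export
fit_mapping_candidates <- function(embeddings, norm_table,
                                   exclude_items = character(),
                                   roster = mapping_candidates(),
                                   seed = 1L, holdout_frac = 0.2) {
  stopifnot(length(roster) >= 1)
  norm_table <- validate_binder(norm_table)
  keep <- !norm_table$item_id %in% exclude_items
  norm_table <- norm_table[keep, ]
  if (nrow(norm_table) < 20) {
    abort(sprintf("only %d training words remain after exclusion; need >= 20",
                  nrow(norm_table)))
  }
  missing <- setdiff(norm_table$item_id, rownames(embeddings))
  if (length(missing)) {
    abort(sprintf("missing embedding vector(s) for: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- embeddings[norm_table$item_id, , drop = FALSE]
  y <- binder_matrix(norm_table)
  n <- nrow(x)
  with_seed(child_seed(seed, "map_split"), {
    hold <- sample.int(n, max(1, round(holdout_frac * n)))
  })
  xtr <- x[-hold, , drop = FALSE]; ytr <- y[-hold, , drop = FALSE]
  xho <- x[hold, , drop = FALSE]; yho <- y[hold, , drop = FALSE]
  scores <- vapply(seq_along(roster), function(i) {
    f <- fit_map_one(roster[i], xtr, ytr, seed = child_seed(seed, roster[i]))
    r2 <- mean_r2(yho, predict(f, xho))
    if (!is.finite(r2)) abort("non-finite mean R-squared")
    r2
  }, numeric(1))
  best <- which.max(scores)
  mapping <- fit_map_one(roster[best], x, y,
                         seed = child_seed(seed, paste0("final_", roster[best])))
  structure(list(scores = tibble::tibble(candidate = roster,
                                         mean_r2 = scores),
                 selected = roster[best], mapping = mapping,
                 training_words = norm_table$item_id),
            class = "dct_mapping_result")
}

#' Predict Binder scores for task items from embeddings
#'
#' @param result A `dct_mapping_result` (or a `dct_mapping`).
#' @param words Words to score, in output order.
#' @param embeddings Embedding matrix covering the words.
#' @return Binder tibble: `item_id` plus 65 predicted feature columns.
#' @export
predict_binder_scores <- function(result, words, embeddings) {
  mapping <- if (inherits(result, "dct_mapping_result")) result$mapping
             else result
  stopifnot(inherits(mapping, "dct_mapping"))
  missing <- setdiff(words, rownames(embeddings))
  if (length(missing)) {
    abort(sprintf("missing embedding vector(s) for: %s",
                  paste(missing, collapse = ", ")))
  }
  pred <- predict(mapping, embeddings[words, , drop = FALSE])
  dplyr::bind_cols(tibble::tibble(item_id = words),
                   tibble::as_tibble(as.data.frame(pred)))
}
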