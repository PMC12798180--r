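#' Medial coding scheme
#'
#' Demonstrative choices are coded on a proximal--distal axis: proximal
#' always +1, distal always -1. The three schemes differ only in the
#' medial code of three-term systems: `drop_medial` codes it 0 (the
#' medial response then contributes nothing to the profile numerator),
#' `medial_as_distal` codes it -1 (proximal vs medial+distal) and
#' `medial_as_proximal` codes it +1 (proximal+medial vs distal).
#'
#' @param name One of `"drop_medial"`, `"medial_as_distal"`,
#'   `"medial_as_proximal"`.
#' @return List with `name` and `codes` (named numeric vector over
#'   proximal/medial/distal), class `dct_coding_scheme`.
#' @export
coding_scheme <- function(name = c("drop_medial", "medial_as_distal",
                                   "medial_as_proximal")) {
  name <- match.arg(name)
  medial <- switch(name, drop_medial = 0, medial_as_distal = -1,
                   medial_as_proximal = 1)
  structure(list(name = name,
                 codes = c(proximal = 1, medial = medial, distal = -1)),
            class = "dct_coding_scheme")
}

#' Recode trials into a subject-by-item response matrix
#'
#' Maps each retained subject's chosen demonstrative form on each item to
#' its numeric code under the given scheme and arranges codes in a
#' subjects-by-items matrix whose columns follow the Binder item order.
#' Attention-check trials are dropped. Each subject must answer each item
#' exactly once; repeated answers fail loudly.
#'
#' @param trials Trial tibble.
#' @param binder Binder tibble (fixes the item order).
#' @param scheme A [coding_scheme()] or scheme name.
#' @param subject_ids Subjects to include (e.g. [qc_retained()] output);
#'   default all subjects appearing in `trials`.
#' @return Tibble with `subject_id` and one numeric column per item;
#'   attribute `scheme` carries the scheme name.
#' @export
recode_responses <- function(trials, binder, scheme = "drop_medial",
                             subject_ids = NULL) {
  if (is.character(scheme)) scheme <- coding_scheme(scheme)
  trials <- validate_trials(trials)
  real <- trials[!trials$is_attention_check, ]
  if (!is.null(subject_ids)) {
    real <- real[real$subject_id %in% subject_ids, ]
  }
  if (!nrow(real)) abort("recode_responses: no trials after filtering")
  unknown <- setdiff(unique(real$item_id), binder$item_id)
  if (length(unknown)) {
    abort(sprintf("trials reference item(s) not in the Binder table: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  dup <- real |>
    dplyr::count(.data$subject_id, .data$item_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("subject %s answered item %s %d times; expected exactly once",
                  dup$subject_id[1], dup$item_id[1], dup$n[1]))
  }
  wide <- real |>
    dplyr::mutate(code = unname(scheme$codes[.data$choice])) |>
    dplyr::select("subject_id", "item_id", "code") |>
    tidyr::pivot_wider(names_from = "item_id", values_from = "code")
  if (anyNA(wide)) {
    i <- which(rowSums(is.na(wide)) > 0)[1]
    abort(sprintf("subject %s did not answer every item", wide$subject_id[i]))
  }
  wide <- wide[c("subject_id", binder$item_id)]
  attr(wide, "scheme") <- scheme$name
  wide
}

#' Compute per-subject semantic profiles
#'
#' The core aggregation statistic: the subjects-by-items response matrix
#' `R` (codes +1/0/-1) is multiplied with the items-by-features Binder
#' matrix `B` and divided by the number of items, giving each subject a
#' mean response-weighted score on each of the 65 semantic features.
#' Positive values mean relatively more proximal choices on items scoring
#' high on the feature; zero means no proximal/distal asymmetry. The
#' denominator is always the full item count, so under `drop_medial`
#' medial responses contribute zero to the numerator while the scale
#' stays comparable across schemes.
#'
#' @param responses Tibble from [recode_responses()].
#' @param binder Binder tibble whose items match the response columns.
#' @return Tibble with `subject_id` and one column per feature;
#'   attributes `scheme` and `scaling` (`"raw"`).
#' @export
#' @examples
#' b <- tibble::tibble(item_id = c("party", "car", "shame"),
#'                     Social = c(5.9, 2, 2.5), Sad = c(0.03, 0.1, 4.8))
#' r <- tibble::tibble(subject_id = "A", party = 1, car = -1, shame = -1)
#' compute_profiles(r, b)  # Social 0.467, Sad -1.62
compute_profiles <- function(responses, binder) {
  items <- setdiff(names(responses), "subject_id")
  if (!identical(items, as.character(binder$item_id))) {
    if (!setequal(items, binder$item_id)) {
      abort("response items and Binder items do not match")
    }
    binder <- binder[match(items, binder$item_id), ]
  }
  R <- as.matrix(responses[items])
  B <- binder_matrix(binder)
  P <- (R %*% B) / length(items)
  out <- dplyr::bind_cols(tibble::tibble(subject_id = responses$subject_id),
                          tibble::as_tibble(as.data.frame(P)))
  attr(out, "scheme") <- attr(responses, "scheme")
  attr(out, "scaling") <- "raw"
  out
}

#' Z-score semantic profiles with training-set statistics
#'
#' Scales each feature column to mean 0, SD 1 using either its own
#' statistics (when `stats` is `NULL`, i.e. on the training set) or
#' previously stored training statistics (for validation/test rows, so no
#' test information leaks into the scaling). Constant features scale to
#' zeros.
#'
#' @param profiles Profile tibble from [compute_profiles()].
#' @param stats `NULL`, or the `scaling_stats` attribute of a previously
#'   scaled training set (a list of `mean` and `sd` vectors).
#' @return Scaled profile tibble; attributes `scaling = "zscored"` and
#'   `scaling_stats`.
#' @export
scale_profiles <- function(profiles, stats = NULL) {
  feats <- setdiff(names(profiles), "subject_id")
  m <- as.matrix(profiles[feats])
  if (is.null(stats)) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, sd)
  } else {
    stopifnot(setequal(names(stats$mean), feats))
    mu <- stats$mean[feats]
    sdv <- stats$sd[feats]
  }
  sdv_safe <- ifelse(is.na(sdv) | sdv == 0, 1, sdv)
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdv_safe, "/")
  z[, is.na(sdv) | sdv == 0] <- 0
  out <- dplyr::bind_cols(tibble::tibble(subject_id = profiles$subject_id),
                          tibble::as_tibble(as.data.frame(z)))
  attr(out, "scheme") <- attr(profiles, "scheme")
  attr(out, "scaling") <- "zscored"
  attr(out, "scaling_stats") <- list(mean = mu, sd = sdv)
  out
}

profile_matrix <- function(profiles) {
  feats <- setdiff(names(profiles), "subject_id")
  m <- as.matrix(profiles[feats])
  rownames(m) <- profiles$subject_id
  m
}
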