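#' Study configuration
#'
#' Bundles the analysis constants used across the pipeline: the
#' quality-control thresholds (fast-response cutoff in ms, tolerated
#' fraction of fast responses, minimum normalized response entropy,
#' tolerated attention-check failures out of the number of checks), the
#' split fractions (test share of the data, validation share of the
#' training set), the medial coding scheme, the bootstrap count and the
#' global seed.
#'
#' @param rt_ms Fast-response cutoff in milliseconds (responses strictly
#'   below count as fast). Default 300.
#' @param rt_frac Tolerated fraction of fast responses; a subject is
#'   excluded when their fraction is strictly greater. Default 0.10.
#' @param entropy_min Minimum normalized response entropy (bits divided by
#'   log2 of the number of demonstrative forms); exclusion when strictly
#'   below. Default 0.80.
#' @param max_check_fails Tolerated failed attention checks; exclusion when
#'   strictly more fail. Default 3.
#' @param n_checks Number of attention-check trials per subject. Default 15.
#' @param test_frac Share of subjects held out for testing. Default 0.30.
#' @param val_of_train Share of the training set used for hyperparameter
#'   validation. Default 0.20.
#' @param coding_scheme Medial coding scheme name; see [coding_scheme()].
#' @param n_bootstrap Number of bootstrap re-splits for robustness tests.
#' @param seed Global seed from which all child seeds derive.
#' @return A list with class `dct_config`.
#' @export
study_config <- function(rt_ms = 300, rt_frac = 0.10, entropy_min = 0.80,
                         max_check_fails = 3, n_checks = 15,
                         test_frac = 0.30, val_of_train = 0.20,
                         coding_scheme = "drop_medial",
                         n_bootstrap = 1000, seed = 1L) {
  stopifnot(rt_ms > 0, rt_frac > 0, entropy_min > 0, max_check_fails > 0,
            n_checks > 0, test_frac > 0, test_frac < 1,
            val_of_train > 0, val_of_train < 1, n_bootstrap >= 1)
  structure(list(rt_ms = rt_ms, rt_frac = rt_frac,
                 entropy_min = entropy_min,
                 max_check_fails = max_check_fails, n_checks = n_checks,
                 test_frac = test_frac, val_of_train = val_of_train,
                 coding_scheme = coding_scheme,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed)),
            class = "dct_config")
}

#' Read a study configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [study_config()].
#' @return A `dct_config` list.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals[intersect(names(vals), names(formals(study_config)))])
}

#' @export
print.dct_config <- function(x, ...) {
  cat("DCT study configuration\n")
  cat(sprintf("  QC: rt < %g ms in > %g of trials; entropy < %g; > %d/%d failed checks\n",
              x$rt_ms, x$rt_frac, x$entropy_min, x$max_check_fails, x$n_checks))
  cat(sprintf("  Split: %g test, %g of train for validation; scheme %s; %d bootstraps; seed %d\n",
              x$test_frac, x$val_of_train, x$coding_scheme, x$n_bootstrap, x$seed))
  invisible(x)
}

choice_levels <- function() c("proximal", "medial", "distal")

three_term_languages <- function() c("Spanish", "Filipino")

#' Derive PHQ-9 sums and depression group from item scores
#'
#' Sums the nine PHQ-9 item scores (each 0--3) and assigns subjects with a
#' sum of 10 or more (moderate to severe symptoms) to the depression
#' group, all others to the control group. Groups are coded
#' control = 0, depression = 1.
#'
#' @param subjects Data frame with columns `phq1` ... `phq9`.
#' @return The input as a tibble with columns `phq9_sum` (integer 0--27)
#'   and `group` (factor control/depression) added or replaced.
#' @export
#' @examples
#' s <- tibble::tibble(subject_id = "a", phq1 = 3, phq2 = 3, phq3 = 3,
#'                     phq4 = 1, phq5 = 0, phq6 = 0, phq7 = 0, phq8 = 0,
#'                     phq9 = 0)
#' assign_group(s)$group  # sum 10 -> depression
assign_group <- function(subjects) {
  items <- paste0("phq", 1:9)
  assert_cols(subjects, items, "subjects")
  m <- as.matrix(subjects[items])
  bad <- which(!is.finite(m) | m < 0 | m > 3 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("PHQ-9 item out of range [0,3] at row %d, item phq%d",
                  bad[1, 1], bad[1, 2]))
  }
  subjects <- tibble::as_tibble(subjects)
  subjects$phq9_sum <- as.integer(rowSums(m))
  subjects$group <- factor(ifelse(subjects$phq9_sum >= 10, "depression", "control"),
                           levels = c("control", "depression"))
  subjects
}

#' Numeric 0/1 coding of the depression group
#' @param group Factor as produced by [assign_group()].
#' @return Integer vector, control = 0, depression = 1.
#' @export
group_code <- function(group) as.integer(group == "depression")

validate_trials <- function(trials) {
  assert_cols(trials, c("subject_id", "item_id", "choice", "rt_ms",
                        "is_attention_check"), "trials")
  bad <- setdiff(unique(trials$choice), choice_levels())
  if (length(bad)) {
    abort(sprintf("unknown choice label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(trials$rt_ms) | trials$rt_ms < 0)) {
    i <- which(!is.finite(trials$rt_ms) | trials$rt_ms < 0)[1]
    abort(sprintf("negative or missing rt_ms at trial row %d (subject %s)",
                  i, trials$subject_id[i]))
  }
  if (!"attention_passed" %in% names(trials)) trials$attention_passed <- NA
  mism <- xor(trials$is_attention_check, !is.na(trials$attention_passed))
  if (any(mism)) {
    abort(sprintf(
      "attention_passed must be present exactly for attention-check trials (first offending row %d)",
      which(mism)[1]))
  }
  tibble::as_tibble(trials)
}

validate_binder <- function(binder) {
  assert_cols(binder, "item_id", "binder table")
  feats <- setdiff(names(binder), "item_id")
  if (length(feats) != 65) {
    abort(sprintf("binder table must have exactly 65 feature columns, found %d",
                  length(feats)))
  }
  if (anyDuplicated(feats)) abort("binder feature names must be unique")
  if (anyDuplicated(binder$item_id)) abort("binder item_ids must be unique")
  if (anyNA(binder)) abort("binder table contains missing cells")
  tibble::as_tibble(binder)
}

#' Read a study from delimited text files
#'
#' Reads the three study tables (trials, subjects, Binder item norms),
#' validates their schemas, recomputes PHQ-9 sums and groups, and checks
#' referential integrity: every trial must resolve to a known subject and
#' (for non-check trials) to an item present in the Binder table.
#'
#' @param trials_path,subjects_path,binder_path CSV paths. `trials.csv`
#'   has columns subject_id, item_id, choice, rt_ms, button_layout,
#'   is_attention_check, attention_passed; `subjects.csv` has subject_id,
#'   language, system_terms, age, gender, phq1..phq9; `binder.csv` has
#'   item_id plus 65 feature columns.
#' @return A list with class `dct_study`: tibbles `trials`, `subjects`,
#'   `binder`, and `trial_counts` (non-check trials per subject).
#' @export
read_study <- function(trials_path, subjects_path, binder_path) {
  trials <- readr::read_csv(trials_path, show_col_types = FALSE, progress = FALSE)
  subjects <- readr::read_csv(subjects_path, show_col_types = FALSE, progress = FALSE)
  binder <- readr::read_csv(binder_path, show_col_types = FALSE, progress = FALSE)
  dct_study(trials, subjects, binder)
}

#' Assemble and validate a study object from in-memory tables
#'
#' @param trials,subjects,binder Data frames following the `read_study()`
#'   schemas.
#' @return A `dct_study` list; see [read_study()].
#' @export
dct_study <- function(trials, subjects, binder) {
  trials <- validate_trials(trials)
  assert_cols(subjects, c("subject_id", "language", "system_terms", "age",
                          "gender", paste0("phq", 1:9)), "subjects")
  incomplete <- !complete.cases(
    subjects[c("language", "system_terms", "age", "gender", paste0("phq", 1:9))])
  if (any(incomplete)) {
    abort(sprintf("malformed subject row for subject %s: missing field(s)",
                  subjects$subject_id[which(incomplete)[1]]))
  }
  subjects <- assign_group(subjects)
  binder <- validate_binder(binder)

  orphan_subj <- setdiff(unique(trials$subject_id), subjects$subject_id)
  if (length(orphan_subj)) {
    abort(sprintf("trials reference unknown subject(s): %s",
                  paste(utils::head(orphan_subj, 5), collapse = ", ")))
  }
  real <- trials[!trials$is_attention_check, ]
  orphan_item <- setdiff(unique(real$item_id), binder$item_id)
  if (length(orphan_item)) {
    abort(sprintf("trials reference item(s) absent from the Binder table: %s",
                  paste(utils::head(orphan_item, 5), collapse = ", ")))
  }
  medial_ok <- subjects$subject_id[subjects$system_terms == 3]
  bad_medial <- real$subject_id[real$choice == "medial" & !real$subject_id %in% medial_ok]
  if (length(bad_medial)) {
    abort(sprintf("medial choice recorded for two-term-system subject %s",
                  bad_medial[1]))
  }
  counts <- dplyr::count(real, .data$subject_id, name = "n_trials")
  structure(list(trials = trials, subjects = subjects, binder = binder,
                 trial_counts = counts),
            class = "dct_study")
}

#' @export
print.dct_study <- function(x, ...) {
  cat(sprintf("DCT study: %d subjects, %d items, %d trials (%d checks)\n",
              nrow(x$subjects), nrow(x$binder), nrow(x$trials),
              sum(x$trials$is_attention_check)))
  print(dplyr::count(x$subjects, .data$language, .data$group))
  invisible(x)
}

#' Write a study to delimited text files
#'
#' Inverse of [read_study()]; a round trip reproduces the tables
#' field-for-field.
#'
#' @param study A `dct_study` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dct_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "subjects.csv", "binder.csv"))
  readr::write_csv(study$trials, paths[1], progress = FALSE)
  subj <- study$subjects[setdiff(names(study$subjects), c("phq9_sum", "group"))]
  readr::write_csv(subj, paths[2], progress = FALSE)
  readr::write_csv(study$binder, paths[3], progress = FALSE)
  invisible(paths)
}

#' Convert a Binder tibble to a numeric matrix
#'
#' @param binder Tibble with `item_id` and 65 feature columns.
#' @return Numeric matrix, items in rows (named by item_id), features in
#'   columns.
#' @export
binder_matrix <- function(binder) {
  feats <- setdiff(names(binder), "item_id")
  m <- as.matrix(binder[feats])
  rownames(m) <- binder$item_id
  m
}
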