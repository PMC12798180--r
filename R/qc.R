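#' Fraction of fast responses
#'
#' Share of (non-check) trials answered faster than the cutoff; responses
#' strictly below `cutoff_ms` count as fast. Subjects with a fraction
#' strictly above 10% are treated as low-effort responders.
#'
#' @param rt_ms Numeric vector of reaction times for one subject's
#'   non-check trials.
#' @param cutoff_ms Fast cutoff in milliseconds. Default 300.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' fast_rt_fraction(c(250, 500, 500, 500))  # 0.25
fast_rt_fraction <- function(rt_ms, cutoff_ms = 300) {
  if (!length(rt_ms)) abort("fast_rt_fraction: subject has zero trials")
  mean(rt_ms < cutoff_ms)
}

#' Normalized response entropy
#'
#' Shannon entropy (base 2) of a subject's empirical distribution over the
#' demonstrative forms of their language, divided by `log2(n_forms)` so
#' that a uniform responder scores 1 in both two- and three-term systems
#' and the single 0.80 exclusion floor applies to both. The convention
#' `0 * log(0) = 0` is used for unused forms.
#'
#' @param choices Character vector of chosen forms for one subject's
#'   non-check trials.
#' @param n_forms Number of demonstrative forms in the subject's system
#'   (2 or 3).
#' @return Normalized entropy in `[0, 1]`.
#' @export
#' @examples
#' response_entropy(rep(c("proximal", "distal"), 10), 2)  # 1
#' response_entropy(rep("proximal", 10), 2)               # 0
response_entropy <- function(choices, n_forms) {
  if (!length(choices)) abort("response_entropy: subject has zero trials")
  stopifnot(n_forms >= 2)
  p <- tabulate(factor(choices, levels = choice_levels()), 3) / length(choices)
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(n_forms)
}

#' Per-subject quality-control metrics
#'
#' Computes, for every subject, the fast-response fraction and normalized
#' response entropy over non-check trials and the number of failed
#' attention checks. Attention-check trials are excluded from the RT and
#' entropy computations: they have a correct answer and would bias both.
#'
#' @param trials Trial tibble (`read_study()` schema).
#' @param subjects Subject tibble (needed for `system_terms`).
#' @param config A [study_config()].
#' @return Tibble with one row per subject: `subject_id`,
#'   `fast_rt_fraction`, `response_entropy`, `n_check_fails`, `n_trials`.
#' @export
qc_metrics <- function(trials, subjects, config = study_config()) {
  trials <- validate_trials(trials)
  real <- trials[!trials$is_attention_check, ]
  checks <- trials[trials$is_attention_check, ]
  sys <- setNames(subjects$system_terms, subjects$subject_id)
  met <- real |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      fast_rt_fraction = fast_rt_fraction(.data$rt_ms, config$rt_ms),
      response_entropy = response_entropy(.data$choice,
                                          sys[[.data$subject_id[1]]]),
      n_trials = dplyr::n(), .groups = "drop")
  fails <- checks |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_check_fails = sum(!.data$attention_passed),
                     .groups = "drop")
  out <- tibble::tibble(subject_id = subjects$subject_id) |>
    dplyr::left_join(met, by = "subject_id") |>
    dplyr::left_join(fails, by = "subject_id")
  out$n_check_fails[is.na(out$n_check_fails)] <- 0L
  out$n_trials[is.na(out$n_trials)] <- 0L
  out
}

#' Apply the low-effort and missing-data exclusion rules
#'
#' A subject is excluded when any of the following holds, each comparison
#' strict: more than 10% of non-check responses faster than 300 ms
#' (`fast_rt`), normalized response entropy below 0.80 (`low_entropy`),
#' more than 3 of 15 attention checks failed (`attention`), or missing
#' data — no trials, or an incomplete trial set relative to the item roster
#' (`missing`). Thresholds come from `config`.
#'
#' @param subjects,trials Study tables.
#' @param config A [study_config()].
#' @param n_items Expected number of non-check trials per subject; when
#'   `NULL` (default) the modal per-subject count is used.
#' @return A QC report tibble: per subject the three metrics, `excluded`
#'   (logical) and `reasons` (semicolon-joined subset of
#'   fast_rt/low_entropy/attention/missing; empty string when retained).
#' @export
apply_exclusions <- function(subjects, trials, config = study_config(),
                             n_items = NULL) {
  met <- qc_metrics(trials, subjects, config)
  if (is.null(n_items)) {
    tab <- table(met$n_trials[met$n_trials > 0])
    n_items <- as.integer(names(tab)[which.max(tab)])
  }
  phq_ok <- complete.cases(subjects[paste0("phq", 1:9)])
  demo_ok <- complete.cases(subjects[c("language", "age", "gender")])
  missing <- met$n_trials < n_items |
    !phq_ok[match(met$subject_id, subjects$subject_id)] |
    !demo_ok[match(met$subject_id, subjects$subject_id)]
  reasons <- purrr::pmap_chr(
    list(met$fast_rt_fraction, met$response_entropy, met$n_check_fails, missing),
    function(fr, ent, nf, mis) {
      r <- character()
      if (isTRUE(fr > config$rt_frac)) r <- c(r, "fast_rt")
      if (isTRUE(ent < config$entropy_min)) r <- c(r, "low_entropy")
      if (nf > config$max_check_fails) r <- c(r, "attention")
      if (mis) r <- c(r, "missing")
      paste(r, collapse = ";")
    })
  met |>
    dplyr::mutate(excluded = reasons != "", reasons = reasons)
}

#' Retained subjects after quality control
#'
#' @param qc_report Tibble from [apply_exclusions()].
#' @return Character vector of retained subject ids.
#' @export
qc_retained <- function(qc_report) {
  qc_report$subject_id[!qc_report$excluded]
}
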