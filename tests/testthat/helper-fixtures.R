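# Shared fixtures, all built in code.

# A hand-written two-subject, three-item study.
tiny_study_tables <- function() {
  trials <- tibble::tibble(
    subject_id = rep(c("s1", "s2"), each = 3),
    item_id = rep(c("party", "car", "shame"), 2),
    choice = c("proximal", "distal", "distal", "distal", "proximal", "distal"),
    rt_ms = c(500, 650, 700, 480, 520, 610),
    button_layout = "horizontal",
    is_attention_check = FALSE,
    attention_passed = NA)
  subjects <- tibble::tibble(
    subject_id = c("s1", "s2"),
    language = "English", system_terms = 2L,
    age = c(30, 40), gender = c("female", "male"),
    phq1 = c(3, 0), phq2 = c(3, 0), phq3 = c(3, 1), phq4 = c(1, 0),
    phq5 = 0, phq6 = 0, phq7 = 0, phq8 = 0, phq9 = 0)
  binder <- tiny_binder(c("party", "car", "shame"))
  list(trials = trials, subjects = subjects, binder = binder)
}

# A 65-column Binder table for arbitrary items; Social and Sad carry the
# in-text worked-example ratings when the items are party/car/shame.
tiny_binder <- function(item_ids) {
  feats <- binder_feature_names()
  set.seed(404)
  m <- matrix(round(runif(length(item_ids) * 65, 0, 6), 2),
              length(item_ids), 65, dimnames = list(NULL, feats))
  if (identical(item_ids, c("party", "car", "shame"))) {
    m[, "Social"] <- c(5.9, 2, 2.5)
    m[, "Sad"] <- c(0.03, 0.1, 4.8)
  }
  dplyr::bind_cols(tibble::tibble(item_id = item_ids),
                   tibble::as_tibble(as.data.frame(m)))
}

# Cohorts are expensive to simulate; cache by spec-defining arguments.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, spec_fun) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, simulate_study(spec_fun()), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# Null cohort: no planted effect, moderate size.
null_cohort <- function() {
  cached_cohort("null1000", function() {
    synthetic_spec(n_subjects = 1000,
                   beta_dep = numeric(65), beta_ctrl = numeric(65),
                   seed = 202)
  })
}

# Planted-effect cohort at the default effect template.
planted_cohort <- function() {
  cached_cohort("planted1500", function() synthetic_spec(n_subjects = 1500,
                                                         seed = 303))
}

profiles_of <- function(study, scheme = "drop_medial") {
  qc <- apply_exclusions(study$subjects, study$trials)
  resp <- recode_responses(study$trials, study$binder, scheme,
                           qc_retained(qc))
  compute_profiles(resp, study$binder)
}

# Profiles + subjects with a perfectly separable single-feature signal,
# for classifier sanity checks.
separable_profiles <- function(n = 300, seed = 9) {
  set.seed(seed)
  feats <- binder_feature_names()
  x <- matrix(rnorm(n * 65), n, 65, dimnames = list(NULL, feats))
  y <- as.integer(x[, "Sad"] > 0)
  x[, "Sad"] <- x[, "Sad"] + 3 * (2 * y - 1)  # widen the margin
  profiles <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("p%04d", seq_len(n))),
    tibble::as_tibble(as.data.frame(x)))
  subjects <- tibble::tibble(
    subject_id = profiles$subject_id,
    language = "English", system_terms = 2L, age = 30, gender = "female",
    group = factor(ifelse(y == 1, "depression", "control"),
                   levels = c("control", "depression")))
  list(profiles = profiles, subjects = subjects, y = y)
}
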