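#' Specification of a synthetic DCT cohort
#'
#' Defines the generative conditions for a simulated Demonstrative Choice
#' Task study: per-language sample sizes (defaults are the included-sample
#' sizes of the seven-language study the package models), the 290-item
#' task, ~34% depression prevalence, a logistic / proportional-odds choice
#' model over scaled Binder features with planted group effect vectors,
#' log-normal reaction times, and rates of three kinds of low-effort
#' responders.
#'
#' @param n_subjects Either a named integer vector of subjects per
#'   language, or a single total that is spread over the seven default
#'   languages proportionally to the study's included sample sizes.
#' @param n_items Number of DCT items. Default 290.
#' @param prevalence Target depression prevalence (PHQ-9 sum >= 10).
#'   Default 0.34.
#' @param beta_dep,beta_ctrl Numeric 65-vectors of log-odds weights of
#'   each (z-scored) Binder feature on proximal choice, for the depression
#'   and control groups. Defaults plant positive weights on the
#'   negative-affect features and negative weights on positive-affect
#'   features for the depression group only; see
#'   [default_effect_template()].
#' @param intercept_mean,intercept_sd Mean and SD of the per-subject
#'   proximal-preference intercept on the log-odds scale. Defaults
#'   qlogis(0.52) and 0.25, reproducing the observed slight proximal
#'   preponderance while keeping marginal response entropy comfortably
#'   above the QC floor for attentive subjects.
#' @param cutpoints Two ordered cutpoints of the proportional-odds model
#'   for three-term systems (distal | medial | proximal). Defaults give
#'   roughly 37/40/23 proximal/medial/distal at the mean intercept,
#'   matching the Spanish pattern.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters
#'   (milliseconds). Defaults log(800) and 0.4.
#' @param rate_fast,rate_constant,rate_inattentive Fractions of subjects
#'   injected as fast responders, constant responders and inattentive
#'   responders. Default 0.
#' @param check_pass_attentive,check_pass_inattentive Attention-check pass
#'   probabilities. Defaults 0.98 and 0.30.
#' @param n_checks Attention checks per subject. Default 15.
#' @param phq_thresholds,phq_loading Ordinal thresholds and latent
#'   severity loading of the PHQ-9 item model; the defaults are calibrated
#'   so the default prevalence target is met.
#' @param seed Global seed.
#' @return A list with class `dct_synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = NULL, n_items = 290,
                           prevalence = 0.34,
                           beta_dep = NULL, beta_ctrl = NULL,
                           intercept_mean = stats::qlogis(0.52),
                           intercept_sd = 0.25,
                           cutpoints = c(-1.13, 0.61),
                           rt_meanlog = log(800), rt_sdlog = 0.4,
                           rate_fast = 0, rate_constant = 0,
                           rate_inattentive = 0,
                           check_pass_attentive = 0.98,
                           check_pass_inattentive = 0.30,
                           n_checks = 15,
                           phq_thresholds = c(-0.15, 0.70, 1.55),
                           phq_loading = 0.75,
                           seed = 1L) {
  default_n <- c(English = 1654, German = 488, Italian = 462, Spanish = 492,
                 Chinese = 279, Filipino = 199, Russian = 307)
  if (is.null(n_subjects)) {
    n_subjects <- default_n
  } else if (is.null(names(n_subjects))) {
    stopifnot(length(n_subjects) == 1L, n_subjects >= 1)
    share <- default_n / sum(default_n)
    n <- floor(share * n_subjects)
    rem <- n_subjects - sum(n)
    if (rem > 0) {
      top <- order(share * n_subjects - n, decreasing = TRUE)[seq_len(rem)]
      n[top] <- n[top] + 1
    }
    n_subjects <- n[n > 0]
  }
  eff <- default_effect_template()
  beta_dep <- beta_dep %||% eff$beta_dep
  beta_ctrl <- beta_ctrl %||% eff$beta_ctrl
  stopifnot(length(beta_dep) == 65, length(beta_ctrl) == 65,
            n_items >= 1, prevalence > 0, prevalence < 1,
            all(c(rate_fast, rate_constant, rate_inattentive) >= 0),
            all(c(rate_fast, rate_constant, rate_inattentive) <= 1),
            length(cutpoints) == 2, cutpoints[1] < cutpoints[2],
            length(phq_thresholds) == 3,
            all(diff(phq_thresholds) > 0),
            phq_loading > 0, phq_loading < 1)
  structure(list(n_subjects = n_subjects, n_items = n_items,
                 prevalence = prevalence,
                 beta_dep = beta_dep, beta_ctrl = beta_ctrl,
                 intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 cutpoints = cutpoints,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rate_fast = rate_fast, rate_constant = rate_constant,
                 rate_inattentive = rate_inattentive,
                 check_pass_attentive = check_pass_attentive,
                 check_pass_inattentive = check_pass_inattentive,
                 n_checks = n_checks,
                 phq_thresholds = phq_thresholds, phq_loading = phq_loading,
                 seed = as.integer(seed)),
            class = "dct_synthetic_spec")
}

#' Generate a synthetic Binder feature matrix
#'
#' Draws item scores on the 65 Binder dimensions on the native 0--6 rating
#' scale. The emotion-domain features (see [emotion_block_loadings()])
#' share a latent valence factor, reproducing the strong
#' multicollinearity of affect features across real words; all other
#' features are drawn independently.
#'
#' @param n_items Number of items.
#' @param seed Seed.
#' @return Tibble with `item_id` and 65 feature columns, all values in
#'   `[0, 6]`.
#' @export
generate_binder_matrix <- function(n_items = 290, seed = 1L) {
  stopifnot(n_items >= 1)
  feats <- binder_feature_names()
  block <- emotion_block_loadings()
  with_seed(child_seed(seed, "binder"), {
    valence <- rnorm(n_items)          # latent negative-affect factor
    lambda <- 0.8                      # block loading; within-block |r| ~ 0.64
    scores <- matrix(rnorm(n_items * 65), n_items, 65,
                     dimnames = list(NULL, feats))
    for (f in names(block)) {
      scores[, f] <- block[[f]] * lambda * valence +
        sqrt(1 - lambda^2) * scores[, f]
    }
    scores <- 3 + 1.1 * scores
    scores <- pmin(pmax(scores, 0), 6)
    out <- tibble::as_tibble(as.data.frame(scores))
    out <- dplyr::bind_cols(
      tibble::tibble(item_id = sprintf("item%03d", seq_len(n_items))), out)
    out
  })
}

#' Model-implied depression prevalence of the PHQ-9 generator
#'
#' Computes P(PHQ-9 sum >= 10) under the ordinal item model by
#' conditioning on the latent severity (numeric grid over the standard
#' normal) and convolving the nine conditional item distributions
#' exactly. Used to calibrate the threshold shift for a prevalence
#' target, and handy as a generator diagnostic.
#'
#' @param thresholds Three ordered ordinal thresholds.
#' @param loading Latent severity loading in (0, 1).
#' @param shift Threshold shift (subtracted from all three).
#' @param n_grid Grid size for the latent integration.
#' @return Expected prevalence in `[0, 1]`.
#' @export
phq_prevalence <- function(thresholds, loading, shift = 0, n_grid = 101) {
  z <- seq(-5, 5, length.out = n_grid)
  w <- stats::dnorm(z); w <- w / sum(w)
  s2 <- sqrt(1 - loading^2)
  prev_z <- vapply(z, function(zz) {
    p_exceed <- stats::pnorm((loading * zz - (thresholds - shift)) / s2)
    # item pmf on 0..3 from ordered exceedance probabilities
    pe <- c(1, p_exceed, 0)
    pmf <- pe[1:4] - pe[2:5]
    dist <- 1
    for (k in 1:9) {
      new <- numeric(length(dist) + 3)
      for (v in 0:3) new[seq_along(dist) + v] <- new[seq_along(dist) + v] + dist * pmf[v + 1]
      dist <- new
    }
    sum(dist[(10 + 1):length(dist)])
  }, numeric(1))
  sum(prev_z * w)
}

# Shift the ordinal thresholds so the model prevalence hits the target.
calibrate_phq_shift <- function(target, thresholds, loading) {
  f <- function(d) phq_prevalence(thresholds, loading, d) - target
  stats::uniroot(f, c(-3, 3), tol = 1e-6)$root
}

#' Simulate a subject table
#'
#' Draws a latent depression severity per subject and ordinalizes it (plus
#' item noise) into the nine PHQ-9 items; sums and the >= 10 group
#' threshold then follow. Demographics (age, gender) are drawn from
#' distributions matching the study's descriptives. The ordinal thresholds
#' are shifted once, analytically, so that expected prevalence equals the
#' spec's target.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble of subjects with `severity` (latent), `phq1..phq9`,
#'   `phq9_sum`, `group`, `language`, `system_terms`, `age`, `gender`.
#' @export
simulate_subjects <- function(spec) {
  stopifnot(inherits(spec, "dct_synthetic_spec"))
  n <- sum(spec$n_subjects)
  shift <- if (abs(spec$prevalence - phq_prevalence(spec$phq_thresholds,
                                                    spec$phq_loading)) < 1e-3) {
    0
  } else {
    calibrate_phq_shift(spec$prevalence, spec$phq_thresholds, spec$phq_loading)
  }
  thr <- spec$phq_thresholds - shift
  with_seed(child_seed(spec$seed, "subjects"), {
    language <- rep(names(spec$n_subjects), spec$n_subjects)
    z <- rnorm(n)
    s2 <- sqrt(1 - spec$phq_loading^2)
    items <- vapply(1:9, function(k) {
      u <- spec$phq_loading * z + s2 * rnorm(n)
      (u > thr[1]) + (u > thr[2]) + (u > thr[3])
    }, numeric(n))
    colnames(items) <- paste0("phq", 1:9)
    subjects <- tibble::tibble(
      subject_id = sprintf("s%05d", seq_len(n)),
      language = language,
      system_terms = ifelse(language %in% three_term_languages(), 3L, 2L),
      age = round(pmin(pmax(rnorm(n, 36, 12), 18), 89)),
      gender = sample(c("female", "male", "nonbinary", "other"), n,
                      replace = TRUE, prob = c(0.51, 0.465, 0.02, 0.005)),
      severity = z)
    subjects <- dplyr::bind_cols(subjects, tibble::as_tibble(as.data.frame(items)))
    assign_group(subjects)
  })
}

simulate_choices_matrix <- function(subjects, binder, spec, rng_key = "trials") {
  bm <- binder_matrix(binder)
  bs <- scale(bm)                      # choice model operates in z-scored space
  bs[is.nan(bs)] <- 0
  n_items <- nrow(bs)
  n <- nrow(subjects)
  with_seed(child_seed(spec$seed, rng_key), {
    intercept <- rnorm(n, spec$intercept_mean, spec$intercept_sd)
    is_dep <- subjects$group == "depression"
    eta <- matrix(0, n_items, n)
    if (any(is_dep)) {
      eta[, is_dep] <- (bs %*% spec$beta_dep)[, 1] + 0 * eta[, is_dep]
    }
    if (any(!is_dep)) {
      eta[, !is_dep] <- (bs %*% spec$beta_ctrl)[, 1] + 0 * eta[, !is_dep]
    }
    eta <- sweep(eta, 2, intercept, "+")
    u <- matrix(runif(n_items * n), n_items, n)
    choice <- matrix("distal", n_items, n)
    two <- subjects$system_terms == 2L
    if (any(two)) {
      p <- stats::plogis(eta[, two, drop = FALSE])
      choice[, two][u[, two, drop = FALSE] < p] <- "proximal"
    }
    if (any(!two)) {
      e3 <- eta[, !two, drop = FALSE]
      u3 <- u[, !two, drop = FALSE]
      p_dist <- stats::plogis(spec$cutpoints[1] - e3)
      p_distmed <- stats::plogis(spec$cutpoints[2] - e3)
      c3 <- ifelse(u3 < p_dist, "distal",
                   ifelse(u3 < p_distmed, "medial", "proximal"))
      choice[, !two] <- c3
    }
    list(choice = choice, intercept = intercept)
  })
}

#' Simulate DCT trials for a subject table
#'
#' Two-term subjects choose proximal with probability
#' `plogis(intercept_subj + beta_group . binder_scaled)`; three-term
#' subjects follow a proportional-odds model with the same linear
#' predictor and the spec's cutpoints. Reaction times are log-normal, and
#' `n_checks` attention-check trials (with a known correct response) are
#' appended per subject.
#'
#' @param subjects Tibble from [simulate_subjects()].
#' @param binder Binder table from [generate_binder_matrix()].
#' @param spec A [synthetic_spec()].
#' @return Tibble of trials following the `read_study()` schema.
#' @export
simulate_trials <- function(subjects, binder, spec) {
  stopifnot(inherits(spec, "dct_synthetic_spec"))
  sim <- simulate_choices_matrix(subjects, binder, spec)
  n <- nrow(subjects)
  n_items <- nrow(binder)
  with_seed(child_seed(spec$seed, "trials_rt"), {
    real <- tibble::tibble(
      subject_id = rep(subjects$subject_id, each = n_items),
      item_id = rep(binder$item_id, times = n),
      choice = as.vector(sim$choice),
      rt_ms = round(rlnorm(n * n_items, spec$rt_meanlog, spec$rt_sdlog)),
      button_layout = sample(c("horizontal", "vertical"), n * n_items,
                             replace = TRUE),
      is_attention_check = FALSE,
      attention_passed = NA)
    nc <- spec$n_checks
    checks <- tibble::tibble(
      subject_id = rep(subjects$subject_id, each = nc),
      item_id = rep(sprintf("check%02d", seq_len(nc)), times = n),
      choice = sample(c("proximal", "distal"), n * nc, replace = TRUE),
      rt_ms = round(rlnorm(n * nc, spec$rt_meanlog, spec$rt_sdlog)),
      button_layout = sample(c("horizontal", "vertical"), n * nc,
                             replace = TRUE),
      is_attention_check = TRUE,
      attention_passed = runif(n * nc) < spec$check_pass_attentive)
    dplyr::bind_rows(real, checks)
  })
}

#' Inject low-effort response patterns into simulated trials
#'
#' Overwrites the trials of randomly designated subjects so that fast
#' responders exceed the fast-RT threshold (a quarter of their responses
#' drawn below 300 ms), constant responders give one fixed form on 97% of
#' trials (driving response entropy under the floor), and inattentive
#' subjects pass checks only with the spec's inattentive probability
#' (expected 10+ failures of 15). The injected ids are returned as ground
#' truth for QC-recovery tests.
#'
#' @param trials Tibble from [simulate_trials()].
#' @param subjects Matching subject tibble.
#' @param spec A [synthetic_spec()] with nonzero low-effort rates.
#' @return A list: `trials` (modified tibble) and `truth`, a list of
#'   character vectors `fast`, `constant`, `inattentive`.
#' @export
inject_low_effort <- function(trials, subjects, spec) {
  stopifnot(inherits(spec, "dct_synthetic_spec"))
  n <- nrow(subjects)
  with_seed(child_seed(spec$seed, "low_effort"), {
    n_fast <- round(spec$rate_fast * n)
    n_const <- round(spec$rate_constant * n)
    n_inatt <- round(spec$rate_inattentive * n)
    picked <- sample(subjects$subject_id, min(n, n_fast + n_const + n_inatt))
    truth <- list(
      fast = picked[seq_len(n_fast)] %theni% character(),
      constant = picked[n_fast + seq_len(n_const)] %theni% character(),
      inattentive = picked[n_fast + n_const + seq_len(n_inatt)] %theni% character())

    real <- !trials$is_attention_check
    for (sid in truth$fast) {
      idx <- which(real & trials$subject_id == sid)
      hit <- idx[runif(length(idx)) < 0.25]
      trials$rt_ms[hit] <- round(runif(length(hit), 80, 295))
    }
    for (sid in truth$constant) {
      idx <- which(real & trials$subject_id == sid)
      form <- sample(c("proximal", "distal"), 1)
      keep <- idx[runif(length(idx)) < 0.03]
      trials$choice[idx] <- form
      other <- setdiff(c("proximal", "distal"), form)
      trials$choice[keep] <- other
    }
    for (sid in truth$inattentive) {
      idx <- which(trials$is_attention_check & trials$subject_id == sid)
      trials$attention_passed[idx] <- runif(length(idx)) < spec$check_pass_inattentive
    }
    list(trials = trials, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_binder_matrix()],
#' [simulate_subjects()], [simulate_trials()] and [inject_low_effort()]
#' into a validated `dct_study`, with the planted truth attached.
#'
#' @param spec A [synthetic_spec()].
#' @return A `dct_study` with extra elements `truth` (planted effect
#'   vectors and injected low-effort ids) and `spec`.
#' @export
simulate_study <- function(spec = synthetic_spec()) {
  binder <- generate_binder_matrix(spec$n_items, seed = spec$seed)
  subjects <- simulate_subjects(spec)
  trials <- simulate_trials(subjects, binder, spec)
  inj <- inject_low_effort(trials, subjects, spec)
  study <- dct_study(inj$trials, subjects, binder)
  study$truth <- list(beta_dep = spec$beta_dep, beta_ctrl = spec$beta_ctrl,
                      low_effort = inj$truth)
  study$spec <- spec
  study
}
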