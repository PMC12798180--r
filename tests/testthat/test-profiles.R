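test_that("the three-word worked example reproduces the printed scores", {
  binder <- tibble::tibble(item_id = c("party", "car", "shame"),
                           Social = c(5.9, 2, 2.5),
                           Sad = c(0.03, 0.1, 4.8))
  responses <- tibble::tibble(subject_id = "A", party = 1, car = -1,
                              shame = -1)
  prof <- compute_profiles(responses, binder)
  expect_equal(prof$Social, (5.9 - 2 - 2.5) / 3, tolerance = 1e-12)
  expect_equal(round(prof$Social, 1), 0.5)
  expect_equal(prof$Sad, (0.03 - 0.1 - 4.8) / 3, tolerance = 1e-12)
  expect_equal(round(prof$Sad, 1), -1.6)
})

test_that("recoding follows the scheme codebooks", {
  trials <- tibble::tibble(
    subject_id = "s1", item_id = c("a", "b", "c"),
    choice = c("proximal", "medial", "distal"),
    rt_ms = 500, button_layout = "horizontal",
    is_attention_check = FALSE, attention_passed = NA)
  binder <- tiny_binder(c("a", "b", "c"))
  for (case in list(c("drop_medial", 0), c("medial_as_distal", -1),
                    c("medial_as_proximal", 1))) {
    r <- recode_responses(trials, binder, case[1])
    expect_equal(unname(unlist(r[1, c("a", "b", "c")])),
                 c(1, as.numeric(case[2]), -1))
    expect_identical(attr(r, "scheme"), case[1])
  }
  bad <- trials
  bad$choice[1] <- "hither"
  expect_error(recode_responses(bad, binder), "hither")
  dup <- dplyr::bind_rows(trials, trials[1, ])
  expect_error(recode_responses(dup, binder), "exactly once")
})

test_that("a medial-free study gives identical responses under all schemes", {
  study <- cached_cohort("two_term_only", function() {
    synthetic_spec(n_subjects = c(English = 40, German = 20), seed = 21)
  })
  mats <- lapply(c("drop_medial", "medial_as_distal", "medial_as_proximal"),
                 function(s) {
                   r <- recode_responses(study$trials, study$binder, s)
                   attr(r, "scheme") <- NULL
                   r
                 })
  expect_identical(mats[[1]], mats[[2]])
  expect_identical(mats[[1]], mats[[3]])
})

test_that("profiles match a nested-loop brute-force oracle", {
  set.seed(88)
  n_s <- 5; n_i <- 10; n_f <- 4
  R <- matrix(sample(c(-1, 0, 1), n_s * n_i, replace = TRUE), n_s, n_i)
  B <- matrix(runif(n_i * n_f, 0, 6), n_i, n_f,
              dimnames = list(NULL, paste0("f", 1:n_f)))
  items <- paste0("w", 1:n_i)
  responses <- dplyr::bind_cols(
    tibble::tibble(subject_id = paste0("s", 1:n_s)),
    tibble::as_tibble(as.data.frame(setNames(as.data.frame(R), items))))
  binder <- dplyr::bind_cols(tibble::tibble(item_id = items),
                             tibble::as_tibble(as.data.frame(B)))
  prof <- compute_profiles(responses, binder)
  for (s in 1:n_s) {
    for (f in 1:n_f) {
      acc <- 0
      for (i in 1:n_i) acc <- acc + R[s, i] * B[i, f]
      expect_equal(prof[[paste0("f", f)]][s], unname(acc) / n_i,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("profile aggregation is linear and sign-symmetric", {
  binder <- tiny_binder(c("party", "car", "shame"))
  r1 <- tibble::tibble(subject_id = "x", party = 1, car = 0, shame = -1)
  r2 <- tibble::tibble(subject_id = "x", party = -1, car = 1, shame = 1)
  rsum <- tibble::tibble(subject_id = "x", party = 0, car = 1, shame = 0)
  p1 <- profile_vec <- function(p) unlist(p[setdiff(names(p), "subject_id")])
  expect_equal(profile_vec(compute_profiles(r1, binder)) +
                 profile_vec(compute_profiles(r2, binder)),
               profile_vec(compute_profiles(rsum, binder)), tolerance = 1e-12)
  all_prox <- tibble::tibble(subject_id = "x", party = 1, car = 1, shame = 1)
  expect_equal(profile_vec(compute_profiles(all_prox, binder)),
               colMeans(binder_matrix(binder)), tolerance = 1e-12)
  neg <- tibble::tibble(subject_id = "x", party = -1, car = -1, shame = -1)
  expect_equal(profile_vec(compute_profiles(neg, binder)),
               -profile_vec(compute_profiles(all_prox, binder)))
})

test_that("dropping medial keeps the full-item denominator", {
  binder <- tiny_binder(c("a", "b", "c"))
  trials <- tibble::tibble(
    subject_id = "s1", item_id = c("a", "b", "c"),
    choice = c("proximal", "medial", "medial"),
    rt_ms = 500, button_layout = "h",
    is_attention_check = FALSE, attention_passed = NA)
  prof <- compute_profiles(recode_responses(trials, binder, "drop_medial"),
                           binder)
  b <- binder_matrix(binder)
  expect_equal(unname(prof$Social), b["a", "Social"] / 3, tolerance = 1e-12)
})

test_that("profiles of uniform random responders center on zero", {
  set.seed(510)
  n_s <- 1000
  binder <- generate_binder_matrix(50, seed = 3)
  R <- matrix(sample(c(-1, 1), n_s * 50, replace = TRUE), n_s, 50)
  responses <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%04d", 1:n_s)),
    tibble::as_tibble(as.data.frame(setNames(as.data.frame(R),
                                             binder$item_id))))
  prof <- compute_profiles(responses, binder)
  m <- as.matrix(prof[setdiff(names(prof), "subject_id")])
  se <- apply(m, 2, sd) / sqrt(n_s)
  expect_true(all(abs(colMeans(m)) < 3 * se))
})

test_that("profile headers carry each of the 65 features exactly once", {
  study <- cached_cohort("qc_small", function() {
    synthetic_spec(n_subjects = 50, seed = 17, rate_fast = 0.1)
  })
  prof <- profiles_of(study)
  feats <- setdiff(names(prof), "subject_id")
  expect_identical(sort(feats), sort(binder_feature_names()))
  expect_equal(anyDuplicated(feats), 0L)
  expect_length(feats, 65)
})

test_that("z-scoring uses and stores training statistics", {
  study <- cached_cohort("qc_small", function() {
    synthetic_spec(n_subjects = 50, seed = 17, rate_fast = 0.1)
  })
  prof <- profiles_of(study)
  scaled <- scale_profiles(prof)
  m <- as.matrix(scaled[setdiff(names(scaled), "subject_id")])
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))

  # constant column degenerates to zeros
  prof2 <- prof
  prof2$Sad <- 5
  s2 <- scale_profiles(prof2)
  expect_true(all(s2$Sad == 0))

  # test rows scaled with train stats differ from self-scaled rows
  shifted <- prof
  shifted$Happy <- shifted$Happy + 2
  with_train_stats <- scale_profiles(shifted,
                                     attr(scaled, "scaling_stats"))
  self_scaled <- scale_profiles(shifted)
  expect_gt(mean(abs(with_train_stats$Happy - self_scaled$Happy)), 0.5)
})
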