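test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_spec(n = 40, seed = 123))
  b <- generate_cohort(cohort_spec(n = 40, seed = 123))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n = 40, seed = 124))
  expect_false(identical(a$cohort, c$cohort))
})

test_that("cards decompose indexes exactly and invert the time formula", {
  idx <- data.frame(participant_id = "X", age_years = 40, education_years = 13,
                    gender = "F", SA = 50, OA = 20, FA = 10, Err = 0)
  cards <- indices_to_cards(idx, interaction = 0, omission_rate = 0, seed = 1)
  expect_equal(cards$execution_time_s, c(50, 60, 70, 80))
  expect_equal(cards$omissions, rep(0L, 4))
  # inversion of the performance-time formula: P = 75, 5 omissions -> t = 60
  expect_equal(75 * (25 - 5) / 25, 60)
  expect_equal(performance_time(60, 5), 75)
})

test_that("cards -> indexes round trip is the identity at I = 0", {
  gc <- generate_cohort(cohort_spec(n = 80, seed = 9))
  idx <- compute_indexes(gc$cohort)
  truth <- gc$truth[match(idx$participant_id, gc$truth$participant_id), ]
  for (v in c("SA", "OA", "FA"))
    expect_equal(idx[[v]], truth[[v]], tolerance = 1e-9)
  expect_identical(as.integer(idx$Err), as.integer(truth$Err))
})

test_that("sampled demographics follow the normative cell structure", {
  spec <- cohort_spec(n = 10000, seed = 60)
  d <- sample_demographics(spec)
  expect_equal(mean(d$gender == "M"), 256 / 550, tolerance = 0.02)
  tab <- spec$demographic_table
  dec_p <- tapply(tab$count, tab$decade, sum) / sum(tab$count)
  dec_obs <- table(cut(d$age_years, c(19, 29, 39, 49, 59, 69, 79))) / nrow(d)
  expect_true(all(abs(as.numeric(dec_obs) - as.numeric(dec_p)) < 0.02))
  expect_true(all(d$age_years >= 20 & d$age_years <= 79))
  expect_true(all(d$education_years >= 5 & d$education_years <= 21))

  one <- sample_demographics(cohort_spec(n = 1, seed = 2))
  expect_equal(nrow(one), 1)
})

test_that("generated indexes carry the inverted demographic effects", {
  # zero noise at the centering point returns the baseline exactly
  spec <- cohort_spec(n = 1, seed = 1)
  demo <- data.frame(participant_id = "Z", age_years = 86.9 - exp(3.628),
                     education_years = 1 / 0.081, gender = "F")
  spec2 <- spec; spec2$noise_scale <- c(SA = 1e-9, OA = 1e-9, FA = 1e-9, Err = 8.83)
  idx <- generate_indices(demo, spec2, seed = 4)
  expect_equal(idx$SA, unname(spec$baseline_means["SA"]), tolerance = 1e-6)
  expect_equal(idx$corr_SA, 0, tolerance = 1e-10)

  # deterministic age effect: raw shift equals the sign-flipped correction gap
  demo2 <- data.frame(participant_id = c("Y1", "Y2"), age_years = c(25, 75),
                      education_years = 13, gender = "F")
  idx2 <- generate_indices(demo2, spec2, seed = 4)
  nrm <- brevis_norms()
  gap <- correction_score(nrm, "SA", 25, 13) - correction_score(nrm, "SA", 75, 13)
  expect_equal(idx2$SA[2] - idx2$SA[1], as.vector(gap), tolerance = 1e-5)

  # raw SA rises with age in a default cohort (age effect direction)
  big <- generate_indices(sample_demographics(cohort_spec(n = 2000, seed = 14)),
                          cohort_spec(n = 2000, seed = 14))
  expect_gt(mean(big$SA[big$age_years >= 60 & big$age_years <= 69]),
            mean(big$SA[big$age_years <= 29]))
  expect_true(all(big$Err >= 0))
  expect_true(all(big$Err == trunc(big$Err)))
})

test_that("injected outliers are exactly the ones the filter removes", {
  gc <- generate_cohort(cohort_spec(n = 563, seed = 42, outliers = 13))
  expect_equal(nrow(gc$cohort), 563 * 4)
  res <- filter_outliers(gc$cohort)
  expect_equal(length(unique(res$retained$participant_id)), 550)
  expect_setequal(res$removed_ids, gc$truth$participant_id[gc$truth$is_outlier])
})
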