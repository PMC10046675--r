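nrm <- brevis_norms()

test_that("correction grids reproduce the published cells", {
  sa <- build_correction_grid(nrm, "SA")
  got <- matrix(sa$correction[order(match(sa$education, grid_edus), match(sa$age, grid_ages))],
                nrow = 12)
  expect_equal(got, unname(published_sa_grid))

  oa <- build_correction_grid(nrm, "OA")
  expect_equal(oa$correction[match(grid_ages, oa$age)], published_oa_grid)
  fa <- build_correction_grid(nrm, "FA")
  expect_equal(fa$correction[match(grid_ages, fa$age)], published_fa_grid)

  err <- build_correction_grid(nrm, "Err")
  for (g in c("F", "M")) {
    blk <- err[err$gender == g, ]
    got <- sapply(grid_edus, function(e)
      blk$correction[blk$education == e][match(grid_ages, blk$age[blk$education == e])])
    expect_equal(unname(got),
                 unname(if (g == "F") published_err_grid_f else published_err_grid_m))
  }
})

test_that("correction is zero at the centering point and matches spot values", {
  # both SA terms centered at their sample means
  expect_equal(correction_score(nrm, "SA", age = 86.9 - exp(3.628),
                                education = 1 / 0.081)[1], 0, tolerance = 1e-12)
  expect_equal(round_half_away(correction_score(nrm, "SA", 22, 8)), 1.8)
  expect_equal(round_half_away(correction_score(nrm, "OA", 77)), -13.1)
  expect_equal(correction_score(nrm, "OA", 77)[1], -0.00004 * (77^3 - 129295))
})

test_that("correction domain errors and extrapolation warnings fire", {
  expect_error(correction_score(nrm, "SA", age = 87, education = 10), "86.9")
  expect_error(correction_score(nrm, "SA", age = 86.9, education = 10), "86.9")
  expect_error(correction_score(nrm, "Err", age = 40, education = 0, gender = "F"),
               "education")
  expect_warning(correction_score(nrm, "OA", age = 85),
                 class = "brevis_extrapolation_warning")
  expect_warning(correction_score(nrm, "SA", age = 19, education = 10),
                 class = "brevis_extrapolation_warning")
  w <- suppressWarnings(correction_score(nrm, "OA", age = c(40, 85)))
  expect_equal(attr(w, "extrapolated"), c(FALSE, TRUE))
})

test_that("corrections are monotone in demographics over the normative range", {
  ages <- 20:79
  expect_true(all(diff(correction_score(nrm, "SA", ages, education = 13)) < 0))
  edus <- 1:21
  expect_true(all(diff(correction_score(nrm, "SA", age = 50, education = edus)) > 0))
  expect_true(all(diff(correction_score(nrm, "OA", ages)) < 0))
  expect_true(all(diff(correction_score(nrm, "FA", ages)) < 0))
  expect_true(all(diff(correction_score(nrm, "Err", ages, 13, "F")) < 0))
  expect_true(all(diff(correction_score(nrm, "Err", 50, edus, "F")) > 0))
  expect_gt(correction_score(nrm, "Err", 50, 13, "M"),
            correction_score(nrm, "Err", 50, 13, "F"))
})

test_that("adjusted = raw + correction and matches worked examples", {
  idx <- data.frame(participant_id = "P1", age_years = 22, education_years = 8,
                    gender = "F", SA = 60, OA = 10, FA = 5, Err = 10)
  adj <- adjust_scores(idx, nrm)
  expect_equal(adj$adj_SA, adj$SA + adj$corr_SA)
  expect_equal(round_half_away(adj$adj_SA), 61.8)

  idx2 <- data.frame(participant_id = "P2", age_years = 47, education_years = 13,
                     gender = "F", SA = 60, OA = 10, FA = 5, Err = 10)
  adj2 <- adjust_scores(idx2, nrm)
  expect_equal(round_half_away(adj2$adj_Err), 8.2)
})

test_that("tolerance classification honours the printed bands", {
  expect_equal(classify_tolerance(nrm, "SA", 90.0), "within_limits")
  expect_equal(classify_tolerance(nrm, "SA", 97.4), "pathological")
  expect_equal(classify_tolerance(nrm, "SA", 93.0), "borderline")
  expect_equal(classify_tolerance(nrm, "SA", 98.5), "pathological")
  expect_equal(classify_tolerance(nrm, "OA", 98.8), "pathological")
  expect_equal(classify_tolerance(nrm, "Err", c(29.9, 30.0, 35.2)),
               c("within_limits", "borderline", "pathological"))
})

test_that("equivalent scores bin adjusted values per the published cuts", {
  expect_equal(equivalent_score(nrm, "SA", 98.0), 0L)
  expect_equal(equivalent_score(nrm, "SA", 61.4), 4L)
  expect_equal(equivalent_score(nrm, "FA", 20.0), 2L)
  expect_equal(equivalent_score(nrm, "SA", c(97.4, 97.3, 74.8, 74.7, 67.1, 67.0, 61.5)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("ES 0 and pathological classification coincide everywhere", {
  set.seed(7)
  for (ix in c("SA", "OA", "FA", "Err")) {
    x <- runif(500, -40, 140)
    expect_equal(equivalent_score(nrm, ix, x) == 0L,
                 classify_tolerance(nrm, ix, x) == "pathological")
  }
})

test_that("classification is a step function inside bands", {
  # nudges below the table resolution never change the class
  for (ix in c("SA", "OA", "FA", "Err")) {
    anchors <- nrm$tables[[ix]]$es_cuts + 0.2
    for (a in anchors) {
      eps <- 0.04
      expect_equal(equivalent_score(nrm, ix, a + eps), equivalent_score(nrm, ix, a))
      expect_equal(classify_tolerance(nrm, ix, a + eps), classify_tolerance(nrm, ix, a))
    }
  }
})

test_that("percentile bands are step-function lookups with tail labels", {
  expect_equal(percentile_band(nrm, "SA", 61.5), "50th percentile")
  expect_equal(percentile_band(nrm, "SA", 30.0), ">99th percentile")
  expect_equal(percentile_band(nrm, "Err", 45.0), "1st percentile")
  expect_equal(percentile_band(nrm, "Err", 46.0), "<1st percentile")
  expect_equal(percentile_band(nrm, "SA", 62.0), "45th percentile")
  expect_equal(percentile_band(nrm, "OA", 4.5), "99th percentile")
})

test_that("norm files round-trip and the shipped published file matches", {
  tmp <- tempfile(fileext = ".json")
  write_norms(nrm, tmp)
  back <- read_norms(tmp)
  expect_equal(back$models, nrm$models)
  expect_equal(back$tables, nrm$tables)
  expect_equal(back$version, nrm$version)

  shipped <- system.file("extdata", "brevis_norms_published.json", package = "brevis")
  expect_true(nzchar(shipped))
  pub <- brevis_norms(shipped)
  expect_equal(pub$models, nrm$models)
  expect_equal(pub$tables, nrm$tables)
  expect_equal(correction_score(pub, "SA", 47, 13), correction_score(nrm, "SA", 47, 13))
})

test_that("score reports summarise equivalent scores and flag extrapolation", {
  coh <- rbind(make_cards("A", age = 30, edu = 13, times = c(50, 60, 70, 80)),
               make_cards("B", age = 82, edu = 8, times = c(90, 100, 120, 130)))
  rep <- suppressWarnings(score_brevis(coh, nrm))
  expect_s3_class(rep, "brevis_report")
  expect_equal(rep$extrapolated, c(FALSE, TRUE))
  sm <- summary(rep)
  expect_equal(sum(sm$es_counts["SA", ]), 2)
  expect_equal(rep$adj_SA, rep$SA + rep$corr_SA)
})
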