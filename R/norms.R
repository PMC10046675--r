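## Published demographic-correction models and classification tables.
##
## The four correction regressions (natural log throughout; gender coded
## 0 = female, 1 = male):
##   SA : 13.796*(ln(86.9 - Age) - 3.628) - 129.5*((1/Edu) - 0.081)
##   OA : -0.00004  * (Age^3 - 129295)
##   FA : -0.000019 * (Age^3 - 129295)
##   Err: 195.11*((1/Age) - 0.0251) - 38.13*((1/Edu) - 0.0812) + 2.6*(Gender - 0.47)
## Adding the correction to the raw index gives the demographically adjusted
## score, which is then classified against the tolerance limits (ITL/OTL),
## equivalent-score cuts and the percentile grid.

published_norms_data <- function() {
  term <- function(predictor, family, coefficient, center, offset = NULL)
    list(predictor = predictor,
         transform = list(family = family, offset = offset),
         coefficient = coefficient, center = center)
  pct_ranks <- c(99, 95, 90, 85, 80, 75, 70, 65, 60, 55, 50, 45, 40, 35,
                 30, 25, 20, 15, 10, 5, 4, 3, 2, 1)
  list(
    version = "published-1.0",
    normative_sample = list(n = 550, age_range = c(20, 79)),
    models = list(
      SA = list(
        terms = list(term("age", "reflected_log", 13.796, 3.628, offset = 86.9),
                     term("education", "inverse", -129.5, 0.081)),
        fit = list(r2 = 0.238, adj_r2 = 0.236, rse = 16.01)),
      OA = list(
        terms = list(term("age", "cube", -0.00004, 129295)),
        fit = list(r2 = 0.041, adj_r2 = 0.039, rse = 23.38)),
      FA = list(
        terms = list(term("age", "cube", -0.000019, 129295)),
        fit = list(r2 = 0.017, adj_r2 = 0.015, rse = 18.11)),
      Err = list(
        terms = list(term("age", "inverse", 195.11, 0.0251),
                     term("education", "inverse", -38.13, 0.0812),
                     term("gender", "identity", 2.6, 0.47)),
        fit = list(r2 = 0.091, adj_r2 = 0.086, rse = 8.83))
    ),
    tables = list(
      SA = list(itl = 90.0, otl = 97.4,
                es_cuts = c(97.4, 74.8, 67.1, 61.5),
                percentile_ranks = pct_ranks,
                percentile_values = c(38.4, 42.2, 45.5, 47.6, 50.7, 52.5, 54,
                                      55.8, 57.4, 59.9, 61.5, 63.1, 65, 67.1,
                                      69.7, 71.6, 74, 77.8, 83.7, 92.5, 96.9,
                                      98, 102.1, 114.1)),
      # The published ES row for OA prints 98.9 / 46.3 where the tolerance
      # table's OTL is 98.8 and the printed median is 46.2; the cuts below
      # use the OTL and the median so that ES 0 <=> pathological and the
      # ES-4 cut equals the 50th percentile, as for the other three indexes.
      OA = list(itl = 86.1, otl = 98.8,
                es_cuts = c(98.8, 67.9, 55.6, 46.2),
                percentile_ranks = pct_ranks,
                percentile_values = c(4.5, 12.9, 22.2, 27.2, 30.2, 34.1, 36.4,
                                      38.2, 41.3, 44.0, 46.2, 48.6, 51.5, 55.1,
                                      58.4, 61.0, 66.7, 72.9, 78.9, 88.5, 95.1,
                                      100.8, 107.7, 120.3)),
      FA = list(itl = 41.0, otl = 49.2,
                es_cuts = c(49.2, 24.8, 15.5, 8.4),
                percentile_ranks = pct_ranks,
                percentile_values = c(-29.3, -13.7, -8.8, -4.9, -2.7, -0.5, 1.4,
                                      2.9, 4.9, 6.4, 8.4, 10.7, 13.5, 15.4,
                                      17.3, 19.6, 23.6, 27.4, 32.8, 44.1, 45.6,
                                      50.9, 56.5, 60.5)),
      Err = list(itl = 29.9, otl = 35.2,
                 es_cuts = c(35.2, 23.1, 18.1, 14.7),
                 percentile_ranks = pct_ranks,
                 percentile_values = c(1.0, 4.3, 6.1, 7.4, 8.3, 9.9, 10.9, 11.9,
                                       12.9, 13.7, 14.7, 15.9, 16.7, 18.0, 19.2,
                                       20.3, 22.6, 24.3, 27.5, 31.3, 33.5, 35.5,
                                       38.1, 45.0))
    )
  )
}

#' Load a BReViS norm set
#'
#' With `source = "published"` returns the published norms: the four
#' demographic-correction regressions plus the tolerance limits,
#' equivalent-score cuts and percentile grids derived from the 550-participant
#' normative sample. A file path loads an alternative norm set written by
#' [write_norms()] or [build_norms()].
#'
#' @param source `"published"` or a path to a JSON norm file.
#' @return an object of class `brevis_norms`.
#' @export
#' @examples
#' nrm <- brevis_norms()
#' correction_score(nrm, "SA", age = 22, education = 8)
brevis_norms <- function(source = "published") {
  if (identical(source, "published")) {
    return(structure(published_norms_data(), class = "brevis_norms"))
  }
  read_norms(source)
}

#' @export
print.brevis_norms <- function(x, ...) {
  cat("BReViS norm set [", x$version, "]\n", sep = "")
  for (ix in names(x$models)) {
    m <- x$models[[ix]]
    preds <- vapply(m$terms, function(t) {
      fam <- t$transform$family
      lbl <- switch(fam, identity = t$predictor,
                    inverse = paste0("1/", t$predictor),
                    cube = paste0(t$predictor, "^3"),
                    square = paste0(t$predictor, "^2"),
                    log = paste0("ln(", t$predictor, ")"),
                    reflected_log = paste0("ln(", t$transform$offset, "-", t$predictor, ")"))
      sprintf("%+g*(%s - %g)", t$coefficient, lbl, t$center)
    }, "")
    cat(sprintf("  %-3s: %s\n", ix, if (length(preds)) paste(preds, collapse = " ") else "(no correction)"))
    if (!is.null(x$tables[[ix]]))
      cat(sprintf("       ITL %.1f | OTL %.1f | ES cuts %s\n",
                  x$tables[[ix]]$itl, x$tables[[ix]]$otl,
                  paste(format(x$tables[[ix]]$es_cuts), collapse = " / ")))
  }
  invisible(x)
}

apply_transform <- function(transform, x) {
  fam <- transform$family
  switch(fam,
    identity = x,
    square = x^2,
    cube = x^3,
    inverse = {
      if (any(x == 0)) stop_brevis("inverse transform undefined at 0")
      1 / x
    },
    log = {
      if (any(x <= 0)) stop_brevis("log transform requires positive values")
      log(x)
    },
    reflected_log = {
      off <- transform$offset
      if (any(x >= off))
        stop_brevis("reflected log ln(", off, " - x) undefined for x >= ", off)
      log(off - x)
    },
    stop_brevis("unknown transform family: ", fam)
  )
}

#' Demographic correction score for one index
#'
#' Evaluates the correction regression of `index`: the sum over its terms of
#' `coefficient * (transform(predictor) - center)`. The correction is added to
#' the raw index to obtain the demographically adjusted score.
#'
#' Ages outside the normative range 20--79 (or education above 21) are allowed
#' but flagged with an extrapolation warning; a hard domain error is raised
#' where a transform is undefined (e.g. age >= 86.9 for the SA log term).
#'
#' @param norms a [brevis_norms()] object.
#' @param index one of `"SA"`, `"OA"`, `"FA"`, `"Err"`.
#' @param age age in years. Vectorized (as are the other demographics).
#' @param education years of formal schooling (>= 1). Ignored by OA/FA.
#' @param gender `"F"`/`"M"` or 0/1 (female/male). Only used by Err.
#' @return numeric vector of corrections, with attribute `extrapolated`
#'   flagging inputs outside the normative demographic range.
#' @export
#' @examples
#' nrm <- brevis_norms()
#' correction_score(nrm, "SA", age = 22, education = 8)        # 1.82
#' correction_score(nrm, "Err", age = 22, education = 8, gender = "M")
correction_score <- function(norms, index, age, education = NULL, gender = NULL) {
  stopifnot(inherits(norms, "brevis_norms"))
  if (!index %in% names(norms$models)) stop_brevis("unknown index: ", index)
  model <- norms$models[[index]]
  if (any(age <= 0)) stop_brevis("age must be positive")
  if (!is.null(education) && any(education < 1))
    stop_brevis("education must be >= 1 year")

  n <- max(length(age), length(education %||% 1), length(gender %||% 1))
  out <- numeric(n)
  for (t in model$terms) {
    x <- switch(t$predictor,
      age = age,
      education = {
        if (is.null(education)) stop_brevis(index, " correction requires education")
        education
      },
      gender = {
        if (is.null(gender)) stop_brevis(index, " correction requires gender")
        as_gender01(gender)
      },
      stop_brevis("unknown predictor: ", t$predictor))
    out <- out + t$coefficient * (apply_transform(t$transform, x) - t$center)
  }
  lo <- norms$normative_sample$age_range[1] %||% 20
  hi <- norms$normative_sample$age_range[2] %||% 79
  extrap <- rep(age < lo | age > hi, length.out = n)
  if (!is.null(education)) extrap <- extrap | rep(education > 21, length.out = n)
  if (any(extrap))
    warning(warningCondition(
      paste0(index, " correction extrapolated outside the normative demographic range"),
      class = "brevis_extrapolation_warning"))
  attr(out, "extrapolated") <- extrap
  out
}

#' Classify an adjusted score against the tolerance limits
#'
#' Scores at or below the inner tolerance limit (ITL) are within normal
#' limits; scores at or above the outer tolerance limit (OTL) are
#' pathological; scores strictly between the limits are borderline. Adjusted
#' values are rounded to one decimal (half away from zero) before lookup so
#' the printed band boundaries are unambiguous.
#'
#' @param norms a [brevis_norms()] object.
#' @param index one of `"SA"`, `"OA"`, `"FA"`, `"Err"`.
#' @param adjusted adjusted score(s).
#' @return character vector: `"within_limits"`, `"borderline"` or
#'   `"pathological"`.
#' @export
classify_tolerance <- function(norms, index, adjusted) {
  tab <- norms$tables[[index]]
  if (is.null(tab)) stop_brevis("no normative table for index: ", index)
  x <- round_half_away(adjusted, 1)
  ifelse(x >= tab$otl, "pathological",
         ifelse(x <= tab$itl, "within_limits", "borderline"))
}

#' Equivalent score (0--4) of an adjusted value
#'
#' Five-level ordinal classification: ES 0 (pathological, at or beyond the
#' outer tolerance limit) to ES 4 (at or better than the sample median).
#' Lower adjusted scores are better, so lower values map to higher ES.
#'
#' @inheritParams classify_tolerance
#' @return integer vector of equivalent scores 0--4.
#' @export
equivalent_score <- function(norms, index, adjusted) {
  tab <- norms$tables[[index]]
  if (is.null(tab)) stop_brevis("no normative table for index: ", index)
  cuts <- tab$es_cuts  # ES0 | ES1 | ES2 | ES3 cut points, descending
  x <- round_half_away(adjusted, 1)
  ifelse(x >= cuts[1], 0L,
    ifelse(x >= cuts[2], 1L,
      ifelse(x >= cuts[3], 2L,
        ifelse(x >= cuts[4], 3L, 4L))))
}

#' Percentile band of an adjusted value
#'
#' Step-function lookup in the published percentile grid (no interpolation):
#' returns the printed percentile rank whose value brackets the adjusted
#' score, as a label such as `"50th percentile"`. Scores better than the 99th
#' percentile entry report `">99th percentile"`, worse than the 1st report
#' `"<1st percentile"`.
#'
#' @inheritParams classify_tolerance
#' @return character vector of percentile labels.
#' @export
percentile_band <- function(norms, index, adjusted) {
  tab <- norms$tables[[index]]
  if (is.null(tab)) stop_brevis("no normative table for index: ", index)
  ranks <- tab$percentile_ranks        # 99 down to 1
  vals <- tab$percentile_values        # ascending (better to worse)
  x <- round_half_away(adjusted, 1)
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < vals[1]) return(">99th percentile")
    if (v > vals[length(vals)]) return("<1st percentile")
    # largest printed rank whose value is >= v (values ascend as ranks fall)
    p <- ranks[which(vals >= v)[1]]
    suffix <- if (p %% 10 == 1 && p != 11) "st" else if (p %% 10 == 2 && p != 12) "nd"
              else if (p %% 10 == 3 && p != 13) "rd" else "th"
    paste0(p, suffix, " percentile")
  }, "")
}

#' Adjust raw indexes for demographics and classify them
#'
#' For each index, computes the demographic correction, adds it to the raw
#' value (`adjusted = raw + correction`), and classifies the adjusted value
#' (tolerance class, equivalent score 0--4, percentile band).
#'
#' @param indexes data frame from [compute_indexes()] (columns `SA`, `OA`,
#'   `FA`, `Err`, `age_years`, `education_years`, `gender`).
#' @param norms a [brevis_norms()] object (default: published norms).
#' @return the input with, per index `<ix>`, columns `corr_<ix>`, `adj_<ix>`,
#'   `es_<ix>`, `tol_<ix>`, `pct_<ix>`, plus a logical `extrapolated` flag.
#' @export
adjust_scores <- function(indexes, norms = brevis_norms()) {
  out <- indexes
  extrap <- rep(FALSE, nrow(indexes))
  for (ix in index_names()) {
    corr <- correction_score(norms, ix, age = indexes$age_years,
                             education = indexes$education_years,
                             gender = indexes$gender)
    extrap <- extrap | attr(corr, "extrapolated")
    adj <- indexes[[ix]] + as.numeric(corr)
    out[[paste0("corr_", ix)]] <- as.numeric(corr)
    out[[paste0("adj_", ix)]] <- adj
    out[[paste0("es_", ix)]] <- equivalent_score(norms, ix, adj)
    out[[paste0("tol_", ix)]] <- classify_tolerance(norms, ix, adj)
    out[[paste0("pct_", ix)]] <- percentile_band(norms, ix, adj)
  }
  out$extrapolated <- extrap
  out
}

#' Score a cohort end to end
#'
#' Convenience wrapper: [compute_indexes()] then [adjust_scores()]. Returns a
#' `brevis_report` whose `summary()` tabulates equivalent-score levels per
#' index (ES 0 = pathological).
#'
#' @param cohort long-format cohort data frame (see [read_cohort()]).
#' @param norms a [brevis_norms()] object.
#' @return data frame of class `brevis_report`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 20, seed = 7))$cohort
#' rep <- score_brevis(coh)
#' summary(rep)
score_brevis <- function(cohort, norms = brevis_norms()) {
  rep <- adjust_scores(compute_indexes(cohort), norms)
  attr(rep, "norms_version") <- norms$version
  class(rep) <- c("brevis_report", class(rep))
  rep
}

#' @export
summary.brevis_report <- function(object, ...) {
  counts <- sapply(index_names(), function(ix)
    tabulate(object[[paste0("es_", ix)]] + 1L, nbins = 5L))
  rownames(counts) <- paste0("ES", 0:4)
  structure(list(n = nrow(object), es_counts = t(counts),
                 norms_version = attr(object, "norms_version")),
            class = "summary.brevis_report")
}

#' @export
print.summary.brevis_report <- function(x, ...) {
  cat("BReViS score report:", x$n, "participant(s), norms", x$norms_version, "\n")
  cat("Equivalent-score counts (ES0 = pathological):\n")
  print(x$es_counts)
  invisible(x)
}

#' Correction grid over demographic levels
#'
#' Evaluates the correction regression of an index on a grid of demographic
#' levels and rounds half away from zero to one decimal, reproducing the
#' published quick-scoring grids. Defaults are the published levels
#' (ages 22--77 in steps of 5; educations 8, 13, 16, 18, 21).
#'
#' @param norms a [brevis_norms()] object.
#' @param index one of `"SA"`, `"OA"`, `"FA"`, `"Err"`.
#' @param ages,educations,genders grid levels; `educations`/`genders` are
#'   ignored by indexes whose model does not use them.
#' @return data frame with one row per grid cell and a rounded `correction`
#'   column.
#' @export
#' @examples
#' g <- build_correction_grid(brevis_norms(), "SA")
#' g[g$age == 22 & g$education == 8, ]  # 1.8
build_correction_grid <- function(norms, index,
                                  ages = seq(22, 77, by = 5),
                                  educations = c(8, 13, 16, 18, 21),
                                  genders = c("F", "M")) {
  preds <- vapply(norms$models[[index]]$terms, function(t) t$predictor, "")
  grid <- expand.grid(
    age = ages,
    education = if ("education" %in% preds) educations else NA,
    gender = if ("gender" %in% preds) genders else NA,
    stringsAsFactors = FALSE)
  corr <- withCallingHandlers(
    correction_score(norms, index, age = grid$age,
                     education = if ("education" %in% preds) grid$education,
                     gender = if ("gender" %in% preds) grid$gender),
    brevis_extrapolation_warning = function(w) invokeRestart("muffleWarning"))
  grid$correction <- round_half_away(as.numeric(corr), 1)
  grid
}
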