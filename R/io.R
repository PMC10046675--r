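#' Read a cohort file
#'
#' Reads a comma-separated cohort file (UTF-8, header row, "." decimal
#' separator regardless of locale). The native layout is long format, one row
#' per participant x card, with columns `participant_id`, `age_years`,
#' `education_years`, `gender` (F/M), `card` (1-4), `execution_time_s`,
#' `omissions`, `substitutions`, `autocorrections`. A wide layout (columns
#' `execution_time_1`..`4`, `omissions_1`..`4`, etc.) is auto-detected and
#' reshaped. Malformed rows are reported with their line numbers.
#'
#' @param path path to the CSV file.
#' @return validated long-format cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_brevis("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"card" %in% names(df) && any(grepl("^execution_time_[1-4]$", names(df)))) {
    long <- lapply(1:4, function(k) {
      cols <- paste0(c("execution_time_", "omissions_", "substitutions_",
                       "autocorrections_"), k)
      miss <- setdiff(cols, names(df))
      if (length(miss)) stop_brevis("wide cohort file missing columns: ",
                                    paste(miss, collapse = ", "))
      data.frame(participant_id = df$participant_id,
                 age_years = df$age_years,
                 education_years = df$education_years,
                 gender = df$gender, card = k,
                 execution_time_s = df[[cols[1]]],
                 omissions = df[[cols[2]]],
                 substitutions = df[[cols[3]]],
                 autocorrections = df[[cols[4]]],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, long)
  }
  num_cols <- c("age_years", "education_years", "card", "execution_time_s",
                "omissions", "substitutions", "autocorrections")
  for (cl in intersect(num_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && !all(is.na(df[[cl]]) == is.na(v))) {
      bad <- which(is.na(v) & !is.na(df[[cl]])) + 1L  # +1 for the header line
      stop_brevis("non-numeric values in column '", cl, "' at line(s) ",
                  paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[cl]] <- v
  }
  validate_cohort(df)
  df[order(df$participant_id, df$card), , drop = FALSE]
}

#' Write a cohort file
#'
#' @param cohort long-format cohort data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a norm set to a JSON norm file
#'
#' Serializes a [brevis_norms()] object to a human-readable, versioned JSON
#' file (one document per index: transforms, reversed coefficients, centering
#' constants, tolerance limits, equivalent-score cuts, percentile grid) that
#' [read_norms()] and `brevis_norms(path)` can load.
#'
#' @param norms a `brevis_norms` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "brevis_norms"))
  jsonlite::write_json(unclass(norms), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a norm set from a JSON norm file
#'
#' @param path path to a norm file written by [write_norms()].
#' @return a `brevis_norms` object.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop_brevis("norm file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  norms <- list(
    version = raw$version,
    normative_sample = list(n = raw$normative_sample$n,
                            age_range = unlist(raw$normative_sample$age_range)),
    models = lapply(raw$models, function(m) list(
      terms = lapply(m$terms, function(t) list(
        predictor = t$predictor,
        transform = list(family = t$transform$family,
                         offset = t$transform$offset %||% NULL),
        coefficient = t$coefficient,
        center = t$center)),
      fit = lapply(m$fit, function(v) v %||% NA_real_))),
    tables = lapply(raw$tables, function(tb) {
      out <- list(itl = tb$itl, otl = tb$otl,
                  es_cuts = unlist(tb$es_cuts),
                  percentile_ranks = unlist(tb$percentile_ranks),
                  percentile_values = unlist(tb$percentile_values))
      out$tolerance_method <- tb$tolerance_method %||% NULL
      out$normality_p <- tb$normality_p %||% NULL
      out
    }))
  structure(norms, class = "brevis_norms")
}

#' Write a score report
#'
#' Writes the per-participant report produced by [score_brevis()] either as
#' CSV (seconds-valued quantities rounded to one decimal, matching the
#' published table precision) or as JSON (full precision plus the cohort
#' equivalent-score summary).
#'
#' @param report a `brevis_report` from [score_brevis()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  sec_cols <- grep("^(P[1-4]|SA|OA|FA|corr_|adj_)", names(df), value = TRUE)
  sec_cols <- setdiff(sec_cols, c("corr_Err", "adj_Err"))
  for (cl in sec_cols) df[[cl]] <- round_half_away(df[[cl]], 1)
  df$corr_Err <- round_half_away(df$corr_Err, 1)
  df$adj_Err <- round_half_away(df$adj_Err, 1)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    es <- summary(report)$es_counts
    jsonlite::write_json(
      list(norms_version = attr(report, "norms_version"),
           n = nrow(df),
           es_summary = as.data.frame(cbind(index = rownames(es), as.data.frame(es))),
           participants = df),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
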