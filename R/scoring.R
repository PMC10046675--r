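#' Performance time for one card
#'
#' Inflates the raw execution time for missed targets. Each card has 25
#' targets; a participant who misses `omissions` of them effectively searched
#' only `25 - omissions` targets in `execution_time` seconds, so
#' `performance_time = 25 * execution_time / (25 - omissions)`.
#'
#' @param execution_time execution time in seconds (> 0). Vectorized.
#' @param omissions number of targets not crossed out, 0--24. A card with all
#'   25 targets missed is unscoreable and raises an error.
#' @param card_id optional card identifier used in error messages.
#' @return performance time in seconds; equals `execution_time` iff
#'   `omissions == 0`.
#' @export
#' @examples
#' performance_time(60, 5)  # 75
performance_time <- function(execution_time, omissions, card_id = NULL) {
  if (any(!is.finite(execution_time)) || any(execution_time <= 0))
    stop_brevis("execution_time must be positive")
  if (any(!is.finite(omissions)) || any(omissions < 0) || any(omissions > 25) ||
      any(omissions != trunc(omissions)))
    stop_brevis("omissions must be an integer in 0..25")
  if (any(omissions == 25)) {
    bad <- if (!is.null(card_id)) paste0(" (card ", paste(card_id[omissions == 25], collapse = ","), ")") else ""
    stop_brevis("card with 25 omissions is unscoreable", bad,
                class = "brevis_scoring_error")
  }
  25 * execution_time / (25 - omissions)
}

validate_cohort <- function(cohort) {
  need <- c("participant_id", "age_years", "education_years", "gender",
            "card", "execution_time_s", "omissions", "substitutions",
            "autocorrections")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_brevis("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$card %in% 1:4)) stop_brevis("card must be 1, 2, 3 or 4")
  tab <- table(cohort$participant_id, factor(cohort$card, levels = 1:4))
  if (any(tab > 1)) {
    bad <- rownames(tab)[rowSums(tab > 1) > 0]
    stop_brevis("duplicate participant x card rows for: ", paste(bad, collapse = ", "))
  }
  if (any(tab == 0)) {
    i <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop_brevis("participant ", rownames(tab)[i[1]], ": missing card ", colnames(tab)[i[2]])
  }
  if (any(cohort$education_years < 1)) stop_brevis("education_years must be >= 1")
  if (any(cohort$substitutions < 0) || any(cohort$autocorrections < 0))
    stop_brevis("error counts must be non-negative")
  invisible(cohort)
}

#' Compute the four BReViS indexes for a cohort
#'
#' Takes a long-format cohort (one row per participant x card, as read by
#' [read_cohort()] or produced by [generate_cohort()]) and returns one row per
#' participant with the per-card performance times and the four indexes.
#'
#' Letting `P1..P4` be the performance times of cards 1--4
#' (1 = linear/low crowding, 2 = linear/high, 3 = random/low, 4 = random/high):
#' `SA = P1`, `OA = (P3 + P4)/2 - (P1 + P2)/2`, `FA = (P2 + P4)/2 - (P1 + P3)/2`,
#' and `Err` is the sum of omissions and substitutions over all cards
#' (autocorrections are tallied separately as `autocorrections`, not counted
#' as errors: the participant self-corrected).
#'
#' @param cohort data frame with columns `participant_id`, `age_years`,
#'   `education_years`, `gender` (F/M), `card` (1--4), `execution_time_s`,
#'   `omissions`, `substitutions`, `autocorrections`.
#' @return data frame with one row per participant: demographics, `P1`..`P4`,
#'   `SA`, `OA`, `FA`, `Err`, `autocorrections`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 5, seed = 1))$cohort
#' compute_indexes(coh)
compute_indexes <- function(cohort) {
  validate_cohort(cohort)
  cohort <- cohort[order(cohort$participant_id, cohort$card), ]
  ids <- unique(cohort$participant_id)
  first <- cohort[cohort$card == 1, ]
  first <- first[match(ids, first$participant_id), ]

  pt <- matrix(NA_real_, nrow = length(ids), ncol = 4,
               dimnames = list(NULL, paste0("P", 1:4)))
  err <- auto <- numeric(length(ids))
  for (k in 1:4) {
    rows <- cohort[cohort$card == k, ]
    rows <- rows[match(ids, rows$participant_id), ]
    if (any(rows$omissions == 25)) {
      bad <- rows$participant_id[rows$omissions == 25][1]
      stop_brevis("participant ", bad, ": card ", k,
                  " has 25 omissions and cannot be scored",
                  class = "brevis_scoring_error")
    }
    pt[, k] <- performance_time(rows$execution_time_s, rows$omissions)
    err <- err + rows$omissions + rows$substitutions
    auto <- auto + rows$autocorrections
  }

  data.frame(
    participant_id = ids,
    age_years = first$age_years,
    education_years = first$education_years,
    gender = first$gender,
    P1 = pt[, 1], P2 = pt[, 2], P3 = pt[, 3], P4 = pt[, 4],
    SA = pt[, 1],
    OA = (pt[, 3] + pt[, 4]) / 2 - (pt[, 1] + pt[, 2]) / 2,
    FA = (pt[, 2] + pt[, 4]) / 2 - (pt[, 1] + pt[, 3]) / 2,
    Err = err,
    autocorrections = auto,
    stringsAsFactors = FALSE
  )
}
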