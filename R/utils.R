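#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used by the published correction grids (e.g. -0.45 rounds to
#' -0.5, not -0.4 as banker's rounding would give).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the grids' resolution).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.25, -0.45, 1.84), 1)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  # tiny epsilon guards values like 2.25 stored as 2.2499999...96
  as.vector(sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p)
}

index_names <- function() c("SA", "OA", "FA", "Err")

stop_brevis <- function(..., class = "brevis_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_gender01 <- function(gender) {
  if (is.numeric(gender)) {
    if (!all(gender %in% c(0, 1))) stop_brevis("numeric gender must be 0 (female) or 1 (male)")
    return(as.numeric(gender))
  }
  g <- toupper(trimws(as.character(gender)))
  out <- ifelse(g %in% c("F", "FEMALE"), 0,
         ifelse(g %in% c("M", "MALE"), 1, NA_real_))
  if (anyNA(out)) stop_brevis("gender must be F or M (got: ",
                              paste(unique(gender[is.na(out)]), collapse = ", "), ")")
  out
}
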