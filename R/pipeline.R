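## Regression-based norming pipeline: outlier filtering, AICc-driven
## transformation and model selection, reversed-coefficient correction
## regressions, nonparametric tolerance limits, equivalent scores and
## percentiles.

#' Filter extreme outliers by the 3 x IQR rule
#'
#' For each card, the threshold is the third quartile plus three times the
#' interquartile range of that card's performance times over the whole
#' cohort (quartiles by linear interpolation between order statistics,
#' `stats::quantile` type 7). Any participant whose performance time on at
#' least one card is at or above its card's threshold is removed casewise.
#' Thresholds are computed once, on the input cohort (single pass); set
#' `recompute = TRUE` to iterate until no removals occur.
#'
#' @param cohort long-format cohort data frame (see [read_cohort()]).
#' @param recompute recompute thresholds on the retained set and repeat until
#'   stable (default `FALSE`, single pass).
#' @return list with `retained` (filtered cohort), `removed_ids`,
#'   `thresholds` (per card) and `quantile_type` metadata.
#' @export
filter_outliers <- function(cohort, recompute = FALSE) {
  validate_cohort(cohort)
  pass <- function(coh) {
    thr <- vapply(1:4, function(k) {
      rows <- coh[coh$card == k, ]
      pt <- performance_time(rows$execution_time_s, rows$omissions)
      q <- quantile(pt, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      if (iqr == 0) {
        warning(warningCondition(
          paste0("card ", k, ": degenerate performance-time distribution (IQR = 0); no removals on this card"),
          class = "brevis_degenerate_warning"))
        return(Inf)
      }
      q[2] + 3 * iqr
    }, 0)
    bad <- character(0)
    for (k in 1:4) {
      rows <- coh[coh$card == k, ]
      pt <- performance_time(rows$execution_time_s, rows$omissions)
      bad <- union(bad, rows$participant_id[pt >= thr[k]])
    }
    list(retained = coh[!coh$participant_id %in% bad, ], removed = bad, thr = thr)
  }
  res <- pass(cohort)
  removed <- res$removed
  if (recompute) {
    while (length(res$removed) > 0) {
      res <- pass(res$retained)
      removed <- union(removed, res$removed)
    }
  }
  list(retained = res$retained, removed_ids = removed,
       thresholds = setNames(res$thr, paste0("card", 1:4)),
       quantile_type = 7L)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2*LL + 2k + 2k(k+1)/(n-k-1)`, where `k` counts all estimated
#' parameters (intercept, slopes and the residual variance, so a
#' one-predictor Gaussian regression has `k = 3`).
#'
#' @param log_likelihood model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
#' @examples
#' aicc(-2512.9, k = 3, n = 550)
aicc <- function(log_likelihood, k, n) {
  if (any(n <= k + 1)) stop_brevis("AICc requires n > k + 1")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

gaussian_ll_from_rss <- function(rss, n) -n / 2 * (log(2 * pi) + log(rss / n) + 1)

transform_candidates <- function(predictor) {
  if (predictor == "age")
    list(list(family = "identity"), list(family = "square"),
         list(family = "cube"), list(family = "inverse"),
         list(family = "log"), list(family = "reflected_log"))
  else
    list(list(family = "identity"), list(family = "inverse"),
         list(family = "log"))
}

# RSS of a simple linear regression of y on x, vectorized over nothing fancy
simple_rss <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy - sxy^2 / sxx
}

#' Select the best predictor transformation by AICc
#'
#' Fits one bivariate Gaussian regression of the raw index on each candidate
#' transform of the predictor and returns the transform with the lowest AICc.
#' Candidates for age: identity, square, cube, inverse, natural log and
#' reflected log `ln(c - x)`; for education: identity, inverse, natural log.
#' The reflected-log offset `c` is profiled over
#' `max(x) + 0.1 ... max(x) + 25` in steps of 0.1 and the best-offset fit
#' represents the family.
#'
#' @param indexes data frame of scored participants (from [compute_indexes()]).
#' @param predictor `"age"` or `"education"`.
#' @param index the index column to model (`"SA"`, `"OA"`, `"FA"`, `"Err"`).
#' @param candidates optional character vector restricting the candidate
#'   families (default: the full set for the predictor).
#' @return list with `family`, `offset` (reflected log only) and an
#'   `aicc_table` of all candidates.
#' @export
select_transform <- function(indexes, predictor = c("age", "education"),
                             index = index_names(), candidates = NULL) {
  predictor <- match.arg(predictor)
  index <- match.arg(index)
  x <- indexes[[paste0(predictor, "_years")]]
  y <- indexes[[index]]
  n <- length(y)
  if (sd(x) == 0) {
    warning(warningCondition(paste0("degenerate predictor ", predictor,
                                    ": constant across the cohort"),
                             class = "brevis_degenerate_warning"))
    return(list(family = "identity", offset = NULL, aicc_table = NULL))
  }
  cands <- transform_candidates(predictor)
  if (!is.null(candidates))
    cands <- Filter(function(c) c$family %in% candidates, cands)
  if (!length(cands)) stop_brevis("no candidate transforms left after restriction")
  rows <- list()
  for (cand in cands) {
    if (cand$family == "reflected_log") {
      offsets <- seq(max(x) + 0.1, max(x) + 25, by = 0.1)
      rss <- vapply(offsets, function(off) simple_rss(log(off - x), y), 0)
      best <- which.min(rss)
      cand$offset <- offsets[best]
      r <- rss[best]
    } else {
      xt <- tryCatch(apply_transform(cand, x), error = function(e) NULL)
      r <- if (is.null(xt)) NA_real_ else simple_rss(xt, y)
    }
    if (!is.finite(r)) {
      warning(warningCondition(paste0("singular fit for transform ", cand$family,
                                      " of ", predictor, "; excluded"),
                               class = "brevis_fit_warning"))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      family = cand$family, offset = cand$offset %||% NA_real_,
      aicc = aicc(gaussian_ll_from_rss(r, n), k = 3, n = n))
  }
  if (!length(rows)) stop_brevis("all candidate transforms failed for ", predictor)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), ]
  best <- tab[1, ]
  list(family = best$family,
       offset = if (is.na(best$offset)) NULL else best$offset,
       aicc_table = tab)
}

transformed_design <- function(indexes, transforms) {
  out <- data.frame(row.names = seq_len(nrow(indexes)))
  out$age <- apply_transform(transforms$age, indexes$age_years)
  out$education <- apply_transform(transforms$education %||% list(family = "identity"),
                                   indexes$education_years)
  out$gender <- as_gender01(indexes$gender)
  out
}

#' Select the demographic model by AICc with a parsimony rule
#'
#' Fits the seven non-empty subsets of {age, education, gender} (predictors in
#' their chosen transformations, gender untransformed 0/1) and ranks them by
#' AICc. If a model nested in the AICc-best model lies within `delta < 2`, the
#' model with fewer predictors is preferred. The chosen model must pass the
#' overall regression F-test at `p < 0.05`; otherwise no correction is
#' warranted and an empty model is returned.
#'
#' @param indexes data frame of scored participants.
#' @param index the index column to model.
#' @param transforms list with elements `age` and `education`, each a
#'   transform spec as returned by [select_transform()].
#' @return list of class `brevis_model_selection`: `chosen` (character vector
#'   of predictors, possibly empty), `p_value`, and `table` mirroring the
#'   published model-comparison layout (K, AICc, Delta_AICc, ModelLik,
#'   AICcWt, LL, Cum.Wt).
#' @export
select_model <- function(indexes, index, transforms) {
  y <- indexes[[index]]
  n <- length(y)
  X <- transformed_design(indexes, transforms)
  subsets <- list("age", "education", "gender",
                  c("age", "education"), c("age", "gender"),
                  c("education", "gender"), c("age", "education", "gender"))
  rows <- lapply(subsets, function(pr) {
    dat <- cbind(y = y, X[, pr, drop = FALSE])
    fit <- lm(y ~ ., data = dat)
    if (any(is.na(coef(fit))))
      warning(warningCondition(paste0("collinear predictors in model {",
                                      paste(pr, collapse = ", "), "}"),
                               class = "brevis_fit_warning"))
    k <- length(pr) + 2  # intercept + slopes + residual variance
    ll <- gaussian_ll_from_rss(sum(fit$residuals^2), n)
    fs <- summary(fit)$fstatistic
    data.frame(model = paste(pr, collapse = " + "), npred = length(pr),
               K = k, AICc = aicc(ll, k, n), LL = ll,
               p_value = pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AICc), ]
  tab$Delta_AICc <- tab$AICc - tab$AICc[1]
  tab$ModelLik <- exp(-tab$Delta_AICc / 2)
  tab$AICcWt <- tab$ModelLik / sum(tab$ModelLik)
  tab$Cum.Wt <- cumsum(tab$AICcWt)
  rownames(tab) <- NULL

  best_preds <- strsplit(tab$model[1], " \\+ ")[[1]]
  nested <- vapply(seq_len(nrow(tab)), function(i) {
    pr <- strsplit(tab$model[i], " \\+ ")[[1]]
    all(pr %in% best_preds) && tab$Delta_AICc[i] < 2
  }, TRUE)
  cand <- tab[nested, ]
  chosen_row <- cand[order(cand$npred, cand$AICc), ][1, ]
  chosen <- strsplit(chosen_row$model, " \\+ ")[[1]]
  if (chosen_row$p_value >= 0.05) chosen <- character(0)

  structure(list(index = index, chosen = chosen, p_value = chosen_row$p_value,
                 transforms = transforms,
                 table = tab[, c("model", "K", "AICc", "Delta_AICc",
                                 "ModelLik", "AICcWt", "LL", "Cum.Wt", "p_value")]),
            class = "brevis_model_selection")
}

#' @export
print.brevis_model_selection <- function(x, ...) {
  cat("Model selection for", x$index, "- chosen:",
      if (length(x$chosen)) paste(x$chosen, collapse = " + ") else "(no correction)",
      sprintf("(F-test p = %.3g)\n", x$p_value))
  print(x$table, digits = 6)
  invisible(x)
}

#' Fit the correction regression for one index
#'
#' Centers each transformed predictor at its cohort mean (the means become
#' the centering constants) and the raw index at its mean, fits ordinary
#' least squares, and reverses the signs of the slopes. The reversed
#' coefficients define the correction equation: evaluated at the cohort mean
#' demographics the correction is 0 by construction, and adding it to a raw
#' score removes the fitted demographic gradient.
#'
#' @param indexes data frame of scored participants.
#' @param index the index column to model.
#' @param predictors character vector of predictors (subset of
#'   age/education/gender), e.g. the `chosen` element of [select_model()].
#' @param transforms list with transform specs for `age` and `education`.
#' @return list of class `brevis_correction_model`: `model` (term list in the
#'   same format as [brevis_norms()] models, with `fit` metadata R^2,
#'   adjusted R^2 and residual standard error), `coef_ci` (95% confidence
#'   intervals of the reversed coefficients) and the underlying `lm` fit.
#' @export
fit_correction_regression <- function(indexes, index, predictors, transforms) {
  if (!length(predictors)) stop_brevis("cannot fit an empty correction model")
  y <- indexes[[index]]
  X <- transformed_design(indexes, transforms)[, predictors, drop = FALSE]
  centers <- colMeans(X)
  Xc <- sweep(as.matrix(X), 2, centers)
  dat <- data.frame(y = y - mean(y), Xc)
  fit <- lm(y ~ ., data = dat)
  sm <- summary(fit)
  slopes <- coef(fit)[-1]
  ci <- -confint(fit, level = 0.95)[-1, c(2, 1), drop = FALSE]
  colnames(ci) <- c("lwr", "upr")

  terms <- lapply(predictors, function(p) {
    tr <- if (p == "gender") list(family = "identity")
          else transforms[[p]] %||% list(family = "identity")
    list(predictor = p,
         transform = list(family = tr$family, offset = tr$offset %||% NULL),
         coefficient = unname(-slopes[p]),
         center = unname(centers[p]))
  })
  structure(list(
    index = index,
    model = list(terms = terms,
                 fit = list(r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                            rse = sm$sigma)),
    coef_ci = ci, lm = fit), class = "brevis_correction_model")
}

# evaluate a term-list correction model on demographics (internal; the
# exported surface is correction_score() on a brevis_norms object)
eval_correction_model <- function(model, age, education, gender01) {
  out <- 0
  for (t in model$terms) {
    x <- switch(t$predictor, age = age, education = education, gender = gender01)
    out <- out + t$coefficient * (apply_transform(t$transform, x) - t$center)
  }
  out
}

#' Order-statistic ranks of nonparametric one-sided tolerance limits
#'
#' With scores ordered ascending (lower = better), the outer limit rank is
#' the smallest `m` such that `P(Binomial(n, content) <= m - 1) >= confidence`
#' (the m-th order statistic exceeds the `content` quantile with at least
#' `confidence` probability) and the inner limit rank is the smallest `m`
#' with that CDF at least `1 - confidence`. For `n = 550`, content 0.95 and
#' confidence 0.95 these are the 515th and 532nd ordered observations.
#'
#' @param n sample size.
#' @param content covered proportion (default 0.95).
#' @param confidence confidence level (default 0.95).
#' @return list with `inner_rank` and `outer_rank`; a rank is `NA` (not
#'   computable at this `n`) when it would exceed `n`.
#' @export
#' @examples
#' tolerance_ranks(550)  # 515, 532
tolerance_ranks <- function(n, content = 0.95, confidence = 0.95) {
  if (n < 1) stop_brevis("n must be >= 1")
  # qbinom(p, n, c) is the smallest x with CDF >= p, i.e. m - 1
  inner <- stats::qbinom(1 - confidence, n, content) + 1
  outer <- stats::qbinom(confidence, n, content) + 1
  if (pbinom(outer - 1, n, content) < confidence || outer > n) outer <- NA_integer_
  if (inner > n) inner <- NA_integer_
  list(inner_rank = as.integer(inner), outer_rank = as.integer(outer))
}

normal_tolerance_factor <- function(n, content, confidence) {
  qt(confidence, df = n - 1, ncp = qnorm(content) * sqrt(n)) / sqrt(n)
}

#' One-sided tolerance limits of adjusted scores
#'
#' Tests the adjusted scores for normality (Shapiro-Wilk, alpha = 0.05). If
#' normality is rejected -- the usual case for right-skewed time scores --
#' the inner and outer limits are the order statistics at the
#' [tolerance_ranks()] ranks; otherwise normal-theory one-sided tolerance
#' bounds `mean + k * sd` are used. Higher scores are worse throughout.
#'
#' @param adjusted numeric vector of adjusted scores.
#' @param content covered proportion (default 0.95).
#' @param confidence confidence level (default 0.95).
#' @param method `"auto"` (Shapiro-Wilk gate), `"nonparametric"` or
#'   `"parametric"`.
#' @return list with `itl`, `otl`, `borderline` (the band between them at
#'   one-decimal resolution), `method` used, `normality_p` and `ranks`.
#' @export
tolerance_limits <- function(adjusted, content = 0.95, confidence = 0.95,
                             method = c("auto", "nonparametric", "parametric")) {
  method <- match.arg(method)
  n <- length(adjusted)
  p_norm <- if (n >= 3 && n <= 5000) shapiro.test(adjusted)$p.value else NA_real_
  if (method == "auto")
    method <- if (!is.na(p_norm) && p_norm >= 0.05) "parametric" else "nonparametric"

  if (method == "nonparametric") {
    rk <- tolerance_ranks(n, content, confidence)
    xs <- sort(adjusted)
    itl <- if (is.na(rk$inner_rank)) NA_real_ else xs[rk$inner_rank]
    otl <- if (is.na(rk$outer_rank)) NA_real_ else xs[rk$outer_rank]
  } else {
    rk <- list(inner_rank = NA_integer_, outer_rank = NA_integer_)
    m <- mean(adjusted); s <- sd(adjusted)
    itl <- m + normal_tolerance_factor(n, content, 1 - confidence) * s
    otl <- m + normal_tolerance_factor(n, content, confidence) * s
  }
  borderline <- if (is.na(itl) || is.na(otl)) c(NA_real_, NA_real_) else
    c(round_half_away(itl, 1) + 0.1, round_half_away(otl, 1) - 0.1)
  list(itl = itl, otl = otl, borderline = borderline, method = method,
       normality_p = p_norm, ranks = rk)
}

#' Equivalent-score cut points from adjusted scores
#'
#' ES 0 begins at the outer tolerance limit; ES 4 is bounded by the sample
#' median; the ES1/ES2 and ES2/ES3 cuts are the order statistics at the 0.80
#' and 0.65 cumulative proportions of the ascending scores, giving three
#' equal 15%-probability bands between the 5% worse tail and the median.
#'
#' @param adjusted numeric vector of adjusted scores (lower = better).
#' @param otl the outer tolerance limit (from [tolerance_limits()]).
#' @param probs cumulative proportions of the two intermediate cuts
#'   (default `c(0.80, 0.65)`).
#' @return numeric vector of four descending cut points (ES0, ES1/2, ES2/3,
#'   ES3/4) as used by [equivalent_score()].
#' @export
derive_equivalent_scores <- function(adjusted, otl, probs = c(0.80, 0.65)) {
  if (length(adjusted) < 20) stop_brevis("need at least 20 scores to place ES cuts")
  mid <- quantile(adjusted, probs, type = 1, names = FALSE)  # order statistics
  med <- quantile(adjusted, 0.5, type = 7, names = FALSE)    # sample median
  c(otl, mid[1], mid[2], med)
}

#' Percentile grid of adjusted scores
#'
#' The value at percentile rank `p` is the empirical quantile of the
#' ascending scores at cumulative proportion `1 - p/100`, so `p` is the
#' fraction of the sample performing worse (higher). Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param adjusted numeric vector of adjusted scores.
#' @param ranks percentile ranks to tabulate (default the published grid,
#'   99, 95, 90, ..., 5, 4, 3, 2, 1).
#' @return data frame with columns `rank` and `value`.
#' @export
derive_percentiles <- function(adjusted,
                               ranks = c(99, seq(95, 5, by = -5), 4, 3, 2, 1)) {
  data.frame(rank = ranks,
             value = quantile(adjusted, 1 - ranks / 100, type = 7, names = FALSE))
}

#' Build a norm set from a raw cohort
#'
#' Runs the full regression-based norming pipeline: 3 x IQR outlier
#' filtering, per-predictor transformation selection by AICc, demographic
#' model selection with the parsimony rule, reversed-coefficient correction
#' regression, demographic adjustment, tolerance limits, equivalent-score
#' cuts and the percentile grid, for each of the four indexes.
#'
#' @param cohort long-format cohort data frame (see [read_cohort()]).
#' @param content,confidence tolerance-limit parameters (defaults 0.95/0.95).
#' @param version label stored in the resulting norm set.
#' @return list of class `brevis_norming`: `norms` (a [brevis_norms()]
#'   object usable by [score_brevis()]), `selection` (per-index model
#'   selection tables), `transforms`, `filter` (outlier-filter report) and
#'   `n` (normative sample size after filtering).
#' @export
build_norms <- function(cohort, content = 0.95, confidence = 0.95,
                        version = "custom-1.0") {
  flt <- filter_outliers(cohort)
  idx <- compute_indexes(flt$retained)
  n <- nrow(idx)

  models <- list(); tables <- list(); selection <- list(); transforms_all <- list()
  for (ix in index_names()) {
    tr <- list(age = select_transform(idx, "age", ix),
               education = select_transform(idx, "education", ix))
    sel <- select_model(idx, ix, tr)
    if (length(sel$chosen)) {
      cm <- fit_correction_regression(idx, ix, sel$chosen, tr)
      models[[ix]] <- cm$model
      corr <- eval_correction_model(cm$model, idx$age_years,
                                    idx$education_years, as_gender01(idx$gender))
    } else {
      models[[ix]] <- list(terms = list(), fit = list(r2 = 0, adj_r2 = 0, rse = sd(idx[[ix]])))
      corr <- rep(0, n)
    }
    adj <- idx[[ix]] + corr
    tl <- tolerance_limits(adj, content, confidence)
    pct <- derive_percentiles(adj)
    tables[[ix]] <- list(
      itl = tl$itl, otl = tl$otl,
      es_cuts = as.numeric(derive_equivalent_scores(adj, tl$otl)),
      percentile_ranks = pct$rank, percentile_values = pct$value,
      tolerance_method = tl$method, normality_p = tl$normality_p)
    selection[[ix]] <- sel
    transforms_all[[ix]] <- tr
  }

  norms <- structure(list(version = version,
                          normative_sample = list(n = n, age_range = range(idx$age_years)),
                          models = models, tables = tables),
                     class = "brevis_norms")
  structure(list(norms = norms, selection = selection, transforms = transforms_all,
                 filter = flt[c("removed_ids", "thresholds", "quantile_type")],
                 n = n),
            class = "brevis_norming")
}

#' @export
print.brevis_norming <- function(x, ...) {
  cat("BReViS norming run: n =", x$n, "after removing",
      length(x$filter$removed_ids), "outlier(s)\n")
  for (ix in names(x$selection)) {
    sel <- x$selection[[ix]]
    cat(sprintf("  %-3s: %s\n", ix,
                if (length(sel$chosen)) paste(sel$chosen, collapse = " + ")
                else "(no correction)"))
  }
  print(x$norms)
  invisible(x)
}
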