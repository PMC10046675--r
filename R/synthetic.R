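## Synthetic normative cohorts. The generator emulates the published
## normative sample: its demographic structure (gender x age-decade x
## education-band cell counts), the demographic dependence of the four
## indexes (the published correction models, inverted: raw index =
## baseline - correction + noise, so applying the published correction
## recenters scores), right-skewed residuals, and the card-level
## decomposition of each index.

# gender x decade x education-band cell counts of the normative sample
demographic_table_default <- function() {
  decades <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
  bands <- c("0-5", "6-8", "9-13", ">13")
  counts <- rbind(  # bands x (F,M per decade)
    "0-5"  = c(0, 0,  0, 0,  0, 1,  0, 0,  0, 3,  6, 2),
    "6-8"  = c(0, 0,  2, 5,  3, 5,  3, 9,  9, 6, 10, 10),
    "9-13" = c(11, 12, 16, 20, 25, 21, 34, 22, 19, 20, 4, 10),
    ">13"  = c(55, 30, 34, 32, 33, 19, 22, 15, 5, 9, 3, 5))
  data.frame(
    band = rep(bands, each = 12),
    decade = rep(rep(decades, each = 2), times = 4),
    gender = rep(c("F", "M"), times = 24),
    count = as.vector(t(counts)),
    stringsAsFactors = FALSE)
}

# per-decade index means of the normative sample; the generator's baseline
# intercepts are their weighted grand means
index_decade_means <- function() {
  m <- rbind(SA = c(54.5, 57.7, 59.6, 66.7, 74.8, 79.9),
             OA = c(46.5, 48.6, 46.7, 44.6, 54.5, 61.2),
             FA = c(9.0, 10.1, 7.2, 12.7, 13.1, 16.4),
             Err = c(11.8, 14.9, 17.8, 17.3, 17.9, 19.1))
  colnames(m) <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
  m
}

#' Specification of a synthetic normative cohort
#'
#' Bundles everything [generate_cohort()] needs: the demographic cell counts
#' (default: the normative sample's gender x age-decade x education-band
#' table), the true per-index effect models (default: the published
#' correction regressions, inverted), per-index baseline means (default: the
#' decade means of the normative sample weighted by decade size), a
#' right-skewed residual model scaled to the published residual standard
#' errors, an optional layout x crowding interaction, the per-card omission
#' rate and the seed.
#'
#' @param n cohort size (default 550, the normative sample).
#' @param seed integer seed; every stochastic routine in the generator is
#'   deterministic given it.
#' @param demographic_table data frame with columns `band`, `decade`,
#'   `gender`, `count`; counts are rescaled to `n`.
#' @param index_models per-index term lists (true effects); default the
#'   published correction models.
#' @param baseline_means named per-index intercepts in raw units.
#' @param noise_scale named per-index residual scales (seconds / errors).
#' @param noise_family `"gamma"` (right-skewed, shape 4; the default, so the
#'   nonparametric tolerance branch is exercised) or `"normal"`.
#' @param interaction layout x crowding interaction I added to card 4's
#'   performance time (default 0, giving an exact cards-indexes round trip).
#' @param omission_rate mean omissions per card (default 2).
#' @param outliers number of extreme-outlier participants to inject (their
#'   card times are placed far above the 3 x IQR threshold of the clean
#'   cohort so they are deterministically caught by [filter_outliers()]).
#' @return list of class `brevis_cohort_spec`.
#' @export
cohort_spec <- function(n = 550, seed = 1,
                        demographic_table = demographic_table_default(),
                        index_models = published_norms_data()$models,
                        baseline_means = NULL,
                        noise_scale = c(SA = 16.01, OA = 23.38, FA = 18.11, Err = 8.83),
                        noise_family = c("gamma", "normal"),
                        interaction = 0,
                        omission_rate = 2,
                        outliers = 0) {
  noise_family <- match.arg(noise_family)
  if (any(noise_scale <= 0)) stop_brevis("noise scale must be positive")
  if (n < 1) stop_brevis("n must be >= 1")
  if (is.null(baseline_means)) {
    dec_tot <- tapply(demographic_table$count, demographic_table$decade, sum)
    m <- index_decade_means()
    dec_tot <- dec_tot[colnames(m)]
    baseline_means <- drop(m %*% as.numeric(dec_tot)) / sum(dec_tot)
  }
  structure(list(n = n, seed = seed, demographic_table = demographic_table,
                 index_models = index_models, baseline_means = baseline_means,
                 noise_scale = noise_scale, noise_family = noise_family,
                 interaction = interaction, omission_rate = omission_rate,
                 outliers = outliers),
            class = "brevis_cohort_spec")
}

draw_noise <- function(n, scale, family) {
  if (family == "normal") return(stats::rnorm(n, 0, scale))
  shape <- 4  # skewness 2/sqrt(shape) = 1, a moderate right skew
  rate <- sqrt(shape) / scale
  rgamma(n, shape = shape, rate = rate) - shape / rate
}

#' Sample demographics from the normative cell structure
#'
#' Draws cell membership proportional to the demographic table's counts
#' (rescaled to `n`), then age uniformly within the decade and education
#' years within the band (0-5 -> 5; 6-8 -> 8; 9-13 -> uniform 9..13;
#' >13 -> uniform 14..21).
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed; `NULL` continues from the current RNG state.
#' @return data frame with `participant_id`, `age_years`, `education_years`,
#'   `gender`.
#' @export
sample_demographics <- function(spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  tab <- spec$demographic_table
  cells <- sample(nrow(tab), spec$n, replace = TRUE, prob = tab$count)
  dec_lo <- as.integer(sub("-.*", "", tab$decade[cells]))
  age <- dec_lo + sample.int(10, spec$n, replace = TRUE) - 1L
  band <- tab$band[cells]
  edu <- integer(spec$n)
  edu[band == "0-5"] <- 5L
  edu[band == "6-8"] <- 8L
  n913 <- sum(band == "9-13")
  edu[band == "9-13"] <- sample(9:13, n913, replace = TRUE)
  n13 <- sum(band == ">13")
  edu[band == ">13"] <- sample(14:21, n13, replace = TRUE)
  data.frame(participant_id = sprintf("S%04d", seq_len(spec$n)),
             age_years = age, education_years = edu, gender = tab$gender[cells],
             stringsAsFactors = FALSE)
}

#' Generate true index values for sampled demographics
#'
#' Inverts the correction model: `raw = baseline - correction(demographics)
#' + noise`, so that adding the published correction to a generated raw score
#' recenters it at the baseline for every demographic cell (up to the noise
#' mean). SA/OA/FA are continuous; Err is a non-negative integer drawn from a
#' negative-binomial with demographic-dependent mean and variance matched to
#' the Err residual scale.
#'
#' @param demographics data frame from [sample_demographics()].
#' @param spec a [cohort_spec()].
#' @param seed optional seed; `NULL` continues from the current RNG state.
#' @return data frame: demographics plus true `SA`, `OA`, `FA`, `Err` and the
#'   per-index corrections used.
#' @export
generate_indices <- function(demographics, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(demographics)
  g01 <- as_gender01(demographics$gender)
  out <- demographics
  for (ix in c("SA", "OA", "FA")) {
    corr <- eval_correction_model(spec$index_models[[ix]],
                                  demographics$age_years,
                                  demographics$education_years, g01)
    out[[ix]] <- spec$baseline_means[[ix]] - corr +
      draw_noise(n, spec$noise_scale[[ix]], spec$noise_family)
    out[[paste0("corr_", ix)]] <- corr
  }
  corrE <- eval_correction_model(spec$index_models$Err,
                                 demographics$age_years,
                                 demographics$education_years, g01)
  mu <- pmax(0.2, spec$baseline_means[["Err"]] - corrE)
  v <- spec$noise_scale[["Err"]]^2
  out$Err <- ifelse(v > mu,
                    rnbinom(n, size = mu^2 / (v - mu), mu = mu),
                    rpois(n, mu))
  out$corr_Err <- corrE
  out
}

#' Decompose index values into four card observations
#'
#' Inverts the index definitions: `P1 = SA`, `P2 = SA + FA`, `P3 = SA + OA`,
#' `P4 = SA + OA + FA + I` (I = layout x crowding interaction). Per card,
#' omissions are drawn so their total does not exceed `Err`, execution time
#' is set to `P * (25 - omissions) / 25`, and substitutions take up the
#' remaining errors, so [compute_indexes()] on the produced cards returns the
#' input indexes exactly when `I = 0`.
#'
#' @param indices data frame from [generate_indices()] (needs `SA`, `OA`,
#'   `FA`, `Err` and demographics).
#' @param interaction layout x crowding interaction I (seconds).
#' @param omission_rate mean omissions per card.
#' @param seed optional seed; `NULL` continues from the current RNG state.
#' @return long-format cohort data frame (one row per participant x card).
#' @export
indices_to_cards <- function(indices, interaction = 0, omission_rate = 2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(indices)
  P <- cbind(indices$SA,
             indices$SA + indices$FA,
             indices$SA + indices$OA,
             indices$SA + indices$OA + indices$FA + interaction)
  if (any(P <= 0))
    stop_brevis("index set implies non-positive card performance times; ",
                "reduce noise or raise baselines")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    err <- indices$Err[i]
    # keep expected omissions comfortably below Err so the split is feasible
    target <- min(4 * omission_rate, floor(err * 0.6))
    p_om <- target / 100
    om <- c(0L, 0L, 0L, 0L)
    if (p_om > 0) {
      ok <- FALSE
      for (try in 1:50) {
        om <- rbinom(4, 25, p_om)
        if (sum(om) <= err && all(om < 25)) { ok <- TRUE; break }
      }
      if (!ok) stop_brevis("participant ", indices$participant_id[i],
                           ": could not split Err = ", err, " into omissions")
    }
    subs <- if (err - sum(om) > 0)
      as.integer(stats::rmultinom(1, err - sum(om), rep(0.25, 4))) else rep(0L, 4)
    rows[[i]] <- data.frame(
      participant_id = indices$participant_id[i],
      age_years = indices$age_years[i],
      education_years = indices$education_years[i],
      gender = indices$gender[i],
      card = 1:4,
      execution_time_s = P[i, ] * (25 - om) / 25,
      omissions = om, substitutions = subs,
      autocorrections = rpois(4, 0.2),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic normative cohort
#'
#' Full generator: demographics, true indexes, card-level decomposition, and
#' (optionally) injected extreme outliers. Deterministic given `spec$seed`.
#'
#' When `spec$outliers = K > 0`, the clean `n - K` members are guaranteed to
#' fall below their own cohort's 3 x IQR card thresholds (offending draws are
#' regenerated, bounded retries) and the K outliers are given one card at
#' twice the clean threshold, so [filter_outliers()] on the combined cohort
#' removes exactly those K. This is a structural emulation for exercising the
#' filter, not a model of real outlier behaviour.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (long-format data frame) and `truth` (sidecar:
#'   per-participant true indexes and corrections, plus `is_outlier`).
#' @export
#' @examples
#' gc <- generate_cohort(cohort_spec(n = 30, seed = 3))
#' head(gc$cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "brevis_cohort_spec"))
  set.seed(spec$seed)
  k_out <- spec$outliers
  n_clean <- spec$n - k_out
  if (n_clean < 1) stop_brevis("outliers must be < n")

  clean_spec <- spec; clean_spec$n <- n_clean
  demog <- sample_demographics(clean_spec, seed = NULL)
  idx <- generate_indices(demog, clean_spec)
  cohort <- indices_to_cards(idx, spec$interaction, spec$omission_rate)

  truth <- idx
  truth$is_outlier <- FALSE

  if (k_out > 0) {
    # redraw clean members that would exceed their own cohort's thresholds
    for (iter in 1:25) {
      thr <- vapply(1:4, function(k) {
        rows <- cohort[cohort$card == k, ]
        pt <- performance_time(rows$execution_time_s, rows$omissions)
        q <- quantile(pt, c(0.25, 0.75), type = 7, names = FALSE)
        q[2] + 3 * (q[2] - q[1])
      }, 0)
      flagged <- filter_outliers(cohort)$removed_ids
      if (!length(flagged)) break
      keep <- !demog$participant_id %in% flagged
      redo <- demog[!keep, , drop = FALSE]
      idx_redo <- generate_indices(redo, clean_spec)
      cohort <- rbind(cohort[!cohort$participant_id %in% flagged, ],
                      indices_to_cards(idx_redo, spec$interaction, spec$omission_rate))
      truth[match(redo$participant_id, truth$participant_id),
            setdiff(names(idx_redo), "participant_id")] <-
        idx_redo[, setdiff(names(idx_redo), "participant_id")]
    }

    out_spec <- spec; out_spec$n <- k_out
    demog_o <- sample_demographics(out_spec, seed = NULL)
    demog_o$participant_id <- sprintf("OUT%03d", seq_len(k_out))
    idx_o <- generate_indices(demog_o, out_spec)
    cards_o <- indices_to_cards(idx_o, spec$interaction, spec$omission_rate)
    bad_card <- sample(1:4, k_out, replace = TRUE)
    for (j in seq_len(k_out)) {
      sel <- cards_o$participant_id == demog_o$participant_id[j] &
             cards_o$card == bad_card[j]
      cards_o$execution_time_s[sel] <-
        2 * thr[bad_card[j]] * (25 - cards_o$omissions[sel]) / 25
    }
    idx_o$is_outlier <- TRUE
    cohort <- rbind(cohort, cards_o)
    truth <- rbind(truth, idx_o)
  }
  rownames(cohort) <- rownames(truth) <- NULL
  list(cohort = cohort, truth = truth)
}
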