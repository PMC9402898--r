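# Synthetic cohort generator calibrated to the published per-class
# total-score and blood-loss summaries, so the full pipeline is testable
# without patient-level data.

#' Construct a per-class generator profile
#'
#' @param n Number of patients in the class.
#' @param item_probs List of 11 probability triplets `(p0, p1, p2)`, one per
#'   item of [mri_score_items()]; the cesarean item must have `p0 = 0`.
#' @param score_mean,score_sd Calibration targets for the class total score
#'   (points).
#' @param score_min,score_max Hard bounds enforced by rejection (points).
#' @param blood_loss_median,blood_loss_min,blood_loss_max Blood-loss
#'   distribution parameters (ml).
#' @param age_mean,age_sd Maternal age (years).
#' @param weight_mean,weight_sd Neonatal weight (g).
#' @param ga_median,ga_min,ga_max Gestational age at delivery (weeks).
#' @param previa_complete_prop Proportion with complete previa.
#' @return Object of class `class_profile`.
#' @export
class_profile <- function(n, item_probs,
                          score_mean, score_sd, score_min, score_max,
                          blood_loss_median, blood_loss_min, blood_loss_max,
                          age_mean = NA, age_sd = NA,
                          weight_mean = NA, weight_sd = NA,
                          ga_median = NA, ga_min = NA, ga_max = NA,
                          previa_complete_prop = NA) {
  stopifnot(n >= 1, length(item_probs) == 11L)
  for (i in seq_along(item_probs)) {
    p <- item_probs[[i]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("item_probs[[", i, "]] is not a probability triplet", call. = FALSE)
    }
  }
  if (item_probs[[11]][1] != 0) {
    stop("the cesarean item cannot have mass on 0 (all patients have a ",
         "cesarean history)", call. = FALSE)
  }
  stopifnot(score_min <= score_mean, score_mean <= score_max,
            blood_loss_min <= blood_loss_median,
            blood_loss_median <= blood_loss_max)
  structure(as.list(environment()), class = "class_profile")
}

#' Default synthetic-cohort configuration
#'
#' The shipped calibration: class sizes 30/77/60/26 (193 patients in total);
#' per-item probability triplets tuned so the class total-score means and
#' spreads track the published per-class summaries (means 5.6/9.4/12.8/15.5)
#' within the generator's tolerance, with scores rejected outside the
#' published per-class min/max; blood loss drawn from a split log-normal
#' centred at the published medians 225/600/1500/3000 ml and bounded by the
#' published ranges. The cesarean-item probabilities come from the published
#' once/twice-or-more counts per class.
#'
#' @param seed Integer seed stored in the config; [generate_cohort()] seeds
#'   the RNG with it.
#' @return Object of class `cohort_config`: list with `profiles` (named
#'   `non_pas`, `pa`, `pi`, `pp`) and `seed`.
#' @export
#' @examples
#' cfg <- default_config()
#' sum(vapply(cfg$profiles, function(p) p$n, numeric(1)))  # 193
default_config <- function(seed = 20220811) {
  mri_triplet <- function(p) rep(list(p), 10)
  ces <- function(p2) c(0, 1 - p2, p2)
  profiles <- list(
    non_pas = class_profile(
      n = 30,
      item_probs = c(mri_triplet(c(0.76, 0.06, 0.18)), list(ces(1 / 30))),
      score_mean = 5.6, score_sd = 2.5, score_min = 3, score_max = 13,
      blood_loss_median = 225, blood_loss_min = 100, blood_loss_max = 3700,
      age_mean = 31.9, age_sd = 3.8, weight_mean = 2765.1, weight_sd = 559.0,
      ga_median = 36.7, ga_min = 29.3, ga_max = 37.9,
      previa_complete_prop = 24 / 30),
    pa = class_profile(
      n = 77,
      item_probs = c(mri_triplet(c(0.55, 0.12, 0.33)), list(ces(13 / 77))),
      score_mean = 9.4, score_sd = 2.9, score_min = 5, score_max = 19,
      blood_loss_median = 600, blood_loss_min = 200, blood_loss_max = 6000,
      age_mean = 32.8, age_sd = 4.4, weight_mean = 2744.8, weight_sd = 570.9,
      ga_median = 36.6, ga_min = 28.4, ga_max = 38.7,
      previa_complete_prop = 57 / 77),
    pi = class_profile(
      n = 60,
      item_probs = c(mri_triplet(c(0.235, 0.38, 0.385)), list(ces(17 / 60))),
      score_mean = 12.8, score_sd = 2.5, score_min = 6, score_max = 20,
      blood_loss_median = 1500, blood_loss_min = 300, blood_loss_max = 7000,
      age_mean = 34.1, age_sd = 4.2, weight_mean = 2867.2, weight_sd = 646.6,
      ga_median = 36.9, ga_min = 28.1, ga_max = 38.9,
      previa_complete_prop = 46 / 60),
    pp = class_profile(
      n = 26,
      item_probs = c(mri_triplet(c(0.29, 0.00, 0.71)), list(ces(6 / 26))),
      score_mean = 15.5, score_sd = 3.5, score_min = 9, score_max = 21,
      blood_loss_median = 3000, blood_loss_min = 400, blood_loss_max = 6300,
      age_mean = 32.8, age_sd = 3.8, weight_mean = 2976.8, weight_sd = 689.5,
      ga_median = 36.8, ga_min = 29.0, ga_max = 38.9,
      previa_complete_prop = 1)
  )
  structure(list(profiles = profiles, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Validate a cohort configuration
#'
#' @param config A `cohort_config`.
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("not a cohort_config", call. = FALSE)
  }
  if (!identical(sort(names(config$profiles)), sort(pas_levels()))) {
    stop("config must have one profile per PAS class: ",
         paste(pas_levels(), collapse = ", "), call. = FALSE)
  }
  for (p in config$profiles) {
    if (!inherits(p, "class_profile")) stop("invalid profile", call. = FALSE)
  }
  invisible(config)
}

# Vectorized feature draws for one class, with rejection of totals outside
# [score_min, score_max]. Errors if acceptance is implausibly rare
# (calibration infeasible).
sample_features_n <- function(class, config, n) {
  validate_config(config)
  profile <- config$profiles[[as.character(class)]]
  items <- mri_score_items()
  accepted <- matrix(0L, nrow = 0, ncol = 11)
  attempts <- 0L
  while (nrow(accepted) < n) {
    m <- max(2L * (n - nrow(accepted)), 50L)
    attempts <- attempts + m
    if (attempts > 10000L * n) {
      stop("feature rejection sampling failed for class '", class,
           "': score bounds are infeasible under the item probabilities",
           call. = FALSE)
    }
    draws <- vapply(seq_len(11), function(i) {
      p <- profile$item_probs[[i]]
      sample(0:2, m, replace = TRUE, prob = p)
    }, integer(m))
    draws <- matrix(draws, nrow = m)
    totals <- rowSums(draws)
    keep <- totals >= profile$score_min & totals <= profile$score_max
    accepted <- rbind(accepted, draws[keep, , drop = FALSE])
  }
  accepted <- accepted[seq_len(n), , drop = FALSE]
  colnames(accepted) <- items
  as.data.frame(accepted)
}

#' Draw one patient's score items
#'
#' Items are drawn independently from the class-conditional probability
#' triplets; the draw is rejected and repeated until the total score lies
#' within the profile's `[score_min, score_max]`. Uses the current RNG state.
#'
#' @param class PAS class name (one of [pas_levels()]).
#' @param config A `cohort_config`.
#' @return Named integer vector of the 11 items (a valid feature set).
#' @export
sample_features <- function(class, config) {
  row <- sample_features_n(class, config, 1L)
  stats::setNames(as.integer(row[1, ]), names(row))
}

# Split (two-piece) log-normal bounded draw: the median is `med` exactly by
# construction; each side's log-scale sigma is set so the bound sits at the
# 99.5th percentile of its half, and draws beyond the bound are rejected.
sample_split_lognormal <- function(n, med, lo, hi) {
  stopifnot(lo <= med, med <= hi)
  if (lo == hi) return(rep(lo, n))
  z995 <- stats::qnorm(0.995)
  sig_lo <- log(med / lo) / z995
  sig_hi <- log(hi / med) / z995
  out <- numeric(n)
  upper <- stats::runif(n) < 0.5
  z <- abs(stats::rnorm(n))
  # redraw the ~1% of half-normal draws beyond the bound
  while (any(z > z995)) z[z > z995] <- abs(stats::rnorm(sum(z > z995)))
  out[upper] <- med * exp(z[upper] * sig_hi)
  out[!upper] <- med * exp(-z[!upper] * sig_lo)
  # degenerate side (sigma 0) collapses to the median, which is fine
  pmin(pmax(out, lo), hi)
}

#' Draw intraoperative blood loss for a class
#'
#' Split log-normal centred at the class's published median and bounded by
#' its published (min, max) range: with probability 1/2 the draw falls on
#' each side of the median, each side following a half log-normal whose
#' 99.5th percentile is the corresponding bound (rejection beyond it). The
#' empirical median therefore recovers the configured median exactly up to
#' Monte-Carlo error. Uses the current RNG state.
#'
#' @inheritParams sample_features
#' @param n Number of draws.
#' @return Numeric vector of blood losses (ml) within `[min, max]`.
#' @export
sample_blood_loss <- function(class, config, n = 1) {
  validate_config(config)
  p <- config$profiles[[as.character(class)]]
  sample_split_lognormal(n, p$blood_loss_median,
                         p$blood_loss_min, p$blood_loss_max)
}

#' Generate a synthetic cohort
#'
#' Draws exactly `profile$n` patients per PAS class: score items by
#' class-conditional sampling with score-range rejection, blood loss from the
#' bounded split log-normal, and the optional demographic columns (age,
#' gestational age, neonatal weight, previa type) from the per-class summary
#' parameters. Deterministic given `config$seed`; two calls with the same
#' config produce identical tables.
#'
#' @param config A `cohort_config`, e.g. [default_config()].
#' @param path Optional path; when given, the cohort is also written as a
#'   cohort CSV via [write_cohort()].
#' @return Validated cohort data.frame (one row per patient).
#' @export
#' @examples
#' cohort <- generate_cohort(default_config())
#' nrow(cohort)  # 193
generate_cohort <- function(config, path = NULL) {
  validate_config(config)
  set.seed(config$seed)
  pieces <- lapply(pas_levels(), function(cls) {
    p <- config$profiles[[cls]]
    feats <- sample_features_n(cls, config, p$n)
    age <- round(stats::rnorm(p$n, p$age_mean, p$age_sd), 1)
    age <- pmax(age, 18)
    ga <- round(sample_split_lognormal(p$n, p$ga_median, p$ga_min, p$ga_max), 1)
    # keep within the study's 28-39 week inclusion window
    ga <- pmin(pmax(ga, 28), 39)
    wt <- round(pmax(stats::rnorm(p$n, p$weight_mean, p$weight_sd), 500))
    previa <- ifelse(stats::runif(p$n) < p$previa_complete_prop,
                     "complete", "low")
    cbind(
      data.frame(pas_class = cls, stringsAsFactors = FALSE),
      feats,
      data.frame(
        blood_loss_ml = round(sample_blood_loss(cls, config, p$n)),
        age_years = age,
        gestational_age_weeks = ga,
        neonatal_weight_g = wt,
        previa_type = previa,
        stringsAsFactors = FALSE))
  })
  cohort <- do.call(rbind, pieces)
  cohort <- cbind(
    data.frame(patient_id = sprintf("P%03d", seq_len(nrow(cohort))),
               stringsAsFactors = FALSE),
    cohort[, c(mri_score_items(), "pas_class", "blood_loss_ml", "age_years",
               "gestational_age_weeks", "neonatal_weight_g", "previa_type")])
  rownames(cohort) <- NULL
  cohort <- validate_cohort(cohort)
  if (!is.null(path)) write_cohort(cohort, path)
  cohort
}

#' Published per-class total-score summary
#'
#' The per-class total-score summary used as the generator's calibration
#' target: class sizes, mean, standard deviation, min, max and the reported
#' 95% reference-interval limits.
#'
#' @return data.frame with one row per PAS class.
#' @export
reference_score_summary <- function() {
  data.frame(
    pas_class = pas_levels(),
    n = c(30, 77, 60, 26),
    mean = c(5.6, 9.4, 12.8, 15.5),
    sd = c(2.5, 2.9, 2.5, 3.5),
    min = c(3, 5, 6, 9),
    max = c(13, 19, 20, 21),
    ci_lower = c(0.8, 3.7, 8.0, 8.7),
    ci_upper = c(10.5, 15.1, 17.6, 22.3),
    stringsAsFactors = FALSE
  )
}

#' Published diagnostic rates for the three dichotomies
#'
#' The reported sensitivity/specificity, boundary values and group margins
#' for dichotomies A/B/C, usable as inputs to [reconstruct_confusion()].
#'
#' @return data.frame with one row per dichotomy.
#' @export
reference_dichotomy_rates <- function() {
  data.frame(
    dichotomy = c("A", "B", "C"),
    boundary = c(5.5, 11.5, 15.5),
    sensitivity = c(0.994, 0.802, 0.577),
    specificity = c(0.700, 0.869, 0.958),
    n_pos = c(163, 86, 26),
    n_neg = c(30, 107, 167),
    stringsAsFactors = FALSE
  )
}
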