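# ROC construction, trapezoidal AUC, stratified bootstrap CI and
# Youden-maximizing cutoff selection.

check_two_classes <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (any(is.na(scores)) || any(is.na(labels))) {
    stop("scores and labels must not contain NA", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (prediction positive when
#' score >= threshold) plus the two endpoints; AUC by the trapezoidal rule,
#' which on ties equals the tie-corrected Mann-Whitney concordance.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Logical (or 0/1) true class labels.
#' @return Object of class `roc_curve`: list with `thresholds` (descending,
#'   starting at `Inf`), `points` (data.frame `fpr`, `tpr`, one row per
#'   threshold, from (0,0) to (1,1)) and `auc`.
#' @export
#' @examples
#' r <- roc_curve(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc  # 0.875
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !labels) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", length(x$thresholds), "operating points, AUC =",
      format_metric(x$auc), "\n")
  invisible(x)
}

#' Write ROC operating points as CSV
#'
#' @param roc A `roc_curve`.
#' @param path Output path; columns `threshold`, `fpr`, `tpr`.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(
    data.frame(threshold = roc$thresholds, roc$points),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Candidate cutoffs: midpoints between consecutive distinct sorted scores,
# plus one below the minimum and one above the maximum. On integer scores
# with unit gaps these are the half-integer boundary values.
cutoff_candidates <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1L) return(c(s - 0.5, s + 0.5))
  c(s[1] - 0.5, (utils::head(s, -1) + utils::tail(s, -1)) / 2,
    s[length(s)] + 0.5)
}

#' Youden-optimal cutoff
#'
#' Scans all candidate cutoffs (midpoints of consecutive distinct scores plus
#' one below the minimum and one above the maximum) and returns the one
#' maximizing the Youden index (sensitivity + specificity - 1). Ties are
#' broken toward the smallest cutoff, i.e. toward higher sensitivity — the
#' screening-oriented choice.
#'
#' @inheritParams roc_curve
#' @param n_boot Bootstrap replicates for the AUC confidence interval
#'   (`NULL` or 0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `cutoff_result`: list with `cutoff`, `youden`,
#'   `metrics` (a `diagnostic_metrics`), `confusion` (the `confusion_table`
#'   at the cutoff), `auc` and `auc_ci` (`c(low, high)` or `NULL`).
#' @export
select_cutoff_youden <- function(scores, labels, n_boot = 2000,
                                 seed = 20220811) {
  labels <- check_two_classes(scores, labels)
  candidates <- cutoff_candidates(scores)
  youdens <- vapply(candidates, function(cut) {
    sens <- sum(scores >= cut & labels) / sum(labels)
    spec <- sum(scores < cut & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1))
  best <- candidates[which.max(youdens)]  # which.max takes the first = smallest
  ct <- confusion_table(tp = sum(scores >= best & labels),
                        fp = sum(scores >= best & !labels),
                        fn = sum(scores < best & labels),
                        tn = sum(scores < best & !labels))
  roc <- roc_curve(scores, labels)
  ci <- if (!is.null(n_boot) && n_boot > 0) {
    auc_ci_bootstrap(scores, labels, n_boot = n_boot, seed = seed)
  }
  structure(list(cutoff = best, youden = max(youdens),
                 metrics = metrics_from_confusion(ct), confusion = ct,
                 auc = roc$auc, auc_ci = ci),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("Youden-optimal cutoff:", x$cutoff,
      " Youden:", format_metric(x$youden),
      " AUC:", format_metric(x$auc), "\n")
  if (!is.null(x$auc_ci)) {
    cat("AUC 95% CI: (", format_metric(x$auc_ci[1]), "-",
        format_metric(x$auc_ci[2]), ")\n")
  }
  invisible(x)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples with replacement within each label class (so every resample
#' keeps both classes), recomputes the trapezoidal AUC, and returns the
#' 2.5/97.5 percentile interval. Deterministic given `seed`; the caller's
#' RNG state is left untouched.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer RNG seed.
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci_bootstrap <- function(scores, labels, n_boot = 2000, seed = 20220811) {
  labels <- check_two_classes(scores, labels)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  pos <- scores[labels]
  neg <- scores[!labels]
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    bp <- sample(pos, length(pos), replace = TRUE)
    bn <- sample(neg, length(neg), replace = TRUE)
    roc_curve(c(bp, bn), c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))$auc
  }, numeric(1))
  unname(stats::quantile(aucs, c(0.025, 0.975)))
}

#' Run the three PAS dichotomies
#'
#' Applies [roc_curve()], [select_cutoff_youden()] and the metric suite to
#' dichotomies A (non-PAS vs any PAS), B (non-PAS/adhesion vs
#' implantation/percreta) and C (percreta vs the rest), in that order.
#'
#' @param scored Output of [score_cohort()]; all four PAS classes must be
#'   represented so that no dichotomy has an empty side.
#' @param n_boot,seed Passed to [select_cutoff_youden()].
#' @return Named list (`A`, `B`, `C`) of `cutoff_result` objects.
#' @export
run_three_dichotomies <- function(scored, n_boot = 2000, seed = 20220811) {
  lapply(stats::setNames(c("A", "B", "C"), c("A", "B", "C")), function(nm) {
    d <- dichotomy_spec(nm)
    labels <- as.character(scored$pas_class) %in% d$positive_classes
    if (!any(labels) || all(labels)) {
      stop("dichotomy ", nm, " has an empty side: a PAS class is missing",
           call. = FALSE)
    }
    select_cutoff_youden(scored$total_score, labels, n_boot = n_boot,
                         seed = seed)
  })
}
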