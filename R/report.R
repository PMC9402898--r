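# End-to-end orchestration: ingest or simulate a cohort, score it, run the
# three-dichotomy ROC/cutoff analysis and the blood-loss comparisons, and
# serialize the result as JSON and text tables.

metric_row_order <- c("auc", "auc_ci_low", "auc_ci_high", "boundary",
                      "specificity", "sensitivity", "ppv", "npv", "youden",
                      "plr", "nlr", "kappa")

#' Run the full PPP analysis pipeline
#'
#' Accepts a cohort CSV path, an in-memory cohort data.frame, or a
#' [default_config()]-style `cohort_config` (in which case a synthetic
#' cohort is generated first). The cohort is validated and scored; ROC
#' curves, Youden-optimal cutoffs and the full metric suite are computed for
#' dichotomies A/B/C; blood loss is compared across the four classes
#' (Kruskal-Wallis plus adjusted pairwise rank-sum tests); optional
#' demographic columns get one-way ANOVA (age, neonatal weight),
#' Kruskal-Wallis (gestational age) and the Freeman-Halton exact test
#' (previa type by class). Deterministic given the input and `seed`.
#'
#' @param input CSV path, cohort data.frame, or `cohort_config`.
#' @param seed Seed for the bootstrap AUC confidence intervals.
#' @param n_boot Bootstrap replicates (0 to skip CIs).
#' @param adjust Pairwise p-value adjustment method (see
#'   [pairwise_ranksum()]).
#' @return Object of class `ppp_report`: list with `cohort_summary`,
#'   `cutoff_results`, `metric_table`, `group_tests`, `provenance`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_config(), n_boot = 200)
#' cat(render_table4(rep))
#' }
run_pipeline <- function(input, seed = 20220811, n_boot = 2000,
                         adjust = "bonferroni") {
  if (inherits(input, "cohort_config")) {
    cohort <- generate_cohort(input)
    input_type <- "synthetic_config"
  } else if (is.character(input)) {
    cohort <- read_cohort(input)
    input_type <- "csv"
  } else if (is.data.frame(input)) {
    cohort <- validate_cohort(input)
    input_type <- "data.frame"
  } else {
    stop("input must be a cohort CSV path, a cohort data.frame, or a ",
         "cohort_config", call. = FALSE)
  }
  scored <- score_cohort(cohort)
  cls <- as.character(scored$pas_class)

  cohort_summary <- do.call(rbind, lapply(pas_levels(), function(lv) {
    s <- scored$total_score[cls == lv]
    b <- scored$blood_loss_ml[cls == lv]
    data.frame(pas_class = lv, n = length(s),
               score_mean = mean(s), score_sd = stats::sd(s),
               score_min = suppressWarnings(min(s)),
               score_max = suppressWarnings(max(s)),
               blood_loss_median = stats::median(b),
               blood_loss_min = suppressWarnings(min(b)),
               blood_loss_max = suppressWarnings(max(b)),
               stringsAsFactors = FALSE)
  }))

  cutoffs <- run_three_dichotomies(scored, n_boot = n_boot, seed = seed)
  metric_table <- metric_table_from_results(cutoffs)

  blood <- split(scored$blood_loss_ml, factor(cls, levels = pas_levels()))
  group_tests <- list(
    blood_loss_kruskal = kruskal_wallis(blood),
    blood_loss_pairwise = pairwise_ranksum(blood, adjust = adjust)
  )
  if ("age_years" %in% names(cohort)) {
    group_tests$age_anova <-
      one_way_anova(split(cohort$age_years, factor(cls, pas_levels())))
  }
  if ("neonatal_weight_g" %in% names(cohort)) {
    group_tests$weight_anova <-
      one_way_anova(split(cohort$neonatal_weight_g, factor(cls, pas_levels())))
  }
  if ("gestational_age_weeks" %in% names(cohort)) {
    group_tests$ga_kruskal <-
      kruskal_wallis(split(cohort$gestational_age_weeks,
                           factor(cls, pas_levels())))
  }
  if ("previa_type" %in% names(cohort)) {
    tab <- table(factor(cls, pas_levels()), cohort$previa_type)
    group_tests$previa_exact <- freeman_halton_exact(unclass(tab))
  }

  structure(list(
    cohort_summary = cohort_summary,
    cutoff_results = cutoffs,
    metric_table = metric_table,
    group_tests = group_tests,
    provenance = list(
      tool = "pppscore",
      version = as.character(utils::packageVersion("pppscore")),
      input_type = input_type,
      input_hash = rlang::hash(cohort),
      seed = seed, n_boot = n_boot, adjust = adjust)
  ), class = "ppp_report")
}

# Assemble the Table-4-shaped metric table (rows = metrics, columns = A/B/C)
# from three cutoff_result objects.
metric_table_from_results <- function(cutoffs) {
  cols <- lapply(cutoffs, function(r) {
    m <- r$metrics
    c(auc = r$auc,
      auc_ci_low = if (is.null(r$auc_ci)) NA_real_ else r$auc_ci[1],
      auc_ci_high = if (is.null(r$auc_ci)) NA_real_ else r$auc_ci[2],
      boundary = r$cutoff,
      specificity = m$specificity, sensitivity = m$sensitivity,
      ppv = m$ppv, npv = m$npv, youden = m$youden,
      plr = m$plr, nlr = m$nlr, kappa = m$kappa)
  })
  out <- data.frame(metric = metric_row_order, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]][metric_row_order])
  out
}

#' Metric table reconstructed from printed rates
#'
#' Builds the Table-4-shaped metric table directly from printed
#' sensitivity/specificity and group margins (via
#' [reconstruct_confusion()]), without patient-level data. AUC rows are `NA`
#' (not derivable from the rates alone).
#'
#' @param rates data.frame like [reference_dichotomy_rates()]: columns
#'   `dichotomy`, `boundary`, `sensitivity`, `specificity`, `n_pos`,
#'   `n_neg`.
#' @return Metric table data.frame (rows = metrics, one column per
#'   dichotomy).
#' @export
#' @examples
#' mt <- reconstruct_metric_table(reference_dichotomy_rates())
#' cat(render_table4(mt))
reconstruct_metric_table <- function(rates = reference_dichotomy_rates()) {
  results <- lapply(seq_len(nrow(rates)), function(i) {
    ct <- reconstruct_confusion(rates$sensitivity[i], rates$specificity[i],
                                rates$n_pos[i], rates$n_neg[i])
    m <- metrics_from_confusion(ct)
    list(cutoff = rates$boundary[i], youden = m$youden, metrics = m,
         confusion = ct, auc = NA_real_, auc_ci = NULL)
  })
  names(results) <- rates$dichotomy
  metric_table_from_results(results)
}

#' Render the metric table as text
#'
#' Produces the fixed-layout text table: rows AUC (95% CI), boundary value,
#' specificity, sensitivity, PPV, NPV, Youden index, positive and negative
#' likelihood ratios and kappa; one column per dichotomy; values printed at
#' 3 decimals (half-away-from-zero), undefined values as `NA`.
#'
#' @param x A `ppp_report` or a metric-table data.frame (as produced by
#'   [reconstruct_metric_table()]).
#' @return Character scalar (the table text, newline-terminated).
#' @export
render_table4 <- function(x) {
  mt <- if (inherits(x, "ppp_report")) x$metric_table else x
  stopifnot(is.data.frame(mt), "metric" %in% names(mt))
  cols <- setdiff(names(mt), "metric")
  get_row <- function(metric) {
    stats::setNames(as.numeric(mt[mt$metric == metric, cols]), cols)
  }
  fmt <- function(v, digits = 3) {
    vapply(v, format_metric, character(1), digits = digits)
  }
  auc_cells <- vapply(cols, function(cn) {
    auc <- get_row("auc")[cn]
    lo <- get_row("auc_ci_low")[cn]
    hi <- get_row("auc_ci_high")[cn]
    if (is.na(auc)) "NA"
    else if (is.na(lo)) format_metric(auc)
    else sprintf("%s (%s-%s)", format_metric(auc), format_metric(lo),
                 format_metric(hi))
  }, character(1))
  rows <- list(
    "AUC (95% CI)" = auc_cells,
    "Boundary value" = fmt(get_row("boundary"), 1),
    "Specificity" = fmt(get_row("specificity")),
    "Sensitivity" = fmt(get_row("sensitivity")),
    "Positive predictive value" = fmt(get_row("ppv")),
    "Negative predictive value" = fmt(get_row("npv")),
    "Youden index" = fmt(get_row("youden")),
    "Positive likelihood ratio" = fmt(get_row("plr")),
    "Negative likelihood ratio" = fmt(get_row("nlr")),
    "Kappa value" = fmt(get_row("kappa")))
  label_w <- max(nchar(names(rows)))
  cell_w <- max(8, max(vapply(rows, function(r) max(nchar(r)), integer(1))),
                nchar(paste("Compare", cols)))
  header <- paste0(formatC("", width = label_w),
                   paste(formatC(paste("Compare", cols), width = cell_w + 2),
                         collapse = ""))
  body <- vapply(names(rows), function(nm) {
    paste0(formatC(nm, width = label_w, flag = "-"),
           paste(formatC(rows[[nm]], width = cell_w + 2), collapse = ""))
  }, character(1))
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

group_comparison_to_list <- function(g) {
  out <- list(test_name = g$test_name, statistic = g$statistic,
              p_value = g$p_value, df = g$df)
  if (!is.null(g$pairwise)) out$pairwise <- g$pairwise
  out
}

report_to_list <- function(report) {
  list(
    cohort_summary = report$cohort_summary,
    cutoff_results = lapply(report$cutoff_results, function(r) {
      list(cutoff = r$cutoff, youden = r$youden, auc = r$auc,
           auc_ci = r$auc_ci,
           confusion = unclass(r$confusion),
           metrics = unclass(r$metrics))
    }),
    metric_table = report$metric_table,
    group_tests = lapply(report$group_tests, group_comparison_to_list),
    provenance = report$provenance
  )
}

#' Write an analysis report as JSON
#'
#' Serialization is deterministic: the same report writes byte-identical
#' JSON (no timestamps). Infinite likelihood ratios are encoded as the
#' string `"Inf"`.
#'
#' @param report A `ppp_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "ppp_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analysis report from JSON
#'
#' Reconstructs a `ppp_report` whose rendered tables reproduce the original
#' report's exactly.
#'
#' @param path Path to a JSON file written by [write_report_json()].
#' @return A `ppp_report`.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_or_na <- function(v) {
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  x$metric_table <- as.data.frame(x$metric_table, stringsAsFactors = FALSE)
  for (cn in setdiff(names(x$metric_table), "metric")) {
    x$metric_table[[cn]] <- vapply(x$metric_table[[cn]], num_or_na, numeric(1))
  }
  x$cutoff_results <- lapply(x$cutoff_results, function(r) {
    r$confusion <- structure(lapply(r$confusion, as.integer),
                             class = "confusion_table")
    r$metrics <- structure(lapply(r$metrics, num_or_na),
                           class = "diagnostic_metrics")
    r
  })
  x$group_tests <- lapply(x$group_tests, function(g) {
    structure(g, class = "group_comparison")
  })
  structure(x, class = "ppp_report")
}

#' @export
print.ppp_report <- function(x, ...) {
  cat("PPP analysis report (", x$provenance$input_type, " input, seed ",
      x$provenance$seed, ")\n\n", sep = "")
  cat("Per-class summary:\n")
  print(x$cohort_summary, row.names = FALSE, digits = 4)
  cat("\n", render_table4(x), "\n", sep = "")
  cat("Blood loss across classes: ")
  print(x$group_tests$blood_loss_kruskal)
  invisible(x)
}
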