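# Confusion tables and the diagnostic metric suite for the three ordinal
# PAS dichotomies, plus reconstruction of integer confusion tables from
# printed sensitivity/specificity and group margins.

#' The three ordinal PAS dichotomies
#'
#' Dichotomy A splits no-PAS from any PAS (positive: pa/pi/pp); B splits
#' superficial from deep invasion (positive: pi/pp); C isolates placenta
#' percreta (positive: pp).
#'
#' @param name One of `"A"`, `"B"`, `"C"`.
#' @return List with `name` and `positive_classes`.
#' @export
#' @examples
#' dichotomy_spec("B")$positive_classes
dichotomy_spec <- function(name) {
  name <- match.arg(toupper(name), c("A", "B", "C"))
  positive <- switch(name,
    A = c("pa", "pi", "pp"),
    B = c("pi", "pp"),
    C = "pp")
  structure(list(name = name, positive_classes = positive),
            class = "dichotomy_spec")
}

#' Construct a 2x2 confusion table
#'
#' @param tp,fp,fn,tn Non-negative integer counts (patients).
#' @return Object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion table is empty", call. = FALSE)
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3],
                 tn = counts[4]), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("pos", "neg"),
                              truth = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Build a confusion table from scored patients at a cutoff
#'
#' Prediction is positive when `total_score >= cutoff`; truth is positive
#' when the patient's PAS class belongs to the dichotomy's positive set.
#' With half-integer cutoffs on integer scores the choice of `>=` versus `>`
#' is immaterial.
#'
#' @param scored Output of [score_cohort()] (columns `total_score`,
#'   `pas_class`).
#' @param dichotomy A [dichotomy_spec()] or its name `"A"`/`"B"`/`"C"`.
#' @param cutoff Numeric decision threshold.
#' @return A `confusion_table`.
#' @export
build_confusion <- function(scored, dichotomy, cutoff) {
  if (!is.data.frame(scored) || nrow(scored) == 0L) {
    stop("'scored' must be a non-empty data.frame", call. = FALSE)
  }
  if (is.character(dichotomy)) dichotomy <- dichotomy_spec(dichotomy)
  truth <- as.character(scored$pas_class) %in% dichotomy$positive_classes
  pred <- scored$total_score >= cutoff
  confusion_table(tp = sum(pred & truth), fp = sum(pred & !truth),
                  fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Cohen's kappa from a 2x2 confusion table
#'
#' Unweighted kappa: `(po - pe) / (1 - pe)` with observed agreement
#' `po = (tp + tn) / n` and chance agreement
#' `pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`. When `pe == 1` kappa is
#' defined as 1 if agreement is also perfect, otherwise it is undefined.
#'
#' @param ct A `confusion_table`.
#' @return Numeric kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  po <- (ct$tp + ct$tn) / n
  pe <- ((ct$tp + ct$fp) * (ct$tp + ct$fn) +
           (ct$fn + ct$tn) * (ct$fp + ct$tn)) / n^2
  if (pe == 1) {
    if (po == 1) return(1)
    stop("kappa undefined: chance agreement is 1 but observed agreement < 1",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Diagnostic metric suite from a confusion table
#'
#' Computes sensitivity, specificity, predictive values, Youden index,
#' likelihood ratios, accuracy and Cohen's kappa at full precision.
#' Ratios with a zero denominator are reported as `NA` (undefined), never
#' silently 0 or 1; the positive likelihood ratio is `+Inf` when specificity
#' is 1 with non-zero sensitivity.
#'
#' @param ct A `confusion_table` with at least one true positive-or-negative
#'   on each margin (`tp + fn > 0` and `tn + fp > 0`).
#' @return Object of class `diagnostic_metrics`: named list with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden`, `plr`, `nlr`,
#'   `accuracy`, `kappa`.
#' @export
metrics_from_confusion <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  n_pos <- ct$tp + ct$fn
  n_neg <- ct$tn + ct$fp
  if (n_pos == 0 || n_neg == 0) {
    stop("rate metrics need both classes present (tp+fn > 0 and tn+fp > 0)",
         call. = FALSE)
  }
  sens <- ct$tp / n_pos
  spec <- ct$tn / n_neg
  ppv <- if (ct$tp + ct$fp > 0) ct$tp / (ct$tp + ct$fp) else NA_real_
  npv <- if (ct$tn + ct$fn > 0) ct$tn / (ct$tn + ct$fn) else NA_real_
  plr <- if (spec < 1) sens / (1 - spec) else if (sens > 0) Inf else NA_real_
  nlr <- if (spec > 0) (1 - sens) / spec else NA_real_
  structure(list(
    sensitivity = sens,
    specificity = spec,
    ppv = ppv,
    npv = npv,
    youden = sens + spec - 1,
    plr = plr,
    nlr = nlr,
    accuracy = (ct$tp + ct$tn) / (n_pos + n_neg),
    kappa = cohen_kappa(ct)
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 3, ...) {
  v <- vapply(unclass(x), function(m) format_metric(m, digits), character(1))
  cat(paste0(format(names(v), width = 12), " ", v, collapse = "\n"), "\n")
  invisible(x)
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Inverts printed sensitivity/specificity against known group sizes:
#' `tp = round(sensitivity * n_pos)`, `tn = round(specificity * n_neg)`,
#' with `fn`/`fp` as the complements. Warns if a reconstructed rate deviates
#' from its input by more than half a 3-dp print ulp (5e-4), i.e. when the
#' printed rate is inconsistent with every achievable count over the given
#' margin (inconsistent printed rounding).
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_pos,n_neg Positive/negative group sizes (> 0).
#' @return A `confusion_table`.
#' @export
#' @examples
#' reconstruct_confusion(0.994, 0.700, n_pos = 163, n_neg = 30)
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos > 0, n_neg > 0)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  print_ulp <- 5e-4  # half a unit of 3-dp printed precision
  if (abs(tp / n_pos - sensitivity) > print_ulp) {
    warning("printed sensitivity is inconsistent with an integer count ",
            "over n_pos = ", n_pos, call. = FALSE)
  }
  if (abs(tn / n_neg - specificity) > print_ulp) {
    warning("printed specificity is inconsistent with an integer count ",
            "over n_neg = ", n_neg, call. = FALSE)
  }
  confusion_table(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
}

#' Round half away from zero
#'
#' Reporting helper matching the print convention of clinical tables
#' (0.0005 -> 0.001), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Format one metric value for a 3-dp report table.
format_metric <- function(x, digits = 3) {
  if (is.na(x)) return("NA")
  if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
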