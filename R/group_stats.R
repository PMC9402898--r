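# Between-group comparisons: tie-corrected Kruskal-Wallis and pairwise
# Wilcoxon rank-sum on blood loss, one-way ANOVA on continuous demographics,
# and the Freeman-Halton (r x c Fisher) exact test for categorical tables.

group_result <- function(test_name, statistic, p_value, pairwise = NULL,
                         df = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), df = df, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format_pvalue(x$p_value), "\n", sep = "")
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Format a p-value with an explicit floor
#'
#' Values below 1e-16 print as `"<1e-16"`.
#'
#' @param p Numeric p-value.
#' @return Character scalar.
#' @export
format_pvalue <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 1e-16) "<1e-16" else format(p, digits = 3)
}

as_group_list <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(vapply(samples, length, integer(1)) == 0L)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  if (is.null(names(samples))) {
    names(samples) <- paste0("g", seq_along(samples))
  }
  samples
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (base R [stats::kruskal.test()]). When every
#' value is identical across all groups the statistic is 0 and p = 1.
#'
#' @param samples List of numeric vectors, one per group.
#' @return A `group_comparison` with the H statistic and p-value.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
kruskal_wallis <- function(samples) {
  samples <- as_group_list(samples)
  if (length(unique(unlist(samples))) == 1L) {
    return(group_result("Kruskal-Wallis rank sum test", 0, 1,
                        df = length(samples) - 1L))
  }
  kt <- stats::kruskal.test(samples)
  group_result("Kruskal-Wallis rank sum test", kt$statistic, kt$p.value,
               df = unname(kt$parameter))
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test for every pair of groups, using the normal
#' approximation with tie and continuity corrections, with multiplicity
#' adjustment (default Bonferroni).
#'
#' @param samples List of numeric vectors, each of size >= 2.
#' @param adjust Adjustment method: any of [stats::p.adjust.methods],
#'   e.g. `"bonferroni"` (default) or `"none"`.
#' @return A `group_comparison`; `statistic`/`p_value` carry the overall
#'   Kruskal-Wallis result and `pairwise` is a data.frame with one row per
#'   pair (`group_i`, `group_j`, `statistic` = Wilcoxon W, `p_value`,
#'   `adjusted_p`).
#' @export
pairwise_ranksum <- function(samples, adjust = "bonferroni") {
  samples <- as_group_list(samples)
  adjust <- match.arg(adjust, stats::p.adjust.methods)
  if (any(vapply(samples, length, integer(1)) < 2L)) {
    stop("every group must have >= 2 observations for the rank-sum test",
         call. = FALSE)
  }
  pairs <- utils::combn(length(samples), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    wt <- suppressWarnings(
      stats::wilcox.test(samples[[i]], samples[[j]],
                         exact = FALSE, correct = TRUE))
    data.frame(group_i = names(samples)[i], group_j = names(samples)[j],
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$adjusted_p <- stats::p.adjust(pw$p_value, method = adjust)
  overall <- kruskal_wallis(samples)
  group_result("Pairwise Wilcoxon rank-sum (normal approximation)",
               overall$statistic, overall$p_value, pairwise = pw,
               df = overall$df)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA F test. The degenerate case of
#' zero within-group variance with unequal means is reported explicitly as
#' `statistic = Inf`, `p = 0`.
#'
#' @param samples List of numeric vectors, each of size >= 2.
#' @return A `group_comparison` with the F statistic, degrees of freedom and
#'   p-value.
#' @export
one_way_anova <- function(samples) {
  samples <- as_group_list(samples)
  if (any(vapply(samples, length, integer(1)) < 2L)) {
    stop("every group must have >= 2 observations for ANOVA", call. = FALSE)
  }
  x <- unlist(samples)
  g <- factor(rep(names(samples), vapply(samples, length, integer(1))))
  ssw <- sum(vapply(samples, function(v) sum((v - mean(v))^2), numeric(1)))
  means <- vapply(samples, mean, numeric(1))
  if (ssw == 0) {
    if (max(means) > min(means)) {
      return(group_result("One-way ANOVA", Inf, 0,
                          df = c(length(samples) - 1L,
                                 length(x) - length(samples))))
    }
    return(group_result("One-way ANOVA", NaN, 1,
                        df = c(length(samples) - 1L,
                               length(x) - length(samples))))
  }
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  group_result("One-way ANOVA", ft$statistic, ft$p.value,
               df = unname(ft$parameter))
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Exact conditional test generalizing Fisher's 2 x 2 test: the p-value is
#' the total hypergeometric probability of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (base R [stats::fisher.test()] network enumeration). All-zero rows and
#' columns are dropped first, so empty categories do not change the result.
#'
#' @param table Matrix of non-negative integer counts. Enumeration bounds:
#'   total count <= 500 and at most 16 cells after dropping empty
#'   rows/columns.
#' @return A `group_comparison` with the exact p-value (statistic is `NA`:
#'   the test is defined by its p-value, not a single statistic).
#' @export
#' @examples
#' freeman_halton_exact(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))
freeman_halton_exact <- function(table) {
  table <- as.matrix(table)
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) {
    # no free margin left: only one table is consistent with the margins
    return(group_result("Freeman-Halton exact test", NA_real_, 1))
  }
  if (sum(table) > 500 || length(table) > 16) {
    stop("table too large for exact enumeration (need total <= 500 and ",
         "<= 16 cells); a Monte-Carlo approximation is not implemented",
         call. = FALSE)
  }
  ft <- stats::fisher.test(table, workspace = 2e7)
  group_result("Freeman-Halton exact test", NA_real_, ft$p.value)
}
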