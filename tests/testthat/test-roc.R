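test_that("ROC curve endpoints, monotonicity and AUC on canonical inputs", {
  # perfect separation
  r <- roc_curve(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)

  # all scores tied: single non-trivial operating point, chance AUC
  r_tied <- roc_curve(rep(5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r_tied$auc, 0.5)

  # ties across classes: trapezoid equals tie-corrected concordance
  r_mix <- roc_curve(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(r_mix$auc, 0.875)

  expect_equal(r_mix$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r_mix$points[nrow(r_mix$points), ]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r_mix$points$fpr) >= 0))
  expect_true(all(diff(r_mix$points$tpr) >= 0))
  expect_true(all(diff(r_mix$thresholds) < 0))

  expect_error(roc_curve(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
})

test_that("trapezoidal AUC equals brute-force concordance on random data", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(1:12, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with pROC on a tied, noisy instance", {
  set.seed(5)
  scores <- sample(1:15, 80, replace = TRUE)
  labels <- c(TRUE, FALSE, runif(78) < plogis((scores[-(1:2)] - 8) / 3))
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         direction = "<"))))
  expect_equal(roc_curve(scores, labels)$auc, ref)
})

test_that("Youden cutoff: examples, exhaustive-scan oracle, tie-break", {
  res <- select_cutoff_youden(c(1, 2, 3, 9), c(0, 0, 1, 1), n_boot = 0)
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$youden, 1)
  expect_identical(res$youden, res$metrics$youden)

  # all scores equal: no discrimination, the all-positive rule wins the tie
  # and sits below the minimum
  res_flat <- select_cutoff_youden(rep(4, 6), c(1, 0, 1, 0, 1, 0), n_boot = 0)
  expect_equal(res_flat$youden, 0)
  expect_lt(res_flat$cutoff, 4)

  set.seed(77)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    scores <- sample(1:10, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    res_i <- select_cutoff_youden(scores, labels, n_boot = 0)
    expect_equal(res_i$youden, oracle_best_youden(scores, labels))
    # invariance of the achieved confusion table under a strictly monotone
    # transform of the scores
    res_t <- select_cutoff_youden(scores^3 + 2, labels, n_boot = 0)
    expect_identical(unclass(res_t$confusion), unclass(res_i$confusion))
  }
})

test_that("stratified bootstrap CI is deterministic and degenerates correctly", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(0, 0, 0, 1, 1, 1)
  ci <- auc_ci_bootstrap(scores, labels, n_boot = 200, seed = 1)
  expect_equal(ci, c(1, 1))

  set.seed(8)
  s <- rnorm(60) + rep(c(0, 1), each = 30)
  l <- rep(c(FALSE, TRUE), each = 30)
  ci1 <- auc_ci_bootstrap(s, l, n_boot = 300, seed = 42)
  ci2 <- auc_ci_bootstrap(s, l, n_boot = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])
  expect_error(auc_ci_bootstrap(s, l, n_boot = 50), ">= 100")

  # interval width shrinks as the cohort grows
  width <- function(n_per_class, seed) {
    set.seed(seed)
    s <- rnorm(2 * n_per_class) + rep(c(0, 1), each = n_per_class)
    l <- rep(c(FALSE, TRUE), each = n_per_class)
    ci <- auc_ci_bootstrap(s, l, n_boot = 300, seed = 3)
    ci[2] - ci[1]
  }
  expect_lt(width(1200, 2), width(100, 2))
})

test_that("three-dichotomy run recovers the banded boundary values", {
  scored <- score_cohort(banded_cohort())
  res <- run_three_dichotomies(scored, n_boot = 0)
  expect_named(res, c("A", "B", "C"))
  expect_equal(vapply(res, function(r) r$cutoff, numeric(1)),
               c(A = 5.5, B = 11.5, C = 15.5))
  expect_equal(vapply(res, function(r) r$youden, numeric(1)),
               c(A = 1, B = 1, C = 1))
  expect_equal(vapply(res, function(r) r$auc, numeric(1)),
               c(A = 1, B = 1, C = 1))
})

test_that("three-dichotomy run works on a minimal cohort and flags missing classes", {
  minimal <- score_cohort(make_cohort(c(2, 3, 7, 8, 12, 13, 18, 19),
                                      rep(pas_levels(), each = 2)))
  res <- run_three_dichotomies(minimal, n_boot = 0)
  expect_length(res, 3)

  no_pp <- minimal[minimal$pas_class != "pp", ]
  expect_error(run_three_dichotomies(no_pp, n_boot = 0), "dichotomy C")
})

test_that("default synthetic cohort separates all three dichotomies", {
  scored <- score_cohort(generate_cohort(default_config()))
  res <- run_three_dichotomies(scored, n_boot = 0)
  for (r in res) expect_gt(r$auc, 0.5)
})
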