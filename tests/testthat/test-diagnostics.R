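test_that("build_confusion partitions the cohort at a cutoff", {
  co <- score_cohort(make_cohort(c(1, 9), c("non_pas", "pi")))
  ct <- build_confusion(co, "A", cutoff = 5.5)
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  ct2 <- build_confusion(co, "A", cutoff = 100)
  expect_equal(ct2$tp + ct2$fp, 0L)

  scored <- score_cohort(generate_cohort(default_config()))
  ct3 <- build_confusion(scored, "A", cutoff = 5.5)
  expect_equal(ct3$tp + ct3$fp + ct3$fn + ct3$tn, 193L)

  expect_error(build_confusion(scored[0, ], "A", 5.5), "non-empty")
})

test_that("metric suite reproduces published-table values from integer counts", {
  # counts reconstructed from the published rates and group sizes
  cases <- list(
    list(ct = confusion_table(tp = 162, fp = 9, fn = 1, tn = 21),
         exp = c(sensitivity = 0.994, specificity = 0.700, ppv = 0.947,
                 npv = 0.955, youden = 0.694, plr = 3.313, nlr = 0.009)),
    list(ct = confusion_table(tp = 69, fp = 14, fn = 17, tn = 93),
         exp = c(sensitivity = 0.802, specificity = 0.869, ppv = 0.831,
                 npv = 0.845, youden = 0.671, plr = 6.132, nlr = 0.227)),
    list(ct = confusion_table(tp = 15, fp = 7, fn = 11, tn = 160),
         exp = c(sensitivity = 0.577, specificity = 0.958, ppv = 0.682,
                 npv = 0.936, youden = 0.535, plr = 13.764, nlr = 0.442))
  )
  for (case in cases) {
    m <- metrics_from_confusion(case$ct)
    got <- round_half_up(unlist(unclass(m)[names(case$exp)]), 3)
    expect_equal(got, case$exp, tolerance = 1e-12)
  }
})

test_that("metric suite handles simple and degenerate tables", {
  m <- metrics_from_confusion(confusion_table(3, 1, 2, 4))
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$youden, 0.4)
  expect_identical(m$youden, m$sensitivity + m$specificity - 1)

  perfect <- metrics_from_confusion(confusion_table(10, 0, 0, 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$nlr, 0)
  expect_identical(perfect$plr, Inf)  # spec = 1, not reported as a number

  # zero predicted positives: ppv undefined, never 0
  none_pos <- metrics_from_confusion(confusion_table(0, 0, 5, 5))
  expect_true(is.na(none_pos$ppv))
  expect_error(metrics_from_confusion(confusion_table(0, 5, 0, 5)),
               "both classes")
})

test_that("Cohen's kappa matches direct po/pe arithmetic", {
  expect_equal(cohen_kappa(confusion_table(10, 0, 0, 10)), 1)
  expect_equal(round_half_up(cohen_kappa(confusion_table(162, 9, 1, 21)), 3),
               0.779)
  expect_equal(round_half_up(cohen_kappa(confusion_table(69, 14, 17, 93)), 3),
               0.674)
  # degenerate all-true-positive table: chance agreement is 1 but so is
  # observed agreement, hence kappa is defined as 1
  expect_equal(cohen_kappa(confusion_table(5, 0, 0, 0)), 1)
})

test_that("reconstruct_confusion inverts printed rates against margins", {
  ct <- reconstruct_confusion(0.994, 0.700, n_pos = 163, n_neg = 30)
  expect_equal(unclass(ct)[c("tp", "fn", "tn", "fp")],
               list(tp = 162L, fn = 1L, tn = 21L, fp = 9L))

  ct2 <- reconstruct_confusion(1, 1, 10, 10)
  expect_equal(c(ct2$tp, ct2$fp, ct2$fn, ct2$tn), c(10L, 0L, 0L, 10L))

  ct3 <- reconstruct_confusion(0.802, 0.869, n_pos = 86, n_neg = 107)
  expect_equal(c(ct3$tp, ct3$fn, ct3$tn, ct3$fp), c(69L, 17L, 93L, 14L))

  # a rate irreconcilable with the margin triggers the rounding warning
  expect_warning(reconstruct_confusion(0.8, 0.5, n_pos = 7, n_neg = 10),
                 "sensitivity")
})

test_that("metrics -> reconstruct round-trips any table; metric identities hold", {
  set.seed(11)
  for (i in 1:100) {
    counts <- c(sample(0:40, 1), sample(0:40, 1),
                sample(0:40, 1), sample(0:40, 1))
    n_pos <- counts[1] + counts[3]
    n_neg <- counts[4] + counts[2]
    if (n_pos == 0 || n_neg == 0) next
    ct <- confusion_table(tp = counts[1], fp = counts[2],
                          fn = counts[3], tn = counts[4])
    m <- metrics_from_confusion(ct)
    back <- reconstruct_confusion(m$sensitivity, m$specificity, n_pos, n_neg)
    expect_identical(unclass(back), unclass(ct))

    # plr > 1 iff youden > 0, whenever both defined and finite
    if (!is.na(m$plr) && is.finite(m$plr) && m$youden != 0) {
      expect_identical(m$plr > 1, m$youden > 0)
    }
    # kappa = 1 iff no discordant cells; kappa never exceeds raw agreement
    expect_identical(isTRUE(all.equal(m$kappa, 1)), ct$fp == 0 && ct$fn == 0)
    expect_lte(m$kappa, m$accuracy + 1e-12)
  }
})
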