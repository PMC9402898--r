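# Fixture builders and independent oracles used across the suite.

# Feature vector with a given total score: cesarean item first takes 1 (or 2
# if needed), the remainder is distributed over the ten MRI items as 2s then
# a single 1.
features_for_score <- function(total) {
  stopifnot(total >= 1, total <= 22)
  ces <- if (total - 1 > 20) 2L else 1L
  rem <- total - ces
  vals <- integer(10)
  full <- rem %/% 2
  vals[seq_len(full)] <- 2L
  if (rem %% 2 == 1) vals[full + 1] <- 1L
  stats::setNames(c(vals, ces), mri_score_items())
}

# Cohort data.frame from per-patient total scores and class labels.
make_cohort <- function(scores, classes, blood = NULL, ids = NULL) {
  n <- length(scores)
  if (is.null(blood)) blood <- rep(500, n)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  feats <- do.call(rbind, lapply(scores, function(s) {
    as.data.frame(as.list(features_for_score(s)))
  }))
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
        feats,
        data.frame(pas_class = classes, blood_loss_ml = blood,
                   stringsAsFactors = FALSE))
}

# Cohort whose classes occupy disjoint score bands 1-5 / 6-11 / 12-15 /
# 16-22, forcing Youden-optimal boundaries 5.5 / 11.5 / 15.5.
banded_cohort <- function() {
  make_cohort(
    scores = c(1, 3, 5, 5, 6, 8, 11, 11, 12, 14, 15, 15, 16, 19, 22, 22),
    classes = rep(pas_levels(), each = 4),
    blood = rep(c(225, 600, 1500, 3000), each = 4))
}

# Tie-corrected pairwise concordance (Mann-Whitney AUC): brute force over
# all positive x negative pairs.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every threshold position in the sorted data
# (prediction positive at score >= cutoff), including the all-positive and
# all-negative rules.
oracle_best_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  cuts <- c(min(scores) - 1, sort(unique(scores)), max(scores) + 1)
  best <- -Inf
  for (cut in cuts) {
    sens <- sum(scores >= cut & labels) / sum(labels)
    spec <- sum(scores < cut & !labels) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration: sum of P(table) over all tables with the same margins whose
# probability is <= that of the observed table (with the classical 1e-7
# relative tolerance for ties).
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
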