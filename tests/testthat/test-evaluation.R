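# Construct labels/probabilities realizing a given confusion matrix.
probs_for_confusion <- function(tp, fn, tn, fp) {
  labels <- c(rep(1, tp + fn), rep(0, tn + fp))
  probs <- c(rep(0.9, tp), rep(0.1, fn), rep(0.1, tn), rep(0.9, fp))
  list(labels = labels, probs = probs)
}

test_that("screening metrics reproduce the clinical usability numbers", {
  d <- probs_for_confusion(tp = 33, fn = 7, tn = 43, fp = 7)
  m <- binary_metrics(d$labels, d$probs)
  expect_equal(m$sensitivity, 0.825)
  expect_equal(m$specificity, 0.86)
  expect_equal(round(m$lr_positive, 2), 5.89)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 90)
})

test_that("binary metrics handle perfect and degenerate classifiers", {
  perfect <- binary_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  all_pos <- binary_metrics(c(1, 1, 0, 0), rep(0.9, 4))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$lr_positive, 1)       # sens / (1 - spec) = 1/1
  one_class <- binary_metrics(c(1, 1), c(0.2, 0.9))
  expect_true(is.na(one_class$auc))
  # threshold ties count as positive predictions
  tie <- binary_metrics(c(1, 0), c(0.5, 0.5), threshold = 0.5)
  expect_equal(tie$tp, 1)
  expect_equal(tie$fp, 1)
})

test_that("LR+ is consistent with its defining identity", {
  set.seed(3)
  for (rep_ in 1:20) {
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) next
    m <- binary_metrics(labels, runif(50))
    if (m$specificity < 1) {
      expect_equal(m$lr_positive * (1 - m$specificity), m$sensitivity,
                   tolerance = 1e-12)
    } else {
      expect_equal(m$lr_positive, Inf)
    }
  }
})

test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 1), c(0.1, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_true(is.na(auc(c(1, 1), c(0.3, 0.4))))
  pair_oracle <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
    total / (length(pos) * length(neg))
  }
  set.seed(17)
  for (rep_ in 1:25) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)     # coarse grid forces ties
    expect_identical(auc(labels, scores), pair_oracle(labels, scores))
  }
})

test_that("the incremental fold plan grows by ceiling(i*n/k) disjoint patients", {
  ids <- sprintf("p%03d", 1:100)
  plan <- incremental_kfold(ids, k = 5, seed = 1)
  expect_equal(plan$n_patients, c(20, 40, 60, 80, 100))
  expect_equal(plan$cumulative_fraction, seq(0.2, 1, 0.2))
  for (i in 1:5) {
    expect_length(intersect(plan$train_ids[[i]], plan$val_ids[[i]]), 0)
    expect_equal(length(plan$train_ids[[i]]) + length(plan$val_ids[[i]]),
                 plan$n_patients[i])
  }
  expect_setequal(c(plan$train_ids[[5]], plan$val_ids[[5]]), ids)
  expect_identical(incremental_kfold(ids, k = 5, seed = 1), plan)
  expect_false(identical(incremental_kfold(ids, k = 5, seed = 2), plan))
  # ragged case
  plan7 <- incremental_kfold(ids[1:47], k = 5, seed = 3)
  expect_equal(plan7$n_patients, ceiling(1:5 * 47 / 5))
  expect_error(incremental_kfold(ids[1:3], k = 5),
               class = "osadetect_config_error")
})

test_that("patient-wise splits are disjoint and cover the cohort", {
  ids <- sprintf("p%02d", 1:30)
  sp <- split_patients(ids, seed = 4)
  expect_length(sp$train, 21)
  expect_length(sp$val, 6)
  expect_length(sp$test, 3)
  expect_setequal(unlist(sp), ids)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
})

test_that("the AHI is positive windows divided by recording hours", {
  expect_equal(estimate_ahi(rep(c(1, 0), c(40, 440)), 8), 5)
  expect_equal(estimate_ahi(rep(0, 480), 8), 0)
  expect_equal(estimate_ahi(rep(1, 480), 8), 60)
})

test_that("severity bins follow the clinical half-open intervals", {
  expect_equal(as.character(severity_class(c(0, 4.9, 5, 14.9, 15, 29.9, 30, 60))),
               c("no_apnea", "no_apnea", "mild", "mild",
                 "moderate", "moderate", "severe", "severe"))
  expect_error(severity_class(-1), class = "osadetect_domain_error")
  # monotone in AHI
  ahis <- sort(runif(50, 0, 60))
  cls <- severity_class(ahis)
  expect_true(!is.unsorted(cls))
})

test_that("linearly weighted kappa matches the direct disagreement formula", {
  expect_equal(weighted_kappa(matrix(c(2, 1, 1, 2), 2, 2)), 1 / 3)
  expect_equal(weighted_kappa(diag(c(3, 4, 5, 6))), 1)
  # independent oracle: disagreement-weight formulation
  kappa_oracle <- function(O) {
    K <- nrow(O); n <- sum(O)
    d <- abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
    E <- outer(rowSums(O), colSums(O)) / n
    1 - sum(d * O) / sum(d * E)
  }
  set.seed(31)
  for (rep_ in 1:100) {
    O <- matrix(rpois(16, 4) + 1, 4, 4)
    expect_equal(weighted_kappa(O), kappa_oracle(O), tolerance = 1e-12)
  }
})

test_that("the AHI report aggregates agreement statistics correctly", {
  ref <- c(2, 8, 20, 40, 4, 33)
  perfect <- ahi_report(ref, ref)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_true(all(perfect$confusion[lower.tri(perfect$confusion)] == 0))
  # predicting the mean gives R^2 = 0
  at_mean <- ahi_report(rep(mean(ref), 6), ref)
  expect_equal(at_mean$r_squared, 0)
  # zero reference variance flags R^2 undefined
  expect_true(is.na(ahi_report(c(5, 6), c(10, 10))$r_squared))
  # confusion rows sum to reference class counts
  est <- c(3, 12, 18, 29, 6, 35)
  rep_ <- ahi_report(est, ref)
  expect_equal(unname(rowSums(rep_$confusion)),
               as.vector(table(severity_class(ref))))
  # screening metrics at the 5/15/30 cutoffs
  expect_equal(rep_$screening$cutoff, c(5, 15, 30))
  scr5 <- rep_$screening[1, ]
  lab5 <- as.integer(ref >= 5); prd5 <- as.integer(est >= 5)
  expect_equal(scr5$accuracy, mean(lab5 == prd5))
  g <- glance(rep_)
  expect_equal(g$n_patients, 6)
  expect_true(all(c("hit_moderate", "hit_severe") %in% names(g)))
  expect_equal(nrow(tidy(rep_)), 6)
})
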