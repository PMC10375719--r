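SEVERITY_LEVELS <- c("no_apnea", "mild", "moderate", "severe")

confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  lr_pos <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else Inf
  tibble::tibble(accuracy = (tp + tn) / n, sensitivity = sens,
                 specificity = spec, precision = prec, npv = npv, f1 = f1,
                 lr_positive = lr_pos, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Window-level classification metrics
#'
#' Thresholds the probabilities (ties predict positive) and reports the
#' standard confusion-derived rates plus the rank-based AUC, the positive
#' likelihood ratio `LR+ = sensitivity / (1 - specificity)` (`Inf` when
#' specificity is 1) and the mean clipped binary cross-entropy.
#'
#' @param labels Binary vector.
#' @param probabilities Scores in `[0, 1]`, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble of class `metrics_report` with `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `npv`, `f1`, `auc`,
#'   `lr_positive`, `loss`, `threshold` and the confusion counts. `auc` is
#'   `NA` when only one class is present.
#' @export
#' @examples
#' binary_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))
binary_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0, 1)))
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  out <- confusion_metrics(tp, fp, tn, fn)
  out$auc <- if (length(unique(labels)) < 2) NA_real_ else auc(labels, probabilities)
  out$loss <- bce_loss(labels, probabilities)
  out$threshold <- threshold
  out <- out[, c("accuracy", "sensitivity", "specificity", "precision",
                 "npv", "f1", "auc", "lr_positive", "loss", "threshold",
                 "tp", "fp", "tn", "fn")]
  class(out) <- c("metrics_report", class(out))
  out
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Computed with the rank method, so it equals the pairwise statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)` exactly.
#'
#' @param labels Binary vector with both classes present.
#' @param probabilities Scores.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))  # 0.75
auc <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Incremental patient-grouped K-fold plan
#'
#' Patients are shuffled once; fold `i` uses the first `ceiling(i * n / k)`
#' patients of the shuffled order, split patient-wise into train and
#' validation, so the cumulative cohort grows by about `1/k` per fold and
#' the final fold covers everyone. Train and validation patients are
#' disjoint within every fold.
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param k Number of folds (>= 2).
#' @param inner_val_fraction Fraction of each fold's patients held out for
#'   validation.
#' @param seed Shuffle seed.
#' @return A `fold_plan` tibble: `fold`, `train_ids`, `val_ids`
#'   (list-columns), `n_patients`, `cumulative_fraction`.
#' @export
incremental_kfold <- function(patient_ids, k = 5, inner_val_fraction = 0.2,
                              seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (k < 2 || n < k) {
    abort(sprintf("need at least k = %d patients (have %d)", k, n),
          class = "osadetect_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% 2147483647)
  shuffled <- sample(patient_ids)
  rows <- purrr::map(seq_len(k), function(i) {
    m <- ceiling(i * n / k)
    ids <- shuffled[seq_len(m)]
    n_val <- max(1L, round(inner_val_fraction * m))
    if (n_val >= m) n_val <- m - 1L
    tibble::tibble(fold = i,
                   train_ids = list(ids[seq_len(m - n_val)]),
                   val_ids = list(ids[(m - n_val + 1):m]),
                   n_patients = m,
                   cumulative_fraction = m / n)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fold_plan", class(out))
  out
}

#' Patient-wise 70/20/10 split
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param fractions Named numeric `c(train=, val=, test=)` summing to 1.
#' @param seed Shuffle seed.
#' @return A list with `train`, `val`, `test` character vectors, pairwise
#'   disjoint and jointly covering the cohort.
#' @export
split_patients <- function(patient_ids, fractions = c(train = 0.7, val = 0.2,
                                                      test = 0.1),
                           seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% 2147483647)
  shuffled <- sample(patient_ids)
  n_train <- max(1L, round(fractions[["train"]] * n))
  n_val <- max(1L, round(fractions[["val"]] * n))
  if (n_train + n_val >= n) n_train <- n - n_val - 1L
  list(train = shuffled[seq_len(n_train)],
       val = shuffled[n_train + seq_len(n_val)],
       test = shuffled[(n_train + n_val + 1):n])
}

#' Estimate the AHI from window predictions
#'
#' Every positive 60-s window counts as one respiratory event; the AHI is
#' the positive-window count divided by the total recording time in hours
#' (TRT, not total sleep time — a deliberate portable-monitor convention
#' that can understate severity).
#'
#' @param window_predictions Binary vector of consecutive non-overlapping
#'   window predictions for one patient.
#' @param trt_hours Total recording time in hours (default 8).
#' @return Events per hour.
#' @export
#' @examples
#' estimate_ahi(rep(c(1, 0), c(40, 440)), 8)  # 5
estimate_ahi <- function(window_predictions, trt_hours = 8) {
  stopifnot(trt_hours > 0, all(window_predictions %in% c(0, 1)))
  sum(window_predictions) / trt_hours
}

#' OSA severity class from an AHI
#'
#' Half-open clinical bins: `AHI < 5` no apnea, `5 <= AHI < 15` mild,
#' `15 <= AHI < 30` moderate, `AHI >= 30` severe.
#'
#' @param ahi Numeric vector of non-negative AHI values.
#' @return An ordered factor with levels
#'   `no_apnea < mild < moderate < severe`.
#' @export
#' @examples
#' severity_class(c(4.9, 5, 15, 30))
severity_class <- function(ahi) {
  if (any(ahi < 0)) {
    abort("AHI must be non-negative", class = "osadetect_domain_error")
  }
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), labels = SEVERITY_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' Linearly weighted Cohen's kappa
#'
#' Agreement-weighted form: with `K` ordinal classes and weights
#' `w_ij = 1 - |i - j| / (K - 1)`, kappa is
#' `(p_o,w - p_e,w) / (1 - p_e,w)` where `p_o,w` and `p_e,w` are the
#' weighted observed and chance-expected agreement proportions.
#'
#' @param confusion Square contingency matrix (reference in rows, estimate
#'   in columns) of an ordinal classification.
#' @return Kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  K <- nrow(confusion)
  n <- sum(confusion)
  stopifnot(n > 0)
  w <- 1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  po <- sum(w * confusion) / n
  expected <- outer(rowSums(confusion), colSums(confusion)) / n
  pe <- sum(w * expected) / n
  (po - pe) / (1 - pe)
}

#' Patient-level AHI agreement report
#'
#' Aggregates per-patient estimated vs reference AHI into the coefficient of
#' determination (R^2 = 1 - SS_res / SS_tot), the 4 x 4 severity confusion
#' matrix (reference rows), the linearly weighted Cohen's kappa on severity,
#' and binary screening metrics at the AHI cutoffs (patient positive iff
#' `AHI >= cutoff`).
#'
#' @param estimates,references Numeric vectors of per-patient AHI
#'   (events/hour), `>= 2` patients.
#' @param patient_ids Optional patient ids.
#' @param cutoffs Screening thresholds in events/hour (default 5, 15, 30).
#' @return An `ahi_report` object; see [tidy.ahi_report()],
#'   [glance.ahi_report()] and `autoplot()`.
#' @export
ahi_report <- function(estimates, references, patient_ids = NULL,
                       cutoffs = c(5, 15, 30)) {
  stopifnot(length(estimates) == length(references), length(estimates) >= 2,
            all(references >= 0), all(estimates >= 0))
  patient_ids <- patient_ids %||% sprintf("p%03d", seq_along(estimates))
  ss_res <- sum((references - estimates)^2)
  ss_tot <- sum((references - mean(references))^2)
  r_squared <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  sev_est <- severity_class(estimates)
  sev_ref <- severity_class(references)
  confusion <- table(reference = sev_ref, estimate = sev_est)
  confusion <- unclass(confusion)
  kappa <- weighted_kappa(confusion)
  screening <- dplyr::bind_rows(lapply(cutoffs, function(ct) {
    lab <- as.integer(references >= ct)
    pred <- as.integer(estimates >= ct)
    out <- confusion_metrics(sum(pred & lab), sum(pred & !lab),
                             sum(!pred & !lab), sum(!pred & lab))
    out$auc <- if (length(unique(lab)) < 2) NA_real_ else auc(lab, estimates)
    dplyr::mutate(out, cutoff = ct, .before = 1)
  }))
  structure(list(
    patients = tibble::tibble(patient_id = patient_ids,
                              estimated_ahi = estimates,
                              reference_ahi = references,
                              severity_est = sev_est,
                              severity_ref = sev_ref),
    r_squared = r_squared, kappa = kappa, confusion = confusion,
    screening = screening, cutoffs = cutoffs),
    class = "ahi_report")
}

#' @export
print.ahi_report <- function(x, ...) {
  cat(sprintf("<ahi_report> %d patients: R^2 = %.3f, weighted kappa = %.3f\n",
              nrow(x$patients), x$r_squared, x$kappa))
  print(x$confusion)
  invisible(x)
}

#' Tidy / summarize an AHI report
#'
#' `tidy()` returns the per-patient table; `glance()` the one-row aggregate
#' summary.
#'
#' @param x An `ahi_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ahi_report
#' @export
tidy.ahi_report <- function(x, ...) x$patients

#' @rdname tidy.ahi_report
#' @method glance ahi_report
#' @export
glance.ahi_report <- function(x, ...) {
  diag_rate <- diag(x$confusion) / pmax(rowSums(x$confusion), 1)
  tibble::tibble(n_patients = nrow(x$patients), r_squared = x$r_squared,
                 weighted_kappa = x$kappa,
                 hit_no_apnea = diag_rate[1], hit_mild = diag_rate[2],
                 hit_moderate = diag_rate[3], hit_severe = diag_rate[4])
}

#' @rdname tidy.ahi_report
#' @param object An `ahi_report`.
#' @method autoplot ahi_report
#' @export
autoplot.ahi_report <- function(object, ...) {
  df <- object$patients
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_ahi,
                                   y = .data$estimated_ahi,
                                   colour = .data$severity_ref)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotdash") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "reference AHI (events/h)",
                  y = "estimated AHI (events/h)", colour = "severity",
                  title = sprintf("R² = %.2f", object$r_squared)) +
    ggplot2::theme_minimal()
}
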