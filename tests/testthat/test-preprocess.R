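make_record <- function(spo2, hr = NULL, n = length(spo2)) {
  hr <- hr %||% rep(65, n)
  signal_record("t", spo2, hr, sin(seq_len(n)), cos(seq_len(n)))
}

test_that("artifact interpolation replaces flagged samples linearly", {
  rec <- make_record(c(96, 95, 0, 97, 96))
  out <- remove_artifacts(rec)
  expect_equal(out$spo2, c(96, 95, 96, 97, 96))  # midpoint of 95 and 97
  # HR above 200 bpm is flagged and replaced
  rec <- make_record(rep(96, 5), hr = c(60, 220, 64, 65, 66))
  out <- remove_artifacts(rec)
  expect_equal(out$hr, c(60, 62, 64, 65, 66))
  expect_true(all(out$hr >= 40 & out$hr <= 200))
})

test_that("artifact interpolation handles edges, is idempotent and identity-safe", {
  rec <- make_record(c(0, 0, 95, 96, 120, 96, 0))
  out <- remove_artifacts(rec)
  expect_equal(out$spo2, c(95, 95, 95, 96, 96, 96, 96))
  expect_identical(remove_artifacts(out), out)            # idempotent
  clean <- make_record(c(95, 96, 97), hr = c(60, 61, 62))
  expect_identical(remove_artifacts(clean), clean)        # no-op on clean data
  # effort channels untouched even when SpO2/HR are repaired
  expect_identical(out$thor, rec$thor)
})

test_that("a fully flagged channel is rejected as a data-quality failure", {
  rec <- make_record(rep(0, 10))
  expect_error(remove_artifacts(rec), class = "osadetect_quality_error")
})

test_that("windowing produces 480 labeled windows from a full record", {
  p <- test_params(n_patients = 1, record_seconds = 28800, ahi = 10)
  gen <- generate_record(p, 0)
  ws <- make_windows(gen$record, gen$events)
  expect_equal(length(ws$labels), 480)
  expect_equal(dim(ws$windows), c(480, 60, 4))
  expect_equal(ws$window_start_s, (0:479) * 60)
  # windows tile the record exactly
  expect_equal(ws$windows[3, , 1], gen$record$spo2[121:180])
  # no events -> all zero labels
  ws0 <- make_windows(gen$record, event_annotations())
  expect_true(all(ws0$labels == 0L))
})

test_that("a 25-s event at t=100 marks exactly the window with >=10 s overlap", {
  p <- test_params(n_patients = 1, record_seconds = 600, ahi = 0)
  rec <- generate_record(p, 0)$record
  ev <- event_annotations("obstructive_apnea", 100, 25)
  ws <- make_windows(rec, ev)
  # [60,120) gets 20 s, [120,180) only 5 s
  expect_equal(which(ws$labels == 1L), 2L)
})

test_that("window labeling follows the >=10-s union-overlap rule", {
  ev <- event_annotations("obstructive_apnea", 100, 25)
  expect_equal(label_window(120, 180, ev), 0L)   # 5-s overlap
  expect_equal(label_window(60, 120, ev), 1L)    # 20-s overlap
  # a 9-s event fully inside the window is below the threshold
  expect_equal(label_window(0, 60, event_annotations("hypopnea", 20, 9)), 0L)
  # two 6-s events union to 12 s -> positive
  two <- event_annotations(c("hypopnea", "hypopnea"), c(0, 20), c(6, 6))
  expect_equal(label_window(0, 60, two), 1L)
  # overlapping events are not double-counted
  dup <- event_annotations(c("hypopnea", "hypopnea"), c(10, 12), c(8, 6))
  expect_equal(label_window(0, 60, dup), 0L)     # union is [10,18) u [12,18) = 8 s
  # central events only count when enabled
  cen <- event_annotations("central_apnea", 0, 30)
  expect_equal(label_window(0, 60, cen), 0L)
  expect_equal(label_window(0, 60, cen, include_central = TRUE), 1L)
})

test_that("interval labeling matches a per-second brute-force counter", {
  set.seed(123)
  types <- c("obstructive_apnea", "hypopnea", "central_apnea", "other")
  for (rep_ in 1:1000) {
    n_ev <- sample(0:4, 1)
    events <- event_annotations(
      sample(types, n_ev, replace = TRUE),
      start_s = sample(0:540, n_ev, replace = TRUE),
      duration_s = sample(1:70, n_ev, replace = TRUE))
    ws <- sample(0:9, 1) * 60
    inc <- sample(c(TRUE, FALSE), 1)
    expect_identical(
      label_window(ws, ws + 60, events, include_central = inc),
      label_window_oracle(ws, ws + 60, events, include_central = inc))
  }
})

test_that("per-window standardization is an exact per-channel z-score", {
  w <- matrix(rnorm(240, mean = 10, sd = 2), 60, 4)
  z <- standardize_window(w)
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-9)
  pop_sd <- sqrt(colMeans(sweep(z, 2, colMeans(z))^2))
  expect_equal(pop_sd, rep(1, 4), tolerance = 1e-6)
  # a sample one (population) sd above the mean maps to z = 1
  w1 <- matrix(c(8, 12), 60, 4)                  # mean 10, pop sd 2
  expect_equal(standardize_window(w1)[1, 1], -1)
  expect_equal(standardize_window(w1)[2, 2], 1)
  # constant channel -> all zeros
  w[, 2] <- 5
  expect_true(all(standardize_window(w)[, 2] == 0))
  # min-max mode rescales to [0, 1]
  mm <- standardize_window(w, method = "minmax")
  expect_equal(range(mm[, 1]), c(0, 1))
})

test_that("set-level standardization equals the single-window definition", {
  ws <- toy_window_set(n_per_class = 10)
  std <- standardize_windows(ws)
  expect_true(std$variant_flags$standardized)
  for (i in c(1, 7, 15)) {
    expect_equal(std$windows[i, , ], standardize_window(ws$windows[i, , ]),
                 tolerance = 1e-12)
  }
})

test_that("balancing keeps all minority windows and is seeded", {
  ws <- toy_window_set(n_per_class = 200)
  idx <- c(which(ws$labels == 1L)[1:100], which(ws$labels == 0L)[1:300])
  unb <- osadetect:::subset_window_set(ws, sort(idx))
  bal <- balance_windows(unb, seed = 9)
  expect_equal(sum(bal$labels == 1L), 100)
  expect_equal(sum(bal$labels == 0L), 100)
  # every minority window retained
  minority_starts <- unb$window_start_s[unb$labels == 1L]
  expect_true(all(minority_starts %in% bal$window_start_s))
  # ordering preserved
  expect_true(!is.unsorted(match(bal$window_start_s, unb$window_start_s)))
  expect_identical(balance_windows(unb, seed = 9), bal)
  expect_false(identical(balance_windows(unb, seed = 10), bal))
  # already balanced input returns unchanged
  eq <- osadetect:::subset_window_set(ws, c(which(ws$labels == 1L)[1:50],
                                            which(ws$labels == 0L)[1:50]))
  expect_identical(balance_windows(eq, seed = 1)$window_start_s,
                   eq$window_start_s)
  one_class <- osadetect:::subset_window_set(ws, which(ws$labels == 1L))
  expect_error(balance_windows(one_class, seed = 1),
               class = "osadetect_balance_error")
})

test_that("the four dataset variants record their flags and share labels", {
  p <- test_params(n_patients = 2, record_seconds = 3600, ahi = 15,
                   artifact_rate = 5)
  coh <- generate_cohort(p, with_artifacts = TRUE)
  flags <- list(`1` = c(FALSE, FALSE), `2` = c(TRUE, FALSE),
                `3` = c(FALSE, TRUE), `4` = c(TRUE, TRUE))
  labels <- list()
  for (v in 1:4) {
    ws <- build_variant(coh, flags[[v]][1], flags[[v]][2], seed = 1,
                        balance = FALSE)
    expect_equal(ws$variant_flags$artifacts_removed, flags[[v]][1])
    expect_equal(ws$variant_flags$standardized, flags[[v]][2])
    labels[[v]] <- ws$labels
  }
  # labels are independent of the value transforms
  for (v in 2:4) expect_identical(labels[[v]], labels[[1]])
})

test_that("the raw variant passes values through bit-identically", {
  p <- test_params(n_patients = 1, record_seconds = 600, ahi = 10)
  coh <- generate_cohort(p)
  ws <- build_variant(coh, FALSE, FALSE, seed = 1, balance = FALSE)
  rec <- coh$record[[1]]
  expect_identical(as.vector(t(ws$windows[, , 1])), rec$spo2)
  expect_identical(as.vector(t(ws$windows[, , 4])), rec$abdo)
})

test_that("the fully processed variant has clean ranges before scaling", {
  p <- test_params(n_patients = 2, record_seconds = 3600, ahi = 15,
                   artifact_rate = 8)
  coh <- generate_cohort(p, with_artifacts = TRUE)
  # artifact removal alone leaves SpO2/HR inside physiologic bounds
  v2 <- build_variant(coh, TRUE, FALSE, seed = 1, balance = FALSE)
  expect_true(all(v2$windows[, , 1] >= 80 & v2$windows[, , 1] <= 100))
  expect_true(all(v2$windows[, , 2] >= 40 & v2$windows[, , 2] <= 200))
  # adding standardization yields exact per-window z-scores
  v4 <- build_variant(coh, TRUE, TRUE, seed = 1)
  mu <- apply(v4$windows, c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-9)
})
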