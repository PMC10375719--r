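#' Labeled 60-s window set
#'
#' Container for the stacked model inputs: a tensor of non-overlapping 60-s
#' windows (60 samples at 1 Hz, 4 channels in the order `spo2, hr, thor,
#' abdo`), their binary apnea labels, the owning patient ids and window start
#' times, plus flags recording which preprocessing variant produced them.
#'
#' @param windows Numeric array `n_windows x 60 x 4`.
#' @param labels Integer vector in `{0, 1}`.
#' @param patient_ids Character vector, one id per window.
#' @param window_start_s Start times (seconds, multiples of 60).
#' @param variant_flags List with logicals `artifacts_removed` and
#'   `standardized`.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, patient_ids, window_start_s,
                       variant_flags = list(artifacts_removed = FALSE,
                                            standardized = FALSE)) {
  d <- dim(windows)
  if (length(d) != 3 || d[2] != 60 || d[3] != 4) {
    abort("`windows` must be an n x 60 x 4 array",
          class = "osadetect_shape_error")
  }
  labels <- as.integer(labels)
  stopifnot(length(labels) == d[1], all(labels %in% c(0L, 1L)),
            length(patient_ids) == d[1], length(window_start_s) == d[1],
            all(window_start_s %% 60 == 0))
  dimnames(windows) <- list(NULL, NULL, CHANNELS)
  structure(list(windows = windows, labels = labels,
                 patient_ids = as.character(patient_ids),
                 window_start_s = as.numeric(window_start_s),
                 variant_flags = variant_flags),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows (60 s x 4 ch), %d positive, %d patients; artifacts_removed=%s standardized=%s\n",
    length(x$labels), sum(x$labels), length(unique(x$patient_ids)),
    x$variant_flags$artifacts_removed, x$variant_flags$standardized))
  invisible(x)
}

#' @export
length.window_set <- function(x) length(x$labels)

subset_window_set <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$patient_ids[idx], ws$window_start_s[idx], ws$variant_flags)
}

#' Combine window sets
#'
#' @param ... `window_set` objects with identical variant flags.
#' @return A single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  flags <- sets[[1]]$variant_flags
  for (s in sets) {
    if (!identical(s$variant_flags, flags)) {
      abort("cannot bind window sets with different variant flags",
            class = "osadetect_config_error")
    }
  }
  n <- sum(vapply(sets, function(s) length(s$labels), 0L))
  arr <- array(0, c(n, 60, 4))
  at <- 0L
  for (s in sets) {
    m <- length(s$labels)
    arr[at + seq_len(m), , ] <- s$windows
    at <- at + m
  }
  window_set(arr, unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "patient_ids")),
             unlist(lapply(sets, `[[`, "window_start_s")), flags)
}

#' Interpolate out-of-physiologic-range SpO2/HR samples
#'
#' Flags SpO2 samples outside `spo2_bounds` (default below 80% or above
#' 100%) and HR samples outside `hr_bounds` (default below 40 or above 200
#' bpm) as heavy artifacts and replaces them by linear interpolation between
#' the nearest unflagged neighbours; leading/trailing flagged runs take the
#' nearest unflagged value. Effort channels are untouched. Idempotent.
#'
#' @param record A 1-Hz [signal_record()].
#' @param spo2_bounds,hr_bounds Length-2 numeric inclusive validity bounds.
#' @return The cleaned `signal_record`.
#' @export
remove_artifacts <- function(record, spo2_bounds = c(80, 100),
                             hr_bounds = c(40, 200)) {
  stopifnot(inherits(record, "signal_record"))
  fix <- function(x, lo, hi, channel) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    if (all(bad)) {
      abort(sprintf("channel %s of patient %s is entirely out of range",
                    channel, record$patient_id),
            class = "osadetect_quality_error")
    }
    good <- which(!bad)
    x[bad] <- approx(good, x[good], xout = which(bad), rule = 2)$y
    x
  }
  record$spo2 <- fix(record$spo2, spo2_bounds[1], spo2_bounds[2], "spo2")
  record$hr <- fix(record$hr, hr_bounds[1], hr_bounds[2], "hr")
  record
}

# Sum of the union overlap (in seconds) between [ws, we) and the given
# half-open event intervals.
union_overlap <- function(ws, we, start_s, end_s) {
  a <- pmax(start_s, ws)
  b <- pmin(end_s, we)
  keep <- b > a
  if (!any(keep)) return(0)
  a <- a[keep]; b <- b[keep]
  ord <- order(a)
  a <- a[ord]; b <- b[ord]
  total <- 0
  cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cur_b) {
      cur_b <- max(cur_b, b[i])
    } else {
      total <- total + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    }
  }
  total + (cur_b - cur_a)
}

#' Label a 60-s window from scored events
#'
#' A window is positive iff the union of the overlapping respiratory-event
#' intervals covers at least `min_overlap_s` (default 10 s) of the window,
#' regardless of total event duration. Central/mixed/other event types count
#' only when `include_central = TRUE`.
#'
#' @param window_start_s,window_end_s Half-open window interval bounds
#'   (`window_end_s - window_start_s` must be 60).
#' @param events Annotation tibble.
#' @param min_overlap_s Minimum in-window event coverage in seconds.
#' @param include_central Count central/mixed/other events as respiratory.
#' @return `0L` or `1L`.
#' @export
#' @examples
#' ev <- event_annotations("obstructive_apnea", 100, 25)
#' label_window(120, 180, ev)  # 5-s overlap -> 0
#' label_window(60, 120, ev)   # 20-s overlap -> 1
label_window <- function(window_start_s, window_end_s, events,
                         min_overlap_s = 10, include_central = FALSE) {
  stopifnot(window_end_s - window_start_s == 60)
  types <- c("obstructive_apnea", "hypopnea",
             if (include_central) c("central_apnea", "mixed_apnea", "other"))
  ev <- events[events$event_type %in% types, , drop = FALSE]
  if (nrow(ev) == 0) return(0L)
  ov <- union_overlap(window_start_s, window_end_s,
                      ev$start_s, ev$start_s + ev$duration_s)
  as.integer(ov >= min_overlap_s)
}

#' Slice a record into labeled 60-s windows
#'
#' Cuts the record into consecutive non-overlapping 60-sample windows and
#' labels each with [label_window()]. Windows that fall entirely inside a
#' zero-padded tail (`pad_from_s`) are dropped rather than labeled.
#'
#' @param record A 1-Hz [signal_record()] whose length is a multiple of 60.
#' @param events Annotation tibble for the record.
#' @param min_overlap_s,include_central Passed to [label_window()].
#' @param pad_from_s If the record was zero-padded from this second onward,
#'   windows starting at or after it are dropped.
#' @return A [window_set()].
#' @export
make_windows <- function(record, events, min_overlap_s = 10,
                         include_central = FALSE, pad_from_s = NULL) {
  stopifnot(inherits(record, "signal_record"), record$sample_rate == 1)
  n <- record$n_samples
  if (n %% 60 != 0) {
    abort("record length must be divisible by 60 s",
          class = "osadetect_shape_error")
  }
  n_win <- n %/% 60
  m <- as.matrix(record)                      # n x 4
  # (60, n_win, 4) -> (n_win, 60, 4)
  arr <- aperm(array(m, c(60, n_win, 4)), c(2, 1, 3))
  starts <- (seq_len(n_win) - 1) * 60
  keep <- if (is.null(pad_from_s)) rep(TRUE, n_win) else starts < pad_from_s
  labels <- vapply(starts, function(s) {
    label_window(s, s + 60, events, min_overlap_s, include_central)
  }, integer(1))
  window_set(arr[keep, , , drop = FALSE], labels[keep],
             rep(record$patient_id, sum(keep)), starts[keep])
}

#' Standardize one 60 x 4 window
#'
#' Applies the per-window, per-channel z-score `z = (X - mu) / sigma` with
#' the population (divide-by-n) standard deviation; a constant channel
#' (`sigma = 0`) maps to all zeros. An optional min-max mode rescaling each
#' channel to `[0, 1]` is available behind `method`.
#'
#' @param window Numeric 60 x 4 matrix.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return The transformed 60 x 4 matrix.
#' @export
standardize_window <- function(window, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  stopifnot(is.matrix(window))
  mu <- colMeans(window)
  centered <- sweep(window, 2, mu)
  if (method == "zscore") {
    sigma <- sqrt(colMeans(centered^2))
    out <- sweep(centered, 2, ifelse(sigma == 0, 1, sigma), "/")
    out[, sigma == 0] <- 0
  } else {
    rng <- apply(window, 2, range)
    span <- rng[2, ] - rng[1, ]
    out <- sweep(sweep(window, 2, rng[1, ]), 2,
                 ifelse(span == 0, 1, span), "/")
    out[, span == 0] <- 0
  }
  out
}

#' Standardize every window of a set
#'
#' Vectorized application of [standardize_window()] across the tensor; sets
#' the `standardized` variant flag.
#'
#' @param ws A [window_set()].
#' @param method Passed to [standardize_window()].
#' @return The standardized `window_set`.
#' @export
standardize_windows <- function(ws, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  arr <- ws$windows
  for (c_ in 1:4) {
    M <- arr[, , c_, drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = dim(arr)[1])
    if (method == "zscore") {
      mu <- rowMeans(M)
      Mc <- M - mu
      sig <- sqrt(rowMeans(Mc^2))
      Z <- Mc / ifelse(sig == 0, 1, sig)
      Z[sig == 0, ] <- 0
    } else {
      lo <- apply(M, 1, min); hi <- apply(M, 1, max)
      span <- hi - lo
      Z <- (M - lo) / ifelse(span == 0, 1, span)
      Z[span == 0, ] <- 0
    }
    arr[, , c_] <- Z
  }
  ws$windows <- arr
  ws$variant_flags$standardized <- TRUE
  ws
}

#' Balance a window set to equal class counts
#'
#' Keeps every window of the minority class and down-samples the majority
#' class uniformly at random (seeded); the relative window ordering is
#' preserved.
#'
#' @param ws A [window_set()] containing both classes.
#' @param seed Integer seed for the down-sampling draw.
#' @return A balanced `window_set` (50/50 classes).
#' @export
balance_windows <- function(ws, seed) {
  n1 <- sum(ws$labels == 1L)
  n0 <- sum(ws$labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to balance",
          class = "osadetect_balance_error")
  }
  minority <- if (n1 <= n0) 1L else 0L
  keep_min <- which(ws$labels == minority)
  maj <- which(ws$labels != minority)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% 2147483647)
  keep_maj <- sort(sample(maj, length(keep_min)))
  subset_window_set(ws, sort(c(keep_min, keep_maj)))
}

#' Build one preprocessing variant from a cohort
#'
#' Applies the selected preprocessing stages patient by patient and stacks
#' the resulting windows: variant 1 = raw, variant 2 = artifact interpolation
#' only, variant 3 = per-window standardization only, variant 4 = both.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (columns
#'   `patient_id`, `record`, `events`).
#' @param remove_artifacts_flag,standardize_flag Stage switches.
#' @param seed Seed for [balance_windows()].
#' @param balance Balance classes after stacking (default `TRUE`).
#' @param min_overlap_s,include_central Labeling configuration.
#' @return A [window_set()] with the variant flags recorded.
#' @export
build_variant <- function(cohort, remove_artifacts_flag, standardize_flag,
                          seed, balance = TRUE, min_overlap_s = 10,
                          include_central = FALSE) {
  stopifnot(nrow(cohort) >= 1)
  sets <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- cohort$record[[i]]
    if (remove_artifacts_flag) rec <- remove_artifacts(rec)
    make_windows(rec, cohort$events[[i]], min_overlap_s, include_central)
  })
  ws <- bind_window_sets(sets)
  if (standardize_flag) ws <- standardize_windows(ws)
  ws$variant_flags <- list(artifacts_removed = remove_artifacts_flag,
                           standardized = standardize_flag)
  if (balance) ws <- balance_windows(ws, seed)
  ws
}

#' @describeIn build_variant Build by variant number 1-4.
#' @param variant Integer 1-4.
#' @export
build_dataset_variant <- function(cohort, variant, seed, balance = TRUE) {
  stopifnot(variant %in% 1:4)
  flags <- list(`1` = c(FALSE, FALSE), `2` = c(TRUE, FALSE),
                `3` = c(FALSE, TRUE), `4` = c(TRUE, TRUE))[[as.character(variant)]]
  build_variant(cohort, flags[1], flags[2], seed, balance = balance)
}
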