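#' Parameters of the synthetic cohort generator
#'
#' The generator emulates 8-h portable-monitor recordings (four channels at
#' 1 Hz) with planted obstructive-apnea-like and hypopnea-like events.
#' During an event the respiratory-effort envelope is reduced by the
#' configured fraction (>= 90% for apneas, >= 30% for hypopneas), SpO2 shows a
#' desaturation of at least 3% lagged 10-20 s after event onset, and heart
#' rate shows a bradycardia dip during the event followed by a tachycardia
#' surge after it.
#'
#' @param n_patients Number of patients in the cohort.
#' @param record_seconds Record length in seconds; must be divisible by 60.
#'   Default 28,800 (8 h).
#' @param target_ahi_sampler Function of `n` drawing target AHI values
#'   (events/hour) in `[0, 60]`. Default `Uniform(0, 45)`, covering all four
#'   severity classes.
#' @param event_duration_range Event durations in seconds, within `[10, 60]`.
#' @param hypopnea_fraction Proportion of planted events that are hypopneas.
#' @param desat_depth_range SpO2 desaturation depth range (percent points);
#'   minimum must be >= 3.
#' @param apnea_effort_reduction Fractional effort-amplitude reduction during
#'   apneas (>= 0.9).
#' @param hypopnea_effort_reduction Fractional reduction during hypopneas
#'   (>= 0.3).
#' @param hr_dip_bpm,hr_surge_bpm Heart-rate bradycardia dip during and
#'   tachycardia surge after an event, beats/min.
#' @param baseline_spo2,baseline_hr Baseline SpO2 (percent) and HR (bpm).
#' @param breath_period_s Respiratory period of the effort sinusoids, seconds.
#' @param noise_sd Named numeric vector of per-channel Gaussian noise SDs
#'   (names `spo2`, `hr`, `thor`, `abdo`).
#' @param artifact_rate Expected number of heavy-artifact spans per record
#'   (Poisson mean) used by [inject_artifacts()].
#' @param patient_prefix Prefix of generated patient ids (default `"synth"`);
#'   give independently generated cohorts distinct prefixes so their patient
#'   ids never collide.
#' @param seed Integer master seed; per-patient streams are derived from it.
#'
#' @return A validated list of class `synth_params`.
#' @export
#' @examples
#' p <- synth_params(n_patients = 2, record_seconds = 3600)
#' p$record_seconds
synth_params <- function(n_patients = 30,
                         record_seconds = 28800,
                         target_ahi_sampler = function(n) runif(n, 0, 45),
                         event_duration_range = c(10, 40),
                         hypopnea_fraction = 0.5,
                         desat_depth_range = c(3, 8),
                         apnea_effort_reduction = 0.95,
                         hypopnea_effort_reduction = 0.5,
                         hr_dip_bpm = 10,
                         hr_surge_bpm = 12,
                         baseline_spo2 = 96,
                         baseline_hr = 65,
                         breath_period_s = 4,
                         noise_sd = c(spo2 = 0.3, hr = 1.5,
                                      thor = 0.15, abdo = 0.15),
                         artifact_rate = 4,
                         patient_prefix = "synth",
                         seed = 20230714) {
  stopifnot(n_patients >= 1, record_seconds > 0)
  if (record_seconds %% 60 != 0) {
    abort("`record_seconds` must be divisible by 60")
  }
  if (event_duration_range[1] < 10 || event_duration_range[2] > 60 ||
      diff(event_duration_range) < 0) {
    abort("`event_duration_range` must lie within [10, 60]")
  }
  if (desat_depth_range[1] < 3) {
    abort("`desat_depth_range` minimum must be >= 3 (AASM desaturation rule)")
  }
  if (apnea_effort_reduction < 0.9 || apnea_effort_reduction > 1) {
    abort("`apnea_effort_reduction` must be in [0.9, 1]")
  }
  if (hypopnea_effort_reduction < 0.3 || hypopnea_effort_reduction > 1) {
    abort("`hypopnea_effort_reduction` must be in [0.3, 1]")
  }
  stopifnot(hypopnea_fraction >= 0, hypopnea_fraction <= 1,
            all(CHANNELS %in% names(noise_sd)), all(noise_sd >= 0),
            artifact_rate >= 0)
  structure(
    list(n_patients = as.integer(n_patients),
         record_seconds = as.integer(record_seconds),
         target_ahi_sampler = target_ahi_sampler,
         event_duration_range = event_duration_range,
         hypopnea_fraction = hypopnea_fraction,
         desat_depth_range = desat_depth_range,
         apnea_effort_reduction = apnea_effort_reduction,
         hypopnea_effort_reduction = hypopnea_effort_reduction,
         hr_dip_bpm = hr_dip_bpm, hr_surge_bpm = hr_surge_bpm,
         baseline_spo2 = baseline_spo2, baseline_hr = baseline_hr,
         breath_period_s = breath_period_s,
         noise_sd = noise_sd[CHANNELS],
         artifact_rate = artifact_rate,
         patient_prefix = patient_prefix,
         seed = as.integer(seed)),
    class = "synth_params")
}

# Derived, reproducible per-patient seed stream (kept below 2^31).
patient_seed <- function(params, patient_index, salt = 0L) {
  (as.double(params$seed) + 7919 * (patient_index + 1) + 104729 * salt) %%
    2147483647
}

# Rejection-sample non-overlapping event intervals separated by >= 10 s.
place_events <- function(n_events, durations, record_seconds, patient_id,
                         max_attempts = 10000L) {
  starts <- numeric(0)
  ends <- numeric(0)
  kept_dur <- numeric(0)
  attempts <- 0L
  i <- 1L
  while (i <= n_events) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "could not place %d events for patient %s within %d attempts",
        n_events, patient_id, max_attempts),
        class = "osadetect_placement_error")
    }
    d <- durations[i]
    s <- runif(1, 0, record_seconds - d)
    if (all(s + d + 10 <= starts | s >= ends + 10)) {
      starts <- c(starts, s)
      ends <- c(ends, s + d)
      kept_dur <- c(kept_dur, d)
      i <- i + 1L
    }
  }
  ord <- order(starts)
  list(start_s = starts[ord], duration_s = kept_dur[ord])
}

# Piecewise-linear fall / plateau / recovery desaturation shape, as a vector
# of SpO2 deltas over the whole record.
desat_shape <- function(n, onset, event_end, depth, fall_s = 8, recover_s = 12) {
  delta <- numeric(n)
  t1 <- onset + fall_s
  t2 <- max(event_end, t1)            # plateau runs to event end (lagged)
  t3 <- t2 + recover_s
  tt <- seq_len(n) - 1
  fall <- tt >= onset & tt < t1
  delta[fall] <- -depth * (tt[fall] - onset) / fall_s
  delta[tt >= t1 & tt < t2] <- -depth
  rec <- tt >= t2 & tt < t3
  delta[rec] <- -depth * (1 - (tt[rec] - t2) / recover_s)
  delta
}

#' Generate one annotated synthetic recording
#'
#' Draws a target AHI from `params$target_ahi_sampler`, plants
#' `round(AHI * hours)` pairwise non-overlapping events (>= 10-s gaps) and
#' synthesizes the four channels around them: amplitude-modulated effort
#' sinusoids whose envelope drops during events, an SpO2 desaturation lagged
#' 10-20 s after event onset, and a heart-rate dip-then-surge response.
#'
#' @param params A [synth_params()] object.
#' @param patient_index 0-based patient index, `< params$n_patients`.
#' @return A list with elements `record` (a [signal_record()]) and `events`
#'   (an annotation tibble with extra generator columns `desat_depth`,
#'   `desat_lag_s` and `effort_reduction`).
#' @export
#' @examples
#' p <- synth_params(n_patients = 1, record_seconds = 3600,
#'                   target_ahi_sampler = function(n) rep(10, n))
#' r <- generate_record(p, 0)
#' nrow(r$events)  # 10 events/h for 1 h
generate_record <- function(params, patient_index) {
  stopifnot(inherits(params, "synth_params"),
            patient_index >= 0, patient_index < params$n_patients)
  patient_id <- sprintf("%s-%03d", params$patient_prefix, patient_index + 1)
  n <- params$record_seconds
  hours <- n / 3600

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(patient_seed(params, patient_index))

  ahi <- min(max(params$target_ahi_sampler(1), 0), 60)
  n_events <- round(ahi * hours)

  if (n_events > 0) {
    durations <- runif(n_events, params$event_duration_range[1],
                       params$event_duration_range[2])
    placed <- place_events(n_events, durations, n, patient_id)
    is_hyp <- runif(n_events) < params$hypopnea_fraction
    depth <- runif(n_events, params$desat_depth_range[1],
                   params$desat_depth_range[2])
    lag <- runif(n_events, 10, 20)
    events <- tibble::tibble(
      event_type = ifelse(is_hyp, "hypopnea", "obstructive_apnea"),
      start_s = placed$start_s,
      duration_s = placed$duration_s,
      desat_depth = depth,
      desat_lag_s = lag,
      effort_reduction = ifelse(is_hyp, params$hypopnea_effort_reduction,
                                params$apnea_effort_reduction))
  } else {
    events <- tibble::tibble(event_type = character(), start_s = numeric(),
                             duration_s = numeric(), desat_depth = numeric(),
                             desat_lag_s = numeric(),
                             effort_reduction = numeric())
  }

  tt <- seq_len(n) - 1
  envelope <- rep(1, n)
  spo2_delta <- numeric(n)
  hr_delta <- numeric(n)
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; d <- events$duration_s[i]
    in_ev <- tt >= s & tt < s + d
    envelope[in_ev] <- 1 - events$effort_reduction[i]
    spo2_delta <- spo2_delta +
      desat_shape(n, s + events$desat_lag_s[i], s + d + events$desat_lag_s[i],
                  events$desat_depth[i])
    # bradycardia during the event (half-sine dip) ...
    hr_delta[in_ev] <- hr_delta[in_ev] -
      params$hr_dip_bpm * sin(pi * (tt[in_ev] - s) / d)
    # ... then a tachycardia surge over the 15 s after it
    post <- tt >= s + d & tt < s + d + 15
    hr_delta[post] <- hr_delta[post] +
      params$hr_surge_bpm * sin(pi * (tt[post] - s - d) / 15)
  }

  phase <- runif(2, 0, 2 * pi)
  sd <- params$noise_sd
  spo2 <- pmin(params$baseline_spo2 + spo2_delta + rnorm(n, 0, sd["spo2"]), 100)
  hr <- params$baseline_hr + hr_delta + rnorm(n, 0, sd["hr"])
  thor <- envelope * sin(2 * pi * tt / params$breath_period_s + phase[1]) +
    rnorm(n, 0, sd["thor"])
  abdo <- envelope * sin(2 * pi * tt / params$breath_period_s + phase[2]) +
    rnorm(n, 0, sd["abdo"])

  list(record = signal_record(patient_id, spo2, hr, thor, abdo, 1),
       events = events)
}

#' Inject heavy SpO2/HR artifacts into a record
#'
#' Replaces a `Poisson(artifact_rate)` number of 3-30 s spans of the SpO2 and
#' HR channels with zeros or out-of-physiologic-range values, mimicking the
#' sensor dropouts seen in home recordings. Effort channels are untouched.
#'
#' @param record A 1-Hz [signal_record()].
#' @param params A [synth_params()] (supplies `artifact_rate`).
#' @param seed Integer seed for the corruption stream.
#' @return The corrupted `signal_record`; the injected span locations are
#'   attached as the `artifact_spans` attribute (a tibble with `channel`,
#'   `start_s`, `duration_s`, `mode`) for downstream assertions.
#' @export
inject_artifacts <- function(record, params, seed) {
  stopifnot(inherits(record, "signal_record"), record$sample_rate == 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% 2147483647)

  n_spans <- if (params$artifact_rate > 0) rpois(1, params$artifact_rate) else 0L
  spans <- tibble::tibble(channel = character(), start_s = integer(),
                          duration_s = integer(), mode = character())
  if (n_spans > 0) {
    n <- record$n_samples
    for (i in seq_len(n_spans)) {
      ch <- sample(c("spo2", "hr"), 1)
      len <- sample(3:30, 1)
      start <- sample.int(n - len + 1, 1) - 1L
      mode <- sample(c("zero", "spike"), 1, prob = c(0.7, 0.3))
      idx <- (start + 1):(start + len)
      record[[ch]][idx] <- switch(
        mode,
        zero = 0,
        spike = if (ch == "spo2") runif(len, 101, 110) else runif(len, 210, 250))
      spans <- dplyr::bind_rows(
        spans, tibble::tibble(channel = ch, start_s = start,
                              duration_s = len, mode = mode))
    }
  }
  attr(record, "artifact_spans") <- spans
  record
}

#' Generate a reproducible synthetic cohort
#'
#' @param params A [synth_params()] object.
#' @param with_artifacts If `TRUE`, pass each record through
#'   [inject_artifacts()] after generation.
#' @return A tibble with one row per patient: `patient_id`, `record`
#'   (list-column of [signal_record()]s), `events` (list-column of annotation
#'   tibbles), `n_events` and `true_ahi` (planted events per hour).
#' @export
#' @examples
#' coh <- generate_cohort(synth_params(n_patients = 2, record_seconds = 3600))
#' coh$true_ahi
generate_cohort <- function(params, with_artifacts = FALSE) {
  stopifnot(inherits(params, "synth_params"))
  hours <- params$record_seconds / 3600
  rows <- purrr::map(seq_len(params$n_patients) - 1L, function(i) {
    gen <- generate_record(params, i)
    rec <- gen$record
    if (with_artifacts) {
      rec <- inject_artifacts(rec, params, patient_seed(params, i, salt = 1L))
    }
    tibble::tibble(patient_id = rec$patient_id,
                   record = list(rec), events = list(gen$events),
                   n_events = nrow(gen$events),
                   true_ahi = nrow(gen$events) / hours)
  })
  dplyr::bind_rows(rows)
}

# Save/restore the global RNG state so generators are pure given their seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
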