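# Shared fixtures, all built in code.

# Small-cohort generator parameters for fast unit tests.
test_params <- function(n_patients = 2, record_seconds = 3600, ahi = 15,
                        seed = 42, ...) {
  synth_params(n_patients = n_patients, record_seconds = record_seconds,
               target_ahi_sampler = function(n) rep(ahi, n),
               seed = seed, ...)
}

# A linearly separable toy window problem: positive windows carry a strong
# mid-window bump on the effort channels, negatives are pure noise.
toy_window_set <- function(n_per_class = 60, patient_ids = c("a", "b"),
                           seed = 1, sep = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  arr <- array(rnorm(n * 60 * 4, sd = 1), c(n, 60, 4))
  labels <- rep(c(0L, 1L), each = n_per_class)
  bump <- sep * sin(pi * (0:59) / 59)
  for (i in which(labels == 1L)) {
    arr[i, , 3] <- arr[i, , 3] + bump
    arr[i, , 4] <- arr[i, , 4] + bump
  }
  window_set(arr, labels,
             rep_len(patient_ids, n),
             window_start_s = (seq_len(n) - 1) * 60)
}

tiny_model_config <- function(seed = 1, max_epochs = 5, dropout = 0,
                              feature_maps = 8) {
  model_config(list(c(feature_maps, 3, dropout), c(feature_maps, 3, dropout)),
               learning_rate = 0.01, batch_size = 32,
               max_epochs = max_epochs, seed = seed, name = "tiny")
}

# Brute-force per-second window labeling oracle for integer-valued events.
label_window_oracle <- function(ws, we, events, min_overlap_s = 10,
                                include_central = FALSE) {
  types <- c("obstructive_apnea", "hypopnea",
             if (include_central) c("central_apnea", "mixed_apnea", "other"))
  ev <- events[events$event_type %in% types, , drop = FALSE]
  covered <- 0L
  for (s in ws:(we - 1)) {
    if (any(ev$start_s <= s & s < ev$start_s + ev$duration_s)) {
      covered <- covered + 1L
    }
  }
  as.integer(covered >= min_overlap_s)
}
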