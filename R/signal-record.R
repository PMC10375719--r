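#' Four-channel physiological recording
#'
#' A `signal_record` holds one patient's aligned SpO2 (percent), heart rate
#' (beats/min), thoracic and abdominal respiratory-effort traces at a common
#' sample rate. The channel order `(spo2, hr, thor, abdo)` is fixed and relied
#' upon by every downstream stage.
#'
#' @param patient_id Single string identifying the patient.
#' @param spo2,hr,thor,abdo Numeric vectors of equal length.
#' @param sample_rate Sampling rate in Hz (default 1).
#'
#' @return An object of class `signal_record`: a list with the four channel
#'   vectors plus `patient_id`, `sample_rate` and `n_samples`.
#' @export
#' @examples
#' rec <- signal_record("p1", spo2 = rep(96, 60), hr = rep(65, 60),
#'                      thor = sin(1:60), abdo = cos(1:60))
#' rec$n_samples
signal_record <- function(patient_id, spo2, hr, thor, abdo, sample_rate = 1) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  n <- length(spo2)
  if (!all(lengths(list(hr, thor, abdo)) == n)) {
    abort("all four channels must have the same number of samples",
          class = "osadetect_channel_length_error")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be a positive number")
  }
  structure(
    list(patient_id = patient_id,
         spo2 = as.numeric(spo2), hr = as.numeric(hr),
         thor = as.numeric(thor), abdo = as.numeric(abdo),
         sample_rate = sample_rate, n_samples = n),
    class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> patient %s: %d samples @ %g Hz (%.2f h)\n",
              x$patient_id, x$n_samples, x$sample_rate,
              x$n_samples / x$sample_rate / 3600))
  invisible(x)
}

#' @export
as.matrix.signal_record <- function(x, ...) {
  m <- cbind(x$spo2, x$hr, x$thor, x$abdo)
  colnames(m) <- CHANNELS
  m
}

#' Tidy a signal record into a long tibble
#'
#' @param x A [signal_record()].
#' @param ... Unused.
#' @return A tibble with columns `patient_id`, `time_s`, `channel`, `value`.
#' @method as_tibble signal_record
#' @export
as_tibble.signal_record <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id,
    time_s = rep((seq_len(x$n_samples) - 1) / x$sample_rate, times = 4L),
    channel = factor(rep(CHANNELS, each = x$n_samples), levels = CHANNELS),
    value = c(x$spo2, x$hr, x$thor, x$abdo))
}

#' @rdname as_tibble.signal_record
#' @method autoplot signal_record
#' @export
autoplot.signal_record <- function(x, ...) {
  df <- as_tibble.signal_record(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = x$patient_id) +
    ggplot2::theme_minimal()
}

#' Construct an event-annotation table
#'
#' Respiratory events are kept as a tibble with one row per scored event.
#' Intervals are half-open `[start_s, start_s + duration_s)`, 0-based seconds
#' from record start.
#'
#' @param event_type Character vector; one of `obstructive_apnea`, `hypopnea`,
#'   `central_apnea`, `mixed_apnea`, `other`.
#' @param start_s,duration_s Numeric vectors (seconds).
#' @param record_seconds Optional record length used to validate that every
#'   event lies inside the record.
#' @return A tibble with columns `event_type`, `start_s`, `duration_s`,
#'   sorted by `start_s`.
#' @export
event_annotations <- function(event_type = character(), start_s = numeric(),
                              duration_s = numeric(), record_seconds = NULL) {
  known <- c("obstructive_apnea", "hypopnea", "central_apnea",
             "mixed_apnea", "other")
  if (!all(event_type %in% known)) {
    abort(paste0("unknown event_type: ",
                 paste(setdiff(event_type, known), collapse = ", ")))
  }
  if (any(start_s < 0) || any(duration_s <= 0)) {
    abort("events need start_s >= 0 and duration_s > 0")
  }
  if (!is.null(record_seconds) && any(start_s + duration_s > record_seconds)) {
    abort("event extends past the end of the record")
  }
  out <- tibble::tibble(event_type = as.character(event_type),
                        start_s = as.numeric(start_s),
                        duration_s = as.numeric(duration_s))
  dplyr::arrange(out, .data$start_s)
}
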