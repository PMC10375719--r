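#' Block-mean resampling to 1 Hz
#'
#' Downsamples a series recorded at an integer rate to 1 Hz by averaging
#' non-overlapping blocks of `src_rate` samples (anti-aliasing by averaging
#' rather than every-Nth-sample decimation, which preserves the event-scale
#' envelope). `src_rate = 1` is the identity.
#'
#' @param series Numeric vector at `src_rate` Hz.
#' @param src_rate Source rate in Hz; must be a whole number >= 1.
#' @return Numeric vector of length `floor(length(series) / src_rate)`.
#' @export
#' @examples
#' resample_to_1hz(c(1, 1, 1, 1, 1, 3, 3, 3, 3, 3), 5)  # c(1, 3)
resample_to_1hz <- function(series, src_rate) {
  if (length(src_rate) != 1 || src_rate < 1 || src_rate != round(src_rate)) {
    abort("`src_rate` must be a whole number of Hz >= 1 (pre-resample otherwise)",
          class = "osadetect_rate_error")
  }
  src_rate <- as.integer(src_rate)
  if (src_rate == 1L) return(series)
  m <- length(series) %/% src_rate
  if (m == 0L) return(numeric(0))
  colMeans(matrix(series[seq_len(m * src_rate)], nrow = src_rate))
}

#' Write a signal record as EDF
#'
#' Convenience wrapper around [write_edf()] using the canonical channel
#' labels `SpO2`, `HR`, `ThorRes`, `AbdoRes` at the record's sample rate.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record_edf <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  labels <- c(spo2 = "SpO2", hr = "HR", thor = "ThorRes", abdo = "AbdoRes")
  signals <- stats::setNames(
    list(record$spo2, record$hr, record$thor, record$abdo), labels)
  rates <- stats::setNames(rep(record$sample_rate, 4), labels)
  write_edf(path, signals, rates, patient_id = record$patient_id,
            phys_dim = stats::setNames(c("%", "bpm", "", ""), labels))
}

#' Read a polysomnography EDF into a signal record
#'
#' Extracts the four channels named by `channel_map`, downsamples each to
#' 1 Hz with [resample_to_1hz()], and optionally pads/truncates the record to
#' a target length (the pipeline uses 28,800 s; padding/truncation is
#' reported with a warning).
#'
#' @param edf_path Path to an EDF file.
#' @param channel_map Named character vector mapping the roles
#'   `spo2`, `hr`, `thor`, `abdo` to channel labels present in the file.
#' @param target_seconds If non-`NULL`, zero-pad or truncate the 1-Hz record
#'   to exactly this many samples (with a warning when the source differs).
#' @param patient_id Override for the patient id (default: EDF header field).
#' @return A 1-Hz [signal_record()].
#' @export
read_psg <- function(edf_path,
                     channel_map = c(spo2 = "SpO2", hr = "HR",
                                     thor = "ThorRes", abdo = "AbdoRes"),
                     target_seconds = NULL, patient_id = NULL) {
  if (!all(CHANNELS %in% names(channel_map))) {
    abort(sprintf("channel_map must name all of: %s",
                  paste(CHANNELS, collapse = ", ")),
          class = "osadetect_config_error")
  }
  edf <- read_edf(edf_path)
  missing <- setdiff(unname(channel_map[CHANNELS]), edf$labels)
  if (length(missing) > 0) {
    abort(sprintf("channel(s) %s not found in %s; available labels: %s",
                  paste(missing, collapse = ", "), edf_path,
                  paste(edf$labels, collapse = ", ")),
          class = "osadetect_config_error")
  }
  chans <- lapply(CHANNELS, function(role) {
    lab <- channel_map[[role]]
    resample_to_1hz(edf$signals[[lab]], edf$rates[[lab]])
  })
  names(chans) <- CHANNELS
  n <- unique(lengths(chans))
  if (length(n) != 1) {
    abort("channels disagree in duration after resampling",
          class = "osadetect_io_error")
  }
  if (!is.null(target_seconds) && n != target_seconds) {
    warn(sprintf("record is %d s, adjusting to %d s (%s)", n, target_seconds,
                 if (n < target_seconds) "zero-padded tail" else "truncated"))
    chans <- lapply(chans, function(x) {
      if (length(x) >= target_seconds) x[seq_len(target_seconds)]
      else c(x, rep(0, target_seconds - length(x)))
    })
  }
  signal_record(patient_id %||% edf$patient_id,
                chans$spo2, chans$hr, chans$thor, chans$abdo, 1)
}

# Display names used in NSRR-style ScoredEvent entries.
NSRR_EVENT_NAMES <- c(obstructive_apnea = "Obstructive Apnea",
                      hypopnea = "Hypopnea",
                      central_apnea = "Central Apnea",
                      mixed_apnea = "Mixed Apnea",
                      other = "Unscored Event")

#' Write annotations as NSRR-style XML
#'
#' Emits a `PSGAnnotation/ScoredEvents` document with one `ScoredEvent`
#' (Name / Start / Duration) per event, the dialect used by NSRR scoring
#' exports.
#'
#' @param events Annotation tibble (see [event_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_xml <- function(events, path) {
  doc <- xml2::xml_new_root("PSGAnnotation")
  scored <- xml2::xml_add_child(doc, "ScoredEvents")
  for (i in seq_len(nrow(events))) {
    ev <- xml2::xml_add_child(scored, "ScoredEvent")
    xml2::xml_add_child(ev, "EventType", "Respiratory|Respiratory")
    xml2::xml_add_child(ev, "Name",
                        NSRR_EVENT_NAMES[[events$event_type[i]]])
    xml2::xml_add_child(ev, "Start", format(events$start_s[i], digits = 10))
    xml2::xml_add_child(ev, "Duration",
                        format(events$duration_s[i], digits = 10))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

map_event_name <- function(name) {
  n <- tolower(name)
  dplyr::case_when(
    grepl("obstructive apnea", n) ~ "obstructive_apnea",
    grepl("hypopnea", n) ~ "hypopnea",
    grepl("central apnea", n) ~ "central_apnea",
    grepl("mixed apnea", n) ~ "mixed_apnea",
    TRUE ~ "other")
}

#' Read respiratory event annotations
#'
#' Parses NSRR-style `ScoredEvent` XML (`Name` or `EventConcept`, `Start`,
#' `Duration`); event names that do not map to a known respiratory type
#' become `other`. A CSV fallback with columns `type,start_s,duration_s` is
#' supported for convenience.
#'
#' @param path Path to an XML (or CSV) annotation file.
#' @return An annotation tibble sorted by `start_s`.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(event_annotations(df$type, df$start_s, df$duration_s))
  }
  doc <- xml2::read_xml(path)   # malformed XML: xml2 reports the line
  nodes <- xml2::xml_find_all(doc, ".//ScoredEvent")
  if (length(nodes) == 0) {
    return(event_annotations())
  }
  get_field <- function(node, field) {
    xml2::xml_text(xml2::xml_find_first(node, field))
  }
  name <- vapply(nodes, function(nd) {
    v <- get_field(nd, "Name")
    if (is.na(v)) v <- get_field(nd, "EventConcept")
    v %||% ""
  }, "")
  start <- as.numeric(vapply(nodes, get_field, "", field = "Start"))
  dur <- as.numeric(vapply(nodes, get_field, "", field = "Duration"))
  event_annotations(map_event_name(name), start, dur)
}

#' Persist a window set to disk
#'
#' Writes the window tensor plus a JSON manifest (labels, patient ids,
#' window start times, variant flags) into a directory, the package's
#' run-time container for preprocessed datasets.
#'
#' @param ws A [window_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_window_set <- function(ws, dir) {
  stopifnot(inherits(ws, "window_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ws$windows, file.path(dir, "windows.rds"))
  jsonlite::write_json(
    list(labels = ws$labels, patient_ids = ws$patient_ids,
         window_start_s = ws$window_start_s,
         variant_flags = ws$variant_flags,
         n_windows = dim(ws$windows)[1]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  window_set(readRDS(file.path(dir, "windows.rds")),
             labels = as.integer(man$labels),
             patient_ids = man$patient_ids,
             window_start_s = man$window_start_s,
             variant_flags = man$variant_flags)
}
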