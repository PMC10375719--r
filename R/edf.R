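# Minimal continuous-EDF support: 16-bit samples, ASCII headers, one data
# record per second so per-signal sample rates are integers. Covers exactly
# what the pipeline needs (write synthetic fixtures, read 4-channel PSG).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) edf_pad(format(x, trim = TRUE, digits = 8), width)

#' Write signals to an EDF file
#'
#' Low-level writer for continuous EDF: each signal is scaled to 16-bit
#' integers over its physical range and stored in 1-s data records, so
#' per-signal sampling rates must be whole numbers of Hz.
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (channel label -> samples).
#' @param rates Named integer vector of sampling rates (Hz), same names.
#' @param patient_id Free-text patient identification field.
#' @param phys_dim Named character vector of physical dimensions (optional).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, rates, patient_id = "X",
                      phys_dim = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1,
            all(names(signals) %in% names(rates)))
  labels <- names(signals)
  rates <- as.integer(rates[labels])
  if (any(rates < 1)) abort("EDF writer requires integer rates >= 1 Hz")
  secs <- unique(lengths(signals) / rates)
  if (length(secs) != 1 || secs != round(secs)) {
    abort("all signals must span the same whole number of seconds")
  }
  n_rec <- as.integer(secs)
  ns <- length(labels)

  pmin_ <- pmax_ <- numeric(ns)
  digital <- vector("list", ns)
  for (j in seq_len(ns)) {
    x <- signals[[j]]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    pad <- (hi - lo) * 1e-6
    lo <- lo - pad; hi <- hi + pad
    pmin_[j] <- lo; pmax_[j] <- hi
    digital[[j]] <- as.integer(round((x - lo) / (hi - lo) * 65535) - 32768)
  }

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient_id, 80), edf_pad("osadetect", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(256 * (ns + 1), 8), edf_pad("", 44),
    edf_num(n_rec, 8), edf_num(1, 8), edf_num(ns, 4))
  dims <- if (is.null(phys_dim)) rep("", ns) else phys_dim[labels]
  hdr <- paste0(
    hdr,
    paste(vapply(labels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(dims, edf_pad, "", width = 8), collapse = ""),
    paste(vapply(pmin_, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_num(-32768, 8), ns), collapse = ""),
    paste(rep(edf_num(32767, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(vapply(rates, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)

  # data records: per second, each signal's block of `rate` samples in order
  mats <- lapply(seq_len(ns), function(j) matrix(digital[[j]], nrow = rates[j]))
  interleaved <- do.call(rbind, mats)   # (sum rates) x n_rec, column = record
  writeBin(as.integer(interleaved), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with `patient_id`, `labels`, `rates` (Hz, named) and
#'   `signals` (named list of numeric vectors at native rates).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read EDF file: %s", path),
          class = "osadetect_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                  # version
  patient_id <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) {
    abort(sprintf("malformed EDF header in %s", path),
          class = "osadetect_io_error")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  seek(con, header_bytes)

  total <- sum(spr) * n_rec
  raw <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  block <- matrix(raw, nrow = sum(spr), ncol = n_rec)
  offsets <- cumsum(c(0L, spr))
  signals <- vector("list", ns)
  for (j in seq_len(ns)) {
    dig <- as.vector(block[(offsets[j] + 1):offsets[j + 1], , drop = FALSE])
    scale <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
    signals[[j]] <- pmin_[j] + (dig - dmin_[j]) * scale
  }
  names(signals) <- labels
  rates <- stats::setNames(spr / rec_dur, labels)
  list(patient_id = patient_id, labels = labels, rates = rates,
       signals = signals)
}
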