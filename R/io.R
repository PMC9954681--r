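# Reading, validating and writing multichannel resting-state recordings.
#
# Two on-disk forms are supported: EDF (European Data Format, 16-bit) and a
# plain tabular form (CSV with one column per electrode plus a JSON sidecar
# carrying sampling_rate / subject_id / eyes_condition).

#' Construct a validated EEG recording
#'
#' @param data numeric matrix, samples x channels, amplitudes in microvolts.
#' @param channels electrode labels (any capitalisation of the 10-20 names);
#'   defaults to `colnames(data)`.
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id opaque subject identifier.
#' @param reference reference label; recordings are expected against a
#'   linked-ear reference.
#' @param eyes_condition "closed" or "open".
#' @return An object of class `eeg_recording`: a list with elements `data`
#'   (matrix with canonical channel colnames), `channels`, `sampling_rate`,
#'   `subject_id`, `reference`, `eyes_condition`.
#' @export
eeg_recording <- function(data, channels = colnames(data), sampling_rate,
                          subject_id = "anonymous", reference = "linked-ear",
                          eyes_condition = c("closed", "open")) {
  eyes_condition <- match.arg(eyes_condition)
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L) {
    qeeg_error("recording data must be a non-empty numeric matrix",
               "qeeg_io_error")
  }
  if (is.null(channels) || length(channels) != ncol(data)) {
    qeeg_error("channel labels must match the number of data columns",
               "qeeg_montage_error")
  }
  channels <- normalize_channels(channels)
  if (anyDuplicated(channels)) {
    qeeg_error("duplicate channel labels", "qeeg_montage_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    qeeg_error("sampling_rate must be a positive number (Hz)",
               "qeeg_config_error")
  }
  colnames(data) <- channels
  structure(
    list(data = data, channels = channels, sampling_rate = sampling_rate,
         subject_id = as.character(subject_id), reference = reference,
         eyes_condition = eyes_condition),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels, %.1f s @ %g Hz (%s, eyes %s)\n",
              x$subject_id, length(x$channels),
              nrow(x$data) / x$sampling_rate, x$sampling_rate,
              x$reference, x$eyes_condition))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [eeg_recording()].
#' @return Length in seconds.
#' @export
recording_seconds <- function(rec) nrow(rec$data) / rec$sampling_rate

#' Read an EEG recording from disk
#'
#' `format = "tabular"` expects a CSV whose header row names the
#' electrodes and whose rows are samples in microvolts, with a JSON
#' sidecar (`<path>.json` by default) holding `sampling_rate`,
#' `subject_id` and `eyes_condition`. `format = "edf"` reads a 16-bit
#' EDF file.
#'
#' Channel labels are normalised to canonical 10-20 capitalisation;
#' unknown labels raise a montage error. A sampling rate below twice the
#' requested analysis ceiling raises a configuration error.
#'
#' @param path file path.
#' @param format "tabular" or "edf".
#' @param sidecar optional explicit sidecar path (tabular only).
#' @param min_sampling_rate lowest acceptable rate in Hz; the default 60
#'   is twice the 30 Hz upper analysis edge.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("tabular", "edf"), sidecar = NULL,
                           min_sampling_rate = 60) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    qeeg_error(sprintf("no such file: %s", path), "qeeg_io_error")
  }
  rec <- switch(format,
    tabular = read_recording_tabular(path, sidecar),
    edf = read_edf(path)
  )
  if (rec$sampling_rate < min_sampling_rate) {
    qeeg_error(
      sprintf("sampling rate %g Hz is below the required minimum %g Hz",
              rec$sampling_rate, min_sampling_rate),
      "qeeg_config_error"
    )
  }
  rec
}

read_recording_tabular <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  meta <- list(sampling_rate = 256, subject_id = "anonymous",
               eyes_condition = "closed")
  if (file.exists(sidecar)) {
    got <- jsonlite::fromJSON(sidecar)
    meta[names(got)] <- got
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(as.matrix(tab), channels = names(tab),
                sampling_rate = as.numeric(meta$sampling_rate),
                subject_id = meta$subject_id,
                eyes_condition = meta$eyes_condition)
}

#' Write a recording to disk
#'
#' Inverse of [read_recording()]; tabular writes the CSV plus its JSON
#' sidecar, EDF writes a 16-bit EDF with 1-second data records (the
#' trailing partial second, if any, is dropped with a warning).
#'
#' @param rec an [eeg_recording()].
#' @param path destination path.
#' @param format "tabular" or "edf".
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("tabular", "edf")) {
  format <- match.arg(format)
  if (format == "tabular") {
    utils::write.csv(as.data.frame(rec$data), path, row.names = FALSE)
    jsonlite::write_json(
      list(sampling_rate = rec$sampling_rate, subject_id = rec$subject_id,
           eyes_condition = rec$eyes_condition),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

# --- minimal EDF (16-bit) support ------------------------------------------
# EDF: 256-byte fixed header, 256 bytes of header per signal, then data
# records of little-endian int16 samples. Physical values are recovered by
# the usual linear map between the digital and physical ranges.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) {
    qeeg_error("EDF writer requires an integer sampling rate",
               "qeeg_config_error")
  }
  nrec <- floor(nrow(rec$data) / fs)
  if (nrec < 1) qeeg_error("recording shorter than one EDF record (1 s)",
                           "qeeg_io_error")
  if (nrec * fs < nrow(rec$data)) {
    qeeg_warn("trailing partial second dropped when writing EDF",
              "qeeg_io_warning")
  }
  ns <- length(rec$channels)
  x <- rec$data[seq_len(nrec * fs), , drop = FALSE]
  pmax_ <- apply(abs(x), 2, max)
  pmax_ <- ifelse(pmax_ > 0, signif(pmax_ * 1.01, 6), 1)
  dmax_ <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$subject_id, 80),
    edf_field(paste("eyes", rec$eyes_condition, "ref", rec$reference), 80),
    edf_field("01.01.20", 8), edf_field("00.00.00", 8),
    edf_field(256L * (ns + 1L), 8),
    edf_field("", 44),
    edf_field(nrec, 8),
    edf_field("1", 8),
    edf_field(ns, 4),
    paste(vapply(rec$channels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(-pmax_, edf_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_, edf_field, "", width = 8), collapse = ""),
    paste(rep(edf_field(-32768L, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax_, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(fs, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax_ - (-32768)) / (2 * pmax_)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[rows, ch] - (-pmax_[ch])) * scale[ch]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                # date, time
  rd(8)                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")  # transducer
  vapply(seq_len(ns), function(i) rd(8), "")   # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")  # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L) {
    qeeg_error("EDF signals with differing sampling rates are not supported",
               "qeeg_io_error")
  }
  out <- matrix(0, nrow = nrec * spr[1], ncol = ns)
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      rows <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      out[rows, ch] <- (dig - dmin_[ch]) * gain[ch] + pmin_[ch]
    }
  }
  eyes <- if (grepl("eyes open", rec_id, fixed = TRUE)) "open" else "closed"
  eeg_recording(out, channels = labels,
                sampling_rate = spr[1] / rec_dur,
                subject_id = subject_id, eyes_condition = eyes)
}
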