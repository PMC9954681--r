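# Windowed artifact rejection and the minimum-clean-data gate.
#
# Recordings are screened in consecutive fixed-length windows (20 s by
# default, the width used when manually deartifacting resting EEG). A
# window is rejected when any channel exceeds the amplitude limit or jumps
# more than the gradient limit between consecutive samples; surviving
# windows form the clean segment set. The gradient is evaluated within
# windows only, which makes rejection idempotent on the concatenation of
# retained windows.

#' Construct a clean segment set
#'
#' Segments are 0-based half-open sample intervals `[start, end)` into the
#' parent recording, non-overlapping and sorted.
#'
#' @param segments data frame with integer columns `start`, `end`.
#' @param sampling_rate Hz of the parent recording.
#' @param subject_id identifier carried along.
#' @param n_samples total samples of the parent recording (bounds check).
#' @return A `clean_segment_set` with derived `total_clean_seconds`.
#' @export
clean_segment_set <- function(segments, sampling_rate, subject_id = "anonymous",
                              n_samples = Inf) {
  stopifnot(is.data.frame(segments), all(c("start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 0) {
    if (any(segments$end <= segments$start) || any(segments$start < 0) ||
        any(segments$end > n_samples)) {
      qeeg_error("segments must be non-empty intervals within the recording",
                 "qeeg_segment_error")
    }
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      qeeg_error("segments overlap", "qeeg_segment_error")
    }
  }
  structure(
    list(subject_id = subject_id,
         segments = segments[, c("start", "end"), drop = FALSE],
         sampling_rate = sampling_rate,
         total_clean_seconds = sum(segments$end - segments$start) / sampling_rate),
    class = "clean_segment_set"
  )
}

#' @export
print.clean_segment_set <- function(x, ...) {
  cat(sprintf("<clean_segment_set> subject %s: %d segment(s), %.1f clean seconds\n",
              x$subject_id, nrow(x$segments), x$total_clean_seconds))
  invisible(x)
}

#' Windowed artifact rejection
#'
#' Tiles the recording into consecutive windows of `window_seconds`
#' (a trailing partial window is discarded) and rejects any window in
#' which some channel exceeds `amplitude_limit` in absolute value or
#' changes by more than `gradient_limit` between consecutive samples.
#'
#' @param rec an [eeg_recording()].
#' @param window_seconds window length in seconds (default 20).
#' @param amplitude_limit absolute amplitude ceiling in microvolts.
#' @param gradient_limit sample-to-sample step ceiling in microvolts.
#' @return A [clean_segment_set()] of the retained windows.
#' @export
reject_artifacts <- function(rec, window_seconds = 20, amplitude_limit = 100,
                             gradient_limit = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  wlen <- round(window_seconds * rec$sampling_rate)
  n <- nrow(rec$data)
  if (wlen < 2 || n < wlen) {
    qeeg_error("recording shorter than one artifact-screening window",
               "qeeg_segment_error")
  }
  n_win <- n %/% wlen
  keep <- logical(n_win)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * wlen + 1L):(w * wlen)
    block <- rec$data[rows, , drop = FALSE]
    amp_ok <- max(abs(block)) <= amplitude_limit
    grad_ok <- !amp_ok || all(abs(diff(block)) <= gradient_limit)
    keep[w] <- amp_ok && grad_ok
  }
  idx <- which(keep)
  segments <- data.frame(start = (idx - 1L) * wlen, end = idx * wlen)
  clean_segment_set(segments, rec$sampling_rate, rec$subject_id, n_samples = n)
}

#' Enforce the minimum-clean-data gate
#'
#' A subject must retain at least `minimum_seconds` of artifact-free data
#' (60 s by default, boundary inclusive) to stay in the cohort; otherwise
#' an exclusion error with reason "artifact" is raised so the caller can
#' feed the exclusion ledger.
#'
#' @param segs a [clean_segment_set()].
#' @param minimum_seconds required clean duration in seconds.
#' @return `segs`, unchanged, when the gate passes.
#' @export
enforce_minimum_clean <- function(segs, minimum_seconds = 60) {
  stopifnot(inherits(segs, "clean_segment_set"))
  if (segs$total_clean_seconds < minimum_seconds - 1e-9) {
    qeeg_error(
      sprintf("subject %s: %.1f clean seconds, below the %g s minimum",
              segs$subject_id, segs$total_clean_seconds, minimum_seconds),
      "qeeg_exclusion_error", reason = "artifact", subject_id = segs$subject_id
    )
  }
  segs
}

# Concatenate the retained windows of a recording (used by the idempotence
# property and by callers that want a gap-free clean signal).
#' Extract the clean samples of a recording as a new recording
#' @param rec an [eeg_recording()].
#' @param segs a [clean_segment_set()] for `rec`.
#' @return An [eeg_recording()] holding only the retained samples.
#' @export
extract_clean <- function(rec, segs) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(segs, "clean_segment_set"))
  rows <- unlist(lapply(seq_len(nrow(segs$segments)), function(i) {
    (segs$segments$start[i] + 1L):segs$segments$end[i]
  }))
  eeg_recording(rec$data[rows, , drop = FALSE], rec$channels,
                rec$sampling_rate, rec$subject_id, rec$reference,
                rec$eyes_condition)
}
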