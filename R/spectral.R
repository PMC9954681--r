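# Absolute band power per electrode via Welch's method.
#
# The estimator averages Hann-tapered periodograms over epochs drawn from
# clean segments only (2-s epochs, 50% overlap by default, giving 0.5 Hz
# resolution against the 1 Hz band edges). The PSD is one-sided with
# density scaling (uV^2/Hz); absolute band power is the trapezoidal
# integral of the PSD over each band. Under trapezoidal weighting an
# interior shared edge (4, 8, 12, 25 Hz) carries half weight in each
# adjacent band, so it is counted exactly once in total and the five
# bands sum exactly to the 1-30 Hz integral.

welch_taper <- function(n, taper) {
  switch(taper,
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
    none = rep(1, n),
    qeeg_error(sprintf("unknown taper '%s'", taper), "qeeg_config_error")
  )
}

# Average periodogram over epoch start indices (1-based), one channel.
welch_psd_channel <- function(x, starts, nfft, w, fs) {
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * w
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(nfft %/% 2 + 1)]
  }
  psd <- 2 * acc / (length(starts) * fs * u)
  # DC and Nyquist bins are their own mirror image: undo the doubling.
  psd[1] <- psd[1] / 2
  if (nfft %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  psd
}

# Trapezoidal integral of psd over [low, high] on the frequency grid.
band_integral <- function(freq, psd, low, high) {
  inb <- which(freq >= low - 1e-9 & freq <= high + 1e-9)
  if (length(inb) < 2) {
    qeeg_error(sprintf(
      "band [%g, %g) Hz spans fewer than two frequency bins", low, high),
      "qeeg_estimation_error")
  }
  f <- freq[inb]
  p <- psd[inb]
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Absolute band power per electrode
#'
#' Estimates the one-sided power spectral density of each channel by
#' Welch's method over epochs drawn from the clean segments (epochs never
#' cross a segment boundary; segments shorter than one epoch are skipped)
#' and integrates it over each band of the scheme.
#'
#' @param rec an [eeg_recording()].
#' @param segs a [clean_segment_set()]; `NULL` treats the whole recording
#'   as one clean segment.
#' @param scheme a [band_scheme()].
#' @param epoch_seconds epoch length in seconds (default 2, i.e. 0.5 Hz
#'   resolution at any integer sampling rate).
#' @param overlap_fraction fractional overlap between consecutive epochs
#'   in `[0, 1)`; default 0.5.
#' @param taper "hann" or "none".
#' @param log10_power if `TRUE`, report `log10` of the band power instead
#'   of raw microvolts-squared (off by default; scoring operates on
#'   absolute power).
#' @return A data frame with columns `subject_id`, `electrode`, `band`,
#'   `power_uv2`, one row per (electrode, band); attribute
#'   `clean_seconds_used` records the analysed duration.
#' @export
band_power <- function(rec, segs = NULL, scheme = default_band_scheme(),
                       epoch_seconds = 2, overlap_fraction = 0.5,
                       taper = c("hann", "none"), log10_power = FALSE) {
  taper <- match.arg(taper)
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs <= 2 * max(scheme$high_hz)) {
    qeeg_error(sprintf(
      "sampling rate %g Hz cannot resolve the %g Hz band edge", fs,
      max(scheme$high_hz)), "qeeg_config_error")
  }
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1) {
    qeeg_error("overlap_fraction must lie in [0, 1)", "qeeg_config_error")
  }
  if (is.null(segs)) {
    segs <- clean_segment_set(data.frame(start = 0L, end = nrow(rec$data)),
                              fs, rec$subject_id, n_samples = nrow(rec$data))
  }
  nfft <- round(epoch_seconds * fs)
  step <- max(1L, round(nfft * (1 - overlap_fraction)))
  starts <- unlist(lapply(seq_len(nrow(segs$segments)), function(i) {
    a <- segs$segments$start[i] + 1L
    b <- segs$segments$end[i]
    if (b - a + 1L < nfft) return(integer(0))  # segment shorter than epoch
    seq.int(a, b - nfft + 1L, by = step)
  }))
  if (length(starts) == 0) {
    qeeg_error("no clean segment is long enough for a single epoch",
               "qeeg_estimation_error")
  }
  w <- welch_taper(nfft, taper)
  freq <- seq(0, nfft %/% 2) * fs / nfft
  out <- expand.grid(electrode = rec$channels, band = scheme$band,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$power_uv2 <- NA_real_
  for (ch in seq_along(rec$channels)) {
    psd <- welch_psd_channel(rec$data[, ch], starts, nfft, w, fs)
    for (b in seq_len(nrow(scheme))) {
      i <- which(out$electrode == rec$channels[ch] &
                 out$band == scheme$band[b])
      out$power_uv2[i] <- band_integral(freq, psd, scheme$low_hz[b],
                                        scheme$high_hz[b])
    }
  }
  if (log10_power) out$power_uv2 <- log10(out$power_uv2)
  res <- data.frame(subject_id = rec$subject_id, out,
                    stringsAsFactors = FALSE)
  attr(res, "clean_seconds_used") <- segs$total_clean_seconds
  attr(res, "band_scheme") <- scheme
  res
}

#' Regional means across electrode groupings
#'
#' Averages a per-electrode value (band power, z, cohort mean z, ...)
#' across the electrodes of each scalp region, per band — and per subject
#' when a `subject_id` column is present.
#'
#' @param values data frame with columns `electrode`, `band` and one value
#'   column.
#' @param regions named list of electrode sets; see [default_regions()].
#' @param value_col name of the value column; by default the first column
#'   not named `subject_id`/`electrode`/`band`/`age`/`age_group`.
#' @return Data frame with columns (`subject_id`,) `region`, `band` and
#'   the value column, region means in montage order.
#' @export
regional_mean <- function(values, regions = default_regions(),
                          value_col = NULL) {
  stopifnot(is.data.frame(values),
            all(c("electrode", "band") %in% names(values)))
  if (is.null(value_col)) {
    cand <- setdiff(names(values),
                    c("subject_id", "electrode", "band", "age", "age_group",
                      "group", "sex"))
    if (length(cand) == 0) qeeg_error("no value column found",
                                      "qeeg_region_error")
    value_col <- cand[1]
  }
  has_subj <- "subject_id" %in% names(values)
  pieces <- lapply(names(regions), function(rg) {
    elec <- regions[[rg]]
    missing <- setdiff(elec, unique(values$electrode))
    if (length(missing) > 0) {
      qeeg_error(sprintf("region '%s' is missing electrode(s): %s", rg,
                         paste(missing, collapse = ", ")),
                 "qeeg_region_error")
    }
    sub <- values[values$electrode %in% elec, , drop = FALSE]
    keys <- if (has_subj) c("subject_id", "band") else "band"
    agg <- stats::aggregate(sub[[value_col]], by = sub[keys], FUN = mean)
    names(agg)[ncol(agg)] <- value_col
    agg$region <- rg
    agg
  })
  out <- do.call(rbind, pieces)
  cols <- c(if (has_subj) "subject_id", "region", "band", value_col)
  out[, cols, drop = FALSE]
}
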