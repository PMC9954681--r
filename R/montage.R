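# Montage, band scheme, age-group scheme and regional groupings shared by
# every pipeline stage.

# Canonical 19-electrode 10-20 montage (capitalisation as printed on caps).
TEN_TWENTY <- c(
  "Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
  "Cz", "C3", "C4", "T3", "T4", "T5", "T6",
  "Pz", "P3", "P4", "O1", "O2"
)

BAND_LEVELS <- c("delta", "theta", "alpha", "beta", "high-beta")

#' The 19-channel 10-20 montage
#'
#' @return Character vector of the 19 canonical electrode labels
#'   (Fp1 ... O2) in montage order.
#' @export
ten_twenty_channels <- function() TEN_TWENTY

# Map arbitrary-case labels onto canonical capitalisation; unknown labels
# are a montage error.
normalize_channels <- function(labels) {
  idx <- match(toupper(trimws(labels)), toupper(TEN_TWENTY))
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    qeeg_error(
      sprintf("channel label(s) not in the 10-20 montage: %s",
              paste(bad, collapse = ", ")),
      "qeeg_montage_error"
    )
  }
  TEN_TWENTY[idx]
}

#' Frequency band scheme
#'
#' Defines the analysis bands as half-open intervals \code{[low, high)} in
#' Hz. The default is the five-band scheme delta 1-4, theta 4-8, alpha
#' 8-12, beta 12-25 and high-beta 25-30 Hz. Bands must not overlap.
#'
#' @param band character vector of band names.
#' @param low_hz,high_hz numeric vectors of band edges in Hz.
#' @return A `band_scheme` data frame with columns `band`, `low_hz`,
#'   `high_hz`, ordered by `low_hz`.
#' @export
band_scheme <- function(band = BAND_LEVELS,
                        low_hz = c(1, 4, 8, 12, 25),
                        high_hz = c(4, 8, 12, 25, 30)) {
  stopifnot(length(band) == length(low_hz), length(band) == length(high_hz))
  if (any(high_hz <= low_hz)) {
    qeeg_error("band upper edges must exceed lower edges", "qeeg_config_error")
  }
  ord <- order(low_hz)
  band <- as.character(band)[ord]
  low_hz <- low_hz[ord]
  high_hz <- high_hz[ord]
  if (anyDuplicated(band)) {
    qeeg_error("band names must be unique", "qeeg_config_error")
  }
  # Half-open convention: a band may start exactly where the previous ends.
  if (length(band) > 1 && any(low_hz[-1] < high_hz[-length(high_hz)])) {
    qeeg_error("bands overlap", "qeeg_config_error")
  }
  structure(
    data.frame(band = band, low_hz = low_hz, high_hz = high_hz,
               stringsAsFactors = FALSE),
    class = c("band_scheme", "data.frame")
  )
}

#' @rdname band_scheme
#' @export
default_band_scheme <- function() band_scheme()

#' Age-group scheme for normative stratification
#'
#' Ten-year segments with integer-year inclusive bounds; the default is
#' 20-30, 31-40, 41-50, 51-60, 61-70. Groups must be disjoint.
#'
#' @param label group labels.
#' @param min_age,max_age inclusive integer bounds per group.
#' @return An `age_group_scheme` data frame.
#' @export
age_group_scheme <- function(label = c("20-30", "31-40", "41-50", "51-60", "61-70"),
                             min_age = c(20, 31, 41, 51, 61),
                             max_age = c(30, 40, 50, 60, 70)) {
  stopifnot(length(label) == length(min_age), length(label) == length(max_age))
  if (any(max_age < min_age)) {
    qeeg_error("age-group max below min", "qeeg_config_error")
  }
  ord <- order(min_age)
  label <- as.character(label)[ord]
  min_age <- min_age[ord]
  max_age <- max_age[ord]
  if (length(label) > 1 && any(min_age[-1] <= max_age[-length(max_age)])) {
    qeeg_error("age groups overlap", "qeeg_config_error")
  }
  structure(
    data.frame(label = label, min_age = min_age, max_age = max_age,
               stringsAsFactors = FALSE),
    class = c("age_group_scheme", "data.frame")
  )
}

#' @rdname age_group_scheme
#' @export
default_age_groups <- function() age_group_scheme()

#' Assign subjects to age groups
#'
#' Assignment is by integer age with inclusive bounds on both ends, so 30
#' falls in "20-30" and 31 in "31-40" under the default scheme.
#'
#' @param age integer vector of ages in years.
#' @param scheme an [age_group_scheme()].
#' @return Character vector of group labels, same length as `age`.
#' @export
assign_age_group <- function(age, scheme = default_age_groups()) {
  if (any(!is.finite(age)) || any(age != floor(age))) {
    qeeg_error("ages must be finite whole numbers of years",
               "qeeg_assignment_error")
  }
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(scheme))) {
    hit <- age >= scheme$min_age[i] & age <= scheme$max_age[i]
    out[hit] <- scheme$label[i]
  }
  if (anyNA(out)) {
    qeeg_error(
      sprintf("age(s) outside the scheme's range: %s",
              paste(unique(age[is.na(out)]), collapse = ", ")),
      "qeeg_assignment_error"
    )
  }
  out
}

#' Regional electrode groupings
#'
#' The scalp regions used for regional summaries: frontal (F3, F4, Fz),
#' central (C3, C4, Cz), parietal (P3, P4, Pz), temporal (T3, T4, T5, T6)
#' and occipital (O1, O2).
#'
#' @return Named list of electrode-label vectors.
#' @export
default_regions <- function() {
  list(
    frontal   = c("F3", "F4", "Fz"),
    central   = c("C3", "C4", "Cz"),
    parietal  = c("P3", "P4", "Pz"),
    temporal  = c("T3", "T4", "T5", "T6"),
    occipital = c("O1", "O2")
  )
}
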