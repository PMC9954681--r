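# Synthetic cohorts and raw signals with known ground truth.
#
# Band powers are generated directly at the feature level for statistical
# work (cells share a per-subject, per-band factor so that electrodes are
# correlated, as real scalp power is), and at the raw-signal level for
# tests of the signal path (band-limited Gaussian noise calibrated to
# target band powers, plus injected blink/movement transients).

#' Specification of a synthetic cohort
#'
#' @param group cohort label, "HC" or "MDD".
#' @param n_per_group named integer vector of subjects per age group
#'   (names must match the scheme labels).
#' @param sex_split data frame with columns `group`, `F`, `M` giving the
#'   per-age-group sex counts; `NULL` splits each group as evenly as
#'   possible.
#' @param baseline data frame `band`, `mean_uv2`, `sd_uv2`: the
#'   first-age-group population mean and SD of absolute power, identical
#'   across electrodes.
#' @param age_trend matrix of multipliers, age groups x bands, applied to
#'   the baseline means (SDs scale along to keep the coefficient of
#'   variation); the default declines the slow bands ~2% per decade group
#'   and lifts the fast bands after the 51-60 group.
#' @param delta_shift data frame `electrode`, `band`, `delta`: group
#'   effect in SD units added to the cell mean (0 rows = no shift; the
#'   healthy preset).
#' @param electrode_correlation correlation of cell noise across
#'   electrodes within one (subject, band); default 0.9, the regime in
#'   which three central electrodes yield internal consistencies above
#'   0.9.
#' @param questionnaires list with `bdi = c(mean, sd)` and
#'   `bai = c(mean, sd)` target summaries.
#' @param education_probs probabilities over the six education levels.
#' @param age_scheme an [age_group_scheme()].
#' @param band_scheme_ a [band_scheme()].
#' @param seed integer random seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group = "HC",
                        n_per_group = c("20-30" = 84, "31-40" = 47,
                                        "41-50" = 55, "51-60" = 49,
                                        "61-70" = 25),
                        sex_split = NULL,
                        baseline = default_baseline_powers(),
                        age_trend = default_age_trend(),
                        delta_shift = NULL,
                        electrode_correlation = 0.9,
                        questionnaires = list(bdi = c(4.23, 3.52),
                                              bai = c(1.95, 1.93)),
                        education_probs = NULL,
                        age_scheme = default_age_groups(),
                        band_scheme_ = default_band_scheme(),
                        seed = 1L) {
  if (any(n_per_group < 2)) {
    qeeg_error("every age group needs n >= 2", "qeeg_spec_error")
  }
  if (!all(names(n_per_group) %in% age_scheme$label)) {
    qeeg_error("n_per_group names must match the age scheme",
               "qeeg_spec_error")
  }
  if (any(baseline$sd_uv2 <= 0)) {
    qeeg_error("baseline SDs must be positive", "qeeg_spec_error")
  }
  if (electrode_correlation < 0 || electrode_correlation >= 1) {
    qeeg_error("electrode_correlation must lie in [0, 1)", "qeeg_spec_error")
  }
  if (is.null(delta_shift)) {
    delta_shift <- data.frame(electrode = character(0), band = character(0),
                              delta = numeric(0))
  }
  structure(
    list(group = group, n_per_group = n_per_group, sex_split = sex_split,
         baseline = baseline, age_trend = age_trend,
         delta_shift = delta_shift,
         electrode_correlation = electrode_correlation,
         questionnaires = questionnaires,
         education_probs = education_probs,
         age_scheme = age_scheme, band_scheme = band_scheme_, seed = seed),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_baseline_powers <- function() {
  data.frame(band = BAND_LEVELS,
             mean_uv2 = c(20, 12, 18, 9, 4),
             sd_uv2 = c(7, 4.2, 6.3, 3.2, 1.4),
             stringsAsFactors = FALSE)
}

#' @rdname cohort_spec
#' @export
default_age_trend <- function() {
  slow <- c(1, 0.98, 0.96, 0.94, 0.92)
  fast <- c(1, 1, 1, 1.05, 1.08)
  m <- cbind(delta = slow, theta = slow, alpha = slow,
             beta = fast, `high-beta` = fast)
  rownames(m) <- c("20-30", "31-40", "41-50", "51-60", "61-70")
  m
}

# Table of patient-group shifts (in SD units) used by the MDD preset:
# slow bands essentially unshifted, beta raised frontally/centrally and
# high-beta raised over the whole scalp with a frontal maximum.
mdd_delta_table <- function() {
  reg <- default_regions()
  expand <- function(band, frontal, lateral_frontal, central, parietal,
                     temporal, occipital, prefrontal) {
    vals <- c(stats::setNames(rep(frontal, 3), reg$frontal),
              F7 = lateral_frontal, F8 = lateral_frontal,
              stats::setNames(rep(central, 3), reg$central),
              stats::setNames(rep(parietal, 3), reg$parietal),
              stats::setNames(rep(temporal, 4), reg$temporal),
              stats::setNames(rep(occipital, 2), reg$occipital),
              Fp1 = prefrontal, Fp2 = prefrontal)
    data.frame(electrode = names(vals), band = band, delta = unname(vals),
               stringsAsFactors = FALSE)
  }
  rbind(
    expand("delta",     -0.13, -0.12, -0.17, -0.10, -0.16, -0.05, -0.10),
    expand("theta",     -0.03, -0.08, -0.02, -0.04, -0.04,  0.00, -0.03),
    expand("alpha",      0.07,  0.05,  0.08,  0.04,  0.10,  0.08,  0.07),
    expand("beta",       1.20,  0.96,  1.00,  0.70,  0.90,  0.62,  1.00),
    expand("high-beta",  1.73,  1.30,  1.22,  1.31,  1.07,  0.96,  1.50)
  )
}

#' Study-structured cohort presets
#'
#' `hc_cohort_spec()` mirrors the healthy normative cohort: n = 260 over
#' the five age groups (84/47/55/49/25) with the recruited sex splits and
#' sub-clinical questionnaire summaries. `mdd_cohort_spec()` mirrors the
#' patient cohort: n = 221 (65/39/55/37/25), female-predominant, clinical
#' questionnaire summaries, and band-power means shifted by the
#' patient-effect table (beta/high-beta raised, frontal high-beta +1.73
#' SD).
#'
#' @param seed integer random seed.
#' @return A [cohort_spec()].
#' @export
hc_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    group = "HC",
    n_per_group = c("20-30" = 84, "31-40" = 47, "41-50" = 55,
                    "51-60" = 49, "61-70" = 25),
    sex_split = data.frame(group = c("20-30", "31-40", "41-50", "51-60", "61-70"),
                           F = c(40, 23, 26, 26, 15),
                           M = c(44, 24, 29, 23, 10)),
    questionnaires = list(bdi = c(4.23, 3.52), bai = c(1.95, 1.93)),
    education_probs = c(2, 4, 32, 33, 113, 76) / 260,
    seed = seed
  )
}

#' @rdname hc_cohort_spec
#' @export
mdd_cohort_spec <- function(seed = 2L) {
  cohort_spec(
    group = "MDD",
    n_per_group = c("20-30" = 65, "31-40" = 39, "41-50" = 55,
                    "51-60" = 37, "61-70" = 25),
    sex_split = data.frame(group = c("20-30", "31-40", "41-50", "51-60", "61-70"),
                           F = c(41, 33, 43, 28, 18),
                           M = c(24, 6, 12, 9, 7)),
    delta_shift = mdd_delta_table(),
    questionnaires = list(bdi = c(31.93, 10.50), bai = c(22.28, 9.91)),
    education_probs = c(6, 20, 66, 32, 77, 20) / 221,
    seed = seed
  )
}

EDUCATION_LEVELS <- c("primary", "junior_high", "senior_high",
                      "junior_college", "university", "graduate")

#' Generate a synthetic band-power cohort with known ground truth
#'
#' Per (subject, electrode, band) cell, power is drawn from a normal with
#' the group-and-age-adjusted mean (shifted by delta x SD for patient
#' cells) and the cell SD, truncated at 0 by redraw. Within one
#' (subject, band), electrodes share a common factor with loading
#' sqrt(rho), so cells are correlated as on a real scalp. Questionnaire
#' scores and education are drawn per subject. Fully reproducible under
#' the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return List with `powers` (long table: `subject_id`, `age`, `sex`,
#'   `group`, `age_group`, `electrode`, `band`, `power_uv2`), `subjects`
#'   (metadata incl. `bdi_ii`, `bai`, `education`) and `truth` (per
#'   (age_group, electrode, band): true `mean`, `sd`, `delta`, and the
#'   shifted mean actually sampled from).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  labels <- names(spec$n_per_group)
  rho <- spec$electrode_correlation
  n_total <- sum(spec$n_per_group)
  electrodes <- TEN_TWENTY
  bands <- spec$band_scheme$band

  # subject metadata ---------------------------------------------------
  subj <- do.call(rbind, lapply(labels, function(g) {
    n <- spec$n_per_group[[g]]
    row <- spec$age_scheme[spec$age_scheme$label == g, ]
    ages <- sample(row$min_age:row$max_age, n, replace = TRUE)
    if (!is.null(spec$sex_split)) {
      ss <- spec$sex_split[spec$sex_split$group == g, ]
      if (ss$F + ss$M != n) {
        qeeg_error(sprintf("sex split for group %s does not sum to n", g),
                   "qeeg_spec_error")
      }
      sex <- sample(c(rep("F", ss$F), rep("M", ss$M)))
    } else {
      sex <- sample(rep_len(c("F", "M"), n))
    }
    data.frame(age = ages, sex = sex, age_group = g, stringsAsFactors = FALSE)
  }))
  subj$subject_id <- sprintf("%s-%03d", spec$group, seq_len(n_total))
  subj$group <- spec$group
  q <- spec$questionnaires
  if (spec$group == "HC") {
    subj$bdi_ii <- generate_questionnaires(n_total, q$bdi[1], q$bdi[2],
                                           lower = 0, upper = 13)
    subj$bai <- generate_questionnaires(n_total, q$bai[1], q$bai[2],
                                        lower = 0, upper = 7)
  } else {
    subj$bdi_ii <- generate_questionnaires(n_total, q$bdi[1], q$bdi[2],
                                           lower = 15, upper = 63)
    subj$bai <- generate_questionnaires(n_total, q$bai[1], q$bai[2],
                                        lower = 9, upper = 63)
  }
  ed_probs <- spec$education_probs
  if (is.null(ed_probs)) ed_probs <- rep(1 / 6, 6)
  subj$education <- sample(EDUCATION_LEVELS, n_total, replace = TRUE,
                           prob = ed_probs)
  subj$diagnosis <- if (spec$group == "MDD") "MDD" else NA_character_
  subj <- subj[, c("subject_id", "age", "sex", "group", "age_group",
                   "bdi_ii", "bai", "education", "diagnosis")]

  # cell-level truth ----------------------------------------------------
  truth <- expand.grid(age_group = labels, electrode = electrodes,
                       band = bands, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  bl <- spec$baseline[match(truth$band, spec$baseline$band), ]
  mult <- spec$age_trend[cbind(match(truth$age_group, rownames(spec$age_trend)),
                               match(truth$band, colnames(spec$age_trend)))]
  truth$mean <- bl$mean_uv2 * mult
  truth$sd <- bl$sd_uv2 * mult
  truth$delta <- 0
  if (nrow(spec$delta_shift) > 0) {
    key <- paste(truth$electrode, truth$band)
    dkey <- paste(spec$delta_shift$electrode, spec$delta_shift$band)
    hit <- match(key, dkey)
    truth$delta[!is.na(hit)] <- spec$delta_shift$delta[hit[!is.na(hit)]]
  }
  truth$sampled_mean <- truth$mean + truth$delta * truth$sd

  # band powers ---------------------------------------------------------
  pieces <- vector("list", length(labels) * length(bands))
  k <- 0
  for (g in labels) {
    gsub <- subj[subj$age_group == g, ]
    n <- nrow(gsub)
    for (b in bands) {
      cell <- truth[truth$age_group == g & truth$band == b, ]
      cell <- cell[match(electrodes, cell$electrode), ]
      u <- stats::rnorm(n)                       # shared per-subject factor
      eps <- matrix(stats::rnorm(n * length(electrodes)), n)
      zmat <- sqrt(rho) * u + sqrt(1 - rho) * eps
      x <- matrix(cell$sampled_mean, n, length(electrodes), byrow = TRUE) +
        matrix(cell$sd, n, length(electrodes), byrow = TRUE) * zmat
      # truncate at 0 by redrawing the idiosyncratic part (not clipping)
      tries <- 0
      while (any(x <= 0) && tries < 1000) {
        bad <- which(x <= 0)
        eps[bad] <- stats::rnorm(length(bad))
        zb <- sqrt(rho) * u[(bad - 1) %% n + 1] + sqrt(1 - rho) * eps[bad]
        x[bad] <- cell$sampled_mean[(bad - 1) %/% n + 1] +
          cell$sd[(bad - 1) %/% n + 1] * zb
        tries <- tries + 1
      }
      if (any(x <= 0)) x[x <= 0] <- .Machine$double.eps
      k <- k + 1
      pieces[[k]] <- data.frame(
        subject_id = rep(gsub$subject_id, times = length(electrodes)),
        electrode = rep(electrodes, each = n),
        band = b, power_uv2 = as.vector(x), stringsAsFactors = FALSE
      )
    }
  }
  powers <- do.call(rbind, pieces)
  powers <- merge(subj[, c("subject_id", "age", "sex", "group", "age_group")],
                  powers, by = "subject_id")
  powers <- powers[order(match(powers$subject_id, subj$subject_id),
                         match(powers$electrode, electrodes),
                         match(powers$band, bands)), ]
  rownames(powers) <- NULL
  list(powers = powers, subjects = subj, truth = truth)
}

#' Integer questionnaire scores from a moment-matched truncated normal
#'
#' Scores are drawn from a normal, rounded to integers and redrawn until
#' they fall in `[lower, upper]` (so healthy-range and clinical-range
#' screens hold by construction). Because truncating a normal moves its
#' mean, the underlying location is first solved (closed-form truncated
#' normal mean, root-found) so that the *truncated* distribution has the
#' requested mean.
#'
#' @param n number of scores.
#' @param mean,sd target mean and the (pre-truncation) SD.
#' @param lower,upper inclusive integer bounds (questionnaire range 0-63,
#'   narrowed by the screening rule in use).
#' @return Integer vector of length `n`.
#' @export
generate_questionnaires <- function(n, mean, sd, lower = 0, upper = 63) {
  if (sd <= 0 || upper <= lower) {
    qeeg_error("need sd > 0 and upper > lower", "qeeg_spec_error")
  }
  lo <- lower - 0.5
  hi <- upper + 0.5
  trunc_mean <- function(mu0) {
    a <- (lo - mu0) / sd
    b <- (hi - mu0) / sd
    den <- stats::pnorm(b) - stats::pnorm(a)
    mu0 + sd * (stats::dnorm(a) - stats::dnorm(b)) / den
  }
  if (trunc_mean(lo) > mean || trunc_mean(hi) < mean) {
    qeeg_warn("target mean unreachable inside the screening bounds",
              "qeeg_spec_warning")
    mu0 <- if (trunc_mean(lo) > mean) lo else hi  # nearest attainable
  } else {
    # trunc_mean is increasing in mu0 and maps [lo, hi] onto an interval
    # containing every reachable target, so [lo, hi] brackets the root
    mu0 <- stats::uniroot(function(m) trunc_mean(m) - mean,
                          lower = lo, upper = hi, tol = 1e-8)$root
  }
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(stats::rnorm(2 * (n - length(out)) + 10, mu0, sd))
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  as.integer(out[seq_len(n)])
}

#' Specification of a synthetic raw signal
#'
#' @param duration_seconds signal length (> 0).
#' @param sampling_rate Hz (default 256).
#' @param band_targets named vector of target absolute band power in
#'   microvolts-squared over the default bands (missing/zero = silent
#'   band).
#' @param channels electrode labels (default full 19-channel montage).
#' @param artifacts data frame `time_seconds`, `kind` ("blink" or
#'   "movement"), `amplitude_uv`; `NULL` for a clean signal.
#' @param scheme a [band_scheme()].
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(duration_seconds, sampling_rate = 256,
                        band_targets = c(alpha = 200),
                        channels = TEN_TWENTY, artifacts = NULL,
                        scheme = default_band_scheme()) {
  if (duration_seconds <= 0) {
    qeeg_error("duration must be positive", "qeeg_spec_error")
  }
  if (any(band_targets < 0)) {
    qeeg_error("band power targets must be non-negative", "qeeg_spec_error")
  }
  if (!all(names(band_targets) %in% scheme$band)) {
    qeeg_error("band_targets names must match the band scheme",
               "qeeg_spec_error")
  }
  if (sampling_rate <= 2 * max(scheme$high_hz[match(names(band_targets),
                                                    scheme$band)],
                               0)) {
    qeeg_error("sampling rate too low for the requested bands",
               "qeeg_spec_error")
  }
  structure(
    list(duration_seconds = duration_seconds, sampling_rate = sampling_rate,
         band_targets = band_targets, channels = channels,
         artifacts = artifacts, scheme = scheme),
    class = "signal_spec"
  )
}

FRONTAL_BLINK_CHANNELS <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8")

#' Generate a raw multichannel signal from band-power targets
#'
#' Each channel is a sum over bands of band-limited Gaussian noise
#' (white noise filtered in the frequency domain to `[low, high)`) scaled
#' so its variance equals the target band power. Blink artifacts add a
#' low-frequency high-amplitude lobe on the frontal channels; movement
#' artifacts add a broadband high-amplitude burst on all channels.
#' Deterministic for a given seed.
#'
#' @param spec a [signal_spec()].
#' @param seed integer random seed.
#' @return An [eeg_recording()].
#' @export
generate_signal <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "signal_spec"))
  set.seed(seed)
  fs <- spec$sampling_rate
  n <- round(spec$duration_seconds * fs)
  freq <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  nch <- length(spec$channels)
  x <- matrix(0, n, nch)
  for (b in names(spec$band_targets)) {
    target <- spec$band_targets[[b]]
    if (target <= 0) next
    row <- spec$scheme[spec$scheme$band == b, ]
    # guard margin of about one analysis bin keeps the estimator's edge
    # smearing inside the band, so realized band power tracks the target
    guard <- min(0.5, (row$high_hz - row$low_hz) / 8)
    keep <- abs(freq) >= row$low_hz + guard & abs(freq) < row$high_hz - guard
    for (ch in seq_len(nch)) {
      white <- stats::rnorm(n)
      spec_f <- stats::fft(white)
      spec_f[!keep] <- 0
      y <- Re(stats::fft(spec_f, inverse = TRUE)) / n
      y <- y / stats::sd(y) * sqrt(target)
      x[, ch] <- x[, ch] + y
    }
  }
  if (!is.null(spec$artifacts) && nrow(spec$artifacts) > 0) {
    t_axis <- seq_len(n) / fs
    for (i in seq_len(nrow(spec$artifacts))) {
      ev <- spec$artifacts[i, ]
      if (ev$kind == "blink") {
        lobe <- ev$amplitude_uv * exp(-(t_axis - ev$time_seconds)^2 / (2 * 0.15^2))
        cols <- which(spec$channels %in% FRONTAL_BLINK_CHANNELS)
        if (length(cols) == 0) cols <- seq_len(nch)
        x[, cols] <- x[, cols] + lobe
      } else if (ev$kind == "movement") {
        rows <- which(abs(t_axis - ev$time_seconds) <= 0.25)
        burst <- matrix(stats::runif(length(rows) * nch, -1, 1) *
                          ev$amplitude_uv, length(rows), nch)
        x[rows, ] <- x[rows, ] + burst
      } else {
        qeeg_error(sprintf("unknown artifact kind '%s'", ev$kind),
                   "qeeg_spec_error")
      }
    }
  }
  eeg_recording(x, channels = spec$channels, sampling_rate = fs,
                subject_id = "synthetic")
}
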