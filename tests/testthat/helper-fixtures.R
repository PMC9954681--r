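# Fixture builders shared across the suite. Everything is generated in
# code; nothing binary is stored.

# A recording whose every channel is the same pure tone.
make_tone_recording <- function(freq_hz, amplitude_uv, seconds,
                                fs = 256, channels = ten_twenty_channels(),
                                phase = 0) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  x <- amplitude_uv * sin(2 * pi * freq_hz * t + phase)
  eeg_recording(matrix(rep(x, length(channels)), ncol = length(channels)),
                channels = channels, sampling_rate = fs,
                subject_id = "tone")
}

# A small balanced cohort powers table with explicit per-cell values.
make_tiny_powers <- function(values_by_subject, ages,
                             electrodes = c("Fz", "Cz"),
                             bands = c("alpha", "beta")) {
  stopifnot(length(values_by_subject) == length(ages))
  rows <- lapply(seq_along(values_by_subject), function(i) {
    expand.grid(subject_id = sprintf("s%02d", i), electrode = electrodes,
                band = bands, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$age <- rep(ages, each = length(electrodes) * length(bands))
  out$power_uv2 <- unlist(lapply(values_by_subject, function(v) {
    rep_len(v, length(electrodes) * length(bands))
  }))
  out
}

# Balanced gaussian cohort over all 19 electrodes / 5 bands; thin wrapper
# over the generator with a uniform group size.
make_uniform_cohort <- function(n_per_group, seed, group = "HC",
                                rho = 0.9, delta_shift = NULL) {
  q <- if (group == "MDD") {
    list(bdi = c(31.93, 10.50), bai = c(22.28, 9.91))
  } else {
    list(bdi = c(4.23, 3.52), bai = c(1.95, 1.93))
  }
  spec <- cohort_spec(
    group = group,
    n_per_group = c("20-30" = n_per_group, "31-40" = n_per_group,
                    "41-50" = n_per_group, "51-60" = n_per_group,
                    "61-70" = n_per_group),
    electrode_correlation = rho,
    delta_shift = delta_shift,
    questionnaires = q,
    seed = seed
  )
  generate_cohort(spec)
}

expect_qeeg_error <- function(expr, class) {
  expect_error(expr, class = class)
}
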