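# The synthetic generators: determinism, study structure, calibration and
# parameter recovery.

test_that("generation is deterministic under a fixed seed", {
  spec <- cohort_spec(n_per_group = c("20-30" = 4, "31-40" = 4, "41-50" = 4,
                                      "51-60" = 4, "61-70" = 4), seed = 71)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$powers, b$powers)
  expect_identical(a$subjects, b$subjects)
  s <- signal_spec(10, band_targets = c(alpha = 50))
  expect_identical(generate_signal(s, seed = 3)$data,
                   generate_signal(s, seed = 3)$data)
})

test_that("the study presets reproduce the cohort structures", {
  hc <- generate_cohort(hc_cohort_spec(seed = 72))
  expect_equal(nrow(hc$subjects), 260)
  expect_equal(as.integer(table(hc$subjects$age_group)[c("20-30", "31-40",
                                                         "41-50", "51-60",
                                                         "61-70")]),
               c(84, 47, 55, 49, 25))
  expect_equal(sum(hc$subjects$sex == "F"), 130)
  expect_equal(nrow(hc$powers), 260 * 19 * 5)
  # every HC subject passes the healthy screen by construction
  ok <- vapply(seq_len(nrow(hc$subjects)), function(i) {
    screen_subject(hc$subjects[i, ], role = "HC")$accept
  }, TRUE)
  expect_true(all(ok))

  mdd <- generate_cohort(mdd_cohort_spec(seed = 73))
  expect_equal(nrow(mdd$subjects), 221)
  expect_equal(sum(mdd$subjects$sex == "F"), 163)
  ok2 <- vapply(seq_len(nrow(mdd$subjects)), function(i) {
    screen_subject(mdd$subjects[i, ], role = "MDD")$accept
  }, TRUE)
  expect_true(all(ok2))
})

test_that("questionnaire scores hit their target means inside the screen bounds", {
  set.seed(74)
  hc_bdi <- generate_questionnaires(260, 4.23, 3.52, lower = 0, upper = 13)
  expect_true(all(hc_bdi >= 0 & hc_bdi <= 13))
  expect_lt(abs(mean(hc_bdi) - 4.23), 2 * 3.52 / sqrt(260))
  mdd_bai <- generate_questionnaires(221, 22.28, 9.91, lower = 9, upper = 63)
  expect_true(all(mdd_bai > 8))
  expect_lt(abs(mean(mdd_bai) - 22.28), 2 * 9.91 / sqrt(221))
  # unreachable targets warn instead of looping
  expect_warning(generate_questionnaires(10, 30, 2, lower = 0, upper = 13),
                 class = "qeeg_spec_warning")
})

test_that("norm building recovers the generator's cell means", {
  cohort <- make_uniform_cohort(40, seed = 75, rho = 0.5)
  db <- build_norms(cohort$powers)
  cells <- merge(db$cells, cohort$truth,
                 by.x = c("group", "electrode", "band"),
                 by.y = c("age_group", "electrode", "band"))
  ci_half <- qt(0.975, cells$n - 1) * cells$sd.y / sqrt(cells$n)
  inside <- abs(cells$mean.x - cells$sampled_mean) <= ci_half
  expect_gte(mean(inside), 0.9)   # ~95% coverage, margin for truncation
})

test_that("an injected patient shift is recovered by cohort mean z", {
  delta <- data.frame(electrode = c("Fz", "F3", "F4"), band = "high-beta",
                      delta = 1.7)
  hc <- make_uniform_cohort(50, seed = 76)
  mdd <- make_uniform_cohort(44, seed = 77, group = "MDD",
                             delta_shift = delta)
  db <- build_norms(hc$powers)
  z <- zscore_subject(mdd$powers, db)
  summ <- cohort_z_summary(z)
  hb <- summ$regions[summ$regions$region == "frontal" &
                     summ$regions$band == "high-beta", ]
  expect_lt(abs(hb$mean_z - 1.7), 0.35)
  # unshifted bands stay near zero
  qu <- summ$regions[summ$regions$region == "occipital" &
                     summ$regions$band == "alpha", ]
  expect_lt(abs(qu$mean_z), 0.35)
})

test_that("a null generator makes the groups exchangeable", {
  a <- make_uniform_cohort(30, seed = 78)
  b <- make_uniform_cohort(30, seed = 79, group = "MDD")  # no delta_shift
  cell <- function(co) co$powers$power_uv2[co$powers$electrode == "Cz" &
                                           co$powers$band == "beta"]
  tt <- t_test_from_summary(
    two_sample_summary(150, mean(cell(a)), sd(cell(a))),
    two_sample_summary(150, mean(cell(b)), sd(cell(b))), "welch")
  expect_gt(tt$p.value, 0.001)
})

test_that("signal generation calibrates realized band power to target", {
  sp <- signal_spec(60, band_targets = c(alpha = 200, delta = 50))
  rec <- generate_signal(sp, seed = 80)
  bp <- band_power(rec)
  alpha <- mean(bp$power_uv2[bp$band == "alpha"])
  delta <- mean(bp$power_uv2[bp$band == "delta"])
  expect_lt(abs(alpha - 200) / 200, 0.05)
  expect_lt(abs(delta - 50) / 50, 0.05)
  # silent spec
  silent <- generate_signal(signal_spec(30, band_targets = c(alpha = 0)),
                            seed = 81)
  expect_true(all(silent$data == 0))
  expect_true(all(band_power(silent)$power_uv2 == 0))
})

test_that("an injected blink knocks out exactly its window", {
  art <- data.frame(time_seconds = 30, kind = "blink", amplitude_uv = 400)
  rec <- generate_signal(signal_spec(300, band_targets = c(alpha = 30),
                                     artifacts = art), seed = 82)
  segs <- reject_artifacts(rec)
  expect_equal(segs$total_clean_seconds, 280)
  lost <- setdiff(0:14 * 20 * 256, segs$segments$start)
  expect_equal(lost, 1 * 20 * 256)          # the 20-40 s window
  # movement bursts hit all channels
  art2 <- data.frame(time_seconds = 50, kind = "movement",
                     amplitude_uv = 300)
  rec2 <- generate_signal(signal_spec(120, band_targets = c(alpha = 30),
                                      artifacts = art2), seed = 83)
  segs2 <- reject_artifacts(rec2)
  expect_equal(segs2$total_clean_seconds, 100)
})

test_that("invalid specs are rejected up front", {
  expect_qeeg_error(cohort_spec(n_per_group = c("20-30" = 1)),
                    "qeeg_spec_error")
  expect_qeeg_error(signal_spec(-5), "qeeg_spec_error")
  expect_qeeg_error(signal_spec(10, band_targets = c(alpha = -1)),
                    "qeeg_spec_error")
  expect_qeeg_error(signal_spec(10, sampling_rate = 40,
                                band_targets = c(`high-beta` = 10)),
                    "qeeg_spec_error")
})
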