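# Normative database construction and z-scoring.

test_that("cell statistics use the sample (n-1) formulas", {
  # two subjects per group with powers 1 and 3: mean 2, sd sqrt(2)
  ages <- c(25, 25, 35, 35, 45, 45, 55, 55, 65, 65)
  powers <- make_tiny_powers(as.list(rep(c(1, 3), 5)), ages)
  db <- build_norms(powers)
  expect_true(all(db$cells$mean == 2))
  expect_true(all(abs(db$cells$sd - sqrt(2)) < 1e-12))
  expect_true(all(db$cells$n == 2))
})

test_that("identical subjects give degenerate sd = 0 cells that poison scoring", {
  ages <- c(25, 26, 35, 36, 45, 46, 55, 56, 65, 66)
  powers <- make_tiny_powers(rep(list(5), 10), ages)
  db <- build_norms(powers)
  expect_true(all(db$cells$sd == 0))
  expect_qeeg_error(zscore_subject(powers, db), "qeeg_scoring_error")
})

test_that("norm recovery on gaussian draws matches the direct oracle", {
  set.seed(11)
  n <- 30
  draws <- rnorm(n, 50, 10)
  powers <- make_tiny_powers(as.list(draws), ages = rep(21:26, 5),
                             electrodes = "Fz", bands = "alpha")
  scheme <- age_group_scheme("20-30", 20, 30)
  db <- build_norms(powers, scheme)
  expect_equal(db$cells$mean, mean(draws), tolerance = 1e-12)
  expect_equal(db$cells$sd, sd(draws), tolerance = 1e-12)
  # 95% CI of the mean covers the population value here
  expect_lt(abs(db$cells$mean - 50), qt(0.975, n - 1) * 10 / sqrt(n))
})

test_that("age-group assignment is inclusive on both bounds", {
  expect_equal(assign_age_group(c(20, 30, 31, 40, 41, 70)),
               c("20-30", "20-30", "31-40", "31-40", "41-50", "61-70"))
  expect_qeeg_error(assign_age_group(19), "qeeg_assignment_error")
  expect_qeeg_error(assign_age_group(71), "qeeg_assignment_error")
  expect_qeeg_error(assign_age_group(25.5), "qeeg_assignment_error")
})

test_that("z-scores follow (x - mu) / sigma", {
  ages <- c(25, 26, 35, 36, 45, 46, 55, 56, 65, 66)
  powers <- make_tiny_powers(as.list(c(1, 3, 1, 3, 1, 3, 1, 3, 1, 3)), ages)
  db <- build_norms(powers)  # every cell mu = 2, sigma = sqrt(2)
  probe <- make_tiny_powers(list(2), 25)          # x = mu -> z = 0
  z0 <- zscore_subject(probe, db)
  expect_true(all(z0$z == 0))
  probe2 <- make_tiny_powers(list(2 + 2 * sqrt(2)), 25)  # x = mu + 2 sigma
  z2 <- zscore_subject(probe2, db)
  expect_equal(z2$z, rep(2, 4), tolerance = 1e-12)
  expect_equal(z2$abs_z, rep(2, 4), tolerance = 1e-12)
})

test_that("all-groups bookkeeping multiplies subjects x cells x groups", {
  cohort <- make_uniform_cohort(6, seed = 21)
  db <- build_norms(cohort$powers)
  zall <- zscore_subject(cohort$powers, db, mode = "all_groups")
  expect_equal(nrow(zall), 30 * 19 * 5 * 5)
})

test_that("self-scoring normalisation is exact per cell", {
  cohort <- make_uniform_cohort(8, seed = 22)
  db <- build_norms(cohort$powers)
  z <- zscore_subject(cohort$powers, db)
  key <- paste(z$age_group, z$electrode, z$band)
  expect_lt(max(abs(tapply(z$z, key, mean))), 1e-10)
  expect_lt(max(abs(tapply(z$z, key, sd) - 1)), 1e-10)
})

test_that("scoring is invariant to affine transforms applied consistently", {
  cohort <- make_uniform_cohort(5, seed = 23)
  db <- build_norms(cohort$powers)
  z <- zscore_subject(cohort$powers, db)
  shifted <- cohort$powers
  shifted$power_uv2 <- 4 * shifted$power_uv2 + 7
  db_s <- build_norms(shifted)
  z_s <- zscore_subject(shifted, db_s)
  expect_equal(z_s$z, z$z, tolerance = 1e-9)
})

test_that("cohort summary aggregates z and |z| and flags |.| > 1 cells", {
  # two subjects at z = +1 and -1 in one cell: mean z 0, mean |z| 1
  ztab <- data.frame(
    subject_id = c("a", "b"), age_group = "20-30",
    electrode = "Fz", band = "alpha", z = c(1, -1), abs_z = c(1, 1)
  )
  # pad remaining electrodes so regional summaries are defined
  pad <- expand.grid(subject_id = c("a", "b"),
                     electrode = setdiff(ten_twenty_channels(), "Fz"),
                     band = "alpha", KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  pad$age_group <- "20-30"; pad$z <- 0; pad$abs_z <- 0
  rep_ <- cohort_z_summary(rbind(ztab, pad[, names(ztab)]))
  fz <- rep_$cells[rep_$cells$electrode == "Fz", ]
  expect_equal(fz$mean_z, 0)
  expect_equal(fz$mean_abs_z, 1)
  expect_false(fz$flag)          # threshold is strict (> 1)
  others <- rep_$cells[rep_$cells$electrode != "Fz", ]
  expect_true(all(others$mean_z == 0) && !any(others$flag))
  # mean |z| always dominates |mean z|
  expect_true(all(rep_$cells$mean_abs_z >= abs(rep_$cells$mean_z) - 1e-12))
  expect_qeeg_error(cohort_z_summary(ztab[0, ]), "qeeg_summary_error")
})

test_that("the printed report drops the prefrontal pair but scoring keeps it", {
  cohort <- make_uniform_cohort(4, seed = 24)
  db <- build_norms(cohort$powers)
  z <- zscore_subject(cohort$powers, db)
  expect_true(all(c("Fp1", "Fp2") %in% z$electrode))
  tab <- z_report_table(cohort_z_summary(z))
  expect_equal(nrow(tab), 17)
  expect_false(any(rownames(tab) %in% c("Fp1", "Fp2")))
  expect_equal(colnames(tab),
               c("delta", "theta", "alpha", "beta", "high-beta"))
})

test_that("norm databases survive a JSON round trip", {
  cohort <- make_uniform_cohort(4, seed = 25)
  db <- build_norms(cohort$powers)
  path <- withr::local_tempfile(fileext = ".json")
  write_norms(db, path)
  back <- read_norms(path)
  expect_equal(back$cells$mean, db$cells$mean, tolerance = 1e-14)
  expect_equal(back$cells$sd, db$cells$sd, tolerance = 1e-14)
  z1 <- zscore_subject(cohort$powers, db)
  z2 <- zscore_subject(cohort$powers, back)
  expect_equal(z2$z, z1$z, tolerance = 1e-12)
  # csv mirror has the flat cell table
  csv <- withr::local_tempfile(fileext = ".csv")
  write_norms(db, csv, format = "csv")
  flat <- read.csv(csv)
  expect_equal(nrow(flat), 5 * 19 * 5)
})

test_that("underpopulated age groups abort the build with the group named", {
  powers <- make_tiny_powers(as.list(1:4), c(25, 26, 35, 36))
  err <- tryCatch(build_norms(powers), condition = identity)
  expect_s3_class(err, "qeeg_build_error")
  expect_match(conditionMessage(err), "41-50")
})
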