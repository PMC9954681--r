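# Reliability and validity machinery: independent cross-database
# correlation, leave-one-out scoring and Gaussian coverage audits.

#' Independent cross-database validation
#'
#' Scores a benchmark cohort (own-group mode) against two normative
#' databases and correlates the paired z-scores per (electrode, band)
#' across subjects. Identical databases give r = 1 everywhere; two
#' databases estimated from independent cohorts of one population differ
#' only through mean/SD estimation noise, so r stays high.
#'
#' @param benchmark powers table of the benchmark cohort (columns
#'   `subject_id`, `age`, `electrode`, `band`, `power_uv2`).
#' @param db_a,db_b `normative_db` objects.
#' @return A `cross_validation_report`: list with `cells` (per electrode
#'   x band: `r`, `p.value`, `n`) and `min_r` / `max_r` summaries.
#' @export
cross_database_validation <- function(benchmark, db_a, db_b) {
  za <- zscore_subject(benchmark, db_a, mode = "own_group")
  zb <- zscore_subject(benchmark, db_b, mode = "own_group")
  paired <- merge(za[, c("subject_id", "electrode", "band", "z")],
                  zb[, c("subject_id", "electrode", "band", "z")],
                  by = c("subject_id", "electrode", "band"),
                  suffixes = c("_a", "_b"))
  keys <- unique(paired[, c("electrode", "band")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- paired[paired$electrode == keys$electrode[i] &
                  paired$band == keys$band[i], ]
    if (nrow(sub) < 3) {
      qeeg_error("fewer than 3 benchmark subjects per cell",
                 "qeeg_validation_error")
    }
    ct <- pearson_r(sub$z_a, sub$z_b)
    data.frame(electrode = keys$electrode[i], band = keys$band[i],
               r = ct$r, p.value = ct$p.value, n = nrow(sub),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  cells <- cells[order(match(cells$electrode, TEN_TWENTY),
                       match(cells$band, BAND_LEVELS)), ]
  rownames(cells) <- NULL
  structure(
    list(cells = cells, min_r = min(cells$r), max_r = max(cells$r)),
    class = "cross_validation_report"
  )
}

#' @export
print.cross_validation_report <- function(x, ...) {
  cat(sprintf("<cross_validation_report> %d cells, r in [%.3f, %.3f]\n",
              nrow(x$cells), x$min_r, x$max_r))
  invisible(x)
}

#' Leave-one-out normative scoring
#'
#' For each subject, the norms of the subject's own age group are rebuilt
#' from the cohort minus that subject (sample mean and n-1 SD) and the
#' subject is scored against them. One subject's removal never affects
#' another subject's score.
#'
#' @param powers cohort powers table (columns `subject_id`, `age`,
#'   `electrode`, `band`, `power_uv2`).
#' @param scheme an [age_group_scheme()].
#' @return Long data frame `subject_id`, `age_group`, `electrode`,
#'   `band`, `z`.
#' @export
leave_one_out <- function(powers, scheme = default_age_groups()) {
  check_powers_table(powers)
  pcol <- power_column(powers)
  subjects <- unique(powers[, c("subject_id", "age")])
  subjects$group <- assign_age_group(subjects$age, scheme)
  gsize <- table(subjects$group)
  if (any(gsize < 3)) {
    qeeg_error("every age group needs >= 3 subjects for leave-one-out",
               "qeeg_validation_error")
  }
  dat <- merge(powers[, c("subject_id", "electrode", "band", pcol)],
               subjects[, c("subject_id", "group")], by = "subject_id")
  out <- lapply(split(dat, dat$group), function(gd) {
    ids <- unique(gd$subject_id)
    pieces <- lapply(ids, function(id) {
      rest <- gd[gd$subject_id != id, ]
      norm <- stats::aggregate(
        rest[[pcol]], by = rest[c("electrode", "band")],
        FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
      )
      norm <- data.frame(norm[c("electrode", "band")],
                         mean = norm$x[, "mean"], sd = norm$x[, "sd"])
      if (any(norm$sd <= 0)) {
        qeeg_error(sprintf(
          "degenerate leave-one-out cell (sd = 0) in group %s", gd$group[1]),
          "qeeg_scoring_error")
      }
      me <- merge(gd[gd$subject_id == id, ], norm, by = c("electrode", "band"))
      data.frame(subject_id = id, age_group = gd$group[1],
                 electrode = me$electrode, band = me$band,
                 z = (me[[pcol]] - me$mean) / me$sd,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gaussian coverage audit
#'
#' Fractions of a sample falling within the closed intervals
#' mean +- k SD for k = 1, 2, 3. A Gaussian population puts 68.26%,
#' 95.44% and 99.74% of individuals inside these ranges; an empirical
#' z-score distribution should approach those fractions.
#'
#' @param values numeric vector (non-empty).
#' @param mu,sigma reference mean and SD (sigma > 0).
#' @return A `coverage_audit`: named numeric vector `within_1sd`,
#'   `within_2sd`, `within_3sd` of fractions in `[0, 1]`.
#' @export
coverage_audit <- function(values, mu = 0, sigma = 1) {
  if (length(values) == 0 || !all(is.finite(values))) {
    qeeg_error("need a non-empty finite sample", "qeeg_validation_error")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    qeeg_error("sigma must be positive", "qeeg_validation_error")
  }
  frac <- vapply(1:3, function(k) {
    mean(values >= mu - k * sigma & values <= mu + k * sigma)
  }, 0)
  structure(stats::setNames(frac, c("within_1sd", "within_2sd", "within_3sd")),
            class = "coverage_audit")
}

#' @export
print.coverage_audit <- function(x, ...) {
  cat(sprintf("<coverage_audit> +-1 SD %.2f%%  +-2 SD %.2f%%  +-3 SD %.2f%%\n",
              100 * x[1], 100 * x[2], 100 * x[3]))
  invisible(x)
}
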