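# The normative database proper: age-stratified mean/SD cells and the
# z = (x - mu) / sigma scoring machinery.

power_column <- function(powers) {
  for (nm in c("power_uv2", "power")) if (nm %in% names(powers)) return(nm)
  qeeg_error("powers table needs a power_uv2 (or power) column",
             "qeeg_build_error")
}

check_powers_table <- function(powers, need_age = TRUE) {
  need <- c("subject_id", "electrode", "band", if (need_age) "age")
  missing <- setdiff(need, names(powers))
  if (length(missing) > 0) {
    qeeg_error(sprintf("powers table lacks column(s): %s",
                       paste(missing, collapse = ", ")), "qeeg_build_error")
  }
  invisible(powers)
}

#' Build an age-stratified normative database
#'
#' For every (age group, electrode, band) cell, the cell mean is the
#' arithmetic mean and the cell SD the sample (n-1) standard deviation of
#' absolute power over the group's subjects. Each subject contributes one
#' value per cell; each age group needs at least two subjects.
#'
#' @param powers long data frame of a healthy cohort: columns
#'   `subject_id`, `age`, `electrode`, `band`, `power_uv2`.
#' @param scheme an [age_group_scheme()].
#' @return A `normative_db`: list with `cells` (data frame `group`,
#'   `electrode`, `band`, `mean`, `sd`, `n`), the `age_scheme`, the band
#'   and electrode levels, a build timestamp and a cohort hash.
#' @export
build_norms <- function(powers, scheme = default_age_groups()) {
  check_powers_table(powers)
  pcol <- power_column(powers)
  if (any(!is.finite(powers[[pcol]])) || any(powers[[pcol]] < 0)) {
    qeeg_error("powers must be finite and non-negative", "qeeg_build_error")
  }
  subjects <- unique(powers[, c("subject_id", "age")])
  if (anyDuplicated(subjects$subject_id)) {
    qeeg_error("a subject appears with more than one age", "qeeg_build_error")
  }
  subjects$group <- assign_age_group(subjects$age, scheme)
  gsize <- table(subjects$group)
  small <- names(gsize)[gsize < 2]
  if (length(small) > 0 || !all(scheme$label %in% names(gsize))) {
    empty <- setdiff(scheme$label, names(gsize))
    qeeg_error(sprintf("age group(s) with fewer than 2 subjects: %s",
                       paste(c(small, empty), collapse = ", ")),
               "qeeg_build_error")
  }
  dat <- merge(powers[, c("subject_id", "electrode", "band", pcol)],
               subjects[, c("subject_id", "group")], by = "subject_id")
  cells <- stats::aggregate(
    dat[[pcol]], by = dat[c("group", "electrode", "band")],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  )
  cells <- data.frame(cells[c("group", "electrode", "band")],
                      mean = cells$x[, "mean"], sd = cells$x[, "sd"],
                      n = as.integer(cells$x[, "n"]),
                      stringsAsFactors = FALSE)
  electrodes <- unique(as.character(powers$electrode))
  bands <- unique(as.character(powers$band))
  if (nrow(cells) != length(scheme$label) * length(electrodes) * length(bands)) {
    qeeg_error("not every (group, electrode, band) combination is populated",
               "qeeg_build_error")
  }
  cells <- cells[order(match(cells$group, scheme$label),
                       match(cells$electrode, c(TEN_TWENTY, electrodes)),
                       match(cells$band, c(BAND_LEVELS, bands))), ]
  rownames(cells) <- NULL
  structure(
    list(cells = cells, age_scheme = scheme,
         electrodes = electrodes, bands = bands,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         cohort_hash = sprintf("n%d-%.8e", nrow(subjects),
                               sum(powers[[pcol]]))),
    class = "normative_db"
  )
}

#' @export
print.normative_db <- function(x, ...) {
  cat(sprintf(
    "<normative_db> %d cells: %d age groups x %d electrodes x %d bands (cohort %s)\n",
    nrow(x$cells), nrow(x$age_scheme), length(x$electrodes),
    length(x$bands), x$cohort_hash))
  invisible(x)
}

#' Serialise / read a normative database
#'
#' JSON carries the scheme, bands and explicit per-cell keys; `csv` writes
#' the flat cell table alone. Floats are stored at full precision.
#'
#' @param db a `normative_db`.
#' @param path destination path.
#' @param format "json" or "csv".
#' @return `path` invisibly (`write_norms`); a `normative_db`
#'   (`read_norms`, JSON only).
#' @export
write_norms <- function(db, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(db$cells, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(scheme = db$age_scheme, bands = db$bands,
           electrodes = db$electrodes, created = db$created,
           cohort_hash = db$cohort_hash, cells = db$cells),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  raw <- jsonlite::fromJSON(path)
  scheme <- age_group_scheme(raw$scheme$label, raw$scheme$min_age,
                             raw$scheme$max_age)
  structure(
    list(cells = raw$cells, age_scheme = scheme,
         electrodes = raw$electrodes, bands = raw$bands,
         created = raw$created, cohort_hash = raw$cohort_hash),
    class = "normative_db"
  )
}

#' Score subjects against a normative database
#'
#' Computes z = (x - mu) / sigma per (electrode, band) cell. In
#' `own_group` mode each subject is scored against the cells of their own
#' age group; `all_groups` emits one z per cell and *every* age group
#' (the bookkeeping mode whose total count is
#' subjects x electrodes x bands x groups). Any consulted cell with
#' sigma = 0 raises a scoring error naming the cell rather than returning
#' an infinite score.
#'
#' @param bp powers table for one or more subjects (columns `subject_id`,
#'   `age`, `electrode`, `band`, `power_uv2`).
#' @param db a `normative_db` from [build_norms()].
#' @param mode "own_group" or "all_groups".
#' @return Data frame with columns `subject_id`, `age_group`, `electrode`,
#'   `band`, `z`, `abs_z` (one row per cell in `own_group` mode, one per
#'   cell and group in `all_groups`).
#' @export
zscore_subject <- function(bp, db, mode = c("own_group", "all_groups")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "normative_db"))
  check_powers_table(bp, need_age = (mode == "own_group"))
  pcol <- power_column(bp)
  x <- bp[, c("subject_id", if ("age" %in% names(bp)) "age",
              "electrode", "band", pcol)]
  if (mode == "own_group") {
    x$age_group <- assign_age_group(x$age, db$age_scheme)
  } else {
    groups <- db$age_scheme$label
    x <- merge(x, data.frame(age_group = groups), by = NULL)
  }
  scored <- merge(x, db$cells,
                  by.x = c("age_group", "electrode", "band"),
                  by.y = c("group", "electrode", "band"), all.x = TRUE)
  if (anyNA(scored$mean)) {
    qeeg_error("some (group, electrode, band) cells are absent from the database",
               "qeeg_scoring_error")
  }
  degen <- scored$sd <= 0
  if (any(degen)) {
    i <- which(degen)[1]
    qeeg_error(sprintf(
      "degenerate cell (sd = 0) consulted: group %s, electrode %s, band %s",
      scored$age_group[i], scored$electrode[i], scored$band[i]),
      "qeeg_scoring_error")
  }
  scored$z <- (scored[[pcol]] - scored$mean) / scored$sd
  scored$abs_z <- abs(scored$z)
  out <- scored[, c("subject_id", "age_group", "electrode", "band", "z", "abs_z")]
  out <- out[order(out$subject_id, match(out$age_group, db$age_scheme$label),
                   match(out$electrode, TEN_TWENTY),
                   match(out$band, BAND_LEVELS)), ]
  rownames(out) <- NULL
  out
}

#' Cohort-level z summary
#'
#' Aggregates per-subject z tables (own-group scoring against a common
#' database) into per-cell means and SDs of z and of |z|, adds regional
#' means, and flags cells whose mean z or mean |z| exceeds the abnormality
#' threshold (1 by convention: scores beyond +-1 SD of the norm flag
#' potential abnormality).
#'
#' @param ztab z table from [zscore_subject()] (own-group mode), any
#'   number of subjects.
#' @param regions named list of electrode sets for the regional section.
#' @param flag_threshold abnormality threshold on the cohort means.
#' @return A `z_score_report`: list with `cells` (per electrode x band:
#'   `mean_z`, `sd_z`, `mean_abs_z`, `sd_abs_z`, `n`, `flag`), `regions`
#'   (per region x band means) and `n_subjects`.
#' @export
cohort_z_summary <- function(ztab, regions = default_regions(),
                             flag_threshold = 1) {
  if (!is.data.frame(ztab) || nrow(ztab) == 0) {
    qeeg_error("empty cohort: nothing to summarise", "qeeg_summary_error")
  }
  agg <- stats::aggregate(
    ztab[c("z", "abs_z")], by = ztab[c("electrode", "band")],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  )
  cells <- data.frame(agg[c("electrode", "band")],
                      mean_z = agg$z[, "mean"], sd_z = agg$z[, "sd"],
                      mean_abs_z = agg$abs_z[, "mean"],
                      sd_abs_z = agg$abs_z[, "sd"],
                      n = as.integer(agg$z[, "n"]),
                      stringsAsFactors = FALSE)
  cells$flag <- abs(cells$mean_z) > flag_threshold |
    cells$mean_abs_z > flag_threshold
  cells <- cells[order(match(cells$electrode, TEN_TWENTY),
                       match(cells$band, BAND_LEVELS)), ]
  rownames(cells) <- NULL
  reg_z <- regional_mean(cells[, c("electrode", "band", "mean_z")], regions)
  reg_a <- regional_mean(cells[, c("electrode", "band", "mean_abs_z")], regions)
  regions_tab <- merge(reg_z, reg_a, by = c("region", "band"))
  structure(
    list(cells = cells, regions = regions_tab,
         n_subjects = length(unique(ztab$subject_id)),
         flag_threshold = flag_threshold),
    class = "z_score_report"
  )
}

#' @export
print.z_score_report <- function(x, ...) {
  cat(sprintf("<z_score_report> %d subjects, %d cells (%d flagged beyond +-%g)\n",
              x$n_subjects, nrow(x$cells), sum(x$cells$flag),
              x$flag_threshold))
  invisible(x)
}

#' Wide electrode-by-band report table
#'
#' Reshapes a [cohort_z_summary()] into the conventional printed layout:
#' electrodes as rows, bands as columns, "mean (SD)" strings; the
#' prefrontal pair Fp1/Fp2 is dropped from the printed table by default
#' (scores are still computed for all 19 electrodes).
#'
#' @param report a `z_score_report`.
#' @param statistic "z" or "abs_z".
#' @param drop electrodes excluded from the printed table.
#' @param digits decimals in the formatted cells.
#' @return Character matrix, electrodes x bands.
#' @export
z_report_table <- function(report, statistic = c("z", "abs_z"),
                           drop = c("Fp1", "Fp2"), digits = 2) {
  statistic <- match.arg(statistic)
  cells <- report$cells[!report$cells$electrode %in% drop, ]
  mcol <- if (statistic == "z") "mean_z" else "mean_abs_z"
  scol <- if (statistic == "z") "sd_z" else "sd_abs_z"
  elec <- intersect(TEN_TWENTY, unique(cells$electrode))
  bands <- intersect(BAND_LEVELS, unique(cells$band))
  out <- matrix("", length(elec), length(bands),
                dimnames = list(elec, bands))
  for (i in seq_len(nrow(cells))) {
    out[as.character(cells$electrode[i]), as.character(cells$band[i])] <-
      sprintf(paste0("%.", digits, "f(%.", digits, "f)"),
              cells[[mcol]][i], cells[[scol]][i])
  }
  out
}
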