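# Cohort screening rules and the exclusion bookkeeping that accompanies
# normative-database recruitment.

#' Screening thresholds
#'
#' Healthy controls must score *below* both questionnaire cutoffs
#' (BDI-II < 14, BAI < 8); patients must score *above* both (BDI-II > 14,
#' BAI > 8) with a primary MDD diagnosis. Scores exactly at a cutoff fail
#' both screens. Both groups must be aged 20-70 inclusive.
#'
#' @param age_min,age_max inclusive age bounds in years.
#' @param bdi_cutoff,bai_cutoff questionnaire cutoffs.
#' @return Named list of thresholds.
#' @export
screening_thresholds <- function(age_min = 20, age_max = 70,
                                 bdi_cutoff = 14, bai_cutoff = 8) {
  list(age_min = age_min, age_max = age_max,
       bdi_cutoff = bdi_cutoff, bai_cutoff = bai_cutoff)
}

#' Screen one candidate for the healthy-control or patient cohort
#'
#' A pure decision: no error paths. The reason tag names the first failed
#' rule, checked in the order age, BDI-II, BAI, diagnosis.
#'
#' @param record a list or one-row data frame with fields `age`, `bdi_ii`,
#'   `bai` and (for the MDD role) `diagnosis`.
#' @param role "HC" or "MDD".
#' @param thresholds a [screening_thresholds()] list.
#' @return List with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise one of "age", "bdi", "bai", "diagnosis").
#' @export
screen_subject <- function(record, role = c("HC", "MDD"),
                           thresholds = screening_thresholds()) {
  role <- match.arg(role)
  th <- thresholds
  fail <- function(reason) list(accept = FALSE, reason = reason)
  age <- record$age
  if (is.null(age) || is.na(age) || age < th$age_min || age > th$age_max) {
    return(fail("age"))
  }
  if (role == "HC") {
    if (!(record$bdi_ii < th$bdi_cutoff)) return(fail("bdi"))
    if (!(record$bai < th$bai_cutoff)) return(fail("bai"))
  } else {
    if (!(record$bdi_ii > th$bdi_cutoff)) return(fail("bdi"))
    if (!(record$bai > th$bai_cutoff)) return(fail("bai"))
    diag <- record$diagnosis
    if (is.null(diag) || is.na(diag) || diag != "MDD") return(fail("diagnosis"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Tally recruitment and EEG exclusions into a ledger
#'
#' Takes the per-subject decisions of the two screening stages and checks
#' the conservation arithmetic: recruited - screening exclusions =
#' completed EEG; completed - EEG exclusions = final n.
#'
#' @param screening data frame with one row per recruited subject:
#'   columns `subject_id`, `accept` (logical), `reason` (tag, `NA` when
#'   accepted).
#' @param eeg data frame with one row per subject who completed the EEG
#'   stage, same columns; reasons are typically "artifact" or "damaged".
#' @return An `exclusion_ledger` list with counts `recruited`,
#'   `excluded_screening`, `completed_eeg`, `excluded_eeg`, `final_n` and
#'   reason tables `screening_reasons`, `eeg_reasons`.
#' @export
tally_exclusions <- function(screening, eeg) {
  for (d in list(screening, eeg)) {
    if (!all(c("subject_id", "accept", "reason") %in% names(d))) {
      qeeg_error("decision tables need subject_id, accept, reason columns",
                 "qeeg_ledger_error")
    }
  }
  if (anyDuplicated(screening$subject_id) || anyDuplicated(eeg$subject_id)) {
    qeeg_error("a subject has more than one decision in a stage",
               "qeeg_ledger_error")
  }
  recruited <- nrow(screening)
  completed <- sum(screening$accept)
  if (nrow(eeg) != completed) {
    qeeg_error(sprintf(
      "EEG-stage decisions (%d) do not match screening survivors (%d)",
      nrow(eeg), completed), "qeeg_ledger_error")
  }
  if (nrow(eeg) > 0 &&
      !all(eeg$subject_id %in% screening$subject_id[screening$accept])) {
    qeeg_error("EEG-stage decision for a subject not passing screening",
               "qeeg_ledger_error")
  }
  final_n <- sum(eeg$accept)
  tab <- function(d) {
    r <- d$reason[!d$accept]
    if (length(r) == 0) integer(0) else table(r)
  }
  ledger <- structure(
    list(recruited = recruited,
         excluded_screening = recruited - completed,
         completed_eeg = completed,
         excluded_eeg = completed - final_n,
         final_n = final_n,
         screening_reasons = tab(screening),
         eeg_reasons = tab(eeg)),
    class = "exclusion_ledger"
  )
  stopifnot(
    ledger$recruited - ledger$excluded_screening == ledger$completed_eeg,
    ledger$completed_eeg - ledger$excluded_eeg == ledger$final_n
  )
  ledger
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf(
    "<exclusion_ledger> recruited %d -> screened out %d -> completed EEG %d -> EEG exclusions %d -> final n %d\n",
    x$recruited, x$excluded_screening, x$completed_eeg, x$excluded_eeg,
    x$final_n))
  invisible(x)
}
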