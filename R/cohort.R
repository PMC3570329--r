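#' Find new users of 5-ASA treatment
#'
#' A patient's candidate index event is their earliest 5-ASA fill. The
#' new-user (washout) requirement is that no disqualifying fill occurred in
#' the `washout_days` before the index date and, when eligibility data are
#' supplied, that the washout interval was actually observable (continuous
#' eligibility over `[index - washout_days, index - 1]`); patients with
#' left-truncated history are excluded rather than indexed later.
#'
#' @param dispensing dispensing claims (sorted, as returned by
#'   [read_dispensing_claims()]).
#' @param eligibility optional eligibility periods; when `NULL` the washout
#'   interval is assumed observable for everyone.
#' @param washout_days washout length in days (default 90, i.e. "3 months").
#' @param all_drugs_washout if `TRUE`, any dispensing claim in the washout
#'   interval disqualifies; default `FALSE` checks 5-ASA fills only (which,
#'   for the earliest 5-ASA fill, reduces to the observability requirement).
#' @return data.frame of candidates: `patient_id`, `index_date`,
#'   `index_product`, with attribute `n_asa_users` (patients with any 5-ASA
#'   fill, the denominator for attrition).
#' @export
find_new_users <- function(dispensing, eligibility = NULL, washout_days = 90,
                           all_drugs_washout = FALSE) {
  asa <- dispensing[dispensing$drug_class == "FIVE_ASA", , drop = FALSE]
  asa <- asa[order(asa$patient_id, asa$dispense_date, asa$product), ,
             drop = FALSE]
  first <- asa[!duplicated(asa$patient_id), , drop = FALSE]
  n_asa_users <- nrow(first)
  keep <- rep(TRUE, nrow(first))
  if (all_drugs_washout && nrow(first) > 0) {
    idx_date <- first$dispense_date[match(dispensing$patient_id,
                                          first$patient_id)]
    in_washout <- !is.na(idx_date) &
      dispensing$dispense_date >= idx_date - washout_days &
      dispensing$dispense_date <= idx_date - 1
    bad <- unique(dispensing$patient_id[in_washout])
    keep <- keep & !(first$patient_id %in% bad)
  }
  if (!is.null(eligibility) && nrow(first) > 0) {
    elig_by <- split(eligibility, eligibility$patient_id)
    observable <- vapply(seq_len(nrow(first)), function(i) {
      ep <- elig_by[[first$patient_id[i]]]
      if (is.null(ep)) return(FALSE)
      covers_interval(ep, first$dispense_date[i] - washout_days,
                      first$dispense_date[i] - 1)
    }, logical(1))
    keep <- keep & observable
  }
  out <- data.frame(patient_id = first$patient_id[keep],
                    index_date = first$dispense_date[keep],
                    index_product = first$product[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_asa_users") <- n_asa_users
  out
}

is_crohns_code <- function(icd9_code) {
  grepl("^555($|\\.)", icd9_code)
}

#' Apply cohort exclusions
#'
#' Removes candidates with any Crohn's disease medical claim (ICD-9
#' 555.0-555.9, scanned over the entire claims history) and candidates whose
#' drug-plan eligibility does not continuously cover the 365-day observation
#' window, in that fixed order, and records attrition per rule.
#'
#' @param candidates output of [find_new_users()].
#' @param medical medical claims data.frame.
#' @param eligibility eligibility periods data.frame.
#' @param patients optional demographics (`patient_id`, `sex`, `birth_year`)
#'   used to fill in sex and age at index.
#' @return list with `members` (cohort member data.frame: patient_id,
#'   index_date, index_product, window_start, window_end, sex, age_at_index)
#'   and `attrition` (data.frame of rule, n_removed, n_remaining).
#' @export
apply_exclusions <- function(candidates, medical, eligibility,
                             patients = NULL) {
  att <- data.frame(rule = character(0), n_removed = integer(0),
                    n_remaining = integer(0), stringsAsFactors = FALSE)
  cur <- candidates

  crohns_ids <- unique(medical$patient_id[is_crohns_code(medical$icd9_code)])
  keep <- !(cur$patient_id %in% crohns_ids)
  att <- rbind(att, data.frame(rule = "crohns_diagnosis",
                               n_removed = sum(!keep),
                               n_remaining = sum(keep)))
  cur <- cur[keep, , drop = FALSE]

  elig_by <- split(eligibility, eligibility$patient_id)
  covered <- vapply(seq_len(nrow(cur)), function(i) {
    ep <- elig_by[[cur$patient_id[i]]]
    if (is.null(ep)) return(FALSE)
    covers_interval(ep, cur$index_date[i], cur$index_date[i] + 364)
  }, logical(1))
  att <- rbind(att, data.frame(rule = "coverage_lt_1y",
                               n_removed = sum(!covered),
                               n_remaining = sum(covered)))
  cur <- cur[covered, , drop = FALSE]

  members <- data.frame(patient_id = cur$patient_id,
                        index_date = cur$index_date,
                        index_product = cur$index_product,
                        window_start = cur$index_date,
                        window_end = cur$index_date + 364,
                        sex = rep(NA_character_, nrow(cur)),
                        age_at_index = rep(NA_integer_, nrow(cur)),
                        stringsAsFactors = FALSE)
  if (!is.null(patients) && nrow(members) > 0) {
    j <- match(members$patient_id, patients$patient_id)
    members$sex <- patients$sex[j]
    members$age_at_index <-
      as.integer(format(members$index_date, "%Y")) - patients$birth_year[j]
  }
  rownames(members) <- NULL
  list(members = members, attrition = att)
}

#' Build a new-user cohort from claims
#'
#' Convenience wrapper: [find_new_users()] followed by [apply_exclusions()],
#' with an attrition table that also counts the washout/observability rule.
#'
#' @inheritParams find_new_users
#' @inheritParams apply_exclusions
#' @return list with `members` and `attrition` (rules in application order:
#'   washout, Crohn's diagnosis, insufficient coverage).
#' @export
build_cohort <- function(dispensing, medical, eligibility, patients = NULL,
                         washout_days = 90, all_drugs_washout = FALSE) {
  candidates <- find_new_users(dispensing, eligibility, washout_days,
                               all_drugs_washout)
  n_users <- attr(candidates, "n_asa_users")
  res <- apply_exclusions(candidates, medical, eligibility, patients)
  res$attrition <- rbind(
    data.frame(rule = "washout_or_unobservable_history",
               n_removed = n_users - nrow(candidates),
               n_remaining = nrow(candidates)),
    res$attrition)
  res
}
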