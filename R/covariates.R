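#' Default chronic disease score weights
#'
#' A simplified additive medication-based chronic disease score table in the
#' Von Korff spirit: each medication class observed in a patient's dispensing
#' profile contributes its points once, regardless of how many fills. The
#' shipped weights are a pragmatic default for synthetic data and should be
#' replaced with a locally validated table for real analyses; every
#' correctness guarantee in this package is independent of these particular
#' numbers (tests use explicit toy tables).
#'
#' @return data.frame with columns `cds_class`, `points`; attribute `rules`
#'   is a list of combination rules, each `list(classes =, bonus =)` adding
#'   `bonus` points when all named classes co-occur.
#' @export
default_cds_weights <- function() {
  w <- data.frame(
    cds_class = c("heart_disease", "respiratory_illness", "hypertension",
                  "diabetes", "corticosteroid"),
    points = c(4L, 3L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  attr(w, "rules") <- list()
  w
}

#' Compute a medication-based chronic disease score
#'
#' Sums `points` over the distinct medication classes present in the claims
#' (each class counted once), plus any combination-rule bonuses whose classes
#' all co-occur. Claims with no `cds_class` are ignored unless
#' `strict = TRUE`, in which case an unmapped class-bearing fill is an error.
#'
#' @param claims dispensing claims with a `cds_class` column (`NA` = not a
#'   scored medication).
#' @param weights weight table as in [default_cds_weights()].
#' @param strict error on a `cds_class` absent from the weight table
#'   (default: such classes score 0).
#' @return integer score (>= 0).
#' @export
compute_cds <- function(claims, weights = default_cds_weights(),
                        strict = FALSE) {
  if (any(weights$points < 0)) stop("CDS weights must be >= 0")
  classes <- unique(claims$cds_class[!is.na(claims$cds_class)])
  unknown <- setdiff(classes, weights$cds_class)
  if (strict && length(unknown) > 0) {
    stop("medication class(es) not in the CDS weight table: ",
         paste(unknown, collapse = ", "))
  }
  score <- sum(weights$points[weights$cds_class %in% classes])
  for (rule in attr(weights, "rules")) {
    if (all(rule$classes %in% classes)) score <- score + rule$bonus
  }
  as.integer(score)
}

#' Derive determinant covariates for a cohort
#'
#' Per member: `male`; `age_ge_60` (inclusive at 60); comorbidity flags
#' (`hypertension`, `heart_disease`, `respiratory_illness`, `diabetes`), true
#' iff at least one marker-class fill occurs in the lookback (default: 365
#' days pre-index through the window end); `cds_score` over the same
#' lookback and `cds_high` (score at or above the cut); `prior_steroid`
#' (corticosteroid fill in the 365 days before index) and `current_steroid`
#' (corticosteroid fill inside the observation window).
#'
#' @param members cohort members (need `sex` and `age_at_index`).
#' @param dispensing dispensing claims carrying `drug_class` and, for marker
#'   fills, `comorbidity`/`cds_class` columns per the code map. If the
#'   columns are absent they are derived from `code_map`.
#' @param code_map drug code map used to fill in `comorbidity`/`cds_class`
#'   when missing.
#' @param cds_weights chronic disease score weight table.
#' @param cds_cut score cut for `cds_high` (default 6, a typical cohort
#'   median).
#' @param median_cut if `TRUE`, recompute the cut as the cohort median score.
#' @param lookback_days pre-index lookback for comorbidity flags and the
#'   score (default 365).
#' @return data.frame, one row per member, with the covariates above.
#' @export
build_covariates <- function(members, dispensing,
                             code_map = default_code_map(),
                             cds_weights = default_cds_weights(),
                             cds_cut = 6, median_cut = FALSE,
                             lookback_days = 365) {
  d <- dispensing[dispensing$patient_id %in% members$patient_id, ,
                  drop = FALSE]
  j <- match(d$drug_code, code_map$drug_code)
  if (!"comorbidity" %in% names(d)) d$comorbidity <- code_map$comorbidity[j]
  if (!"cds_class" %in% names(d)) d$cds_class <- code_map$cds_class[j]
  mi <- match(d$patient_id, members$patient_id)
  rel <- as.numeric(d$dispense_date - members$index_date[mi])
  wend <- as.numeric(members$window_end[mi] - members$index_date[mi])
  in_lookback <- rel >= -lookback_days & rel <= wend

  flag_for <- function(sel) {
    ids <- unique(d$patient_id[sel])
    members$patient_id %in% ids
  }
  comorb <- c("hypertension", "heart_disease", "respiratory_illness",
              "diabetes")
  flags <- lapply(comorb, function(cm) {
    flag_for(in_lookback & !is.na(d$comorbidity) & d$comorbidity == cm)
  })
  names(flags) <- comorb

  d_look <- d[in_lookback, , drop = FALSE]
  cds <- vapply(members$patient_id, function(pid) {
    compute_cds(d_look[d_look$patient_id == pid, , drop = FALSE], cds_weights)
  }, integer(1))
  cut <- if (median_cut) stats::median(cds) else cds_cut

  steroid <- d$drug_class == "CORTICOSTEROID"
  out <- data.frame(
    patient_id = members$patient_id,
    male = members$sex == "MALE",
    age_ge_60 = members$age_at_index >= 60,
    hypertension = flags$hypertension,
    heart_disease = flags$heart_disease,
    respiratory_illness = flags$respiratory_illness,
    diabetes = flags$diabetes,
    cds_score = cds,
    cds_high = cds >= cut,
    prior_steroid = flag_for(steroid & rel >= -365 & rel <= -1),
    current_steroid = flag_for(steroid & rel >= 0 & rel <= wend),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Derive covariates for one member
#'
#' Single-member wrapper around [build_covariates()].
#'
#' @param member one-row cohort member data.frame.
#' @inheritParams build_covariates
#' @return one-row covariate data.frame.
#' @export
derive_covariates <- function(member, dispensing,
                              code_map = default_code_map(),
                              cds_weights = default_cds_weights(),
                              cds_cut = 6, lookback_days = 365) {
  stopifnot(nrow(member) == 1)
  build_covariates(member, dispensing, code_map, cds_weights, cds_cut,
                   median_cut = FALSE, lookback_days = lookback_days)
}
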