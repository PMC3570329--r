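#' Compute adherence for a cohort
#'
#' For each member, adherence over the fixed 365-day observation window
#' starting at the index date. The default metric is the medication
#' possession ratio (MPR): the sum of days of supply dispensed over
#' qualifying fills, with each fill truncated at the window end and the total
#' capped at 365, divided by 365. The `"pdc"` method instead counts calendar
#' days actually covered, carrying early-refill supply forward (stockpiling),
#' so overlapping fills are not double counted; it is the standard
#' sensitivity analysis and never exceeds the MPR.
#'
#' Qualifying fills are 5-ASA fills dispensed inside the window; set
#' `index_product_only = TRUE` to restrict to the index product.
#'
#' @param members cohort members (see [build_cohort()]).
#' @param dispensing dispensing claims.
#' @param method `"mpr"` (default) or `"pdc"`.
#' @param index_product_only count only index-product fills.
#' @return data.frame with `patient_id`, `index_product`, `days_supplied`,
#'   `mpr` (the chosen metric on \[0, 1\]), `adherent_80`, `adherent_50`
#'   (inclusive thresholds).
#' @export
compute_adherence <- function(members, dispensing, method = c("mpr", "pdc"),
                              index_product_only = FALSE) {
  method <- match.arg(method)
  f <- qualifying_fills(members, dispensing, index_product_only)
  if (nrow(members) > 0 && !all(members$patient_id %in% f$patient_id)) {
    stop("internal consistency error: cohort member(s) with no qualifying ",
         "5-ASA fill in the observation window: ",
         paste(setdiff(members$patient_id, f$patient_id), collapse = ", "))
  }
  if (method == "mpr") {
    contrib <- pmin(f$days_supply, f$rel_end - f$rel_day + 1)
    total <- tapply(contrib, f$patient_id, sum)
  } else {
    total <- vapply(split(f, f$patient_id), function(ff) {
      pdc_days_covered(ff$rel_day, ff$days_supply, ff$rel_end[1])
    }, numeric(1))
  }
  days <- pmin(365, as.numeric(total[members$patient_id]))
  mpr <- days / 365
  data.frame(patient_id = members$patient_id,
             index_product = members$index_product,
             days_supplied = as.integer(days), mpr = mpr,
             adherent_80 = mpr >= 0.80, adherent_50 = mpr >= 0.50,
             stringsAsFactors = FALSE)
}

# Fills inside each member's window, with fill day and window end expressed
# in days relative to the index date.
qualifying_fills <- function(members, dispensing, index_product_only) {
  f <- dispensing[dispensing$drug_class == "FIVE_ASA" &
                    dispensing$patient_id %in% members$patient_id, ,
                  drop = FALSE]
  j <- match(f$patient_id, members$patient_id)
  f$rel_day <- as.numeric(f$dispense_date - members$index_date[j])
  f$rel_end <- as.numeric(members$window_end[j] - members$index_date[j])
  keep <- f$rel_day >= 0 & f$rel_day <= f$rel_end
  if (index_product_only) keep <- keep & f$product == members$index_product[j]
  f[keep, , drop = FALSE]
}

# Days covered in [0, rel_end] with carry-forward stockpiling: a fill whose
# predecessor's supply has not run out starts covering the day after the
# accumulated supply ends. Closed form over fills sorted by day.
pdc_days_covered <- function(rel_day, days_supply, rel_end) {
  o <- order(rel_day)
  rel_day <- rel_day[o]; days_supply <- days_supply[o]
  covered <- 0
  run_end <- -1
  for (k in seq_along(rel_day)) {
    start <- max(rel_day[k], run_end + 1)
    run_end <- start + days_supply[k] - 1
    covered <- covered + max(0, min(run_end, rel_end) - min(start, rel_end + 1) + 1)
  }
  covered
}

#' Compute MPR for one cohort member
#'
#' Single-member wrapper around [compute_adherence()].
#'
#' @param member one-row cohort member data.frame.
#' @param dispensing dispensing claims for (at least) that patient.
#' @inheritParams compute_adherence
#' @return one-row adherence result data.frame.
#' @export
compute_mpr <- function(member, dispensing, method = c("mpr", "pdc"),
                        index_product_only = FALSE) {
  stopifnot(nrow(member) == 1)
  compute_adherence(member, dispensing, method, index_product_only)
}

#' Summarize adherence by group
#'
#' Counts and percentages of members meeting the 80% and 50% MPR thresholds,
#' per level of a grouping partition. Percentages are printed-table style:
#' one decimal, halves rounded up.
#'
#' @param results adherence results from [compute_adherence()].
#' @param by grouping: `NULL` for a single overall group, the name of a
#'   column in `results`, or a vector with one label per member (no `NA`s).
#' @return data.frame with `group`, `n`, `n_adherent_80`, `pct_80`,
#'   `n_adherent_50`, `pct_50`.
#' @export
adherence_summary <- function(results, by = NULL) {
  g <- resolve_grouping(results, by)
  agg <- function(flag) as.vector(tapply(flag, g, sum))
  n <- as.vector(table(g))
  out <- data.frame(group = levels(g), n = n,
                    n_adherent_80 = agg(results$adherent_80),
                    pct_80 = round_half_up(100 * agg(results$adherent_80) / n),
                    n_adherent_50 = agg(results$adherent_50),
                    pct_50 = round_half_up(100 * agg(results$adherent_50) / n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

resolve_grouping <- function(df, by) {
  g <- if (is.null(by)) {
    rep("overall", nrow(df))
  } else if (is.character(by) && length(by) == 1 && by %in% names(df)) {
    df[[by]]
  } else {
    by
  }
  check_partition(g, nrow(df))
  factor(g)
}
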