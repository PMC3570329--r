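#' Demographics table (study-population shape)
#'
#' Age-band counts and percentages, mean (SD) age, male/female split, and
#' comorbidity rates for a cohort. Percentages at one decimal, halves up.
#'
#' @param members cohort members (with `sex`, `age_at_index`).
#' @param covariates covariate data.frame from [build_covariates()].
#' @return data.frame with `item`, `n`, `pct` (value column for mean age).
#' @export
table1_report <- function(members, covariates) {
  n <- nrow(members)
  bands <- cut(members$age_at_index, c(-Inf, 19, 39, 59, 79, Inf),
               labels = c("<20", "20-39", "40-59", "60-79", "80+"))
  rows <- data.frame(item = paste0("age_", levels(bands)),
                     n = as.vector(table(bands)), stringsAsFactors = FALSE)
  rows <- rbind(rows,
                data.frame(item = c("male", "female"),
                           n = c(sum(members$sex == "MALE"),
                                 sum(members$sex == "FEMALE"))))
  for (cm in c("hypertension", "heart_disease", "respiratory_illness",
               "diabetes")) {
    rows <- rbind(rows, data.frame(item = cm, n = sum(covariates[[cm]])))
  }
  rows$pct <- round_half_up(100 * rows$n / n)
  rows <- rbind(rows, data.frame(
    item = "mean_age_sd",
    n = round_half_up(mean(members$age_at_index)),
    pct = round_half_up(stats::sd(members$age_at_index))))
  rownames(rows) <- NULL
  rows
}

#' Prescription characteristics table (per-product shape)
#'
#' Per index product: users, number of 5-ASA scripts of that product
#' dispensed to its index users inside their observation windows, scripts per
#' patient (one decimal), mean (SD) quantity and duration per script, and
#' median duration. User counts sum to the cohort size since each member has
#' exactly one index product.
#'
#' @param members cohort members.
#' @param dispensing dispensing claims.
#' @return data.frame, one row per product present in the cohort.
#' @export
table2_report <- function(members, dispensing) {
  f <- qualifying_fills(members, dispensing, index_product_only = TRUE)
  rows <- lapply(sort(unique(members$index_product)), function(p) {
    users <- sum(members$index_product == p)
    fp <- f[f$product == p, , drop = FALSE]
    data.frame(product = p, users = users, n_scripts = nrow(fp),
               scripts_per_patient = round_half_up(nrow(fp) / users),
               mean_quantity = round_half_up(mean(fp$quantity)),
               sd_quantity = round_half_up(stats::sd(fp$quantity)),
               mean_duration = round_half_up(mean(fp$days_supply)),
               sd_duration = round_half_up(stats::sd(fp$days_supply)),
               median_duration = stats::median(fp$days_supply),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square comparison of group proportions
#'
#' Chi-square test (no continuity correction) on a k x 2 table of successes
#' and failures across groups; a warning is logged when any expected cell is
#' below 1.
#'
#' @param successes integer vector of successes per group.
#' @param totals integer vector of group sizes (> 0).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_compare <- function(successes, totals) {
  stopifnot(length(successes) == length(totals), length(totals) >= 2,
            all(totals > 0), all(successes >= 0), all(successes <= totals))
  tab <- cbind(successes, totals - successes)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("chi-square approximation unreliable: expected cell count < 1")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Run the full claims analysis pipeline
#'
#' Reads the claim files, builds the cohort, computes adherence and
#' persistence, derives covariates, fits the determinant models, and writes
#' every report to `out_dir`: `cohort.csv`, `attrition.csv`,
#' `adherence.csv`, `episodes.csv`, `km_overall.csv` and
#' `km_<product>.csv` per index product (columns time, n_risk, n_event,
#' survival), `adherence_summary.csv`, `persistence_summary.csv`,
#' `table1.csv`, `table2.csv`, `determinants.csv`, and `manifest.yaml`
#' echoing every option. Identical inputs and config give byte-identical
#' outputs.
#'
#' @param dispensing_path,medical_path,eligibility_path input claim files.
#' @param out_dir output directory (created if needed).
#' @param patients_path optional demographics file.
#' @param code_map_path optional YAML drug code map (default map otherwise).
#' @param sep field delimiter of the inputs.
#' @param on_bad malformed-row policy for the readers.
#' @param washout_days,all_drugs_washout cohort options.
#' @param adherence_method,index_product_only adherence options.
#' @param grace_days,require_abandonment persistence options.
#' @param cds_cut,median_cut covariate options.
#' @param alpha stepwise removal threshold.
#' @param seed seed recorded in the manifest and used for any permutation
#'   procedure.
#' @return invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(dispensing_path, medical_path, eligibility_path,
                         out_dir, patients_path = NULL, code_map_path = NULL,
                         sep = ",", on_bad = "error", washout_days = 90,
                         all_drugs_washout = FALSE, adherence_method = "mpr",
                         index_product_only = FALSE, grace_days = 60,
                         require_abandonment = FALSE, cds_cut = 6,
                         median_cut = FALSE, alpha = 0.05, seed = 1L) {
  opts <- list(dispensing = dispensing_path, medical = medical_path,
               eligibility = eligibility_path, patients = patients_path,
               code_map = code_map_path, sep = sep, on_bad = on_bad,
               washout_days = washout_days,
               all_drugs_washout = all_drugs_washout,
               adherence_method = adherence_method,
               index_product_only = index_product_only,
               grace_days = grace_days,
               require_abandonment = require_abandonment,
               cds_cut = cds_cut, median_cut = median_cut, alpha = alpha,
               seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  code_map <- if (is.null(code_map_path)) default_code_map() else
    read_code_map(code_map_path)
  dispensing <- stage("read_dispensing",
                      read_dispensing_claims(dispensing_path, code_map, sep,
                                             on_bad))
  medical <- stage("read_medical", read_medical_claims(medical_path, sep,
                                                       on_bad))
  eligibility <- stage("read_eligibility", read_eligibility(eligibility_path,
                                                            sep, on_bad))
  patients <- if (is.null(patients_path)) NULL else
    stage("read_patients", read_patients(patients_path, sep))

  message(sprintf("stage cohort: %d dispensing rows in", nrow(dispensing)))
  cohort <- stage("cohort", build_cohort(dispensing, medical, eligibility,
                                         patients, washout_days,
                                         all_drugs_washout))
  members <- cohort$members
  message(sprintf("stage cohort: %d members out", nrow(members)))
  adherence <- stage("adherence",
                     compute_adherence(members, dispensing, adherence_method,
                                       index_product_only))
  episodes <- stage("persistence",
                    build_episodes(members, dispensing, eligibility,
                                   grace_days, require_abandonment))
  covariates <- stage("covariates",
                      build_covariates(members, dispensing, code_map,
                                       cds_cut = cds_cut,
                                       median_cut = median_cut))
  fits <- stage("determinants",
                fit_determinants(covariates, adherence, episodes,
                                 alpha = alpha))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(members, file.path(out_dir, "cohort.csv"), sep)
  write_delim_file(cohort$attrition, file.path(out_dir, "attrition.csv"), sep)
  write_delim_file(adherence, file.path(out_dir, "adherence.csv"), sep)
  write_delim_file(episodes, file.path(out_dir, "episodes.csv"), sep)
  write_delim_file(km_estimate(episodes), file.path(out_dir,
                                                    "km_overall.csv"), sep)
  for (p in sort(unique(episodes$index_product))) {
    write_delim_file(km_estimate(episodes[episodes$index_product == p, ]),
                     file.path(out_dir, paste0("km_", p, ".csv")), sep)
  }
  write_delim_file(adherence_summary(adherence, "index_product"),
                   file.path(out_dir, "adherence_summary.csv"), sep)
  write_delim_file(persistence_summary(episodes, "index_product"),
                   file.path(out_dir, "persistence_summary.csv"), sep)
  write_delim_file(table1_report(members, covariates),
                   file.path(out_dir, "table1.csv"), sep)
  write_delim_file(table2_report(members, dispensing),
                   file.path(out_dir, "table2.csv"), sep)
  write_delim_file(determinants_table(fits),
                   file.path(out_dir, "determinants.csv"), sep)
  yaml::write_yaml(opts, file.path(out_dir, "manifest.yaml"))
  invisible(list(members = members, attrition = cohort$attrition,
                 adherence = adherence, episodes = episodes,
                 covariates = covariates, determinants = fits))
}
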