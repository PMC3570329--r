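# Independent brute-force oracles used to validate the implementation.
# These deliberately use literal day-by-day simulation, not the package's
# closed-form algorithms.

# Days covered in [0, rel_end] by a literal daily scan with carry-forward
# stockpiling: each day, fills dispensed that day add to the supply pool,
# and one unit of pool covers the day.
oracle_days_covered <- function(rel_day, days_supply, rel_end = 364) {
  pool <- 0
  covered <- 0
  for (d in 0:rel_end) {
    pool <- pool + sum(days_supply[rel_day == d])
    if (pool > 0) {
      covered <- covered + 1
      pool <- pool - 1
    }
  }
  covered
}

# Classic-MPR oracle: dispensed supply summed per fill, each fill truncated
# at the window end, total capped at 365.
oracle_mpr_days <- function(rel_day, days_supply, rel_end = 364) {
  min(365, sum(pmin(days_supply, rel_end - rel_day + 1)))
}

# Exhaustive day-scan episode classifier under the default policy
# (any 5-ASA fill interrupts a gap; a different product doing so, inside the
# window, is a switch). Days are index-relative; fills must include the index
# fill at day 0.
oracle_episode <- function(rel_day, product, days_supply, index_product,
                           data_end = 364, grace = 60) {
  horizon <- 364 + grace - 1
  keep <- rel_day >= 0 & rel_day <= horizon
  rel_day <- rel_day[keep]
  product <- product[keep]
  days_supply <- days_supply[keep]
  pool <- 0
  runout <- -1 # last day covered by index-product supply so far
  for (d in 0:horizon) {
    idx_fill <- rel_day == d & product == index_product
    other_fill <- any(rel_day == d & product != index_product & d <= 364)
    if ((any(idx_fill) || other_fill) && d > runout + grace) {
      return(list(type = "GAP_DISCONTINUATION", time = runout + 1))
    }
    pool <- pool + sum(days_supply[idx_fill])
    if (other_fill) {
      return(list(type = "SWITCH", time = max(1, d)))
    }
    if (pool > 0) {
      runout <- d
      pool <- pool - 1
    }
  }
  if (runout < 364 && runout + grace <= data_end) {
    return(list(type = "GAP_DISCONTINUATION", time = runout + 1))
  }
  list(type = "CENSORED", time = 365)
}

# Build a one-member cohort and its dispensing claims from index-relative
# fill days, for unit tests that construct patterns by hand.
toy_member <- function(pid = "X1", index = as.Date("2006-01-15"),
                       product = "ASACOL_OR_GENERIC") {
  data.frame(patient_id = pid, index_date = index, index_product = product,
             window_start = index, window_end = index + 364,
             sex = "MALE", age_at_index = 50L, stringsAsFactors = FALSE)
}

toy_fills <- function(member, rel_day, days_supply,
                      product = member$index_product) {
  n <- length(rel_day)
  data.frame(patient_id = member$patient_id,
             dispense_date = member$index_date + rel_day,
             drug_code = "ASA-400",
             product = rep_len(product, n),
             drug_class = "FIVE_ASA",
             quantity = 100L,
             days_supply = as.integer(rep_len(days_supply, n)),
             stringsAsFactors = FALSE)
}

# Small simulated pipeline bundle shared by several test files.
sim_pipeline <- function(n = 400, seed = 7, ...) {
  cfg <- sim_config(n_patients = n, seed = seed, ...)
  pop <- simulate_population(cfg)
  cl <- simulate_claims(pop, cfg)
  cohort <- build_cohort(cl$dispensing, cl$medical, pop$eligibility,
                         pop$patients)
  list(cfg = cfg, pop = pop, claims = cl, members = cohort$members,
       attrition = cohort$attrition,
       eligibility = pop$eligibility, dispensing = cl$dispensing)
}
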