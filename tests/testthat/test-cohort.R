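make_disp <- function(pid, dates, product = "SALOFALK",
                      drug_class = "FIVE_ASA") {
  data.frame(patient_id = pid, dispense_date = as.Date(dates),
             drug_code = "SAL-500", product = product,
             drug_class = drug_class, quantity = 90L, days_supply = 30L,
             stringsAsFactors = FALSE)
}

make_elig <- function(pid, start, end) {
  data.frame(patient_id = pid, start_date = as.Date(start),
             end_date = as.Date(end), stringsAsFactors = FALSE)
}

test_that("a single fill with observable history indexes at that fill", {
  disp <- make_disp("P1", "2006-06-01")
  elig <- make_elig("P1", "2005-01-01", "2008-01-01")
  cand <- find_new_users(disp, elig)
  expect_equal(cand$index_date, as.Date("2006-06-01"))
  expect_equal(cand$index_product, "SALOFALK")
})

test_that("the index event is unique: later fills are refills", {
  disp <- make_disp("P1", c("2006-01-01", "2006-03-02"))
  elig <- make_elig("P1", "2005-06-01", "2008-01-01")
  cand <- find_new_users(disp, elig)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$index_date, as.Date("2006-01-01"))
})

test_that("washout qualification matches a brute-force day-window scan", {
  # five constructed patients; only those with >= 90 days of observable
  # eligibility before their first 5-ASA fill qualify
  disp <- rbind(make_disp("A", "2006-06-01"),
                make_disp("B", "2006-02-01"),
                make_disp("C", "2006-06-01"),
                make_disp("D", "2006-01-20"),
                make_disp("E", "2006-06-01"))
  elig <- rbind(make_elig("A", "2005-01-01", "2008-01-01"),
                make_elig("B", "2006-01-01", "2008-01-01"),  # 31 days history
                make_elig("C", "2006-03-03", "2008-01-01"),  # exactly 90 days
                make_elig("D", "2006-01-01", "2008-01-01"),  # 19 days history
                make_elig("E", "2006-03-04", "2008-01-01"))  # 89 days
  cand <- find_new_users(disp, elig)
  # brute force: check every day in [index-90, index-1] is covered
  expected <- vapply(c("A", "B", "C", "D", "E"), function(p) {
    idx <- min(disp$dispense_date[disp$patient_id == p])
    e <- elig[elig$patient_id == p, ]
    all(vapply(1:90, function(k) {
      any(e$start_date <= idx - k & e$end_date >= idx - k)
    }, logical(1)))
  }, logical(1))
  expect_setequal(cand$patient_id, names(expected)[expected])
  expect_equal(sort(cand$patient_id), c("A", "C"))
})

test_that("all-drugs washout also disqualifies on non-5-ASA claims", {
  disp <- rbind(make_disp("P1", "2006-06-01"),
                make_disp("P1", "2006-05-01", product = "OTHER",
                          drug_class = "CORTICOSTEROID"))
  elig <- make_elig("P1", "2005-01-01", "2008-01-01")
  expect_equal(nrow(find_new_users(disp, elig)), 1)
  expect_equal(nrow(find_new_users(disp, elig, all_drugs_washout = TRUE)), 0)
})

test_that("Crohn's 555.x claims exclude, neighbouring codes do not", {
  cand <- data.frame(patient_id = c("P1", "P2", "P3"),
                     index_date = as.Date("2006-01-01"),
                     index_product = "PENTASA", stringsAsFactors = FALSE)
  medical <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    service_date = as.Date("2007-06-01"),
    icd9_code = c("555.9", "556.9", "555"),
    stringsAsFactors = FALSE)
  elig <- make_elig(c("P1", "P2", "P3"), "2005-01-01", "2008-01-01")
  res <- apply_exclusions(cand, medical, elig)
  expect_equal(res$members$patient_id, "P2")
  expect_equal(res$attrition$n_removed[res$attrition$rule ==
                                         "crohns_diagnosis"], 2)
})

test_that("insufficient post-index coverage removes candidates and is logged", {
  cand <- data.frame(patient_id = sprintf("P%02d", 1:10),
                     index_date = as.Date("2006-01-01"),
                     index_product = "SALOFALK", stringsAsFactors = FALSE)
  end <- rep(as.Date("2008-01-01"), 10)
  end[c(2, 5, 9)] <- as.Date("2006-01-01") + 200
  elig <- make_elig(cand$patient_id, "2005-01-01", end)
  medical <- data.frame(patient_id = character(0),
                        service_date = as.Date(character(0)),
                        icd9_code = character(0), stringsAsFactors = FALSE)
  res <- apply_exclusions(cand, medical, elig)
  expect_equal(nrow(res$members), 7)
  expect_equal(res$attrition$n_removed[res$attrition$rule ==
                                         "coverage_lt_1y"], 3)
})

test_that("split eligibility periods count as continuous when adjacent", {
  cand <- data.frame(patient_id = "P1", index_date = as.Date("2006-01-01"),
                     index_product = "SALOFALK", stringsAsFactors = FALSE)
  medical <- data.frame(patient_id = character(0),
                        service_date = as.Date(character(0)),
                        icd9_code = character(0), stringsAsFactors = FALSE)
  adjacent <- make_elig(c("P1", "P1"),
                        c("2005-01-01", "2006-07-02"),
                        c("2006-07-01", "2008-01-01"))
  gapped <- make_elig(c("P1", "P1"),
                      c("2005-01-01", "2006-07-10"),
                      c("2006-07-01", "2008-01-01"))
  expect_equal(nrow(apply_exclusions(cand, medical, adjacent)$members), 1)
  expect_equal(nrow(apply_exclusions(cand, medical, gapped)$members), 0)
})

test_that("cohort is invariant to input row order and attrition sums add up", {
  s <- sim_pipeline(n = 250, seed = 17, crohns_prob = 0.1,
                    short_history_prob = 0.1, short_coverage_prob = 0.1)
  set.seed(1)
  shuffled <- s$dispensing[sample(nrow(s$dispensing)), ]
  cohort2 <- build_cohort(shuffled, s$claims$medical, s$eligibility,
                          s$pop$patients)
  expect_equal(sort(cohort2$members$patient_id), sort(s$members$patient_id))
  att <- s$attrition
  n_candidates <- att$n_remaining[att$rule == "washout_or_unobservable_history"]
  expect_equal(sum(att$n_removed[att$rule != "washout_or_unobservable_history"]),
               n_candidates - nrow(s$members))
  # every member satisfies the membership invariants
  tr <- s$pop$truth
  m <- s$members
  expect_true(all(!tr$crohns[match(m$patient_id, tr$patient_id)]))
  expect_equal(as.numeric(m$window_end - m$index_date), rep(364, nrow(m)))
  expect_true(all(m$age_at_index >= 0))
})
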