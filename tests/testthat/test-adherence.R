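test_that("a single 365-day fill at index gives MPR 1 and adherence", {
  m <- toy_member()
  d <- toy_fills(m, 0, 365)
  res <- compute_mpr(m, d)
  expect_equal(res$mpr, 1.0)
  expect_true(res$adherent_80)
  expect_true(res$adherent_50)
})

test_that("the 80% threshold is inclusive: 292/365 days is adherent", {
  m <- toy_member()
  d <- toy_fills(m, c(0, 100), c(200, 92))
  res <- compute_mpr(m, d)
  expect_equal(res$days_supplied, 292L)
  expect_equal(res$mpr, 292 / 365)
  expect_equal(res$mpr, 0.8)
  expect_true(res$adherent_80)
})

test_that("supply past the window end is truncated and MPR capped at 1", {
  m <- toy_member()
  d <- toy_fills(m, c(0, 350), c(300, 60))  # second fill: only 15 days fit
  res <- compute_mpr(m, d)
  expect_equal(res$days_supplied, 315L)
  d2 <- toy_fills(m, c(0, 100, 200), c(300, 300, 300))
  expect_equal(compute_mpr(m, d2)$mpr, 1.0)
})

test_that("fills outside the window never count", {
  m <- toy_member()
  d <- toy_fills(m, c(-10, 0, 364, 365), 30)
  res <- compute_mpr(m, d)
  expect_equal(res$days_supplied, 30L + 1L)  # index fill + 1 day of day-364 fill
})

test_that("13 overlapping 30-day fills match the day-scan oracle under both policies", {
  m <- toy_member()
  rel <- seq(0, by = 28, length.out = 13)
  d <- toy_fills(m, rel, 30)
  mpr <- compute_mpr(m, d, method = "mpr")
  pdc <- compute_mpr(m, d, method = "pdc")
  expect_equal(mpr$days_supplied, oracle_mpr_days(rel, rep(30, 13)))
  expect_equal(pdc$days_supplied, oracle_days_covered(rel, rep(30, 13)))
})

test_that("MPR and PDC match their oracles on random fill patterns", {
  set.seed(202)
  for (i in 1:60) {
    m <- toy_member()
    n <- sample(1:12, 1)
    rel <- sort(c(0, sample(1:420, n - 1)))[seq_len(n)]
    ds <- sample(c(7, 14, 30, 60, 90), n, replace = TRUE)
    d <- toy_fills(m, rel, ds)
    in_win <- rel <= 364
    mpr <- compute_mpr(m, d, method = "mpr")
    pdc <- compute_mpr(m, d, method = "pdc")
    expect_equal(mpr$days_supplied,
                 oracle_mpr_days(rel[in_win], ds[in_win]))
    expect_equal(pdc$days_supplied,
                 oracle_days_covered(rel[in_win], ds[in_win]))
    # sum-of-days MPR dominates day-coverage; equal when fills never overlap
    expect_gte(mpr$days_supplied, pdc$days_supplied)
  }
})

test_that("non-overlapping fills give identical MPR and PDC", {
  m <- toy_member()
  d <- toy_fills(m, c(0, 40, 90), 30)
  expect_equal(compute_mpr(m, d, "mpr")$days_supplied,
               compute_mpr(m, d, "pdc")$days_supplied)
})

test_that("index-product-only restriction drops other products' fills", {
  m <- toy_member(product = "PENTASA")
  d <- rbind(toy_fills(m, 0, 30, "PENTASA"),
             toy_fills(m, 40, 30, "SALOFALK"))
  expect_equal(compute_mpr(m, d)$days_supplied, 60L)
  expect_equal(compute_mpr(m, d, index_product_only = TRUE)$days_supplied, 30L)
})

test_that("a member with no qualifying fill raises a consistency error", {
  m <- toy_member()
  d <- toy_fills(m, -30, 30)
  expect_error(compute_mpr(m, d), "consistency")
})

test_that("adherence summary reproduces printed sex-row arithmetic", {
  # 222 of 729 adherent males, 243 of 952 adherent females
  res <- data.frame(
    patient_id = sprintf("P%04d", 1:1681),
    index_product = "SALOFALK",
    days_supplied = 300L, mpr = 0.82,
    adherent_80 = c(rep(TRUE, 222), rep(FALSE, 507),
                    rep(TRUE, 243), rep(FALSE, 709)),
    adherent_50 = TRUE,
    stringsAsFactors = FALSE)
  sex <- c(rep("MALE", 729), rep("FEMALE", 952))
  by_sex <- adherence_summary(res, sex)
  expect_equal(by_sex$pct_80[by_sex$group == "MALE"], 30.5)
  expect_equal(by_sex$pct_80[by_sex$group == "FEMALE"], 25.5)
  overall <- adherence_summary(res)
  expect_equal(overall$n_adherent_80, 465)
  expect_equal(overall$pct_80, 27.7)
  # single-group partition equals the overall row
  one <- adherence_summary(res, rep("all", 1681))
  expect_equal(one$n_adherent_80, overall$n_adherent_80)
  expect_equal(one$pct_80, overall$pct_80)
})

test_that("group counts sum to overall counts for any partition", {
  s <- sim_pipeline(n = 300, seed = 23)
  res <- compute_adherence(s$members, s$dispensing)
  for (by in list(s$members$index_product,
                  s$members$sex,
                  sample(letters[1:5], nrow(res), replace = TRUE))) {
    g <- adherence_summary(res, by)
    expect_equal(sum(g$n), nrow(res))
    expect_equal(sum(g$n_adherent_80), sum(res$adherent_80))
    expect_equal(sum(g$n_adherent_50), sum(res$adherent_50))
  }
  expect_true(all(res$adherent_50[res$adherent_80]))
  expect_true(all(res$mpr > 0 & res$mpr <= 1))
})

test_that("an incomplete partition is rejected", {
  res <- data.frame(patient_id = c("a", "b"), index_product = "PENTASA",
                    days_supplied = 100L, mpr = 0.3,
                    adherent_80 = FALSE, adherent_50 = FALSE)
  expect_error(adherence_summary(res, c("g1", NA)), "partition|group")
  expect_error(adherence_summary(res, "g1"), "partition|group")
})
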