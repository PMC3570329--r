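test_that("a gapless monthly stream is censored and persistent", {
  m <- toy_member()
  d <- toy_fills(m, seq(0, 330, by = 30), 30)
  ep <- build_episode(m, d)
  expect_equal(ep$event_type, "CENSORED")
  expect_equal(ep$event_time_days, 365L)
  expect_true(ep$persistent_at_365)
})

test_that("a 60-day silent period after runout is a gap discontinuation", {
  m <- toy_member()
  d <- toy_fills(m, c(0, 45), 30)  # carry-forward runout at day 74
  ep <- build_episode(m, d)
  expect_equal(ep$event_type, "GAP_DISCONTINUATION")
  expect_equal(ep$event_time_days, 75L)
  expect_false(ep$persistent_at_365)
})

test_that("a refill on the last grace day keeps the episode alive", {
  m <- toy_member()
  # runout day 29; grace window is days 30..89: fill on day 89 closes it,
  # fill on day 90 does not
  alive <- build_episode(m, toy_fills(m, c(0, 89, 120, 150, 180, 210, 240,
                                           270, 300, 330), 30))
  expect_equal(alive$event_type, "CENSORED")
  dead <- build_episode(m, toy_fills(m, c(0, 90), 30))
  expect_equal(dead$event_type, "GAP_DISCONTINUATION")
  expect_equal(dead$event_time_days, 30L)
})

test_that("a different-product fill is a switch at that fill's day", {
  m <- toy_member(product = "ASACOL_OR_GENERIC")
  d <- rbind(toy_fills(m, c(0, 30, 60), 30),
             toy_fills(m, 90, 30, "MEZAVANT"))
  ep <- build_episode(m, d)
  expect_equal(ep$event_type, "SWITCH")
  expect_equal(ep$event_time_days, 90L)
  expect_false(ep$persistent_at_365)
})

test_that("a completed gap takes precedence over a later switch fill", {
  m <- toy_member(product = "ASACOL_OR_GENERIC")
  # runout day 29; the other-product fill lands on day 90, one day after the
  # grace window closed
  d <- rbind(toy_fills(m, 0, 30), toy_fills(m, 90, 30, "MEZAVANT"))
  ep <- build_episode(m, d)
  expect_equal(ep$event_type, "GAP_DISCONTINUATION")
  expect_equal(ep$event_time_days, 30L)
})

test_that("require_abandonment keeps episodes with continuing index fills", {
  m <- toy_member(product = "ASACOL_OR_GENERIC")
  d <- rbind(toy_fills(m, seq(0, 330, 30), 30),
             toy_fills(m, 45, 30, "MEZAVANT"))
  expect_equal(build_episode(m, d)$event_type, "SWITCH")
  ep <- build_episode(m, d, require_abandonment = TRUE)
  expect_equal(ep$event_type, "CENSORED")
})

test_that("a late runout is censored without observable silent period, discontinued with one", {
  m <- toy_member()
  d <- toy_fills(m, seq(0, 300, by = 30), 30)  # runout day 329
  # default data_end = window end: days 330..389 not observable -> censored
  expect_equal(build_episode(m, d)$event_type, "CENSORED")
  # eligibility through day 424 makes the silent period observable
  elig <- data.frame(patient_id = m$patient_id,
                     start_date = m$index_date - 365,
                     end_date = m$index_date + 424, stringsAsFactors = FALSE)
  ep <- build_episodes(m, d, elig)
  expect_equal(ep$event_type, "GAP_DISCONTINUATION")
  expect_equal(ep$event_time_days, 330L)
})

test_that("episode classification matches the exhaustive day-scan oracle", {
  set.seed(404)
  for (i in 1:80) {
    prod <- sample(asa_products(), 1)
    m <- toy_member(product = prod)
    n <- sample(1:14, 1)
    rel <- sort(c(0, sample(1:420, n - 1)))[seq_len(n)]
    ds <- sample(c(15, 30, 45), n, replace = TRUE)
    other <- c(FALSE, runif(n - 1) < 0.15)[seq_len(n)]
    products <- ifelse(other, sample(setdiff(asa_products(), prod), n,
                                     replace = TRUE), prod)
    d <- toy_fills(m, rel, ds, products)
    for (data_end in c(364, 424)) {
      got <- if (data_end == 364) build_episode(m, d) else
        build_episode(m, d, data_end = m$index_date + 424)
      want <- oracle_episode(rel, products, ds, prod, data_end = data_end)
      expect_equal(got$event_type, want$type,
                   label = sprintf("case %d type (data_end %d)", i, data_end))
      expect_equal(got$event_time_days, min(365L, as.integer(want$time)),
                   label = sprintf("case %d time", i))
    }
  }
})

test_that("gap and switch are mutually exclusive classifications", {
  s <- sim_pipeline(n = 300, seed = 31)
  ep <- build_episodes(s$members, s$dispensing, s$eligibility)
  expect_true(all(ep$event_type %in%
                    c("GAP_DISCONTINUATION", "SWITCH", "CENSORED")))
  expect_equal(ep$persistent_at_365, ep$event_type == "CENSORED")
  expect_true(all(ep$event_time_days >= 1 & ep$event_time_days <= 365))
  expect_true(all(ep$event_time_days[ep$event_type == "CENSORED"] == 365))
})

test_that("KM with no events is identically 1", {
  ep <- data.frame(patient_id = letters[1:4], index_product = "PENTASA",
                   event_type = "CENSORED", event_time_days = 365L,
                   persistent_at_365 = TRUE, stringsAsFactors = FALSE)
  curve <- km_estimate(ep)
  expect_true(all(curve$survival == 1))
  expect_equal(km_survival_at(curve, 365), 1)
})

test_that("KM matches the hand product-limit value on a 4-episode fixture", {
  ep <- data.frame(patient_id = letters[1:4], index_product = "PENTASA",
                   event_type = c("GAP_DISCONTINUATION", "SWITCH",
                                  "CENSORED", "CENSORED"),
                   event_time_days = c(10L, 20L, 365L, 365L),
                   persistent_at_365 = c(FALSE, FALSE, TRUE, TRUE),
                   stringsAsFactors = FALSE)
  curve <- km_estimate(ep)
  expect_equal(km_survival_at(curve, 10), 3 / 4)
  expect_equal(km_survival_at(curve, 20), (3 / 4) * (2 / 3))
  expect_equal(km_survival_at(curve, 364), 0.5)
})

test_that("KM at 365 equals the empirical persistent proportion", {
  s <- sim_pipeline(n = 350, seed = 37)
  ep <- build_episodes(s$members, s$dispensing, s$eligibility)
  expect_equal(km_survival_at(km_estimate(ep), 365),
               mean(ep$persistent_at_365))
})

test_that("log-rank on two identical groups is 0 with p 1", {
  ep <- data.frame(patient_id = sprintf("p%d", 1:8),
                   index_product = "PENTASA",
                   event_type = rep(c("GAP_DISCONTINUATION", "CENSORED"), 4),
                   event_time_days = rep(c(50L, 365L), 4),
                   persistent_at_365 = rep(c(FALSE, TRUE), 4),
                   stringsAsFactors = FALSE)
  res <- logrank_compare(ep, rep(c("A", "A", "B", "B"), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("log-rank equals the hand O-E/V value on a 6-episode fixture", {
  ep <- data.frame(patient_id = sprintf("p%d", 1:6),
                   index_product = "PENTASA",
                   event_type = c(rep("GAP_DISCONTINUATION", 5), "CENSORED"),
                   event_time_days = c(10L, 20L, 30L, 100L, 200L, 365L),
                   persistent_at_365 = c(rep(FALSE, 5), TRUE),
                   stringsAsFactors = FALSE)
  grp <- c("A", "A", "A", "B", "B", "B")
  res <- logrank_compare(ep, grp)
  # hand computation: O_A = 3, E_A = 3/6 + 2/5 + 1/4 = 1.15,
  # V = 45/180 + 24/100 + 9/48 = 0.6775, chi2 = (3 - 1.15)^2 / 0.6775
  expect_equal(res$statistic, 5.0516605, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0246023, tolerance = 1e-4)
  # invariant under group relabeling
  res2 <- logrank_compare(ep, c("B", "B", "B", "A", "A", "A"))
  expect_equal(res2$statistic, res$statistic)
})

test_that("log-rank rejects degenerate groupings", {
  ep <- data.frame(patient_id = "p1", index_product = "PENTASA",
                   event_type = "CENSORED", event_time_days = 365L,
                   persistent_at_365 = TRUE, stringsAsFactors = FALSE)
  expect_error(logrank_compare(ep, "A"), "2 non-empty groups")
})

test_that("persistence summary reproduces printed sex-row arithmetic", {
  ep <- data.frame(
    patient_id = sprintf("P%04d", 1:1681),
    index_product = "SALOFALK",
    event_type = "CENSORED", event_time_days = 365L,
    persistent_at_365 = c(rep(TRUE, 365), rep(FALSE, 364),
                          rep(TRUE, 400), rep(FALSE, 552)),
    stringsAsFactors = FALSE)
  sex <- c(rep("MALE", 729), rep("FEMALE", 952))
  by_sex <- persistence_summary(ep, sex)
  expect_equal(by_sex$pct[by_sex$group == "MALE"], 50.1)
  expect_equal(by_sex$pct[by_sex$group == "FEMALE"], 42.0)
  overall <- persistence_summary(ep)
  expect_equal(overall$n_persistent_365, 765)
  expect_equal(overall$pct, 45.5)
})
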