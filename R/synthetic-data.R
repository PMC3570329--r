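#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic claims generator. The
#' defaults emulate a provincial drug-plan cohort of new oral 5-ASA users:
#' age/sex mix and comorbidity prevalences of a mostly older, publicly
#' insured population; four interchangeable products with a 30-day median
#' supply per fill; corticosteroid co-dispensing; and refill behaviour with a
#' right-skewed delay distribution so that both adherence thresholds and the
#' 60-day persistence rule discriminate.
#'
#' Refill behaviour: each patient is a latent "prompt" or "non-prompt"
#' refiller, `prompt ~ Bernoulli(plogis(eta))` with
#' `eta = intercept + male*b_male + age_ge_60*b_age + current_steroid*b_ster`
#' (`covariate_effects`, log-odds). Prompt patients draw small extra refill
#' delays (lognormal, median `prompt_delay_median` days beyond supply
#' runout), non-prompt patients large ones (`nonprompt_delay_median`). At
#' each runout the patient stops refilling for good with probability
#' `1 - exp(-hazard * cycle_days)` (per-product daily hazard), or switches to
#' a different 5-ASA product with probability `switch_prob_per_refill`
#' (one fill of the new product is emitted and the stream ends).
#'
#' @param n_patients number of patients.
#' @param seed RNG seed (integer).
#' @param product_shares named probability vector over the four products
#'   (index product assignment).
#' @param sex_male_prob probability a patient is male.
#' @param age_group_probs probability vector over the age bands
#'   `<20, 20-39, 40-59, 60-79, 80+`.
#' @param days_supply_median days of supply per fill (constant per fill, so
#'   also the median; default 30).
#' @param prompt_delay_median,nonprompt_delay_median median extra days beyond
#'   runout until the next fill for prompt / non-prompt refillers; 0 means
#'   exactly zero delay.
#' @param delay_sdlog lognormal dispersion of the refill delay.
#' @param covariate_effects named list of log-odds coefficients
#'   (`intercept`, `male`, `age_ge_60`, `current_steroid`) on refill
#'   promptness.
#' @param discont_hazard_per_product named vector of daily hazards of
#'   stopping refills, one per product.
#' @param switch_prob_per_refill probability per refill of switching product.
#' @param comorbidity_prevalences named probabilities for `hypertension`,
#'   `heart_disease`, `respiratory_illness`, `diabetes`.
#' @param steroid_prior_prob,steroid_current_prob probability of any
#'   corticosteroid fill in the year before the index date / during the
#'   observation window.
#' @param crohns_prob probability a patient carries a Crohn's disease (ICD-9
#'   555.x) medical claim and is therefore excluded by the cohort builder.
#' @param short_history_prob probability eligibility starts only 30 days
#'   before the first fill (fails the washout-history requirement); 0 by
#'   default so cohort filters pass unless a test perturbs them.
#' @param short_coverage_prob probability eligibility ends 200 days after
#'   index (fails the 1-year coverage requirement); 0 by default.
#' @param index_date_range two dates bounding the uniform index-date draw.
#' @return list of class `rxpersist_sim_config`.
#' @export
sim_config <- function(n_patients = 1681,
                       seed = 1L,
                       product_shares = c(ASACOL_OR_GENERIC = 699,
                                          PENTASA = 208,
                                          SALOFALK = 817,
                                          MEZAVANT = 147) / 1871,
                       sex_male_prob = 0.434,
                       age_group_probs = c(0.036, 0.170, 0.307, 0.437, 0.050),
                       days_supply_median = 30L,
                       prompt_delay_median = 2,
                       nonprompt_delay_median = 35,
                       delay_sdlog = 0.5,
                       covariate_effects = list(intercept = -0.9,
                                                male = 0.26,
                                                age_ge_60 = 0.47,
                                                current_steroid = 0.34),
                       discont_hazard_per_product =
                         c(ASACOL_OR_GENERIC = 0.00076,
                           PENTASA = 0.00090,
                           SALOFALK = 0.00082,
                           MEZAVANT = 0.00020),
                       switch_prob_per_refill = 0.004,
                       comorbidity_prevalences = c(hypertension = 0.501,
                                                   heart_disease = 0.413,
                                                   respiratory_illness = 0.339,
                                                   diabetes = 0.327),
                       steroid_prior_prob = 0.30,
                       steroid_current_prob = 0.325,
                       crohns_prob = 0.02,
                       short_history_prob = 0,
                       short_coverage_prob = 0,
                       index_date_range = as.Date(c("2005-01-01",
                                                    "2009-12-31"))) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    product_shares = product_shares, sex_male_prob = sex_male_prob,
    age_group_probs = age_group_probs,
    days_supply_median = as.integer(days_supply_median),
    prompt_delay_median = prompt_delay_median,
    nonprompt_delay_median = nonprompt_delay_median,
    delay_sdlog = delay_sdlog,
    covariate_effects = covariate_effects,
    discont_hazard_per_product = discont_hazard_per_product,
    switch_prob_per_refill = switch_prob_per_refill,
    comorbidity_prevalences = comorbidity_prevalences,
    steroid_prior_prob = steroid_prior_prob,
    steroid_current_prob = steroid_current_prob,
    crohns_prob = crohns_prob,
    short_history_prob = short_history_prob,
    short_coverage_prob = short_coverage_prob,
    index_date_range = as.Date(index_date_range)
  )
  validate_sim_config(cfg)
  class(cfg) <- "rxpersist_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0, cfg$days_supply_median >= 1)
  check_prob_vector <- function(p, name) {
    if (any(p < 0 | p > 1)) stop(name, ": probabilities must lie in [0,1]")
    if (abs(sum(p) - 1) > 1e-9) stop(name, ": probabilities must sum to 1")
  }
  check_prob_vector(cfg$product_shares, "product_shares")
  check_prob_vector(cfg$age_group_probs, "age_group_probs")
  if (!setequal(names(cfg$product_shares), asa_products())) {
    stop("product_shares must be named over the four 5-ASA products")
  }
  probs <- c(cfg$sex_male_prob, cfg$switch_prob_per_refill,
             cfg$comorbidity_prevalences, cfg$steroid_prior_prob,
             cfg$steroid_current_prob, cfg$crohns_prob,
             cfg$short_history_prob, cfg$short_coverage_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (any(cfg$discont_hazard_per_product < 0)) stop("hazards must be >= 0")
  if (cfg$prompt_delay_median < 0 || cfg$nonprompt_delay_median < 0) {
    stop("delay medians must be >= 0")
  }
  invisible(cfg)
}

#' Read a simulation config from YAML
#'
#' Scalar and named-vector fields of [sim_config()] can be given in a YAML
#' file; anything omitted keeps its default.
#'
#' @param path YAML file path.
#' @return `rxpersist_sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  vec_fields <- c("product_shares", "age_group_probs",
                  "discont_hazard_per_product", "comorbidity_prevalences")
  for (nm in names(y)) {
    val <- y[[nm]]
    if (nm %in% vec_fields && is.list(val)) val <- unlist(val)
    if (nm == "index_date_range") val <- as.Date(unlist(val))
    if (nm == "covariate_effects") val <- as.list(val)
    args[[nm]] <- val
  }
  do.call(sim_config, args)
}

age_band_limits <- function() {
  list(lo = c(10, 20, 40, 60, 80), hi = c(19, 39, 59, 79, 94))
}

#' Simulate a patient population
#'
#' Draws demographics, an index date, eligibility, and the latent covariate
#' flags that drive claim generation. Eligibility spans from one year before
#' the index date to one year plus the 60-day gap-evaluation lookthrough
#' after it, so cohort coverage filters pass unless perturbed via
#' `short_history_prob` / `short_coverage_prob`.
#'
#' @param config a [sim_config()].
#' @return list with data.frames `patients` (patient_id, sex, birth_year,
#'   region), `eligibility`, and `truth` (per-patient latent state: index
#'   date/product, covariate flags, promptness probability and draw).
#' @export
simulate_population <- function(config) {
  set.seed(config$seed)
  n <- config$n_patients
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (n == 0) {
    return(list(patients = empty(c("patient_id", "sex", "birth_year", "region")),
                eligibility = empty(c("patient_id", "start_date", "end_date")),
                truth = empty("patient_id")))
  }
  id <- sprintf("P%05d", seq_len(n))
  male <- stats::runif(n) < config$sex_male_prob
  band <- sample.int(5, n, replace = TRUE, prob = config$age_group_probs)
  lim <- age_band_limits()
  age <- lim$lo[band] + floor(stats::runif(n) * (lim$hi[band] - lim$lo[band] + 1))
  r <- as.numeric(config$index_date_range)
  index_date <- as.Date(floor(stats::runif(n, r[1], r[2] + 1)),
                        origin = "1970-01-01")
  birth_year <- as.integer(format(index_date, "%Y")) - age
  comorb <- sapply(config$comorbidity_prevalences,
                   function(p) stats::runif(n) < p)
  prior_steroid <- stats::runif(n) < config$steroid_prior_prob
  current_steroid <- stats::runif(n) < config$steroid_current_prob
  crohns <- stats::runif(n) < config$crohns_prob
  short_history <- stats::runif(n) < config$short_history_prob
  short_coverage <- stats::runif(n) < config$short_coverage_prob
  product <- sample(asa_products(), n, replace = TRUE,
                    prob = config$product_shares[asa_products()])
  ce <- config$covariate_effects
  eta <- ce$intercept + ce$male * male + ce$age_ge_60 * (age >= 60) +
    ce$current_steroid * current_steroid
  prompt <- stats::runif(n) < stats::plogis(eta)

  elig_start <- index_date - ifelse(short_history, 30, 365)
  elig_end <- index_date + ifelse(short_coverage, 200, 424)
  patients <- data.frame(patient_id = id,
                         sex = ifelse(male, "MALE", "FEMALE"),
                         birth_year = birth_year, region = "QC",
                         stringsAsFactors = FALSE)
  eligibility <- data.frame(patient_id = id, start_date = elig_start,
                            end_date = elig_end, stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = id, index_date = index_date,
                      index_product = product, male = male,
                      age_at_index = age, age_ge_60 = age >= 60,
                      hypertension = comorb[, "hypertension"],
                      heart_disease = comorb[, "heart_disease"],
                      respiratory_illness = comorb[, "respiratory_illness"],
                      diabetes = comorb[, "diabetes"],
                      prior_steroid = prior_steroid,
                      current_steroid = current_steroid,
                      crohns = crohns, short_history = short_history,
                      short_coverage = short_coverage,
                      prompt_logit = eta, prompt = prompt,
                      stringsAsFactors = FALSE)
  list(patients = patients, eligibility = eligibility, truth = truth)
}

# Lognormal delay draws with exact-zero support: a median of 0 yields
# delays identically 0 (limit configurations must hold exactly).
draw_delays <- function(n_draws, median_days, sdlog) {
  if (median_days == 0) return(rep(0, n_draws))
  pmax(0, round(stats::rlnorm(n_draws, meanlog = log(median_days),
                              sdlog = sdlog)))
}

asa_code_for <- function(product) {
  c(ASACOL_OR_GENERIC = "ASA-400", PENTASA = "PEN-500",
    SALOFALK = "SAL-500", MEZAVANT = "MEZ-1200")[product]
}

# Tablets per day used to produce realistic per-script quantities: standard
# divided dosing for three products, once-daily for the multi-matrix one.
tablets_per_day <- function(product) {
  c(ASACOL_OR_GENERIC = 6, PENTASA = 6, SALOFALK = 6, MEZAVANT = 2.4)[product]
}

#' Simulate dispensing and medical claims for a population
#'
#' Emits each patient's index 5-ASA fill and refill stream (see
#' [sim_config()] for the refill model), corticosteroid fills per the prior
#' and current exposure flags, comorbidity-marker fills per the comorbidity
#' flags, and medical claims (benign ICD-9 codes for everyone, a Crohn's
#' 555.x claim for the configured fraction). Fills are only emitted while
#' eligibility lasts.
#'
#' @param population output of [simulate_population()] from the same config.
#' @param config the [sim_config()].
#' @return list with data.frames `dispensing`, `medical`, and `truth` (the
#'   population truth augmented with `n_index_fills`, `stopped`, `switched`).
#' @export
simulate_claims <- function(population, config) {
  set.seed(config$seed + 1L)
  tr <- population$truth
  n <- nrow(tr)
  disp_cols <- c("patient_id", "dispense_date", "drug_code", "product_label",
                 "quantity", "days_supply")
  med_cols <- c("patient_id", "service_date", "icd9_code")
  if (n == 0) {
    empty <- function(cols) as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols))
    return(list(dispensing = empty(disp_cols), medical = empty(med_cols),
                truth = tr))
  }
  ds <- config$days_supply_median
  horizon <- as.numeric(population$eligibility$end_date - tr$index_date)
  kmax <- max(2L, floor(max(horizon) / ds) + 2L)
  med_delay <- ifelse(tr$prompt, config$prompt_delay_median,
                      config$nonprompt_delay_median)
  hazard <- config$discont_hazard_per_product[tr$index_product]

  disp <- vector("list", n)
  n_fills <- integer(n); stopped <- logical(n); switched <- logical(n)
  for (i in seq_len(n)) {
    delays <- draw_delays(kmax, med_delay[i], config$delay_sdlog)
    cycles <- ds + delays
    t_fill <- cumsum(c(0, cycles))[seq_len(kmax)]
    u_stop <- stats::runif(kmax)
    u_switch <- stats::runif(kmax)
    p_stop <- -expm1(-hazard[i] * cycles)
    stop_j <- which(hazard[i] > 0 & u_stop <= p_stop)
    switch_j <- which(config$switch_prob_per_refill > 0 &
                        u_switch <= config$switch_prob_per_refill)
    js <- if (length(stop_j)) stop_j[1] else kmax
    jw <- if (length(switch_j)) switch_j[1] else kmax
    m <- min(js, jw, kmax, sum(t_fill <= horizon[i]))
    dates <- tr$index_date[i] + t_fill[seq_len(m)]
    prods <- rep(tr$index_product[i], m)
    if (jw < js && m == jw && t_fill[jw + 1] <= horizon[i]) {
      # switch: one fill of a different product, then the stream ends
      new_prod <- sample(setdiff(asa_products(), tr$index_product[i]), 1)
      dates <- c(dates, tr$index_date[i] + t_fill[jw + 1])
      prods <- c(prods, new_prod)
      switched[i] <- TRUE
    }
    stopped[i] <- length(stop_j) > 0 && stop_j[1] <= jw && stop_j[1] == m
    n_fills[i] <- m
    disp[[i]] <- data.frame(
      patient_id = tr$patient_id[i], dispense_date = dates,
      drug_code = unname(asa_code_for(prods)), product_label = prods,
      quantity = as.integer(pmax(1, round(tablets_per_day(prods) * ds))),
      days_supply = ds, stringsAsFactors = FALSE)
  }
  dispensing <- do.call(rbind, disp)

  dispensing <- rbind(dispensing,
                      steroid_fills(tr, config),
                      marker_fills(tr))
  dispensing <- dispensing[order(dispensing$patient_id,
                                 dispensing$dispense_date,
                                 dispensing$drug_code), , drop = FALSE]
  rownames(dispensing) <- NULL
  # attach the mapped columns the analysis layer expects; the file writer
  # drops them so written claims stay in the raw input schema
  map <- default_code_map()
  mi <- match(dispensing$drug_code, map$drug_code)
  dispensing$product <- ifelse(is.na(mi), "OTHER", map$product[mi])
  dispensing$drug_class <- ifelse(is.na(mi), "OTHER", map$drug_class[mi])

  medical <- medical_claims(tr)
  tr$n_index_fills <- n_fills
  tr$stopped <- stopped
  tr$switched <- switched
  list(dispensing = dispensing, medical = medical, truth = tr)
}

steroid_fills <- function(tr, config) {
  rows <- list()
  mk <- function(pid, dates) {
    data.frame(patient_id = pid, dispense_date = dates,
               drug_code = "COR-PRED", product_label = "PREDNISONE",
               quantity = 30L, days_supply = 14L, stringsAsFactors = FALSE)
  }
  prior <- which(tr$prior_steroid)
  if (length(prior)) {
    offs <- floor(stats::runif(length(prior), 30, 365))
    rows <- c(rows, list(mk(tr$patient_id[prior], tr$index_date[prior] - offs)))
  }
  cur <- which(tr$current_steroid)
  if (length(cur)) {
    offs <- floor(stats::runif(length(cur), 0, 365))
    rows <- c(rows, list(mk(tr$patient_id[cur], tr$index_date[cur] + offs)))
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

marker_fills <- function(tr) {
  code <- c(hypertension = "MRK-HTN", heart_disease = "MRK-CARD",
            respiratory_illness = "MRK-RESP", diabetes = "MRK-DIAB")
  rows <- list()
  for (cm in names(code)) {
    has <- which(tr[[cm]])
    if (!length(has)) next
    # one marker fill in the pre-index year, one in the window, so both the
    # lookback flag and the chronic disease score see the class
    off1 <- floor(stats::runif(length(has), 1, 365))
    off2 <- floor(stats::runif(length(has), 0, 365))
    rows <- c(rows, list(data.frame(
      patient_id = rep(tr$patient_id[has], 2),
      dispense_date = c(tr$index_date[has] - off1, tr$index_date[has] + off2),
      drug_code = code[[cm]], product_label = cm,
      quantity = 30L, days_supply = 30L, stringsAsFactors = FALSE)))
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

medical_claims <- function(tr) {
  n <- nrow(tr)
  benign <- c("401.9", "486", "715.9", "780.4")
  offs <- floor(stats::runif(n, 0, 365))
  med <- data.frame(patient_id = tr$patient_id,
                    service_date = tr$index_date + offs,
                    icd9_code = sample(benign, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  cr <- which(tr$crohns)
  if (length(cr)) {
    med <- rbind(med, data.frame(
      patient_id = tr$patient_id[cr],
      service_date = tr$index_date[cr] + floor(stats::runif(length(cr), 0, 365)),
      icd9_code = sample(sprintf("555.%d", 0:9), length(cr), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  med <- med[order(med$patient_id, med$service_date), , drop = FALSE]
  rownames(med) <- NULL
  med
}

#' Simulate a claims bundle and write it to disk
#'
#' Runs [simulate_population()] and [simulate_claims()] and writes
#' `dispensing.csv`, `medical.csv`, `eligibility.csv`, `patients.csv`, and a
#' ground-truth sidecar `truth.csv` (latent per-patient state, for testing
#' only) into `out_dir`. Output is byte-identical for identical config.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of generated data.frames.
#' @export
simulate_claims_bundle <- function(config, out_dir) {
  pop <- simulate_population(config)
  cl <- simulate_claims(pop, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt_dates <- function(df) {
    for (col in names(df)) if (inherits(df[[col]], "Date")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    df
  }
  disp_file <- cl$dispensing[, c("patient_id", "dispense_date", "drug_code",
                                 "product_label", "quantity", "days_supply")]
  write_delim_file(fmt_dates(disp_file), file.path(out_dir, "dispensing.csv"))
  write_delim_file(fmt_dates(cl$medical), file.path(out_dir, "medical.csv"))
  write_delim_file(fmt_dates(pop$eligibility),
                   file.path(out_dir, "eligibility.csv"))
  write_delim_file(fmt_dates(pop$patients), file.path(out_dir, "patients.csv"))
  write_delim_file(fmt_dates(cl$truth), file.path(out_dir, "truth.csv"))
  invisible(list(dispensing = cl$dispensing, medical = cl$medical,
                 eligibility = pop$eligibility, patients = pop$patients,
                 truth = cl$truth))
}
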