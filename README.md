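# rxpersist

Medication adherence and persistence analysis for pharmacy dispensing
claims, motivated by oral 5-aminosalicylate (5-ASA / mesalamine) maintenance
therapy in ulcerative colitis. Claims databases record every reimbursed fill
with its date and days of supply; `rxpersist` turns those records into the
standard pharmacoepidemiologic measures and their determinants:

* **New-user cohorts** — index at the first 5-ASA fill after a 90-day
  washout, exclude Crohn's disease (ICD-9 555.x) and patients without a full
  year of post-index drug-plan coverage, with a reproducible attrition log.
* **Adherence** — medication possession ratio over the 365-day window,

      MPR = min(365, Σ_k min(s_k, 365 − d_k)) / 365,

  for fills on index-relative days `d_k` with `s_k` days of supply;
  adherent means MPR ≥ 80% (inclusive), with a complementary ≥ 50%
  threshold and a proportion-of-days-covered (PDC) sensitivity variant.
* **Persistence** — treatment episodes with a 60-day grace period (twice
  the usual 30-day refill time): discontinuation by gap or by switch to a
  different 5-ASA product, otherwise censored at day 365; Kaplan–Meier
  time-to-discontinuation and log-rank comparisons.
* **Determinants** — claims-derived covariates (sex, age ≥ 60,
  medication-marker comorbidities, a medication-based chronic disease
  score, prior/current corticosteroid use) and stepwise backward logistic
  models reporting adjusted odds ratios with Wald 95% CIs.
* **A synthetic claims generator** — seeded, with configurable refill
  promptness (log-odds covariate effects), per-product stop hazards, and
  switching, so every stage is testable without a confidential extract.

See the vignette (`vignettes/claims-adherence-persistence.Rmd`) for the
methodology and modelling choices.

## Worked example

Simulate a study-like cohort of 1,681 patients, run the whole pipeline, and
look at the headline results:

```r
library(rxpersist)

cfg <- sim_config(n_patients = 1681, seed = 2013)
simulate_claims_bundle(cfg, "demo")
res <- run_pipeline("demo/dispensing.csv", "demo/medical.csv",
                    "demo/eligibility.csv", "demo_out",
                    patients_path = "demo/patients.csv")

res$attrition
#>                              rule n_removed n_remaining
#> 1 washout_or_unobservable_history         0        1681
#> 2                crohns_diagnosis        31        1650
#> 3                  coverage_lt_1y         0        1650

adherence_summary(res$adherence)
#>     group    n n_adherent_80 pct_80 n_adherent_50 pct_50
#> 1 overall 1650           512     31           653   39.6

persistence_summary(res$episodes, "index_product")
#>               group   n n_persistent_365  pct
#> 1 ASACOL_OR_GENERIC 619              274 44.3
#> 2          MEZAVANT 145               84 57.9
#> 3           PENTASA 170               71 41.8
#> 4          SALOFALK 716              346 48.3

logrank_compare(res$episodes, res$episodes$index_product)
#> log-rank chi2 = 11.5 on 3 df, p = 0.00946

res$determinants$adherent_80$demographics
#>              term retained odds_ratio   ci_low  ci_high      p_value
#> 1            male     TRUE   1.542075 1.248873 1.904113 0.0000568464
#> 2       age_ge_60     TRUE   1.389322 1.124954 1.715817 0.0022631357
#> 3   prior_steroid    FALSE         NA       NA       NA           NA
#> 4 current_steroid     TRUE   1.366183 1.093267 1.707228 0.0060646673
```

Reading the output: 31 simulated patients carry a Crohn's claim and are
excluded; of the remaining 1,650 new users, 31.0% reach an MPR of at least
80%. Persistence at one year is highest on the once-daily multi-matrix
product (57.9%), and the log-rank test rejects equality of the four
discontinuation curves. In the demographics block, male sex, age ≥ 60, and
current corticosteroid use are retained as determinants of adherence
(OR ≈ 1.4–1.5) while prior corticosteroid use is removed as not
significant — the pattern the generator's defaults encode.

`run_pipeline()` also writes every table (cohort, attrition, adherence,
episodes, KM curves, demographics/prescription/determinants tables, and a
run manifest) to the output directory. A thin command-line driver with
`simulate` and `run-all` verbs lives at `inst/cli/rxpersist.R`.

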