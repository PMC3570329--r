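---
title: "Measuring adherence and persistence from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring adherence and persistence from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oral 5-aminosalicylates (5-ASA, mesalamine) are the first-line maintenance
therapy for mild to moderate ulcerative colitis. Because the disease relapses
and remits, patients often stop or stretch their medication during quiescent
periods, and poor adherence carries a substantially higher relapse risk.
Administrative pharmacy-claims databases let us measure this behaviour at
population scale: every reimbursed fill is recorded with its dispensing date
and days of supply. `rxpersist` implements the standard claims-based
methodology — new-user cohorts, the medication possession ratio, grace-period
persistence episodes, and regression on claims-derived determinants —
together with a synthetic claims generator so the entire pipeline can be
validated without access to a real (and confidential) claims extract.

## Cohort construction

A *new user* is a patient whose earliest observed 5-ASA fill (the *index
date*) is preceded by 90 days with no 5-ASA fill. Because "no fill observed"
is only meaningful where the patient was actually insured, the builder
requires continuous drug-plan eligibility over the 90 pre-index days and
excludes patients with left-truncated history rather than indexing them at a
later fill; an `all_drugs_washout` flag applies the stricter
any-prescription reading. Three exclusion rules run in a fixed order —
washout/observability, any Crohn's disease claim (ICD-9 555.0–555.9, scanned
over the whole claims history since the diagnosis is not time-qualified),
and less than 365 days of post-index eligibility — and an attrition table
records removals per rule, so the counts always sum to candidates minus
members. "3 months" is implemented as 90 days because calendar-month
arithmetic is ambiguous; age at index uses year arithmetic since claims
extracts rarely carry full birth dates.

## Adherence: MPR and its day-coverage check

The medication possession ratio over the fixed 365-day window is

$$\mathrm{MPR} = \frac{\min\left(365,\ \sum_k \min(s_k,\ 365 - d_k)\right)}{365},$$

where fill $k$ is dispensed on index-relative day $d_k$ with $s_k$ days of
supply. The denominator is fixed at 365 for everyone: the study design
estimates adherence over one year, and early discontinuation is analysed
separately as persistence. Each fill is truncated at the window end and the
numerator capped, so $0 < \mathrm{MPR} \le 1$. Thresholds are inclusive:
adherent means MPR ≥ 0.80, with a complementary ≥ 0.50 classification.
Adherence counts all 5-ASA fills by default (the clinically interchangeable
class), with an `index_product_only` flag for the stricter per-product
variant.

Summed supply double-counts overlapping fills, so a proportion-of-days-
covered (PDC) variant is provided (`method = "pdc"`): fills stockpile, a day
is covered while accumulated supply lasts, and the metric is covered days
out of 365. PDC never exceeds MPR and equals it when no fills overlap; the
test suite verifies both against a literal day-by-day simulation oracle on
over a thousand random synthetic patients.

## Persistence: grace-period episodes

Treatment cessation is declared when the patient goes 60 days — twice the
usual 30-day refill interval — without 5-ASA supply. Scanning a member's
fills chronologically with carry-forward stockpiling (an early refill can
never create an artificial gap):

* **Gap discontinuation** — a supply runout followed by 60 days with no
  gap-closing fill. The event time is the day after the runout: the patient
  is still medicated until supply ends, and gap rules as usually stated do
  not define the event time, so this is stated explicitly as the package's
  convention.
* **Switch** — any fill of a different 5-ASA product inside the window,
  before a qualifying gap completes, ends persistence with the initial
  medication at that fill's day. By default a different-product fill also
  interrupts a gap (the patient did receive *a* 5-ASA treatment), which
  reconciles the any-5-ASA gap wording with switch-as-non-persistence; a
  completed gap earlier in time takes precedence. `require_abandonment`
  restricts switches to fills not followed by further index-product fills,
  and `gap_any_asa = FALSE` gives the strict index-product gap reading.
* **Censored** — neither event by day 365.

Right edge: a runout close to day 365 can only be classified as a gap if the
full 60-day silent interval is observable. Episodes therefore accept a
`data_end`; when eligibility is supplied, gaps are evaluated with fills
through day 365+59, and otherwise (fills-only input) late runouts are
censored. This avoids biasing discontinuation downward at the window edge.
The synthetic generator extends eligibility to index + 424 days for the same
reason.

Kaplan–Meier curves (`km_estimate()`, via the `survival` package) treat
censored-at-365 episodes as at-risk non-events; since all censoring occurs
at day 365, the KM estimate at 365 equals the empirical persistent
proportion, which the tests assert. Group comparisons use the log-rank test,
with a seeded permutation version kept as a small-sample cross-check of the
asymptotic chi-square p-value.

## Covariates and the chronic disease score

Determinants are derived from the claims themselves: sex; age dichotomized
at ≥ 60 (inclusive); comorbidity flags for hypertension, heart disease,
respiratory illness, and diabetes, set when a marker-class medication is
dispensed in the lookback (365 days pre-index through window end — claims
data indicate comorbidity via medication profiles, not diagnoses);
corticosteroid exposure in the prior year (`prior_steroid`) and inside the
window (`current_steroid`); and a medication-based chronic disease score
summing configured weights over distinct observed medication classes, with
optional co-occurrence bonus rules, dichotomized at a cut of 6 (a typical
cohort median; `median_cut = TRUE` recomputes it from the data). The
shipped weight table is deliberately simple (heart 4, respiratory 3,
hypertension 2, diabetes 2, corticosteroid 1) and fully overridable; the
published weights for such scores vary by formulary era, so no correctness
claim rests on the default — tests exercise explicit toy tables.

## Determinant models

Two independent stepwise backward logistic models are fitted per outcome
(adherent at 80%, persistent at 365 days): a demographics block (male, age
≥ 60, prior and current corticosteroid use — the exposure variables sit with
demographics, as they are listed alongside sex and age in the standard
analysis) and a comorbidity block (four comorbidity flags plus the
high-score indicator). At each step the covariate with the largest Wald
p-value is removed while that p-value exceeds `alpha` (0.05 by default — the
conventional threshold, exposed as a knob since study reports rarely state
it), refitting after each removal; exact ties remove the earlier-listed
covariate so results are deterministic and row-order invariant. Dropped
covariates are reported as NS. Wald intervals (`exp(beta ± 1.96·SE)`) match
the symmetric intervals such studies print. Separation and rank deficiency
raise errors naming the covariate instead of returning unstable estimates.

## The synthetic generator

`sim_config()` defaults describe a provincial drug-plan cohort of new oral
5-ASA users: 43.4% male; age bands `<20, 20–39, 40–59, 60–79, 80+` with
probabilities (0.036, 0.170, 0.307, 0.437, 0.050); comorbidity prevalences
50.1% / 41.3% / 33.9% / 32.7% (hypertension / heart / respiratory /
diabetes); four products with index shares proportional to user counts
699 : 208 : 817 : 147; and a constant 30-day supply per fill, the observed
median.

Refill behaviour is a two-state mixture chosen to make covariate effects
exactly recoverable: each patient is a latent **prompt** or **non-prompt**
refiller, `prompt ~ Bernoulli(plogis(eta))` with `eta` a linear combination
of male sex, age ≥ 60, and current corticosteroid use (log-odds
coefficients). Prompt patients draw small lognormal extra delays beyond
runout (median 2 days), non-prompt large ones (median 35 days, dispersion
0.5 on the log scale), producing the right-skewed gap distribution that
makes the 60-day rule informative. Because promptness is Bernoulli with a
logit link and the two delay regimes separate cleanly at the 80% MPR
threshold, a logistic regression of adherence on a covariate recovers that
covariate's configured log-odds — the basis of the parameter-recovery test
(50 replicates of n = 5,000 at male log-odds 0.4; the 95% CI covers
exp(0.4) in ≥ 90% of replicates). A location-shift formulation on the delay
distribution would not admit such a clean identity, which is why the mixture
was chosen.

Stopping and switching: at each runout the patient permanently stops with
probability `1 − exp(−h·cycle)` (per-product daily hazard `h`) or switches
with a per-refill probability, emitting one fill of a different product and
ending the index stream. Default hazards (7.6, 9.0, 8.2, 2.0 per 10,000
days for the four products) and a 0.4% switch probability were set once by
decomposing target outcome rates — roughly 28% adherent, 45% persistent,
with the once-daily product most persistent — into stop, switch, and
gap components; the resulting simulated rates land within a few points of
those targets. Per-product differences are qualitative (ordering, not exact
levels), since promptness is product-independent by design.

What the generator does *not* emulate: plan co-pay behaviour,
hospitalization supply gaps, dose titration, seasonal refill patterns, or
diagnosis-coded comorbidity. Passing tests therefore demonstrate
correctness of the measurement algorithms under a controlled refill model,
not calibration of any particular real-world database.

## Numerical conventions and edge cases

* Dates are ISO 8601; supply intervals are closed (a fill on day *d* with
  *s* days covers days *d* … *d+s−1*).
* Printed percentages use one decimal with halves rounded up
  (`round_half_up()`), so published-table arithmetic reproduces exactly.
* Malformed input rows fail fast by default; `on_bad = "skip"` drops them
  with a per-line warning.
* Chi-square comparisons use the Pearson statistic without continuity
  correction and warn when an expected cell is below 1.
* A cohort member with no qualifying fill in the window is an internal
  consistency error (the index fill guarantees at least one).
* Problem sizes in the test suite (about a thousand oracle-checked
  patients, 50 recovery replicates of 5,000, 200 stepwise replicates of
  500) were chosen as the smallest sizes at which the Monte-Carlo tolerances
  are comfortably discriminating.

## Known limitations

Dispensed supply is an upper bound on consumption; claims cannot show
whether medication was taken. Only the first definitive cessation is
modelled — no restart episodes. Comorbidity is medication-inferred, so
untreated disease is invisible. The per-product descriptive table groups
members by index product (counts sum to the cohort size); databases that
count any user of each product will show larger, overlapping counts.
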