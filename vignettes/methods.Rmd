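---
title: "Methods: adjudicating uUTI antibiotic prescribing and estimating its cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adjudicating uUTI antibiotic prescribing and estimating its cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Uncomplicated urinary tract infection (uUTI) is usually treated
empirically: the antibiotic is chosen before culture and susceptibility
results return. Two things can therefore go wrong. The prescription can be
*inappropriate* relative to guidelines (a second-line agent without a
reason, an agent the patient is allergic or resistant to, duplicate
first-line therapy) or *suboptimal* in hindsight (the course must be
switched, escalated to IV, or the isolate turns out not-susceptible to the
agent given). Both mechanisms plausibly raise downstream healthcare
resource use (HCRU) and cost, and both are entangled with antimicrobial
resistance. `uticost` implements the standard retrospective design for
quantifying these effects from EHR-style tables, with every analytic rule
explicit, configurable, and tested.

## Data model

Six flat tables: `patients` (demographics, insurance, data-completeness
flags), `diagnoses` (ICD-10-style codes, symptom and pregnancy/catheter
flags), `encounters` (setting, date, UTI-attribution flag),
`prescriptions` (drug, route, duration, order date), `cultures` (long
format: isolate × antibiotic → S/I/R, organism, CFU/mL), `allergies`
(drug, record date). All dates are calendar dates; the package has no
notion of clock time, so every "within 48 h" rule is evaluated as the
index date plus the following two calendar dates.

## Cohort construction

The **index date** is the earliest of the first uUTI-coded diagnosis and
the first culture with ≥ 10⁴ CFU/mL of a configured uropathogen; which
source(s) defined it is recorded as the `basis` (`diagnosis_code`,
`culture`, `both`). Inclusion then requires female sex, age ≥ 12 years at
index, ≥ 1 *oral* antibiotic order within ± 5 days of index (both
endpoints inclusive — the boundary convention is not externally fixed, so
it is stated here and tested), and ≥ 1 culture with a non-empty
susceptibility panel. The earliest qualifying oral order is the *initial
therapy*; same-day ties break by record order then drug id,
deterministically.

Exclusions run in a fixed, declared order (pregnancy at index; HIV/AIDS;
antibiotic use in `[index−180 d, index−6 d]`; catheter within 48 h;
complicated-UTI symptoms — fever ≥ 38.3 °C, nausea, vomiting, flank pain —
within 48 h; IV antibiotics before the first oral order; complicating
comorbidity; missing follow-up data). The order affects per-filter
attribution in the waterfall but not the final cohort (the filters are
set-intersections); it is fixed for reproducibility and the attrition
report asserts monotone counts and the conservation identity
`n_initial = n_final + Σ drops`.

**Design choices made where the design was genuinely open.** The source
description of the HIV/AIDS-plus-prior-antibiotics exclusion is one
sentence; we implement it as *two independent criteria* (a compound
reading would exclude strictly fewer patients; the two-criteria reading is
the conservative one and each criterion is separately auditable). Code
lists (uUTI, complicated-UTI, complicating comorbidities, prior
infections, uropathogens) are configuration with documented defaults, not
hard-coded clinical claims.

## Scenarios

`cohort_scenario()` defines the sensitivity variants: `strict`
additionally requires `basis == "both"`; `loose` applies only the reduced
exclusion list (pregnancy, catheter, IV initial therapy, complicating
comorbidity); `fu30`/`fu360` change the follow-up window to 30/360 days
(`fu360` also drops patients without 360 days of data availability, with
the drop logged); `no_prior_infection` adds a prior-infection filter;
`fq_only` restricts to index fluoroquinolone recipients. By construction
`strict ⊆ baseline ⊆ loose`, which the tests assert.

## The rule engine

Person-level susceptibility: intermediate (I) and resistant (R) results
are *not-susceptible*; a patient is not-susceptible if any isolate is I/R
for at least one antibiotic in the uUTI-indicated set (all first-, second-
and third-line formulary agents). This is monotone — adding an I/R result
can never make a patient susceptible — and that property is tested.

The adjudication flags are not mutually exclusive (a not-susceptible
initial agent fires both an inappropriateness clause and a suboptimality
clause, which is why "suboptimal and inappropriate" overlap exists in any
such cohort). The final label is *appropriate* iff neither flag is set.
Open points resolved as package decisions:

* **Duration check** is exact equality with the recommended course
  (nitrofurantoin 5 d, fosfomycin 1 d, SXT 3 d) and applies to first-line
  monotherapy only; whether duration rules should bind allergy-driven
  alternates is undefined upstream, and we do not apply them there.
* **"Switch due to treatment failure"** is unobservable as intent in
  structured data; it is operationalized as any different formulary
  antibiotic ordered in `(index, index+28 d]`.
* **The escalation escape** (second-line initial therapy is acceptable
  when the patient cannot take first-line agents) requires
  allergy-or-resistance to *every* first-line agent; untested first-line
  agents do not justify escalation. This is the conservative reading and
  is switch-tested in the truth-table audit.
* **Allergy lookback**: allergy records up to the classification time
  count (EHR allergy tables are cumulative and the upstream design
  tabulates allergy history post-index); a pre-index-only switch exists.

Every true flag carries machine-readable rule ids
(`inapp_two_first_line`, `subopt_iv`, …), so any classification can be
traced to the clause that produced it. The engine is validated against an
independently written 216-row decision table covering initial therapy ×
allergy history × susceptibility × switch timing × IV exposure.

## Costs

HCRU is counted over half-open windows `[start, end)` so an index-date
event belongs to follow-up, never baseline. Costs are counts × unit fees
(encounters) plus duration × per-day price (drugs) from a configurable fee
schedule standing in for Medicare fee-for-service rates and wholesale
acquisition costs. UTI-attribution — undefined upstream — is: an encounter
is UTI-related iff it carries the UTI flag/diagnosis; a drug order iff the
drug is uUTI-indicated and falls within `[index−5, index+28]`. Follow-up
totals include the index date (the index encounter opens the window).

Winsorization caps values above the 98th percentile (linear-interpolation
definition, R quantile type 7) at that percentile, per outcome per
analysis sample. One nuance worth stating: with an interpolated threshold,
re-winsorizing capped data can move the cap by a fraction of the top
inter-order-statistic gap, so exact idempotence holds only when the
percentile lands on an order statistic; the tests assert exact idempotence
there and tolerance-level idempotence otherwise. Currency adjustment is a
price-index ratio to 2020 USD.

## Matched analysis

Propensity scores are plain logistic regressions; the
susceptibility-contrast covariate set is {age, White race, private
insurance, baseline inpatient visits, baseline outpatient visits}. The
appropriateness contrast reuses the demographic trio by default (the
upstream description says only that "a similar calculation" was used; the
utilization covariates are a switch). Matching is 1:1 greedy
nearest-neighbour without replacement on the *logit* of the score,
processing order seed-randomized, caliper defaulting to 0.2 SD of the
logit scores — chosen because the design this emulates matched 1009 of
1030 treated patients, implying a caliper that discards a few hard-to-match
patients. Balance is reported as standardized mean differences with
p(1−p) variances for binaries; SMD with zero pooled variance and unequal
means is reported as infinite and flagged rather than silently dropped.

Cost models are gamma-family log-link GLMs adjusted by Charlson score and
baseline all-cause HCRU (inpatient, ED, outpatient, pharmacy). Zero costs
are incompatible with a gamma likelihood; they are lifted to a $0.01
offset by default (a drop-zeros switch exists). Dollar differences use
recycled predictions — predict every patient under each exposure level,
average, difference against the reference — the standard marginalization
when only absolute differences are reported from a log-link model.
P-values are model-based Wald tests on the exposure coefficients at
α = 0.05.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults state the world the pipeline is tested against,
taken from the published cohort this design emulates where that cohort
reports a value: 40.2 % person-level non-susceptibility,
inappropriate-or-suboptimal prescribing in 48.2 % of not-susceptible vs
23.5 % of susceptible patients, 5.2 % allergy prevalence, mean age 43.5
(SD 18, truncated at 12 — the SD is unreported upstream and is a config
default), race/ethnicity/insurance mixes matching the reported baseline
table, reference follow-up costs $2532 all-cause / $945 UTI-related, and
group cost multipliers {1, 1.105, 1.261, 1.352} implied by the reported
group differences. Non-susceptibility is tilted by a logistic index in
age, White race and private insurance (intercept solved so the marginal
prevalence is honoured exactly), so matching has real confounding to
remove. Follow-up costs are gamma draws (shape 1.5 — no second-moment
information exists upstream, so this is a config default chosen for a
realistically heavy right tail) realised as Poisson encounter counts
priced by the fee schedule: the group mean is exact
(`base × multiplier`, plus a few dollars of initial-drug cost), while the
tables stay count-shaped. Progression to complicated UTI is planted at
4 % / 10 % by susceptibility arm (risk difference 0.06, matching the
reported baseline sensitivity row).

What it does **not** emulate: organism-level resistance epidemiology,
realistic ICD code frequencies, visit-timing structure, dose/formulation
detail, or informative missingness. A green test therefore establishes
that the *pipeline* recovers planted truths under the stated statistical
structure — not that the generator reproduces real EHR complexity.

Planted-exclusion patients (`inject_exclusion_cases()`) are engineered to
pass every filter upstream of their reason and fail exactly that one, so
the attrition waterfall is checkable count-exactly.

## Numerical and testing choices

Report percentages round half-up to one decimal (the field's printing
convention; base R's banker's rounding would print 0.5 cases down).
Matching is O(treated × controls) with explicit tie-breaks (earlier
control wins), deterministic given the seed. The acceptance suite sizes
follow the stated criteria (n = 2000 for balance, ~5000 per exposure group
for multiplier recovery, 500 replicates for the type-I check at n = 150
per arm — sized to keep the suite inside a desktop time budget). The
type-I check accepts a rejection rate within 2 standard errors of 5 %.

## Known limitations

* Calendar-day windows cannot represent sub-day timing; a fever recorded
  49 h after index but on the second calendar day counts as "within 48 h".
* The generator produces at most one isolate per patient by default;
  multi-isolate aggregation is exercised by hand-built fixtures instead.
* Matched-pair dependence is ignored by the default model-based standard
  errors (a cluster-robust option is a documented extension point).
* The fee schedule and price index are plausible magnitudes, not real CMS
  or wholesale-acquisition data; dollar outputs are internally consistent
  but not externally calibrated.
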