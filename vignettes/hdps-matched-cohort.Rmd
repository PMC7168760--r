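---
title: "High-dimensional propensity score matched cohorts on claims data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional propensity score matched cohorts on claims data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study design this package implements

`hdpscohort` implements, end to end, a new-user active-comparator cohort
study of antiplatelet agents (APA) after acute coronary syndrome (ACS) in a
nationwide claims database: patients discharged alive from a first ACS
hospitalization in the inclusion year, assigned to the treatment group of
the first APA (clopidogrel, prasugrel or ticagrelor) dispensed within 30
days of discharge, followed for one year of initial-treatment exposure, and
compared on composite effectiveness and safety endpoints after
high-dimensional propensity score (hdPS) matching. Because nationwide
claims databases are access-restricted, the package ships a synthetic
claims generator with the same relational structure, and every stage is
exercised and tested against it.

The pipeline stages, each an exported function, are:

1. `simulate_claims()` — synthetic claims database (patients, dispensings,
   hospital stays with primary/linked/associated diagnoses and procedures,
   long-term-disease (LTD) registrations, visits, lab claims), integer-day
   dates on a synthetic calendar (day 0 = start of the extraction window,
   365-day years, inclusion year = days 365–729).
2. `select_cohort()` — selection criteria in the study's order with
   flow-chart accounting (first ACS stay of the inclusion year; stay within
   the year; 30-day ACS washout; acute-care hospital; duration > 0 days;
   age ≥ 18; one year of history; alive at discharge; one year of
   follow-up with deaths retained; no rehabilitation stay within 30 days).
3. `derive_exposure()` — treatment group, discontinuation / switch /
   retention, exposure period and medication possession ratio (MPR).
4. `build_covariates()` — the predefined confounders, comorbidity
   algorithms and the age-weighted Charlson index.
5. `generate_empirical_covariates()`, `prioritize_covariates()`,
   `fit_hdps()`, `trim_scores()` — the hdPS.
6. `match_cohort()` — 1:1 caliper matching.
7. `balance_report()` — standardized-difference diagnostics.
8. `derive_event_times()`, `estimate_incidence()`, `compare_incidence()` —
   person-time incidence, Kaplan–Meier, Cox and (quasi-)Poisson
   comparison.
9. `run_study()` — orchestration under one configuration and one master
   seed (per-stage seeds via `substream_seed()`, so adding a stage never
   reshuffles earlier randomness).

The package's users work from R, so the exported functions and
`scripts/acceptance.R` are the command-line surface; no per-stage shell
binaries are installed.

# Exposure algorithms

Dispensed quantity is converted to days of supply through packs × units
per pack × DDD per unit, under the convention that one DDD covers one day.
`track_episode()` walks the dispensings of the initial drug with a running
stock in DDD-days and *uncapped carryover* of unconsumed supply (early
refills accumulate). Discontinuation is *detected* at the first gap longer
than the remaining supply plus a 30-day grace period, and *dated* at the
exhaustion of supply (last dispensing day plus remaining supply) — the
grace period is a detection device, not part of the event date. A
dispensing of a different study APA defines a switch; a switch that occurs
before the discontinuation could be detected (exhaustion + grace)
pre-empts it, because the patient moved to another study drug rather than
stopping therapy. Retention ends at the earlier of the two events.
Exposure runs from the index date (discharge) to retention or to the end
of follow-up (365 days, truncated at death), even though the first
dispensing may occur up to 30 days after discharge; outcome follow-up,
however, *starts at the first dispensing*, so the days between discharge
and initiation contribute no person-time (immortal-time rule). MPR is
100 × DDD dispensed during exposure / exposure days, capped at 100%, and
categorized as 0, ]0–20[, [20–40[, [40–60[, [60–80[, [80–100[, 100.

Same-day events get half a day of person-time so that survival times stay
positive. Death dates known only to the month are resolved by
`resolve_death_day()`: day 15 of the month, overridden by a same-month
hospitalization ending after the 15th.

# The high-dimensional propensity score

Six data dimensions are scanned (hospital diagnoses including the primary
code, drugs, visit specialties, lab claims, in-hospital procedures, LTD
registrations), each over the 365-day lookback before the index admission
(LTD: any registration starting before admission). Within each dimension
the `top_n = 200` most prevalent codes (distinct patients with ≥ 1
occurrence) are expanded into up to three binary covariates at the
once / sporadic / frequent within-patient frequency levels; the sporadic
and frequent thresholds are the ceiling of the median and 75th-percentile
count among patients with the code (integer counts need integer
thresholds; ties collapse into a single covariate, keeping the lowest
level label).

Candidates are ranked by the Bross bias formula. For covariate C with
prevalence $p_{C1}$ among treated and $p_{C0}$ among comparators, and
outcome risk ratio $RR_{CD}$ across covariate levels in the pooled cohort,

$$\mathrm{BM} = \frac{p_{C1}(RR_{CD}-1)+1}{p_{C0}(RR_{CD}-1)+1},$$

and covariates are ranked by $|\log \mathrm{BM}|$. Numerical conventions:
0.1 is added to every cell of the covariate–outcome 2×2 table when any
cell is zero; when $RR_{CD} < 1$ its reciprocal is used, so protective
proxies rank by magnitude; ties break by higher prevalence, then code
(determinism). The top `k = 500` covariates (the published default) join
the forced set — gender, age, CMU-c coverage, index-diagnosis stratum,
index PCI / CABG, intensive care, hospital category, index stay duration,
ACS history, ASA history, naive / incident status and the Charlson score —
in a plain maximum-likelihood logistic model fitted by IRLS (tolerance
1e-8 on the relative deviance change, step-halving, no regularization).
Constant, duplicate and collinear columns are dropped with a warning.
Perfect separation (deviance → 0, no finite maximizer) is an error naming
the offending covariates; quasi-separation on rare covariates converges
quietly, as `glm()` does. The outcome feeding the prioritization is the
primary effectiveness composite (configurable).

# Matching and balance

Matching is 1:1 without replacement, exact on gender and index-diagnosis
stratum, with inclusive calipers of ±1 year on age and ±0.05 on the score.
Greedy mode (the default) processes treated patients in descending score
order — hardest to match first — each taking the eligible comparator with
the smallest score distance (ties: smallest age distance, then lowest id).
Optimal mode minimizes the total score distance over a caliper-restricted
bipartite assignment (shortest-augmenting-path algorithm, intended for
moderate cell sizes); its total distance is never larger than greedy's at
equal cardinality, which the tests verify against an exhaustive oracle.

Balance is quantified with the standardized difference,
$d = (\bar X_1 - \bar X_2)/\sqrt{(s_1^2+s_2^2)/2}$ for continuous and
$d = (\hat p_1 - \hat p_2)/\sqrt{[\hat p_1(1-\hat p_1)+\hat p_2(1-\hat
p_2)]/2}$ for binary covariates (also reported ×100 as percent), crude and
on the matched cohort, plus two adjusted forms: stratified (pooled score
quintiles, boundary patients to the lower stratum, stratum-size-weighted
average, empty-arm strata skipped with renormalized weights) and
regression-weighted (covariate ~ score × group; the two groups' predicted
values are averaged over the *pooled* score distribution — the source is
ambiguous on the evaluation profile, and pooled was chosen; for continuous
covariates the denominator keeps the observed group variances, so a pure
group shift of δ under unit variances yields d ≈ δ).

# Outcome comparison

Endpoints are composites taking the first component event during the
exposure period: e.g. the primary effectiveness endpoint is
hospitalization for ACS (primary diagnosis), ischemic/undefined stroke, or
all-cause death; the safety endpoint is hospitalization for major
bleeding. Death is *not* treated as a competing risk (post-ACS deaths are
overwhelmingly cardiovascular in the first year). With more than 100
events the arms are compared by Cox proportional hazards (Wald CI and
p-value; proportionality checked per covariate on scaled Schoenfeld
residuals and logged, not fatal); with 100 events or fewer, by Poisson
regression with a log person-time offset, upgraded to quasi-Poisson when
the Pearson χ²/df exceeds 1. Matched analyses use a pair-clustered robust
variance; `compare_incidence(stratified = TRUE)` additionally offers the
pair-stratified Cox model. The distinction matters for simulation-based
validation: the generator's treatment effect is a *conditional* hazard
ratio, and with heterogeneous hazards the marginal matched HR is
attenuated towards 1 by non-collapsibility, while the pair-stratified
estimate targets the conditional parameter. The parameter-recovery test
therefore uses the stratified estimate.

# What the synthetic generator emulates — and what it does not

The generator materializes two latent patient states — a cardiometabolic
burden (prevalence 0.32) and a frailty / bleeding-risk state (0.32) — into
every observable layer: treatment channeling (log-odds −1.6 and −0.8 for
ticagrelor vs clopidogrel, plus age, gender and stratum terms; prasugrel
avoided in the elderly), event hazards (baselines 0.07, 0.015, 0.04, 0.03
events/person-year for ACS, stroke, death, bleeding, with log-hazard
contributions per state and per year of age), blocks of proxy codes in all
six dimensions (90 diagnosis, 90 drug, 55 lab, 20 procedure, 6 visit and
4 LTD codes per state, each firing with probability 0.95–0.99 given the
state and 0.001–0.006 otherwise), and the predefined covariates
(comorbidity profiles, CMU-c, ASA history, ICU, hospital category, stay
duration are near-deterministic functions of the states, the stratum and
age). True treatment effects are conditional hazard ratios of 0.8
(ticagrelor vs clopidogrel, effectiveness components), 0.9 (prasugrel) and
1.25 / 1.4 for bleeding. Small configurable patient fractions violate each
selection criterion so that cohort extraction is exercised; a 4% fraction
receives no APA and ~4% initiate beyond 30 days.

Two deliberate departures from real claims data matter for interpreting
test results. First, the latent state space is *compact* (two binary
states): real confounding is higher-dimensional, and a scalar score can
then balance covariates only in expectation, not patient by patient.
Second, the proxy codes are *high-fidelity* (a diabetic patient in claims
data almost always carries antidiabetic dispensings, HbA1c claims and an
LTD registration, and the generator pushes this to 0.95+), which makes
the confounding learnable at desk scale. Passing tests therefore show the
machinery is correct and the design internally consistent — not that hdPS
matching achieves the same balance on real, messier data.

# Problem sizes, numerical choices and known limitations

The full-scale validation study simulates 20,000 patients (analysis set
≈ 15,400 after selection and treatment assignment), fits the default
forced + 500 model, and matches ≈ 4,500 pairs in under a minute; the
parameter-recovery study uses 20 replicates of 6,000 patients with k = 100
selected covariates, scaling the model dimension with the sample roughly
as in the full-scale study (small-sample hdPS practice scales selection
with n).

One limitation deserves emphasis. Nationwide hdPS-matched cohorts of this
design can bring the maximum absolute standardized difference across all
~516 model covariates below 2%. At the package's simulation scale this
bound is not reachable, and the balance reported by `run_study()` at
n = 20,000 is a maximum of roughly 8–11%. The floor is statistical, not an implementation
artifact, and has two verified components: (i) maximum-likelihood
estimation noise of a 516-parameter logistic model at n ≈ 15,400 — the
average variance of the fitted linear predictor is (p/n)/w̄ ≈ 0.17 (logit
sd ≈ 0.41, matching the measured 0.417) — which leaves
regression-to-the-mean residual confounding on every proxy after matching
on the noisy score; and (ii) the ±1-year age caliper, which under age
channeling admits a systematic within-pair age drift of ~0.7 years
(d ≈ 7%) even when matching on the *true* treatment probability (an
oracle experiment in which all proxy covariates balance to ≤ 1.7%).
Reproducing the sub-2% balance requires an analysis set roughly ten times
larger — the scale of the original nationwide study.

Other numerical conventions, chosen once: ties in the first-stay-of-year
selection break by earlier discharge then lower stay id; age is computed
from year of birth only; the Charlson age weight is one point per
completed decade after 50 (age 60 → 1), with severity hierarchies
(end-organ diabetes, severe liver disease, metastatic tumour supersede
their milder forms); quantile thresholds and score-quintile cuts use type-7
quantiles with ceiling for integer counts; the common-support trim keeps
scores between the larger within-arm minimum and the smaller within-arm
maximum; adjusted analyses enter the hdPS as a continuous covariate.
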