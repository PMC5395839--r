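---
title: "Methods: validity and cost-effectiveness of persistent-albuminuria screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validity and cost-effectiveness of persistent-albuminuria screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albuscreen)
```

## The problem

Persistent albuminuria — urine albumin-to-creatinine ratio (ACR)
≥ 30 mg/g creatinine on samples spanning at least three months — is a
diagnostic criterion for chronic kidney disease (CKD). Spot-urine albumin
excretion is highly variable (posture, hydration, activity, intercurrent
illness), so a single elevated measurement frequently reflects a transient
elevation rather than persistent disease, while the guideline-conform
three-month confirmation protocol loses many patients to follow-up.
`albuscreen` evaluates *short-window* screening strategies: conjunction
rules over samples that can all be collected within two days, judged
against the three-monthly-sample gold standard, and then compared
economically in a screen-and-treat model.

Two linked analyses are implemented. **Part I** is diagnostic validity:
2×2 classification of each strategy against the gold standard, the five
standard proportions (sensitivity, specificity, PPV, NPV, accuracy), and
exact confidence intervals. **Part II** is a hybrid decision-tree/Markov
cohort model translating each strategy's validity into lifetime discounted
costs and QALYs for a screened high-risk population, with deterministic
and probabilistic sensitivity analysis.

## Part I: validity assessment

### Strategies and the gold standard

Each patient record carries five ACR values: first-morning samples on
day 1 and day 2 and in months 2 and 3, plus an afternoon random spot on
day 1. A strategy calls a patient positive when *all* of its required
samples are at or above the threshold (inclusive comparison, default
30 mg/g creatinine). The gold standard is the conjunction over day 1,
month 2 and month 3. Because the gold standard includes the day-1 sample,
the single-morning-sample strategy is structurally 100% sensitive; all
interesting differences between strategies are therefore in specificity
and in what a false positive costs downstream.

### Exact intervals

Confidence intervals for the binomial proportions use the Clopper–Pearson
construction from beta quantiles, with the boundary conventions lower = 0
at zero successes and upper = 1 at full successes. The choice of the exact
method over Wilson or Wald deserves a note: interval bounds printed for
observed cohort results (95.6–100.0 for 82/82, 57.6–79.5 for 52/75)
back-calculate exactly to the Clopper–Pearson form — for 82/82 the lower
bound is $(\alpha/2)^{1/n} = 0.025^{1/82} = 0.956$, and the 52/75 interval
is wider than the Wilson interval would be. A unit test documents this
identification, and all interval cells are additionally checked against
`stats::binom.test()` as an independent oracle. Display rounding is
half-up at the printed precision; all internal computation is at full
precision.

### eGFR

The estimated glomerular filtration rate uses the Chinese-modified MDRD
equation, eGFR = 175·SCr^−1.234^·age^−0.179^ (×0.79 if female), with serum
creatinine in mg/dL and an overload accepting µmol/L (divided by 88.4).
It is provided as cohort-description support and does not enter the
screening rules.

## The synthetic cohort generator

No patient-level dataset is shipped; the generator exists so that the full
pipeline is testable and demonstrable on data with a known truth. It
emulates the statistical structure of a 157-patient high-risk cohort with
82 persistent cases.

### Generative model

For subject $i$ with latent persistence label drawn at prevalence $\pi$
(default 82/157):

$$\log \mathrm{ACR}_{ij} = m_i + b_{\mathrm{month}(j)} + e_{ij}
  \; (+\, \delta \text{ for the afternoon spot}),$$

where $m_i \sim N(\mu_k, \tau^2)$ is the subject set-point (class-specific
location $\mu_k$), $b$ is a month-level *occasion* effect shared by all
samples of the same month (day 1, the random spot and day 2 share the
month-1 occasion), and $e_{ij}$ is day-level residual noise; the random
spot gets additional intraday variance and a positive log-shift $\delta$
for activity-driven daytime excretion. All noise factors are mean-one on
the natural scale, so the set-point is the subject's expected ACR, and
every simulated value is strictly positive — the standard multiplicative
lognormal picture for urinary analytes.

The occasion layer is essential, not decorative. The observed confusion
counts imply that, among gold-standard negatives, day-1 and day-2
positivity are far more concordant (17/75 jointly positive against an
independence expectation of about 0.09) than positivity across months —
transient ACR elevations last days, not months. A model with only
between-subject and per-sample variation cannot reproduce that pattern at
any parameter setting, which is why the generator separates
month-to-month from day-to-day variation. Similarly, the afternoon spot is
positive far more often than the morning sample among gold-negatives
(40/75 vs 23/75) yet equally often among gold-positives (79/82 both),
which requires an upward afternoon *shift*, not merely extra noise.

### Calibration

Default parameter values are fitted, not copied from any table:
`scripts/calibrate_cohort.R` expresses the nine observable conditional
rates (gold-standard prevalence; random/day-2 positivity among
gold-positives, singly and jointly; and the five strategy-relevant
positivity rates among gold-negatives) as two-dimensional integrals over
the set-point and occasion distributions, and minimises the summed squared
logit distance to the observed rates by bounded quasi-Newton search with
multiple starts. The frozen defaults are

| parameter | value | meaning |
|---|---|---|
| `log_acr_mean_persistent` | 5.509 | persistent set-point location (≈ 247 mg/g) |
| `log_acr_mean_transient` | 3.324 | transient set-point location (≈ 28 mg/g, just below threshold) |
| `log_acr_sd_between` | 0.617 | between-subject SD, log scale |
| `cv_month_to_month` | 0.685 | occasion (episode) CV |
| `cv_day_to_day` | 0.523 | day-level residual CV |
| `cv_intraday_extra` | 0.923 | extra CV of the afternoon spot |
| `log_acr_shift_random` | 0.801 | afternoon shift (×2.23 on ACR) |

Fitted residuals are below 0.008 on every rate. The combined within-person
day-to-day variation (occasion plus residual, ≈ 93% CV) sits in the range
long reported for micro-albuminuria variability. The transient set-point
lands just below the threshold, consistent with a cohort recruited for a
*prior* elevated ACR: transient subjects are near the boundary and
regularly exceed it on single samples. The persistent set-point exceeds
the observed baseline median of the persistent group, which is expected:
observed baselines are single truncated measurements (inclusion range
30–300 mg/g), not set-points, and carry negative occasion/noise
corrections on the median scale.

### What the generator does and does not emulate

It reproduces prevalence, the marginal and conditional positivity rates of
all five strategies, and the short-vs-long-range correlation structure. It
does **not** model covariates (diabetes/hypertension status, drugs, eGFR),
macro- vs micro-albuminuria severity classes, dropout, laboratory batch
effects, or any time trend in ACR. Tests passing on synthetic cohorts
therefore validate the *pipeline* under the modelled variability, and the
recovery of the published validity point estimates at large n validates
the calibration — they say nothing about strategy performance in a
population with different variance components.

## Part II: the economic model

### Structure

The decision tree allocates a screened cohort by prevalence and strategy
validity: true cases split into detected (treated) and undetected by
sensitivity; non-cases split into truly negative and falsely treated by
1 − specificity. The four clinical states (negative urine test, treated
screen-positive, symptomatic CKD, dead) cannot simultaneously carry truth
status, treatment status and discontinuation history, so the engine runs
on seven sub-states — `NEG_true`, `NEG_false`, `POS_treated_true`,
`POS_treated_false`, `POS_discontinued`, `SYMPTOMATIC`, `DEAD` — and
`aggregate_trace()` reports the four-state view. Cycles are annual over a
30-year horizon.

Per cycle: undetected cases are re-detected at the annual retest (with
probability equal to the strategy's sensitivity, the natural reading of
"annual retest with the same test") or progress to symptomatic CKD;
treated true cases may remit to negative; treated false positives revert
to negative when their non-disease is recognised; treated patients
discontinue (25% in the first cycle for early side effects, 2% per cycle
thereafter) and never restart. Discontinued false positives return to the
truly-negative pool — a healthy person off the drug is simply a negative
screenee — so `POS_discontinued` holds true cases only, and retains
untreated-case mortality. Symptomatic CKD is absorbing except for death.
Death can occur from every state.

### Mortality composition

Excess mortality is composed on the rate scale,
$p = 1 - (1 - p_0)^{RR}$, with $RR = 1.63$ for untreated cases and
$RR\,(1 - RRR)$, $RRR = 0.24$, for treated cases. The rate-based form
keeps probabilities in [0, 1] for any relative risk; a `multiplicative`
option ($p_0 \times RR$, capped) is provided for comparison.

### Rewards, discounting, cycle conventions

Cycle-$t$ rewards are taken on start-of-cycle occupancy and discounted by
$(1+r)^{-t}$ (end-of-cycle accrual, $r = 5\%$); a half-cycle-correction
flag exists and defaults off. Screening cost (per-round, strategy
specific: ¥24/24/48/72) is charged to the whole cohort once at model start
and to both negative sub-states each cycle (annual retest); treated states
accrue the RAS-inhibitor cost (¥2867.2/yr); symptomatic CKD accrues
kidney-disease care (¥34,205/yr). Utilities are 1.0 for non-case states
(including treated false positives, following the source convention of
background utility 1) and 0.899 for all CKD-case states; treated positives
are not retested.

### Parameters without a literature source

Four transition probabilities and the decision-tree prevalence are
structural necessities that the motivating study never reports. They are
exposed as explicit, overridable configuration, flagged *non-paper* in
every run manifest, and defaulted as follows:

* `prevalence_albuminuria = 0.095` — placeholder for the
  persistent-albuminuria prevalence of the high-risk screened population;
  results scale with it but rankings are insensitive across plausible
  values.
* `p_fn_redetect = NA` → strategy sensitivity — annual retest uses the
  same test.
* `p_progress_symptomatic = 0.05` — undetected early CKD becoming
  symptomatic stage 3–5 within a year; single-digit annual progression is
  the conventional range for early-stage disease.
* `p_recover = 0.02` — treated remission to a truly negative state;
  remission of established persistent albuminuria is uncommon.
* `p_fp_revert = 0.10` — recognition of a treated false positive. Because
  the model (deliberately) does not re-test positives, false positives are
  recognised only incidentally, so a low annual rate is the coherent
  choice; it also governs how long unnecessary treatment is paid for, and
  hence how much a strategy's specificity is worth.

With these defaults the deterministic model ranks the two-day
three-sample strategy highest in effectiveness and the acceptability curve
gives it the clearly highest probability of cost-effectiveness at
¥100,000/QALY, reproducing the qualitative conclusion of the motivating
analysis. Absolute costs, QALY totals and ICERs are *not* comparable to
any published base case: they depend on the four unreported probabilities,
and the published incremental-cost row is internally inconsistent with its
own absolute costs (the package reports raw subtraction and labelled
frontier results instead of guessing). The acceptance checks therefore
assert exact agreement for Part I and structural/oracle properties for
Part II, and only log the Part II calibration demonstration.

### Incremental analysis

`incremental_analysis()` reports both presentations found in applied work:
raw pairwise incrementals and ICERs against a named comparator, and a
frontier analysis — strict dominance (no more costly, no less effective,
one strictly), then extended dominance by iterative removal wherever
consecutive frontier ICERs decrease, with frontier ICERs recomputed after
each removal. A dominated strategy's ICER is a flag, never a negative
number. Tests verify the frontier against an independent greedy
minimum-ICER oracle and the equivalence between NMB maximisation and
frontier choice at every willingness-to-pay.

### Sensitivity analysis

**One-way (tornado).** Each parameter in turn is set to its low and high
bound (±25% for mortality and costs, the 1.5–1.77 and 0.08–0.37
confidence ranges for the relative risks, ±0.145 absolute for the CKD
utility, 0–10% for the discount rate) with everything else at base; the
output is the incremental cost, effect and NMB for a strategy pair, sorted
by NMB swing.

**Probabilistic.** Table-style distribution labels are parameterised as:

* lognormal (mortality, relative risks): median at the central value,
  $\sigma = (\log hi - \log lo)/(2 \times 1.96)$; treatment efficacy is
  sampled on the relative-risk scale $1-RRR$ over (0.63, 0.92), which keeps
  the sampled risk reduction inside (0, 1);
* gamma (costs): moment-matched with a "±25%" range read as a 95%
  interval, $\sigma = 0.25\,\mu/1.96$;
* beta (utility): moment-matched with the ±0.145 half-width read as a 95%
  half-width, $\sigma = 0.145/1.96$; infeasible mean/SD combinations are
  rejected with a diagnostic.

Each PSA draw samples all distributions independently and runs every
strategy on the same draw. Per-strategy sensitivity and specificity are
additionally drawn from the beta distributions implied by the observed
confusion counts (validity is itself an estimate from 157 patients; with
it fixed, one strategy dominates almost every draw and the acceptability
curve degenerates to 0/1). A count of zero false negatives yields the
degenerate point mass at 1. Probabilities that leave [0, 1] after
composition are truncated and the truncation events counted and reported.
Ties in maximal NMB are split equally among the tied strategies, so
acceptabilities always sum to 1. The structural non-paper probabilities
stay fixed in PSA, having no stated uncertainty.

## Numerical and reproducibility choices

* Row-stochasticity of every transition matrix is asserted at 1e−12;
  cohort occupancy conservation is tested at 1e−9 per cycle.
* Zero denominators in validity metrics yield flagged `NA`, never `NaN`.
* Threshold comparison is inclusive (≥); display rounding is half-up;
  internal computation full precision.
* Cohort CSVs are written with 17 significant digits, so
  write-then-read round-trips are exact.
* All randomness flows from user-supplied seeds; `run_all()` derives
  per-stage seeds (cohort = seed, PSA = seed + 1) from one master seed so
  stages are independently reproducible and full pipeline outputs are
  byte-identical across reruns.
* Problem sizes used by the test-suite checks were chosen to keep the
  whole suite fast while leaving Monte-Carlo error well inside the asserted
  tolerances: 10,000-patient cohorts for parameter-recovery checks (three
  binomial standard errors), 1,000 random parameter sets for conservation
  properties, 1,000 random instances for frontier/NMB oracles, and
  100,000 draws for sampler central values (1%).

## Known limitations

* Mortality and CKD incidence are age-constant; no staging between
  "early" and "symptomatic" CKD; no individual-level microsimulation.
* The four structural probabilities are calibration choices; any
  conclusion that depends on their absolute values (total costs, ICERs)
  rather than on orderings should be re-examined under user-supplied
  values.
* The generator models the ratio (ACR) directly rather than albumin and
  creatinine separately, and ignores covariates and dropout.
* Currency is nominal yuan with no inflation adjustment; no
  value-of-information analysis; parameters are sampled independently in
  PSA.
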