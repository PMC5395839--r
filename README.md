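# albuscreen

Screening for **persistent albuminuria** — a urine albumin-to-creatinine
ratio (ACR) ≥ 30 mg/g creatinine on samples spanning at least three months —
is the entry point of chronic kidney disease (CKD) detection in high-risk
patients (diabetes, hypertension, coronary heart disease). Because urinary
albumin excretion fluctuates strongly from day to day and within a day, a
single spot sample misclassifies many patients, while the guideline-based
three-month confirmation is slow enough that many patients never complete
it. `albuscreen` is an R package for asking, quantitatively, which
short-window spot-sampling strategy is worth using instead: it evaluates the
diagnostic validity of candidate strategies against the three-monthly-sample
gold standard and feeds that validity into a decision-analytic
cost-effectiveness model of a screen-and-treat programme.

The package implements, end to end:

* **Screening validity.** Five conjunction strategies built from samples
  collectable within two days — `DAY1` (first-morning sample), `RANDOM`
  (afternoon spot), `DAY1+RANDOM`, `DAY1+DAY2`, `DAY1+RANDOM+DAY2` — are
  classified against the gold standard (`DAY1`, `MONTH2`, `MONTH3` all
  positive). For a 2×2 confusion table the usual proportions are computed,
  e.g. sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP), with **exact
  Clopper–Pearson intervals** from beta quantiles:
  lower = B(α/2; x, n−x+1), upper = B(1−α/2; x+1, n−x).
* **A calibrated synthetic-cohort generator.** No patient-level data are
  distributed with the package; `generate_cohort()` draws per-patient
  five-point ACR records from a multi-level lognormal model (subject
  set-point × month-level occasion effect × day-level noise, plus an
  afternoon shift for the random spot) whose defaults are calibrated so
  that a large cohort reproduces the observed gold-standard prevalence
  (82/157) and each strategy's published sensitivity/specificity.
* **A hybrid decision-tree/Markov model.** The decision tree allocates a
  screened population to starting states by prevalence × sensitivity /
  specificity; a 7-sub-state Markov cohort model (negative true/false,
  treated true/false, discontinued, symptomatic CKD, dead) then runs
  30 annual cycles with RAS-inhibitor treatment of screen-positives, 25%
  first-cycle / 2%-per-cycle treatment discontinuation, differential CKD
  mortality (rate-based composition `1−(1−p₀)^RR`), annual retesting of
  negatives, and 5% discounting of costs (¥) and QALYs.
* **Economic analysis.** Incremental costs/effects and ICERs versus a
  comparator, strict and extended dominance on the efficiency frontier, net
  monetary benefit; one-way (tornado) sensitivity analysis; probabilistic
  sensitivity analysis with lognormal/gamma/beta parameter distributions
  and cost-effectiveness acceptability curves (CEAC).

## Worked example

Simulate a cohort the size of the motivating study, assess validity, then
run the economic model on the observed validity of the four strategies
compared economically:

```r
library(albuscreen)

cohort <- generate_cohort(cohort_sim_params(n_patients = 157, seed = 42))
vt <- validity_table(cohort)
vt[, c("strategy", "tp", "fp", "tn", "fn",
       "sensitivity", "specificity", "accuracy")]
#>           strategy tp fp tn fn sensitivity specificity accuracy
#> 1             DAY1 70 25 62  0       100.0        71.3     84.1
#> 2           RANDOM 66 46 41  4        94.3        47.1     68.2
#> 3      DAY1_RANDOM 66 18 69  4        94.3        79.3     86.0
#> 4        DAY1_DAY2 68 21 66  2        97.1        75.9     85.4
#> 5 DAY1_RANDOM_DAY2 66 17 70  4        94.3        80.5     86.6
```

One simulated draw of a 157-patient cohort behaves like the real one: the
single morning sample is maximally sensitive but wastes a quarter of the
negatives, the afternoon spot alone is the least specific, and the two-day
three-sample strategy trades a little sensitivity for the best specificity
and accuracy. Exact intervals for one strategy:

```r
validity_metrics(build_confusion(cohort, "DAY1_RANDOM_DAY2"))
#> Validity metrics (TP=66, FP=17, TN=70, FN=4)
#>   sensitivity: 94.3% (86.0-98.4)
#>   specificity: 80.5% (70.6-88.2)
#>   PPV:         79.5%
#>   NPV:         94.6%
#>   accuracy:    86.6%
```

Feeding the *observed* cohort-study validity (confusion counts of the four
economically compared strategies) into the Markov model:

```r
study <- data.frame(
  strategy = c("DAY1", "RANDOM", "DAY1_RANDOM", "DAY1_RANDOM_DAY2"),
  tp = c(82, 79, 79, 77), fn = c(0, 3, 3, 5),
  fp = c(23, 40, 18, 14), tn = c(52, 35, 57, 61))
study$sensitivity <- 100 * study$tp / (study$tp + study$fn)
study$specificity <- 100 * study$tn / (study$tn + study$fp)

run_cea(model_parameters(), study)
#> Cost-effectiveness analysis (comparator: DAY1, WTP 1e+05/QALY)
#>           strategy    cost  effect incr_cost incr_effect          dominance
#> 1 DAY1_RANDOM_DAY2 5097.54 13.3847  -752.773 0.000478466               none
#> 2      DAY1_RANDOM 5392.76 13.3845  -457.556 0.000295491 strictly_dominated
#> 3             DAY1 5850.32 13.3842     0.000 0.000000000 strictly_dominated
#> 4           RANDOM 8487.14 13.3845  2636.821 0.000295491 strictly_dominated
```

Under the package defaults the three-sample strategy is both the cheapest
(its higher specificity avoids years of unnecessary treatment, outweighing
its higher per-round screening cost) and the most effective, so it strictly
dominates the alternatives. Acceptability under parameter uncertainty:

```r
psa <- run_psa(model_parameters(), study, 1000, seed = 7)
ceac(psa, 100000)
#>     wtp  DAY1 RANDOM DAY1_RANDOM DAY1_RANDOM_DAY2
#> 1 1e+05 0.099      0       0.314            0.587
```

At a willingness-to-pay of ¥100,000/QALY the three-sample strategy has the
highest probability of being cost-effective. The whole pipeline — cohort,
validity, CEA, tornado, PSA/CEAC, run manifest — can also be driven from a
YAML configuration: `run_all("inst/extdata/params.yaml", "results/")`, or
from a shell via `Rscript inst/scripts/run_pipeline.R --config ... --out
...`.

Absolute costs and QALY totals depend on a handful of transition
probabilities that the underlying cohort study never measured (documented
as *non-paper* defaults in `?model_parameters` and in every run manifest),
so they are reported as model outputs, not as reproductions of any
published base case; the vignette discusses which conclusions are robust to
that calibration and which are not.

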