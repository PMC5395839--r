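#' @keywords internal
.strategy_samples <- list(
  DAY1             = "acr_day1",
  RANDOM           = "acr_random",
  DAY1_RANDOM      = c("acr_day1", "acr_random"),
  DAY1_DAY2        = c("acr_day1", "acr_day2"),
  DAY1_RANDOM_DAY2 = c("acr_day1", "acr_random", "acr_day2"),
  GOLD             = c("acr_day1", "acr_month2", "acr_month3"))

#' Names of the available screening strategies
#'
#' The five alternative strategies test samples collected within two days
#' (single first-morning sample, single random spot, and their
#' conjunctions); `GOLD` is the reference standard requiring abnormal ACR on
#' first-morning samples spanning three consecutive months.
#'
#' @return Character vector of strategy names.
#' @export
screening_strategies <- function() names(.strategy_samples)

#' Definition of a screening strategy
#'
#' A strategy is a conjunction rule: it calls a patient positive when every
#' one of its required samples has ACR at or above the threshold.
#'
#' @param name one of `screening_strategies()`.
#' @return A list of class `strategy_definition` with elements `name` and
#'   `required_samples`.
#' @export
strategy_definition <- function(name) {
  name <- match.arg(name, screening_strategies())
  structure(list(name = name, required_samples = .strategy_samples[[name]]),
            class = "strategy_definition")
}

#' Apply a screening strategy to a cohort
#'
#' @param strategy a strategy name or a [strategy_definition()].
#' @param cohort an `acr_cohort` data frame (a single-row data frame works
#'   for one patient).
#' @param threshold positivity threshold in mg/g creatinine; the comparison
#'   is inclusive (ACR >= threshold is positive).
#' @return Logical vector: is each patient strategy-positive?
#' @export
apply_strategy <- function(strategy, cohort, threshold = 30) {
  if (is.character(strategy)) strategy <- strategy_definition(strategy)
  if (!inherits(strategy, "strategy_definition"))
    stop("'strategy' must be a strategy name or definition", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number", call. = FALSE)
  missing_cols <- setdiff(strategy$required_samples, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required sample(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pos <- rep(TRUE, nrow(cohort))
  for (nm in strategy$required_samples) {
    v <- cohort[[nm]]
    if (anyNA(v))
      stop("missing values in required sample '", nm, "'", call. = FALSE)
    pos <- pos & v >= threshold
  }
  pos
}

#' Construct a 2x2 confusion table
#'
#' @param tp,fp,tn,fn non-negative integer counts (true/false
#'   positives/negatives against the gold standard).
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("confusion table must contain at least one observation",
         call. = FALSE)
  structure(as.list(counts), class = "confusion_table")
}

#' Cross-classify a strategy against the gold standard
#'
#' Classifies every patient with both the given strategy and the
#' three-monthly-sample gold standard on the same records and tabulates the
#' 2x2 agreement.
#'
#' @inheritParams apply_strategy
#' @return A [confusion_table()].
#' @export
build_confusion <- function(cohort, strategy, threshold = 30) {
  if (nrow(cohort) == 0)
    stop("cohort is empty", call. = FALSE)
  test <- apply_strategy(strategy, cohort, threshold)
  gold <- apply_strategy("GOLD", cohort, threshold)
  confusion_table(tp = sum(test & gold), fp = sum(test & !gold),
                  tn = sum(!test & !gold), fn = sum(!test & gold))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, from beta-distribution
#' quantiles. The lower bound is exactly 0 when `successes = 0` and the upper
#' bound exactly 1 when `successes = n`.
#'
#' @param successes,n number of successes and trials (vectorised).
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @return A two-column matrix with columns `lower` and `upper` (a single
#'   named vector when the inputs are scalar).
#' @export
clopper_pearson <- function(successes, n, alpha = 0.05) {
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (any(successes < 0 | successes > n))
    stop("'successes' must lie in [0, n]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  lower <- ifelse(successes == 0, 0,
                  stats::qbeta(alpha / 2, successes, n - successes + 1))
  upper <- ifelse(successes == n, 1,
                  stats::qbeta(1 - alpha / 2, successes + 1, n - successes))
  if (length(lower) == 1L) return(c(lower = lower, upper = upper))
  cbind(lower = lower, upper = upper)
}

# proportion with an undefined-on-zero-denominator flag (NA, never NaN)
.safe_prop <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic validity metrics with exact confidence intervals
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, accuracy and the false positive/negative rates from a 2x2
#' confusion table, each as a proportion in \[0, 1\], with exact
#' Clopper-Pearson intervals for sensitivity, specificity and the two error
#' rates. A metric whose denominator is zero is reported as `NA` (undefined)
#' rather than propagating `NaN`.
#'
#' @param ct a [confusion_table()].
#' @param alpha two-sided significance level for the intervals.
#' @return An object of class `validity_metrics`.
#' @export
validity_metrics <- function(ct, alpha = 0.05) {
  if (!inherits(ct, "confusion_table"))
    stop("'ct' must be a 'confusion_table'", call. = FALSE)
  tp <- ct$tp; fp <- ct$fp; tn <- ct$tn; fn <- ct$fn
  n_pos <- tp + fn   # gold-standard positives
  n_neg <- tn + fp
  m <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = .safe_prop(tp, n_pos),
    specificity = .safe_prop(tn, n_neg),
    ppv = .safe_prop(tp, tp + fp),
    npv = .safe_prop(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    false_positive_rate = .safe_prop(fp, n_neg),
    false_negative_rate = .safe_prop(fn, n_pos),
    ci_sensitivity = if (n_pos > 0) clopper_pearson(tp, n_pos, alpha)
                     else c(lower = NA_real_, upper = NA_real_),
    ci_specificity = if (n_neg > 0) clopper_pearson(tn, n_neg, alpha)
                     else c(lower = NA_real_, upper = NA_real_),
    ci_fp_rate = if (n_neg > 0) clopper_pearson(fp, n_neg, alpha)
                 else c(lower = NA_real_, upper = NA_real_),
    ci_fn_rate = if (n_pos > 0) clopper_pearson(fn, n_pos, alpha)
                 else c(lower = NA_real_, upper = NA_real_),
    alpha = alpha)
  structure(m, class = "validity_metrics")
}

#' Round half-up to a fixed number of decimals
#'
#' Display rounding used when reporting percentages (half-up, unlike base
#' `round()`'s round-half-even); internal computation is always at full
#' precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
print.validity_metrics <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "undef.",
                            sprintf("%.1f%%", round_half_up(100 * v, 1)))
  ci <- function(v) if (anyNA(v)) "" else
    sprintf(" (%.1f-%.1f)", round_half_up(100 * v[1], 1),
            round_half_up(100 * v[2], 1))
  cat("Validity metrics (TP=", x$tp, ", FP=", x$fp, ", TN=", x$tn,
      ", FN=", x$fn, ")\n", sep = "")
  cat("  sensitivity: ", pct(x$sensitivity), ci(x$ci_sensitivity), "\n",
      "  specificity: ", pct(x$specificity), ci(x$ci_specificity), "\n",
      "  PPV:         ", pct(x$ppv), "\n",
      "  NPV:         ", pct(x$npv), "\n",
      "  accuracy:    ", pct(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Validity table for a set of strategies on one cohort
#'
#' One row per strategy with the confusion counts, the validity proportions
#' (as percentages) and the exact CI bounds — the tabular summary of a
#' screening-validity study.
#'
#' @param cohort an `acr_cohort` data frame.
#' @param strategies strategy names to evaluate (default: the five
#'   alternative strategies, excluding the gold standard itself).
#' @param threshold positivity threshold, mg/g creatinine.
#' @param alpha two-sided significance level for the intervals.
#' @return A data frame of class `validity_table`.
#' @export
validity_table <- function(cohort,
                           strategies = setdiff(screening_strategies(),
                                                "GOLD"),
                           threshold = 30, alpha = 0.05) {
  rows <- lapply(strategies, function(s) {
    ct <- build_confusion(cohort, s, threshold)
    vm <- validity_metrics(ct, alpha)
    data.frame(strategy = s, tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn,
               sensitivity = 100 * vm$sensitivity,
               specificity = 100 * vm$specificity,
               ppv = 100 * vm$ppv, npv = 100 * vm$npv,
               accuracy = 100 * vm$accuracy,
               fp_rate = 100 * vm$false_positive_rate,
               fn_rate = 100 * vm$false_negative_rate,
               sens_ci_lower = 100 * vm$ci_sensitivity[["lower"]],
               sens_ci_upper = 100 * vm$ci_sensitivity[["upper"]],
               spec_ci_lower = 100 * vm$ci_specificity[["lower"]],
               spec_ci_upper = 100 * vm$ci_specificity[["upper"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validity_table", "data.frame")
  out
}

#' Estimated glomerular filtration rate (Chinese-modified MDRD equation)
#'
#' `eGFR = 175 x SCr^-1.234 x age^-0.179`, multiplied by 0.79 for women,
#' with serum creatinine in mg/dL. Creatinine reported in umol/L is divided
#' by 88.4 first.
#'
#' @param scr serum creatinine (> 0).
#' @param age age in years (> 0).
#' @param female logical; apply the 0.79 female factor.
#' @param scr_unit `"mg_dl"` (default) or `"umol_l"`.
#' @return eGFR in mL/min/1.73 m^2 (vectorised).
#' @export
compute_egfr <- function(scr, age, female = FALSE,
                         scr_unit = c("mg_dl", "umol_l")) {
  scr_unit <- match.arg(scr_unit)
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("'scr' must be positive and finite", call. = FALSE)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("'age' must be positive and finite", call. = FALSE)
  if (scr_unit == "umol_l") scr <- scr / 88.4
  175 * scr^-1.234 * age^-0.179 * ifelse(female, 0.79, 1)
}
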