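#' @keywords internal
.markov_states <- c("NEG_true", "NEG_false", "POS_treated_true",
                    "POS_treated_false", "POS_discontinued",
                    "SYMPTOMATIC", "DEAD")

# parameters whose defaults are not sourced from the study's parameter table
# (they are required by the state-transition structure but never printed);
# every one is overridable and echoed as non-paper provenance in run manifests
.non_paper_params <- c("prevalence_albuminuria", "p_fn_redetect",
                       "p_progress_symptomatic", "p_fp_revert", "p_recover")

#' Parameters of the screening cost-effectiveness model
#'
#' Collects every input of the hybrid decision-tree/Markov model: annual
#' mortality and relative risks, costs (Chinese yuan), utilities, the
#' discounting and discontinuation rules, the decision-tree prevalence, and
#' the per-cycle transition probabilities of the expanded state space.
#'
#' The Markov cohort model runs on seven expanded sub-states of the four
#' clinical states (negative urine test / screen-detected treated CKD /
#' symptomatic CKD / dead): `NEG_true` (truly negative, annually retested),
#' `NEG_false` (undetected true case), `POS_treated_true` (true case on
#' RAS-inhibitor treatment), `POS_treated_false` (false positive on
#' treatment), `POS_discontinued` (true case that stopped treatment and does
#' not restart), `SYMPTOMATIC` (symptomatic CKD receiving kidney-disease
#' care) and the absorbing `DEAD`.
#'
#' Four transition probabilities (`p_fn_redetect`, `p_progress_symptomatic`,
#' `p_fp_revert`, `p_recover`) and `prevalence_albuminuria` are structural
#' inputs with package-chosen defaults (flagged *non-paper* in run
#' manifests); `p_fn_redetect = NA` means "use the screening strategy's own
#' sensitivity at the annual retest", which is the default.
#'
#' @param general_mortality annual background death probability.
#' @param rr_ckd_mortality relative risk of death for untreated CKD (>= 1).
#' @param rrr_treatment relative risk reduction of CKD mortality on
#'   treatment, in \[0, 1\].
#' @param screening_costs named vector of per-round screening costs (yuan)
#'   for the strategies compared in the economic analysis.
#' @param ras_inhibitor_annual_cost annual RAS-inhibitor (ACEI/ARB) cost.
#' @param ckd_annual_cost annual symptomatic CKD care cost.
#' @param utility_ckd QALY weight of (any) CKD state, in \[0, 1\].
#' @param utility_background QALY weight of the non-case states.
#' @param discount_rate annual discount rate applied to costs and QALYs.
#' @param horizon_years model horizon in 1-year cycles.
#' @param discontinue_first_cycle fraction of treated patients stopping
#'   treatment in the first model cycle (early side effects).
#' @param discontinue_annual fraction stopping in each later cycle
#'   (noncompliance); discontinued patients never restart.
#' @param prevalence_albuminuria persistent-albuminuria prevalence in the
#'   screened population, feeding the decision tree (non-paper default).
#' @param p_fn_redetect per-cycle probability an undetected case is picked up
#'   at the annual retest; `NA` = use the strategy's sensitivity.
#' @param p_progress_symptomatic per-cycle probability an undetected case
#'   becomes symptomatic CKD.
#' @param p_fp_revert per-cycle probability a treated false positive reverts
#'   to the negative state (treatment stopped).
#' @param p_recover per-cycle probability a treated true case remits to the
#'   negative state.
#' @param wtp_threshold willingness-to-pay per QALY (yuan).
#' @param half_cycle_correction average start- and end-of-cycle occupancy
#'   when accruing rewards (default `FALSE`: end-of-cycle accrual).
#' @param mortality_composition how excess mortality composes with the
#'   background probability: `"rate"` (default), `p = 1 - (1 - p0)^RR`,
#'   which stays in \[0, 1\] for any RR, or `"multiplicative"`,
#'   `p = min(p0 x RR, 1)`.
#' @param initial_screening_charged charge one round of screening to the
#'   whole cohort at model start (cycle 0, undiscounted).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(general_mortality = 0.0119,
                             rr_ckd_mortality = 1.63,
                             rrr_treatment = 0.24,
                             screening_costs = c(DAY1 = 24.0, RANDOM = 24.0,
                                                 DAY1_RANDOM = 48.0,
                                                 DAY1_RANDOM_DAY2 = 72.0),
                             ras_inhibitor_annual_cost = 2867.2,
                             ckd_annual_cost = 34205.0,
                             utility_ckd = 0.899,
                             utility_background = 1.0,
                             discount_rate = 0.05,
                             horizon_years = 30,
                             discontinue_first_cycle = 0.25,
                             discontinue_annual = 0.02,
                             prevalence_albuminuria = 0.095,
                             p_fn_redetect = NA_real_,
                             p_progress_symptomatic = 0.05,
                             p_fp_revert = 0.10,
                             p_recover = 0.02,
                             wtp_threshold = 100000,
                             half_cycle_correction = FALSE,
                             mortality_composition = c("rate",
                                                       "multiplicative"),
                             initial_screening_charged = TRUE) {
  p <- list(general_mortality = general_mortality,
            rr_ckd_mortality = rr_ckd_mortality,
            rrr_treatment = rrr_treatment,
            screening_costs = screening_costs,
            ras_inhibitor_annual_cost = ras_inhibitor_annual_cost,
            ckd_annual_cost = ckd_annual_cost,
            utility_ckd = utility_ckd,
            utility_background = utility_background,
            discount_rate = discount_rate,
            horizon_years = horizon_years,
            discontinue_first_cycle = discontinue_first_cycle,
            discontinue_annual = discontinue_annual,
            prevalence_albuminuria = prevalence_albuminuria,
            p_fn_redetect = p_fn_redetect,
            p_progress_symptomatic = p_progress_symptomatic,
            p_fp_revert = p_fp_revert,
            p_recover = p_recover,
            wtp_threshold = wtp_threshold,
            half_cycle_correction = isTRUE(half_cycle_correction),
            mortality_composition = match.arg(mortality_composition),
            initial_screening_charged = isTRUE(initial_screening_charged))
  .validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

.validate_model_parameters <- function(p) {
  probs <- c("general_mortality", "rrr_treatment", "discount_rate",
             "discontinue_first_cycle", "discontinue_annual",
             "prevalence_albuminuria", "p_progress_symptomatic",
             "p_fp_revert", "p_recover", "utility_ckd",
             "utility_background")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.na(p$p_fn_redetect) &&
      (p$p_fn_redetect < 0 || p$p_fn_redetect > 1))
    stop("'p_fn_redetect' must be NA or in [0, 1]", call. = FALSE)
  if (!is.numeric(p$rr_ckd_mortality) || p$rr_ckd_mortality < 1)
    stop("'rr_ckd_mortality' must be >= 1", call. = FALSE)
  costs <- c(p$screening_costs, p$ras_inhibitor_annual_cost,
             p$ckd_annual_cost)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("costs must be non-negative and finite", call. = FALSE)
  if (p$horizon_years < 1 || p$horizon_years != round(p$horizon_years))
    stop("'horizon_years' must be a positive integer", call. = FALSE)
  if (p$wtp_threshold < 0)
    stop("'wtp_threshold' must be >= 0", call. = FALSE)
  invisible(p)
}

#' Discount factor for a given cycle
#'
#' End-of-cycle convention: rewards accrued during cycle `t` (1-based) are
#' multiplied by `(1 + rate)^-t`; `t = 0` anchors the undiscounted model
#' start.
#'
#' @param rate annual discount rate (>= 0).
#' @param t cycle index (>= 0, vectorised).
#' @return Discount multiplier(s).
#' @export
discount_factor <- function(rate, t) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate < 0)
    stop("'rate' must be a single non-negative number", call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  (1 + rate)^(-t)
}

#' Initial state allocation from the decision tree
#'
#' Allocates the screened cohort to the Markov starting states from the
#' population prevalence of persistent albuminuria and the screening
#' strategy's sensitivity and specificity: true cases split into treated
#' (detected) and undetected by sensitivity; non-cases split into truly
#' negative and falsely treated by specificity.
#'
#' @param prevalence persistent-albuminuria prevalence in \[0, 1\].
#' @param validity a [validity_metrics()] object, or a list/vector with
#'   elements `sensitivity` and `specificity` as fractions in \[0, 1\].
#' @return Named occupancy vector over the seven model states, summing to 1.
#' @export
initial_distribution <- function(prevalence, validity) {
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("'prevalence' must lie in [0, 1]", call. = FALSE)
  sens <- validity[["sensitivity"]]
  spec <- validity[["specificity"]]
  if (is.null(sens) || is.null(spec) || is.na(sens) || is.na(spec))
    stop("sensitivity and specificity must be defined", call. = FALSE)
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  v <- stats::setNames(numeric(length(.markov_states)), .markov_states)
  v["POS_treated_true"]  <- prevalence * sens
  v["NEG_false"]         <- prevalence * (1 - sens)
  v["POS_treated_false"] <- (1 - prevalence) * (1 - spec)
  v["NEG_true"]          <- (1 - prevalence) * spec
  v
}

# per-cycle death probabilities for the three mortality tiers
.death_probs <- function(p) {
  p0 <- p$general_mortality
  rr <- p$rr_ckd_mortality
  rr_tr <- rr * (1 - p$rrr_treatment)
  if (p$mortality_composition == "rate") {
    c(bg = p0, case = 1 - (1 - p0)^rr, treated = 1 - (1 - p0)^rr_tr)
  } else {
    c(bg = p0, case = min(p0 * rr, 1), treated = min(p0 * rr_tr, 1))
  }
}

#' Per-cycle transition matrix of the Markov model
#'
#' Builds the row-stochastic transition operator for one cycle. Death may
#' occur from every state: at the background probability for non-case states
#' (`NEG_true`, `POS_treated_false`), at case-level risk for untreated cases
#' (`NEG_false`, `POS_discontinued`, `SYMPTOMATIC`) and at treatment-reduced
#' case risk for `POS_treated_true`. Among survivors: undetected cases are
#' re-detected at the annual retest or progress to symptomatic CKD; treated
#' true cases discontinue (first-cycle vs later-cycle fraction) or remit to
#' negative; treated false positives stop treatment by discontinuation or
#' test reversion, returning to the truly-negative pool.
#'
#' @param params a [model_parameters()] object.
#' @param cycle_index 1-based cycle number; the first cycle uses
#'   `discontinue_first_cycle`, later cycles `discontinue_annual`.
#' @param sensitivity strategy sensitivity used for re-detection when
#'   `params$p_fn_redetect` is `NA`.
#' @return A 7x7 row-stochastic matrix with dimnames over the model states.
#' @export
build_transition <- function(params, cycle_index, sensitivity = NULL) {
  if (!inherits(params, "model_parameters"))
    stop("'params' must be a 'model_parameters' object", call. = FALSE)
  if (cycle_index < 1 || cycle_index != round(cycle_index))
    stop("'cycle_index' must be a positive integer", call. = FALSE)
  p_fn <- params$p_fn_redetect
  if (is.na(p_fn)) {
    if (is.null(sensitivity))
      stop("'sensitivity' is required when p_fn_redetect is NA",
           call. = FALSE)
    p_fn <- sensitivity
  }
  dp <- .death_probs(params)
  d_t <- if (cycle_index == 1) params$discontinue_first_cycle
         else params$discontinue_annual
  s <- .markov_states
  M <- matrix(0, 7, 7, dimnames = list(s, s))

  M["NEG_true", "DEAD"] <- dp["bg"]
  M["NEG_true", "NEG_true"] <- 1 - dp["bg"]

  surv <- 1 - dp["case"]
  M["NEG_false", "DEAD"] <- dp["case"]
  M["NEG_false", "POS_treated_true"] <- surv * p_fn
  M["NEG_false", "SYMPTOMATIC"] <- surv * (1 - p_fn) *
    params$p_progress_symptomatic
  M["NEG_false", "NEG_false"] <- surv * (1 - p_fn) *
    (1 - params$p_progress_symptomatic)

  surv <- 1 - dp["treated"]
  M["POS_treated_true", "DEAD"] <- dp["treated"]
  M["POS_treated_true", "POS_discontinued"] <- surv * d_t
  M["POS_treated_true", "NEG_true"] <- surv * (1 - d_t) * params$p_recover
  M["POS_treated_true", "POS_treated_true"] <- surv * (1 - d_t) *
    (1 - params$p_recover)

  surv <- 1 - dp["bg"]
  M["POS_treated_false", "DEAD"] <- dp["bg"]
  # discontinuation and reversion both end treatment of a non-case: back to
  # the truly-negative, annually-retested pool
  leave <- d_t + (1 - d_t) * params$p_fp_revert
  M["POS_treated_false", "NEG_true"] <- surv * leave
  M["POS_treated_false", "POS_treated_false"] <- surv * (1 - leave)

  M["POS_discontinued", "DEAD"] <- dp["case"]
  M["POS_discontinued", "POS_discontinued"] <- 1 - dp["case"]

  M["SYMPTOMATIC", "DEAD"] <- dp["case"]
  M["SYMPTOMATIC", "SYMPTOMATIC"] <- 1 - dp["case"]

  M["DEAD", "DEAD"] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12))
    stop("internal consistency error: transition rows do not sum to 1",
         call. = FALSE)
  M
}

#' Run the Markov cohort model for one screening strategy
#'
#' Starts from the decision-tree allocation of [initial_distribution()] and
#' iterates the per-cycle transition operator over the model horizon,
#' accruing per-cycle costs (annual retest for the negative states,
#' RAS-inhibitor cost for the treated states, kidney-disease care for
#' symptomatic CKD) and QALYs (background utility for non-case states, the
#' CKD utility for case states, zero when dead). Rewards for cycle `t` are
#' taken on start-of-cycle occupancy and discounted by
#' `discount_factor(rate, t)`; the optional initial screening round is
#' charged undiscounted at cycle 0.
#'
#' @param params a [model_parameters()] object.
#' @param validity sensitivity/specificity input, as for
#'   [initial_distribution()].
#' @param screening_cost per-round cost of this strategy; when `NULL` and
#'   `strategy` is given, looked up in `params$screening_costs`.
#' @param strategy optional strategy name used for the cost lookup and
#'   carried in the output.
#' @return An object of class `cohort_trace`: a list with the per-cycle
#'   `trace` data frame (state occupancies, undiscounted and discounted cost
#'   and QALY accruals), and cumulative discounted `total_cost` and
#'   `total_qaly`.
#' @export
run_markov <- function(params, validity, screening_cost = NULL,
                       strategy = NULL) {
  if (!inherits(params, "model_parameters"))
    stop("'params' must be a 'model_parameters' object", call. = FALSE)
  if (is.null(screening_cost)) {
    if (is.null(strategy) || !strategy %in% names(params$screening_costs))
      stop("supply 'screening_cost' or a 'strategy' present in ",
           "params$screening_costs", call. = FALSE)
    screening_cost <- params$screening_costs[[strategy]]
  }
  sens <- validity[["sensitivity"]]
  v <- initial_distribution(params$prevalence_albuminuria, validity)
  H <- params$horizon_years
  # the transition operator only differs between the first and later cycles
  P1 <- build_transition(params, 1, sens)
  P2 <- if (H > 1) build_transition(params, 2, sens) else NULL

  occ <- matrix(0, H + 1, 7, dimnames = list(NULL, .markov_states))
  occ[1, ] <- v
  cost_u <- qaly_u <- cost_d <- qaly_d <- numeric(H + 1)
  if (params$initial_screening_charged) {
    cost_u[1] <- screening_cost
    cost_d[1] <- screening_cost
  }
  u_bg <- params$utility_background
  u_ckd <- params$utility_ckd
  for (t in seq_len(H)) {
    P <- if (t == 1) P1 else P2
    v_next <- drop(v %*% P)
    w <- if (params$half_cycle_correction) (v + v_next) / 2 else v
    cost_t <- screening_cost * (w[["NEG_true"]] + w[["NEG_false"]]) +
      params$ras_inhibitor_annual_cost *
        (w[["POS_treated_true"]] + w[["POS_treated_false"]]) +
      params$ckd_annual_cost * w[["SYMPTOMATIC"]]
    qaly_t <- u_bg * (w[["NEG_true"]] + w[["POS_treated_false"]]) +
      u_ckd * (w[["NEG_false"]] + w[["POS_treated_true"]] +
               w[["POS_discontinued"]] + w[["SYMPTOMATIC"]])
    disc <- discount_factor(params$discount_rate, t)
    cost_u[t + 1] <- cost_t
    qaly_u[t + 1] <- qaly_t
    cost_d[t + 1] <- cost_t * disc
    qaly_d[t + 1] <- qaly_t * disc
    v <- v_next
    occ[t + 1, ] <- v
  }
  trace <- data.frame(cycle = 0:H, occ,
                      cost = cost_u, qaly = qaly_u,
                      cost_disc = cost_d, qaly_disc = qaly_d)
  structure(list(strategy = strategy,
                 trace = trace,
                 total_cost = sum(cost_d),
                 total_qaly = sum(qaly_d),
                 sensitivity = sens,
                 specificity = validity[["specificity"]],
                 screening_cost = screening_cost,
                 params = params),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Markov cohort trace",
      if (!is.null(x$strategy)) paste0(" [", x$strategy, "]"), "\n",
      "  horizon: ", nrow(x$trace) - 1, " cycles\n",
      "  discounted total cost:  ", format(x$total_cost, digits = 7), "\n",
      "  discounted total QALYs: ", format(x$total_qaly, digits = 7), "\n",
      sep = "")
  invisible(x)
}

#' Aggregate an expanded trace to the four clinical states
#'
#' Collapses the seven modelled sub-states to the four clinical states of
#' the screening pathway: negative urine test, screen-detected (positive)
#' CKD, symptomatic CKD, and dead.
#'
#' @param trace a `cohort_trace` object.
#' @return Data frame with columns `cycle`, `NEGATIVE`, `POSITIVE`,
#'   `SYMPTOMATIC`, `DEAD`.
#' @export
aggregate_trace <- function(trace) {
  tr <- trace$trace
  data.frame(cycle = tr$cycle,
             NEGATIVE = tr$NEG_true + tr$NEG_false,
             POSITIVE = tr$POS_treated_true + tr$POS_treated_false +
               tr$POS_discontinued,
             SYMPTOMATIC = tr$SYMPTOMATIC,
             DEAD = tr$DEAD)
}
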