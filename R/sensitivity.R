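#' Declare a sampling distribution for one model parameter
#'
#' Describes how a parameter is sampled in probabilistic sensitivity
#' analysis. Supported families and their parameterisations:
#'
#' * `fixed` — every draw equals `central`.
#' * `lognormal` — `meanlog = log(central)` (so `central` is the median) and
#'   `sdlog = (log(high) - log(low)) / (2 x 1.96)`, reading `(low, high)` as
#'   a 95% interval. A `half_width` fraction `f` expands to
#'   `low = central (1 - f)`, `high = central (1 + f)`.
#' * `gamma` — moment-matched to mean `central` and
#'   `sd = half_width x central / 1.96` (a "+/- f" range read as a 95%
#'   interval); an explicit `sd` overrides.
#' * `beta` — moment-matched to mean `central` and
#'   `sd = half_width / 1.96` (an absolute "+/- h" half-width read as a 95%
#'   half-width); an explicit `sd` overrides. Infeasible mean/sd
#'   combinations (`sd^2 >= central (1 - central)`) are rejected with a
#'   diagnostic.
#'
#' @param name parameter name (a [model_parameters()] field, a
#'   `screening_cost_<STRATEGY>` entry, or `rr_treatment` for the treated
#'   relative risk `1 - rrr_treatment`).
#' @param family `"fixed"`, `"lognormal"`, `"gamma"` or `"beta"`.
#' @param central central value (median for lognormal, mean otherwise).
#' @param low,high explicit 95% range bounds (lognormal).
#' @param half_width fractional (`gamma`, `lognormal`) or absolute (`beta`)
#'   half-width of the 95% range.
#' @param sd explicit standard deviation (gamma, beta).
#' @return An object of class `parameter_distribution`.
#' @export
parameter_distribution <- function(name,
                                   family = c("fixed", "lognormal",
                                              "gamma", "beta"),
                                   central, low = NULL, high = NULL,
                                   half_width = NULL, sd = NULL) {
  family <- match.arg(family)
  if (!is.numeric(central) || length(central) != 1L || !is.finite(central))
    stop("'central' must be a single finite number", call. = FALSE)
  spec <- structure(list(name = name, family = family, central = central,
                         low = low, high = high, half_width = half_width,
                         sd = sd),
                    class = "parameter_distribution")
  parameterize_distribution(spec)  # validate eagerly
  spec
}

#' Build a sampler from a parameter distribution
#'
#' @param spec a [parameter_distribution()].
#' @return A function of `n` returning `n` draws; deterministic given the
#'   RNG state.
#' @export
parameterize_distribution <- function(spec) {
  if (!inherits(spec, "parameter_distribution"))
    stop("'spec' must be a 'parameter_distribution'", call. = FALSE)
  central <- spec$central
  z975 <- stats::qnorm(0.975)
  switch(spec$family,
    fixed = function(n) rep(central, n),
    lognormal = {
      low <- spec$low; high <- spec$high
      if (is.null(low) || is.null(high)) {
        if (is.null(spec$half_width))
          stop("lognormal for '", spec$name,
               "' needs (low, high) or half_width", call. = FALSE)
        low <- central * (1 - spec$half_width)
        high <- central * (1 + spec$half_width)
      }
      if (low <= 0 || high <= low || central <= 0)
        stop("lognormal for '", spec$name,
             "' needs 0 < low < high and central > 0", call. = FALSE)
      meanlog <- log(central)
      sdlog <- (log(high) - log(low)) / (2 * z975)
      function(n) stats::rlnorm(n, meanlog, sdlog)
    },
    gamma = {
      sd <- spec$sd
      if (is.null(sd)) {
        if (is.null(spec$half_width))
          stop("gamma for '", spec$name, "' needs half_width or sd",
               call. = FALSE)
        sd <- spec$half_width * central / z975
      }
      if (central <= 0 || sd <= 0)
        stop("gamma for '", spec$name, "' needs positive mean and sd",
             call. = FALSE)
      shape <- (central / sd)^2
      rate <- shape / central
      function(n) stats::rgamma(n, shape = shape, rate = rate)
    },
    beta = {
      sd <- spec$sd
      if (is.null(sd)) {
        if (is.null(spec$half_width))
          stop("beta for '", spec$name, "' needs half_width or sd",
               call. = FALSE)
        sd <- spec$half_width / z975
      }
      if (central <= 0 || central >= 1)
        stop("beta for '", spec$name, "' needs mean in (0, 1)",
             call. = FALSE)
      if (sd^2 >= central * (1 - central))
        stop("beta for '", spec$name, "' infeasible: sd^2 = ",
             signif(sd^2, 4), " >= mean(1-mean) = ",
             signif(central * (1 - central), 4), call. = FALSE)
      nu <- central * (1 - central) / sd^2 - 1
      function(n) stats::rbeta(n, shape1 = central * nu,
                               shape2 = (1 - central) * nu)
    })
}

#' Default PSA distributions for the model parameters
#'
#' Mortality and relative risks are lognormal (background mortality over a
#' +/- 25% range, the CKD mortality relative risk over its 1.5-1.77
#' confidence interval, and treatment efficacy sampled on the relative-risk
#' scale `1 - rrr` over the interval implied by the 0.08-0.37 risk-reduction
#' range). Costs are gamma over +/- 25% ranges; the CKD utility is beta with
#' an absolute +/- 0.145 half-width. The structural (non-paper) transition
#' probabilities stay fixed.
#'
#' @param params a [model_parameters()] object.
#' @param rrr_range 95% range of the relative risk reduction of CKD
#'   mortality on treatment.
#' @return Named list of [parameter_distribution()] objects.
#' @export
default_psa_distributions <- function(params,
                                      rrr_range = c(0.08, 0.37)) {
  specs <- list(
    parameter_distribution("general_mortality", "lognormal",
                           params$general_mortality, half_width = 0.25),
    parameter_distribution("rr_ckd_mortality", "lognormal",
                           params$rr_ckd_mortality, low = 1.5, high = 1.77),
    # efficacy on the RR scale keeps the sampled RRR inside (0, 1)
    parameter_distribution("rr_treatment", "lognormal",
                           1 - params$rrr_treatment,
                           low = 1 - max(rrr_range),
                           high = 1 - min(rrr_range)),
    parameter_distribution("ras_inhibitor_annual_cost", "gamma",
                           params$ras_inhibitor_annual_cost,
                           half_width = 0.25),
    parameter_distribution("ckd_annual_cost", "gamma",
                           params$ckd_annual_cost, half_width = 0.25),
    parameter_distribution("utility_ckd", "beta", params$utility_ckd,
                           half_width = 0.145))
  for (s in names(params$screening_costs))
    specs <- c(specs, list(parameter_distribution(
      paste0("screening_cost_", s), "gamma",
      params$screening_costs[[s]], half_width = 0.25)))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

# set one (possibly derived) parameter on a model_parameters object,
# clamping probabilities into [0, 1]; returns list(params, n_clamped)
.set_param <- function(params, name, value) {
  clamped <- 0L
  clamp01 <- function(v) {
    if (v < 0 || v > 1) clamped <<- clamped + 1L
    min(max(v, 0), 1)
  }
  if (name == "rr_treatment") {
    params$rrr_treatment <- clamp01(1 - value)
  } else if (startsWith(name, "screening_cost_")) {
    s <- sub("^screening_cost_", "", name)
    if (!s %in% names(params$screening_costs))
      stop("unknown screening cost '", s, "'", call. = FALSE)
    params$screening_costs[[s]] <- max(value, 0)
  } else if (name %in% c("general_mortality", "utility_ckd",
                         "utility_background", "discount_rate",
                         "discontinue_first_cycle", "discontinue_annual",
                         "prevalence_albuminuria", "p_fn_redetect",
                         "p_progress_symptomatic", "p_fp_revert",
                         "p_recover", "rrr_treatment")) {
    params[[name]] <- clamp01(value)
  } else if (name %in% c("rr_ckd_mortality", "ras_inhibitor_annual_cost",
                         "ckd_annual_cost", "wtp_threshold")) {
    params[[name]] <- max(value, if (name == "rr_ckd_mortality") 1 else 0)
  } else {
    stop("unknown parameter name '", name, "'", call. = FALSE)
  }
  list(params = params, n_clamped = clamped)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic model for a pair of strategies with each
#' parameter set to its low and then its high bound, all other parameters at
#' base values, and reports the resulting incremental cost, incremental
#' effect and incremental net monetary benefit (second strategy minus
#' first). Entries are sorted by the absolute NMB swing `|high - low|`.
#'
#' @param params base-case [model_parameters()].
#' @param validity a `validity_table` with the strategies' sensitivity and
#'   specificity.
#' @param param_ranges named list of `c(low, high)` input bounds; the
#'   default varies mortality, relative risks (efficacy over its
#'   confidence interval), every cost by +/- 25%, the CKD utility by
#'   +/- 0.145 and the discount rate over 0-10%.
#' @param pair character vector of two strategy names
#'   `(reference, alternative)`.
#' @param wtp willingness-to-pay for the NMB outcome.
#' @return A data frame of class `tornado_table`, one row per parameter.
#' @export
one_way_tornado <- function(params, validity,
                            param_ranges = default_tornado_ranges(params),
                            pair = c("DAY1", "DAY1_RANDOM_DAY2"),
                            wtp = NULL) {
  if (is.null(wtp)) wtp <- params$wtp_threshold
  if (length(pair) != 2)
    stop("'pair' must name two strategies", call. = FALSE)
  eval_pair <- function(p) {
    tr <- lapply(pair, function(s) {
      row <- validity[validity$strategy == s, ]
      if (nrow(row) != 1)
        stop("strategy '", s, "' not in validity table", call. = FALSE)
      run_markov(p, list(sensitivity = row$sensitivity / 100,
                         specificity = row$specificity / 100),
                 strategy = s)
    })
    c(incr_cost = tr[[2]]$total_cost - tr[[1]]$total_cost,
      incr_effect = tr[[2]]$total_qaly - tr[[1]]$total_qaly)
  }
  base <- eval_pair(params)
  rows <- lapply(names(param_ranges), function(nm) {
    rng <- param_ranges[[nm]]
    lo <- eval_pair(.set_param(params, nm, rng[1])$params)
    hi <- eval_pair(.set_param(params, nm, rng[2])$params)
    nmb_lo <- wtp * lo["incr_effect"] - lo["incr_cost"]
    nmb_hi <- wtp * hi["incr_effect"] - hi["incr_cost"]
    data.frame(parameter = nm, low_input = rng[1], high_input = rng[2],
               incr_cost_low = lo[["incr_cost"]],
               incr_cost_high = hi[["incr_cost"]],
               incr_effect_low = lo[["incr_effect"]],
               incr_effect_high = hi[["incr_effect"]],
               incr_nmb_low = unname(nmb_lo),
               incr_nmb_high = unname(nmb_hi),
               swing = abs(unname(nmb_hi - nmb_lo)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "base_incr_cost") <- base[["incr_cost"]]
  attr(out, "base_incr_effect") <- base[["incr_effect"]]
  attr(out, "pair") <- pair
  attr(out, "wtp") <- wtp
  class(out) <- c("tornado_table", "data.frame")
  out
}

#' Default one-way ranges for the tornado analysis
#'
#' @param params a [model_parameters()] object.
#' @param rrr_range confidence-interval range for treatment efficacy.
#' @param discount_range range for the annual discount rate.
#' @return Named list of `c(low, high)` bounds.
#' @export
default_tornado_ranges <- function(params, rrr_range = c(0.08, 0.37),
                                   discount_range = c(0, 0.10)) {
  pm25 <- function(v) c(0.75 * v, 1.25 * v)
  ranges <- list(
    general_mortality = pm25(params$general_mortality),
    rr_ckd_mortality = c(1.5, 1.77),
    rrr_treatment = rrr_range,
    ras_inhibitor_annual_cost = pm25(params$ras_inhibitor_annual_cost),
    ckd_annual_cost = pm25(params$ckd_annual_cost),
    utility_ckd = c(params$utility_ckd - 0.145,
                    params$utility_ckd + 0.145),
    discount_rate = discount_range)
  for (s in names(params$screening_costs))
    ranges[[paste0("screening_cost_", s)]] <-
      pm25(params$screening_costs[[s]])
  ranges
}

# beta draws for a binomial proportion implied by confusion counts;
# a zero failure count gives the degenerate point mass at 1 (and vice versa)
.rbeta_counts <- function(n, successes, failures) {
  if (failures == 0) return(rep(1, n))
  if (successes == 0) return(rep(0, n))
  stats::rbeta(n, successes, failures)
}

#' Probabilistic sensitivity analysis
#'
#' Samples all parameter distributions jointly (independently across
#' parameters) and, for each draw, runs the Markov model for every strategy
#' on the *same* parameter draw (common random numbers across strategies
#' within a draw). Strategy validity is, by default, also sampled: each
#' strategy's sensitivity and specificity are drawn from the beta
#' distributions implied by its confusion counts, since the observed
#' validity is itself an estimate from a finite cohort.
#'
#' Sampled probabilities are truncated into \[0, 1\] after composition; the
#' number of truncation events is reported as an attribute.
#'
#' @param params base-case [model_parameters()].
#' @param validity a `validity_table` including confusion counts.
#' @param n_iterations number of PSA draws (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param dists list of [parameter_distribution()] objects (default
#'   [default_psa_distributions()]).
#' @param sample_validity draw per-strategy sensitivity/specificity from
#'   their count-based beta distributions (default `TRUE`).
#' @return A data frame of class `psa_result` with columns `draw`,
#'   `strategy`, `cost`, `effect`; attribute `n_truncated` counts clamped
#'   probability draws.
#' @export
run_psa <- function(params, validity, n_iterations, seed = NULL,
                    dists = default_psa_distributions(params),
                    sample_validity = TRUE) {
  if (n_iterations < 1)
    stop("'n_iterations' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  strategies <- intersect(validity$strategy, names(params$screening_costs))
  samplers <- lapply(dists, parameterize_distribution)
  draws <- lapply(samplers, function(f) f(n_iterations))
  names(draws) <- vapply(dists, `[[`, "", "name")

  if (sample_validity) {
    vs <- lapply(strategies, function(s) {
      row <- validity[validity$strategy == s, ]
      list(sens = .rbeta_counts(n_iterations, row$tp, row$fn),
           spec = .rbeta_counts(n_iterations, row$tn, row$fp))
    })
  } else {
    vs <- lapply(strategies, function(s) {
      row <- validity[validity$strategy == s, ]
      list(sens = rep(row$sensitivity / 100, n_iterations),
           spec = rep(row$specificity / 100, n_iterations))
    })
  }
  names(vs) <- strategies

  n_truncated <- 0L
  cost <- effect <- matrix(NA_real_, n_iterations, length(strategies),
                           dimnames = list(NULL, strategies))
  for (i in seq_len(n_iterations)) {
    p_i <- params
    for (nm in names(draws)) {
      res <- .set_param(p_i, nm, draws[[nm]][i])
      p_i <- res$params
      n_truncated <- n_truncated + res$n_clamped
    }
    for (s in strategies) {
      tr <- run_markov(p_i, list(sensitivity = vs[[s]]$sens[i],
                                 specificity = vs[[s]]$spec[i]),
                       strategy = s)
      cost[i, s] <- tr$total_cost
      effect[i, s] <- tr$total_qaly
    }
  }
  out <- data.frame(draw = rep(seq_len(n_iterations), length(strategies)),
                    strategy = rep(strategies, each = n_iterations),
                    cost = as.vector(cost), effect = as.vector(effect),
                    stringsAsFactors = FALSE)
  attr(out, "n_truncated") <- n_truncated
  attr(out, "strategies") <- strategies
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the acceptability of a strategy is the
#' fraction of PSA draws in which it attains the maximal net monetary
#' benefit; draws where several strategies tie are split equally among the
#' tied strategies, so acceptabilities sum to 1 at every WTP.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid numeric vector of willingness-to-pay values (non-empty).
#' @return A data frame of class `ceac_curve`: column `wtp` plus one
#'   acceptability column per strategy.
#' @export
ceac <- function(psa, wtp_grid) {
  if (nrow(psa) == 0) stop("PSA table is empty", call. = FALSE)
  if (length(wtp_grid) == 0) stop("'wtp_grid' is empty", call. = FALSE)
  if (any(wtp_grid < 0)) stop("'wtp_grid' must be >= 0", call. = FALSE)
  strategies <- unique(psa$strategy)
  C <- matrix(psa$cost, ncol = length(strategies),
              dimnames = list(NULL, strategies))
  E <- matrix(psa$effect, ncol = length(strategies),
              dimnames = list(NULL, strategies))
  rows <- lapply(wtp_grid, function(w) {
    nmb <- w * E - C
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)   # ties split equally
    as.data.frame(c(list(wtp = w), as.list(colMeans(share))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ceac_curve", "data.frame")
  out
}
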