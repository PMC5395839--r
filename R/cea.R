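#' Net monetary benefit
#'
#' `NMB = wtp x effect - cost`: positive differences in NMB identify the
#' preferred strategy at a given willingness-to-pay.
#'
#' @param cost total cost (yuan).
#' @param effect total effect (QALYs).
#' @param wtp willingness-to-pay per QALY (>= 0).
#' @return NMB in yuan (vectorised).
#' @export
net_monetary_benefit <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("'wtp' must be >= 0", call. = FALSE)
  wtp * effect - cost
}

# frontier analysis on (cost, effect) pairs; returns dominance labels and
# frontier ICERs. Strict dominance: some other strategy costs no more and is
# at least as effective, one strictly. Extended dominance: removed when its
# incremental ICER along the cost-sorted frontier exceeds that of the next,
# more effective option; ICERs are recomputed after each removal.
.frontier <- function(cost, effect) {
  n <- length(cost)
  dominance <- rep("none", n)
  for (i in seq_len(n)) {
    better <- cost <= cost[i] & effect >= effect[i] &
      (cost < cost[i] | effect > effect[i])
    if (any(better)) dominance[i] <- "strictly_dominated"
  }
  frontier_icer <- rep(NA_real_, n)
  alive <- which(dominance == "none")
  repeat {
    ord <- alive[order(cost[alive], -effect[alive])]
    if (length(ord) < 3) break
    icers <- diff(cost[ord]) / diff(effect[ord])
    drop_idx <- NULL
    for (k in seq_len(length(icers) - 1)) {
      if (icers[k] > icers[k + 1]) { drop_idx <- ord[k + 1]; break }
    }
    if (is.null(drop_idx)) break
    dominance[drop_idx] <- "extendedly_dominated"
    alive <- setdiff(alive, drop_idx)
  }
  ord <- alive[order(cost[alive], -effect[alive])]
  if (length(ord) > 1)
    frontier_icer[ord[-1]] <- diff(cost[ord]) / diff(effect[ord])
  list(dominance = dominance, frontier_icer = frontier_icer)
}

#' Incremental cost-effectiveness analysis
#'
#' Given total (cost, effect) pairs per strategy, reports both presentations
#' used in cost-effectiveness tables: raw pairwise incrementals (and ICERs)
#' against a named comparator, and the efficiency-frontier analysis with
#' strict and extended dominance and recomputed frontier ICERs. The ICER of
#' a strategy that is more costly and no more effective than the comparator
#' is reported as a dominance flag (`NA` ICER), never as a negative number.
#'
#' @param results data frame with columns `strategy`, `cost`, `effect` (one
#'   row per strategy; at least two).
#' @param comparator strategy name the pairwise incrementals refer to.
#' @param wtp willingness-to-pay used for the net-monetary-benefit column.
#' @return A data frame of class `cea_table` with columns `strategy`,
#'   `cost`, `effect`, `incr_cost`, `incr_effect`, `icer_vs_comparator`,
#'   `dominated_vs_comparator`, `dominance`, `frontier_icer`, `nmb`, ordered
#'   by cost.
#' @export
incremental_analysis <- function(results, comparator, wtp = 100000) {
  req <- c("strategy", "cost", "effect")
  if (!all(req %in% names(results)))
    stop("'results' needs columns strategy, cost, effect", call. = FALSE)
  if (nrow(results) < 2)
    stop("need at least two strategies", call. = FALSE)
  if (anyDuplicated(results$strategy))
    stop("duplicate strategy names", call. = FALSE)
  if (!comparator %in% results$strategy)
    stop("comparator '", comparator, "' not among strategies", call. = FALSE)
  cost <- results$cost; effect <- results$effect
  i0 <- match(comparator, results$strategy)
  incr_cost <- cost - cost[i0]
  incr_effect <- effect - effect[i0]
  icer <- ifelse(incr_effect != 0, incr_cost / incr_effect, NA_real_)
  dominated_vs <- incr_effect <= 0 & incr_cost > 0
  icer[dominated_vs] <- NA_real_
  fr <- .frontier(cost, effect)
  out <- data.frame(strategy = results$strategy, cost = cost,
                    effect = effect, incr_cost = incr_cost,
                    incr_effect = incr_effect,
                    icer_vs_comparator = icer,
                    dominated_vs_comparator = dominated_vs,
                    dominance = fr$dominance,
                    frontier_icer = fr$frontier_icer,
                    nmb = net_monetary_benefit(cost, effect, wtp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cost, -out$effect), ]
  rownames(out) <- NULL
  attr(out, "comparator") <- comparator
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_table", "data.frame")
  out
}

#' Base-case cost-effectiveness analysis across strategies
#'
#' Runs the Markov model once per strategy in a validity table (using each
#' strategy's observed sensitivity and specificity and its per-round
#' screening cost) and performs the incremental analysis.
#'
#' @param params a [model_parameters()] object.
#' @param validity a `validity_table` (see [validity_table()]); only
#'   strategies present in `params$screening_costs` are analysed.
#' @param comparator comparator strategy for pairwise incrementals.
#' @param wtp willingness-to-pay per QALY (default: `params$wtp_threshold`).
#' @return A list of class `cea_result` with elements `results` (total
#'   cost/effect per strategy), `table` (the [incremental_analysis()]
#'   output) and `traces` (named list of `cohort_trace` objects).
#' @export
run_cea <- function(params, validity, comparator = "DAY1", wtp = NULL) {
  if (is.null(wtp)) wtp <- params$wtp_threshold
  strategies <- intersect(validity$strategy, names(params$screening_costs))
  if (length(strategies) < 2)
    stop("fewer than two strategies have screening costs", call. = FALSE)
  traces <- lapply(strategies, function(s) {
    row <- validity[validity$strategy == s, ]
    run_markov(params,
               list(sensitivity = row$sensitivity / 100,
                    specificity = row$specificity / 100),
               strategy = s)
  })
  names(traces) <- strategies
  results <- data.frame(strategy = strategies,
                        cost = vapply(traces, `[[`, 0, "total_cost"),
                        effect = vapply(traces, `[[`, 0, "total_qaly"),
                        stringsAsFactors = FALSE)
  rownames(results) <- NULL
  structure(list(results = results,
                 table = incremental_analysis(results, comparator, wtp),
                 traces = traces),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness analysis (comparator: ",
      attr(x$table, "comparator"), ", WTP ", attr(x$table, "wtp"),
      "/QALY)\n", sep = "")
  tab <- x$table
  tab$cost <- round(tab$cost, 2)
  tab$effect <- round(tab$effect, 4)
  tab$nmb <- round(tab$nmb, 2)
  print.data.frame(tab, digits = 6)
  invisible(x)
}
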