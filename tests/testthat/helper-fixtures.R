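# Confusion counts of the five screening strategies against the
# three-monthly-sample gold standard in the motivating cohort (n = 157,
# 82 persistent): inputs for validity and CEA tests.
study_counts <- function() {
  data.frame(
    strategy = c("DAY1", "RANDOM", "DAY1_RANDOM", "DAY1_DAY2",
                 "DAY1_RANDOM_DAY2"),
    tp = c(82, 79, 79, 79, 77),
    fn = c(0, 3, 3, 3, 5),
    fp = c(23, 40, 18, 17, 14),
    tn = c(52, 35, 57, 58, 61),
    stringsAsFactors = FALSE)
}

# validity_table-shaped input for the economic model (percent scale)
study_validity <- function() {
  vt <- study_counts()
  vt$sensitivity <- 100 * vt$tp / (vt$tp + vt$fn)
  vt$specificity <- 100 * vt$tn / (vt$tn + vt$fp)
  vt
}

# a cohort data frame from explicit per-sample ACR vectors
make_cohort <- function(day1, random = day1, day2 = day1,
                        month2 = day1, month3 = day1, truth = NULL) {
  df <- data.frame(patient_id = sprintf("P%03d", seq_along(day1)),
                   acr_day1 = day1, acr_random = random, acr_day2 = day2,
                   acr_month2 = month2, acr_month3 = month3)
  if (!is.null(truth)) df$truth_persistent <- truth
  class(df) <- c("acr_cohort", "data.frame")
  df
}

# independent frontier oracle: pairwise strict dominance plus the standard
# greedy minimum-ICER walk from the cheapest undominated strategy
oracle_frontier <- function(cost, effect) {
  n <- length(cost)
  strict <- vapply(seq_len(n), function(i)
    any(cost <= cost[i] & effect >= effect[i] &
          (cost < cost[i] | effect > effect[i])), logical(1))
  alive <- which(!strict)
  ord <- alive[order(cost[alive], -effect[alive])]
  cur <- ord[1]
  frontier <- cur
  repeat {
    cand <- alive[effect[alive] > effect[cur]]
    if (!length(cand)) break
    icers <- (cost[cand] - cost[cur]) / (effect[cand] - effect[cur])
    nxt <- cand[which.min(icers)]
    frontier <- c(frontier, nxt)
    cur <- nxt
  }
  list(strict = which(strict), frontier = frontier,
       extended = setdiff(alive, frontier))
}
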