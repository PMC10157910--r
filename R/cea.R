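# Incremental cost-effectiveness analysis: ICERs, dominance classification,
# the efficiency frontier, net monetary benefit and the decision rule.

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (C1 - C2) / (E1 - E2)`: the extra cost per extra QALY of the first
#' option over the second.
#'
#' @param cost1,cost2 Discounted costs ($).
#' @param eff1,eff2 Discounted effectiveness (QALYs); must differ.
#' @return $/QALY.
#' @examples
#' icer(62362.63, 13458.63, 8.71, 8.34)
#' @export
icer <- function(cost1, cost2, eff1, eff2) {
  if (isTRUE(all.equal(eff1, eff2, tolerance = 0)) || eff1 == eff2)
    stop("icer: undefined for equal effectiveness")
  (cost1 - cost2) / (eff1 - eff2)
}

#' Net monetary benefit
#'
#' `NMB = qalys * wtp - cost`. The difference in NMB between two strategies
#' changes sign exactly at their ICER as the willingness to pay sweeps.
#'
#' @param cost Discounted cost ($).
#' @param qalys Discounted QALYs.
#' @param wtp Willingness to pay ($/QALY).
#' @return $ (vectorised).
#' @export
nmb <- function(cost, qalys, wtp) {
  qalys * wtp - cost
}

as_cea_input <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    stopifnot(all(c("strategy", "cost", "qalys") %in% names(outcomes)))
    df <- outcomes[, c("strategy", "cost", "qalys")]
  } else {
    df <- outcomes_table(outcomes)
  }
  if (anyDuplicated(df$strategy)) stop("cea: duplicated strategy names")
  df
}

#' Efficiency frontier with dominance classification
#'
#' Sorts strategies by cost and classifies each as `undominated`,
#' `dominated-strict` (some other strategy costs no more and yields at least
#' as many QALYs) or `dominated-extended` (its step ICER exceeds that of the
#' next frontier step, i.e. a blend of two other strategies dominates it).
#' Frontier ICERs are chained along the frontier and strictly increase.
#' Ties are broken toward the lower-cost strategy, then lexicographic name,
#' so the result does not depend on input order.
#'
#' The returned table also reports, for every strategy, incremental cost /
#' QALYs / ICER against the cheapest strategy as common baseline (the
#' conventional "all referencing common baseline" presentation; these signed
#' ICERs of dominated strategies are reported but never used for decisions).
#'
#' @param outcomes List of `sarco_outcome` or a data frame with columns
#'   `strategy`, `cost`, `qalys`.
#' @return A `sarco_cea` data frame: `strategy`, `cost`, `qalys`,
#'   `incremental_cost`, `incremental_qalys`, `icer` (vs common baseline; NA
#'   for the baseline row), `category`, `on_frontier`, `frontier_icer`
#'   (chained; NA off frontier and for the cheapest frontier member).
#' @export
efficiency_frontier <- function(outcomes) {
  df <- as_cea_input(outcomes)
  ord <- order(df$cost, -df$qalys, df$strategy)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  category <- rep("undominated", n)

  # strict (simple) dominance, deterministic tie handling via the sort order:
  # an earlier row with qalys >= this row's qalys dominates it
  for (i in seq_len(n)) {
    if (i == 1L) next
    best_before <- max(df$qalys[seq_len(i - 1L)])
    if (best_before >= df$qalys[i]) category[i] <- "dominated-strict"
  }

  # extended dominance: on the remaining chain, remove members whose step
  # ICER is >= the following step's until ICERs strictly increase
  idx <- which(category == "undominated")
  repeat {
    if (length(idx) <= 2L) break
    icers <- vapply(seq_along(idx)[-1L], function(k) {
      i <- idx[k]; j <- idx[k - 1L]
      (df$cost[i] - df$cost[j]) / (df$qalys[i] - df$qalys[j])
    }, 0)
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    drop <- idx[bad[1L] + 1L]  # the strategy whose step violates monotonicity
    category[drop] <- "dominated-extended"
    idx <- setdiff(idx, drop)
  }

  base <- 1L  # cheapest row after sorting
  inc_cost <- df$cost - df$cost[base]
  inc_qaly <- df$qalys - df$qalys[base]
  icer_base <- ifelse(seq_len(n) == base | inc_qaly == 0, NA_real_,
                      inc_cost / inc_qaly)
  frontier_icer <- rep(NA_real_, n)
  if (length(idx) > 1L) {
    for (k in seq_along(idx)[-1L]) {
      i <- idx[k]; j <- idx[k - 1L]
      frontier_icer[i] <- (df$cost[i] - df$cost[j]) / (df$qalys[i] - df$qalys[j])
    }
  }
  structure(data.frame(strategy = df$strategy, cost = df$cost,
                       qalys = df$qalys, incremental_cost = inc_cost,
                       incremental_qalys = inc_qaly, icer = icer_base,
                       category = category,
                       on_frontier = category == "undominated",
                       frontier_icer = frontier_icer, row.names = NULL),
            class = c("sarco_cea", "data.frame"))
}

#' Frontier-only table with chained increments
#'
#' @param cea A `sarco_cea` from [efficiency_frontier()].
#' @return Data frame of undominated strategies sorted by cost, with
#'   incremental cost / QALYs / ICER against the previous frontier member.
#' @export
frontier_table <- function(cea) {
  stopifnot(inherits(cea, "sarco_cea"))
  f <- cea[cea$on_frontier, c("strategy", "cost", "qalys"), drop = FALSE]
  n <- nrow(f)
  f$incremental_cost <- c(NA_real_, diff(f$cost))
  f$incremental_qalys <- c(NA_real_, diff(f$qalys))
  f$icer <- c(NA_real_, diff(f$cost) / diff(f$qalys))
  row.names(f) <- NULL
  f
}

#' Decision rule at a willingness-to-pay threshold
#'
#' Walks up the efficiency frontier and returns the highest-QALY strategy
#' whose step ICER does not exceed the threshold (the cheapest frontier
#' strategy when every step exceeds it). Equivalent to maximising net
#' monetary benefit over frontier strategies.
#'
#' @param cea A `sarco_cea` from [efficiency_frontier()].
#' @param wtp Willingness to pay ($/QALY).
#' @return Strategy name.
#' @export
decide_cost_effective <- function(cea, wtp) {
  stopifnot(inherits(cea, "sarco_cea"))
  f <- frontier_table(cea)
  if (!nrow(f)) stop("decide_cost_effective: empty frontier")
  pick <- 1L
  for (k in seq_len(nrow(f))[-1L]) {
    if (f$icer[k] <= wtp) pick <- k else break
  }
  f$strategy[pick]
}

#' Export CEA tables to CSV
#'
#' Writes the full common-baseline table and the frontier-only table.
#' Monetary columns are rounded to 2 decimals at this presentation layer
#' only; internal accumulation is unrounded.
#'
#' @param cea A `sarco_cea`.
#' @param full_path,frontier_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cea_tables <- function(cea, full_path, frontier_path) {
  stopifnot(inherits(cea, "sarco_cea"))
  money <- function(df) {
    for (cl in intersect(c("cost", "incremental_cost", "icer"), names(df)))
      df[[cl]] <- round(df[[cl]], 2)
    for (cl in intersect(c("frontier_icer"), names(df)))
      df[[cl]] <- round(df[[cl]], 2)
    df
  }
  utils::write.csv(money(as.data.frame(cea)), full_path, row.names = FALSE)
  utils::write.csv(money(frontier_table(cea)), frontier_path, row.names = FALSE)
  invisible(c(full_path, frontier_path))
}
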