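# Uncertainty analysis: one-way deterministic sensitivity (tornado on net
# monetary benefit), Monte-Carlo probabilistic sensitivity analysis,
# cost-effectiveness acceptability curves, and the expected value of perfect
# information.

#' One-way (tornado) sensitivity analysis on incremental net monetary benefit
#'
#' For each selected global parameter, re-runs the full cohort model with
#' that parameter set to the low and the high end of its range (published CI
#' or range where available, otherwise the 2.5/97.5 percentiles of its fitted
#' distribution) while all other parameters stay at base case. The outcome of
#' each bar is the incremental NMB of `pair[1]` versus `pair[2]` (by default
#' the two frontier strategies, protein + vitamin D versus vitamin D alone).
#' Bars are sorted by decreasing spread.
#'
#' @param params A `sarco_params`.
#' @param strategies Named list of `sarco_strategy`.
#' @param life_table A `sarco_lifetable`.
#' @param pair Character vector of two strategy names to compare.
#' @param wtp Willingness to pay; defaults to `params$wtp`.
#' @param parameters Which global parameters to vary; defaults to every
#'   parameter with a non-fixed distribution.
#' @param ranges Optional named list of length-2 numeric overrides for
#'   individual parameter ranges.
#' @param start_age Cohort entry age.
#' @return A `sarco_tornado` data frame: `parameter`, `low`, `high`,
#'   `nmb_low`, `nmb_high`, `spread`, plus attribute `base_nmb`.
#' @export
tornado <- function(params, strategies, life_table,
                    pair = c("P+D", "D"), wtp = NULL,
                    parameters = NULL, ranges = list(), start_age = 60) {
  stopifnot(inherits(params, "sarco_params"))
  if (length(pair) != 2L || !all(pair %in% names(strategies)))
    stop("tornado: 'pair' must name two strategies present in 'strategies'")
  if (is.null(wtp)) wtp <- params$wtp
  dists <- attr(params, "dists")
  if (is.null(parameters))
    parameters <- names(dists)[vapply(dists, function(d) d$family != "fixed",
                                      TRUE)]
  unknown <- setdiff(c(parameters, names(ranges)), PARAM_NAMES)
  if (length(unknown))
    stop("tornado: unknown parameter(s): ", paste(unknown, collapse = ", "))

  inc_nmb <- function(p) {
    o1 <- run_strategy(strategies[[pair[1]]], p, life_table, start_age)
    o2 <- run_strategy(strategies[[pair[2]]], p, life_table, start_age)
    nmb(o1$cost, o1$qalys, wtp) - nmb(o2$cost, o2$qalys, wtp)
  }
  at <- function(nm, value) {
    v <- unclass(params)
    v[[nm]] <- value
    structure(v, dists = dists, class = "sarco_params")
  }
  support_ok <- function(nm, lo, hi) {
    d <- dists[[nm]]
    bounds <- switch(d$family,
      beta = c(d$fit$low, d$fit$high),
      gamma = c(0, Inf), lognormal = c(0, Inf), fixed = c(-Inf, Inf))
    if (lo < bounds[1] || hi > bounds[2])
      stop("tornado: range for '", nm, "' outside the parameter support")
  }
  base_nmb <- inc_nmb(params)
  rows <- lapply(parameters, function(nm) {
    rg <- if (!is.null(ranges[[nm]])) as.numeric(ranges[[nm]])
          else dist_range(dists[[nm]])
    if (rg[1] > rg[2]) rg <- rev(rg)
    support_ok(nm, rg[1], rg[2])
    lo_nmb <- if (rg[1] == params[[nm]]) base_nmb else inc_nmb(at(nm, rg[1]))
    hi_nmb <- if (rg[2] == params[[nm]]) base_nmb else inc_nmb(at(nm, rg[2]))
    data.frame(parameter = nm, low = rg[1], high = rg[2],
               nmb_low = lo_nmb, nmb_high = hi_nmb,
               spread = abs(hi_nmb - lo_nmb))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  row.names(out) <- NULL
  structure(out, class = c("sarco_tornado", "data.frame"),
            base_nmb = base_nmb, pair = pair, wtp = wtp)
}

#' Probabilistic sensitivity analysis by Monte-Carlo simulation
#'
#' Draws `n_iterations` joint parameter realizations (common draws shared by
#' all strategies within an iteration) and evaluates the full cohort model
#' for every strategy under each draw. The off-treatment arm is identical
#' across strategies for a given draw and is computed once per iteration.
#'
#' @param params A `sarco_params`.
#' @param strategies Named list of `sarco_strategy`.
#' @param life_table A `sarco_lifetable`.
#' @param n_iterations Number of Monte-Carlo repetitions (>= 1; 1000 in the
#'   base analysis).
#' @param seed Integer seed; recorded on the result so it can be reproduced
#'   exactly.
#' @param start_age Cohort entry age.
#' @return A `sarco_psa`: list with `n_iterations`, `seed`, `strategies`,
#'   matrices `cost` and `qalys` (iterations x strategies), and `draws`
#'   (data frame of the realized global parameters per iteration).
#' @export
run_psa <- function(params, strategies, life_table, n_iterations = 1000,
                    seed = 1L, start_age = 60) {
  stopifnot(inherits(params, "sarco_params"))
  if (!is.numeric(n_iterations) || n_iterations < 1)
    stop("run_psa: n_iterations must be >= 1")
  n_iterations <- as.integer(n_iterations)
  set.seed(seed)
  snames <- vapply(strategies, `[[`, "", "name")
  S <- length(strategies)
  cost <- qalys <- matrix(NA_real_, n_iterations, S,
                          dimnames = list(NULL, snames))
  draws <- matrix(NA_real_, n_iterations, length(PARAM_NAMES),
                  dimnames = list(NULL, PARAM_NAMES))
  for (i in seq_len(n_iterations)) {
    dr <- sample_parameters(params, strategies, draw_index = i)
    p <- dr$params
    draws[i, ] <- unlist(p[PARAM_NAMES])
    off <- arm_totals(dr$strategies[[1L]], "off_treatment", p, life_table,
                      start_age)
    for (s in seq_len(S)) {
      st <- dr$strategies[[s]]
      if (st$name == "None") {
        cost[i, s] <- off["cost"]; qalys[i, s] <- off["qalys"]
      } else {
        on <- arm_totals(st, "on_treatment", p, life_table, start_age)
        a <- st$acceptance
        cost[i, s] <- a * on["cost"] + (1 - a) * off["cost"]
        qalys[i, s] <- a * on["qalys"] + (1 - a) * off["qalys"]
      }
    }
  }
  structure(list(n_iterations = n_iterations, seed = seed,
                 strategies = snames, cost = cost, qalys = qalys,
                 draws = as.data.frame(draws)),
            class = "sarco_psa")
}

#' Probability each strategy is optimal at one willingness-to-pay value
#'
#' The probability is the fraction of PSA iterations in which the strategy
#' attains the maximal net monetary benefit; exact ties within an iteration
#' are split equally among the tied strategies.
#'
#' @param psa A `sarco_psa`.
#' @param wtp Willingness to pay ($/QALY).
#' @return Named numeric vector of probabilities summing to 1.
#' @export
acceptability_at_wtp <- function(psa, wtp) {
  stopifnot(inherits(psa, "sarco_psa"))
  m <- nmb(psa$cost, psa$qalys, wtp)
  rowmax <- do.call(pmax, as.data.frame(m))
  tied <- m == rowmax
  w <- tied / rowSums(tied)
  stats::setNames(colMeans(w), psa$strategies)
}

#' Cost-effectiveness acceptability curve
#'
#' [acceptability_at_wtp()] evaluated over a grid of thresholds. The default
#' grid spans 0 to three times the configured threshold in 60 steps.
#'
#' @param psa A `sarco_psa`.
#' @param wtp_grid Ascending numeric grid of thresholds; when `NULL`,
#'   `seq(0, 3 * base_wtp, length.out = 61)` where `base_wtp` must be given.
#' @param base_wtp Base threshold used to build the default grid.
#' @return A `sarco_ceac` data frame: `wtp` plus one probability column per
#'   strategy; each row sums to 1.
#' @export
ceac <- function(psa, wtp_grid = NULL, base_wtp = NULL) {
  stopifnot(inherits(psa, "sarco_psa"))
  if (is.null(wtp_grid)) {
    if (is.null(base_wtp)) stop("ceac: give wtp_grid or base_wtp")
    wtp_grid <- seq(0, 3 * base_wtp, length.out = 61L)
  }
  if (is.unsorted(wtp_grid)) stop("ceac: wtp_grid must be ascending")
  probs <- t(vapply(wtp_grid, function(w) acceptability_at_wtp(psa, w),
                    numeric(length(psa$strategies))))
  out <- data.frame(wtp = wtp_grid, probs, check.names = FALSE)
  structure(out, class = c("sarco_ceac", "data.frame"))
}

#' Expected value of perfect information at one threshold
#'
#' Per-person EVPI from the PSA draw matrix:
#' `EVPI = mean over draws of max-strategy NMB  -  max over strategies of mean NMB`.
#' Also reports the average incremental cost and effectiveness between the
#' per-draw NMB-maximising strategy and the strategy that maximises expected
#' NMB overall (the base-case choice under current information).
#'
#' @param psa A `sarco_psa`.
#' @param wtp Willingness to pay ($/QALY).
#' @return A `sarco_evpi` list: `wtp`, `evpi`,
#'   `avg_incremental_cost_perfect_info`, `avg_incremental_eff_perfect_info`,
#'   `optimal_strategy` (expected-NMB maximiser).
#' @export
evpi <- function(psa, wtp) {
  stopifnot(inherits(psa, "sarco_psa"))
  m <- nmb(psa$cost, psa$qalys, wtp)
  rowmax <- do.call(pmax, as.data.frame(m))
  base <- which.max(colMeans(m))
  winner <- max.col(m, ties.method = "first")
  n <- nrow(m)
  pick <- cbind(seq_len(n), winner)
  structure(list(
    wtp = wtp,
    evpi = mean(rowmax) - max(colMeans(m)),
    avg_incremental_cost_perfect_info = mean(psa$cost[pick] - psa$cost[, base]),
    avg_incremental_eff_perfect_info = mean(psa$qalys[pick] - psa$qalys[, base]),
    optimal_strategy = psa$strategies[base]),
    class = "sarco_evpi")
}

#' EVPI across a grid of thresholds
#'
#' @param psa A `sarco_psa`.
#' @param wtp_grid Ascending numeric grid of thresholds.
#' @return Data frame: `wtp`, `evpi`, `avg_incremental_cost_perfect_info`,
#'   `avg_incremental_eff_perfect_info`.
#' @export
evpi_curve <- function(psa, wtp_grid) {
  if (is.unsorted(wtp_grid)) stop("evpi_curve: wtp_grid must be ascending")
  rows <- lapply(wtp_grid, function(w) {
    e <- evpi(psa, w)
    data.frame(wtp = w, evpi = e$evpi,
               avg_incremental_cost_perfect_info =
                 e$avg_incremental_cost_perfect_info,
               avg_incremental_eff_perfect_info =
                 e$avg_incremental_eff_perfect_info)
  })
  do.call(rbind, rows)
}

#' Incremental cost-effectiveness scatter of two strategies across PSA draws
#'
#' @param psa A `sarco_psa`.
#' @param pair Character vector of two strategy names (incremental =
#'   first minus second).
#' @return Data frame: `draw`, `incremental_cost`, `incremental_qalys`.
#' @export
psa_scatter <- function(psa, pair = c("P+D", "D")) {
  stopifnot(inherits(psa, "sarco_psa"), all(pair %in% psa$strategies))
  data.frame(draw = seq_len(psa$n_iterations),
             incremental_cost = psa$cost[, pair[1]] - psa$cost[, pair[2]],
             incremental_qalys = psa$qalys[, pair[1]] - psa$qalys[, pair[2]])
}

#' @export
print.sarco_evpi <- function(x, ...) {
  cat(sprintf("<sarco_evpi> WTP %.2f: EVPI $%.2f/person (avg incr cost $%.2f, avg incr eff %.4f QALY; optimal: %s)\n",
              x$wtp, x$evpi, x$avg_incremental_cost_perfect_info,
              x$avg_incremental_eff_perfect_info, x$optimal_strategy))
  invisible(x)
}
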