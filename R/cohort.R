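# The cohort engine: decision-tree split into on/off-treatment arms, annual
# Markov cycles over {sarcopenic, fracture-year, post-fracture, dead}, and
# discounted accumulation of costs and QALYs over a lifetime horizon.

STATES <- c("sarcopenic", "fracture_year", "post_fracture", "dead")
ARMS <- c("on_treatment", "off_treatment")

#' Combined fall-risk reduction of a strategy
#'
#' The intervention's effectiveness is carried by three equally weighted
#' indicators (muscle mass, muscle strength, physical performance), each
#' contributing its own percent reduction of the annual fall probability.
#' The combined reduction is their sum, capped at 100%, returned as a
#' fraction; indicators without a published effect contribute 0. The
#' additive equal-weight combination is the one that reproduces the
#' published per-strategy effectiveness pattern (see the methods vignette
#' for the comparison against mean and multiplicative pooling).
#'
#' @param strategy A `sarco_strategy`.
#' @return Fraction in `[0, 1]` by which the annual fall probability is
#'   reduced while on treatment.
#' @examples
#' combined_fall_risk_reduction(strategy_spec("D", 129.276, frr_mp = 27.08))
#' @export
combined_fall_risk_reduction <- function(strategy) {
  stopifnot(inherits(strategy, "sarco_strategy"))
  min(1, (strategy$frr_mm + strategy$frr_ms + strategy$frr_mp) / 100)
}

#' One row of the annual transition matrix
#'
#' Transition probabilities out of `state` at age `age`. Death is resolved
#' first (background probability from the life table, hazard-adjusted by the
#' sarcopenia mortality HR, additionally by the first-year fracture mortality
#' RR in the fracture-year tunnel); survivors of the sarcopenic and
#' post-fracture states then fall and fracture with probability
#' `p_fall * (1 - FRR) * p_fracture_given_fall`, where the combined
#' fall-risk reduction FRR applies only in the on-treatment arm. Fracture-year
#' survivors all move to post-fracture (one-cycle tunnel); death is absorbing.
#'
#' @param state One of `"sarcopenic"`, `"fracture_year"`, `"post_fracture"`,
#'   `"dead"`.
#' @param age Age in years (must be within the life-table range).
#' @param arm `"on_treatment"` or `"off_treatment"`.
#' @param strategy A `sarco_strategy`.
#' @param params A `sarco_params` (base values or one realized draw).
#' @param life_table A `sarco_lifetable`.
#' @return Named probability vector over the four states, summing to 1.
#' @export
build_transition_row <- function(state, age, arm, strategy, params, life_table) {
  state <- match.arg(state, STATES)
  arm <- match.arg(arm, ARMS)
  if (state == "dead") return(c(sarcopenic = 0, fracture_year = 0,
                                post_fracture = 0, dead = 1))
  qx <- lt_qx(life_table, age)
  hr <- params$hr_sarcopenia_mortality
  frr <- if (arm == "on_treatment") combined_fall_risk_reduction(strategy) else 0
  p_fx <- params$p_fall * (1 - frr) * params$p_fracture_given_fall
  if (state == "fracture_year") {
    p_die <- adjusted_death_prob(qx, hr * params$rr_fracture_mortality_y1)
    row <- c(0, 0, 1 - p_die, p_die)
  } else {
    p_die <- adjusted_death_prob(qx, hr)
    p_to_fx <- (1 - p_die) * p_fx
    stay <- 1 - p_die - p_to_fx
    row <- if (state == "sarcopenic") c(stay, p_to_fx, 0, p_die)
           else c(0, p_to_fx, stay, p_die)
  }
  names(row) <- STATES
  row
}

#' Per-cycle cost and utility of each health state
#'
#' Undiscounted annual rewards: the sarcopenic state carries the sarcopenic
#' utility; the fracture-year tunnel subtracts the first-year fracture
#' disutility and accrues the first-year fracture cost; post-fracture
#' subtracts the chronic disutility and accrues the annual post-fracture
#' cost; death yields nothing. In the on-treatment arm every alive state
#' additionally accrues the strategy's annual intervention cost plus the
#' annual visit/laboratory cost; the off-treatment arm accrues neither.
#'
#' @inheritParams build_transition_row
#' @return Named numeric: `cost` ($/yr) and `utility` (QALY/yr).
#' @export
cycle_rewards <- function(state, arm, strategy, params) {
  state <- match.arg(state, STATES)
  arm <- match.arg(arm, ARMS)
  if (state == "dead") return(c(cost = 0, utility = 0))
  treat <- if (arm == "on_treatment")
    strategy$annual_cost + params$cost_visits_labs else 0
  switch(state,
    sarcopenic = c(cost = treat, utility = params$utility_sarcopenic),
    fracture_year = c(cost = params$cost_fracture_y1 + treat,
                      utility = params$utility_sarcopenic -
                                params$disutility_fracture_y1),
    post_fracture = c(cost = params$cost_post_fracture + treat,
                      utility = params$utility_sarcopenic -
                                params$disutility_post_fracture))
}

# Fast internal arm run: returns occupancy matrix ((T+1) x 4), per-cycle
# discounted cost and qaly vectors (length T). Cycle t (t = 0 for the first)
# rewards occupancy at the start of the cycle, discounted by (1+r)^(-t).
arm_core <- function(strategy, arm, params, life_table, start_age = 60) {
  ages <- seq.int(start_age, life_table$age[nrow(life_table)])
  qx <- lt_qx(life_table, ages)
  n <- length(ages)
  hr <- params$hr_sarcopenia_mortality
  rr <- params$rr_fracture_mortality_y1
  frr <- if (arm == "on_treatment") combined_fall_risk_reduction(strategy) else 0
  p_fx <- params$p_fall * (1 - frr) * params$p_fracture_given_fall
  treat <- if (arm == "on_treatment")
    strategy$annual_cost + params$cost_visits_labs else 0
  state_cost <- c(treat, params$cost_fracture_y1 + treat,
                  params$cost_post_fracture + treat, 0)
  state_util <- c(params$utility_sarcopenic,
                  params$utility_sarcopenic - params$disutility_fracture_y1,
                  params$utility_sarcopenic - params$disutility_post_fracture, 0)
  die_s <- 1 - (1 - qx)^hr            # sarcopenic / post-fracture
  die_f <- 1 - (1 - qx)^(hr * rr)     # fracture-year tunnel
  dc <- (1 + params$discount_rate_costs)^-(0:(n - 1))
  do <- (1 + params$discount_rate_outcomes)^-(0:(n - 1))
  occ <- matrix(0, n + 1L, 4L, dimnames = list(NULL, STATES))
  occ[1L, 1L] <- 1
  cost <- qaly <- numeric(n)
  v <- occ[1L, ]
  for (t in seq_len(n)) {
    cost[t] <- sum(v * state_cost) * dc[t]
    qaly[t] <- sum(v * state_util) * do[t]
    pd_s <- die_s[t]; pd_f <- die_f[t]
    fx <- (1 - pd_s) * p_fx
    v <- c(v[1L] * (1 - pd_s - fx),
           (v[1L] + v[3L]) * fx,
           v[2L] * (1 - pd_f) + v[3L] * (1 - pd_s - fx),
           v[4L] + (v[1L] + v[3L]) * pd_s + v[2L] * pd_f)
    occ[t + 1L, ] <- v
  }
  list(ages = ages, occupancy = occ, cost = cost, qaly = qaly)
}

#' Run one Markov arm of the cohort model
#'
#' Starts the whole cohort sarcopenic at `start_age` and iterates one-year
#' cycles until the end of the life table (where death is certain). Cycle
#' `t` rewards the state occupied at the start of the cycle and is discounted
#' by `(1 + r)^(-t)` with `t = 0` for the first cycle (no half-cycle
#' correction); costs and outcomes use their respective discount rates.
#'
#' @inheritParams build_transition_row
#' @param start_age Cohort entry age (years).
#' @return A `sarco_trace` data frame with one row per cycle (plus a terminal
#'   row after the last transition): `cycle`, `age`, the four state
#'   occupancies, and the cycle's discounted `cost` and `qaly` increments.
#'   Attributes `strategy`, `arm`, `total_cost`, `total_qalys`.
#' @export
run_arm <- function(strategy, arm, params, life_table, start_age = 60) {
  stopifnot(inherits(strategy, "sarco_strategy"),
            inherits(params, "sarco_params"),
            inherits(life_table, "sarco_lifetable"))
  arm <- match.arg(arm, ARMS)
  if (start_age < life_table$age[1L])
    stop("run_arm: start_age below the life-table range")
  core <- arm_core(strategy, arm, params, life_table, start_age)
  n <- length(core$ages)
  tr <- data.frame(cycle = 0:n,
                   age = c(core$ages, core$ages[n] + 1L),
                   core$occupancy,
                   cost = c(core$cost, 0), qaly = c(core$qaly, 0))
  structure(tr, class = c("sarco_trace", "data.frame"),
            strategy = strategy$name, arm = arm,
            total_cost = sum(core$cost), total_qalys = sum(core$qaly))
}

#' Run one strategy through the decision tree and both Markov arms
#'
#' Active strategies split the cohort by the acceptance probability: a
#' fraction `acceptance` runs on treatment (intervention effect and costs
#' applied) and the remainder off treatment. The comparator strategy `"None"`
#' runs entirely off treatment.
#'
#' @inheritParams run_arm
#' @return A `sarco_outcome`: list with `strategy`, expected discounted
#'   `cost` and `qalys`, and the per-arm `traces`.
#' @export
run_strategy <- function(strategy, params, life_table, start_age = 60) {
  stopifnot(inherits(strategy, "sarco_strategy"))
  off <- run_arm(strategy, "off_treatment", params, life_table, start_age)
  if (strategy$name == "None") {
    return(structure(list(strategy = strategy$name,
                          cost = attr(off, "total_cost"),
                          qalys = attr(off, "total_qalys"),
                          traces = list(off_treatment = off)),
                     class = "sarco_outcome"))
  }
  on <- run_arm(strategy, "on_treatment", params, life_table, start_age)
  a <- strategy$acceptance
  structure(list(strategy = strategy$name,
                 cost = a * attr(on, "total_cost") +
                        (1 - a) * attr(off, "total_cost"),
                 qalys = a * attr(on, "total_qalys") +
                         (1 - a) * attr(off, "total_qalys"),
                 traces = list(on_treatment = on, off_treatment = off)),
            class = "sarco_outcome")
}

#' Run every strategy on one parameter set
#'
#' @param params A `sarco_params` (or the `params` of a draw).
#' @param strategies List of `sarco_strategy` (or realized draws).
#' @param life_table A `sarco_lifetable`.
#' @param start_age Cohort entry age.
#' @return Named list of `sarco_outcome`.
#' @export
run_all_strategies <- function(params, strategies, life_table, start_age = 60) {
  out <- lapply(strategies, run_strategy, params = params,
                life_table = life_table, start_age = start_age)
  names(out) <- vapply(out, `[[`, "", "strategy")
  out
}

#' Tabulate strategy outcomes
#'
#' @param outcomes List of `sarco_outcome` (from [run_all_strategies()]).
#' @return Data frame with columns `strategy`, `cost`, `qalys`.
#' @export
outcomes_table <- function(outcomes) {
  data.frame(strategy = vapply(outcomes, `[[`, "", "strategy"),
             cost = vapply(outcomes, `[[`, 0, "cost"),
             qalys = vapply(outcomes, `[[`, 0, "qalys"),
             row.names = NULL)
}

# Expected discounted (cost, qalys) of one arm without trace construction;
# used by the PSA loop.
arm_totals <- function(strategy, arm, params, life_table, start_age = 60) {
  core <- arm_core(strategy, arm, params, life_table, start_age)
  c(cost = sum(core$cost), qalys = sum(core$qaly))
}

#' Export a cohort trace to CSV
#'
#' @param trace A `sarco_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sarco_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.sarco_outcome <- function(x, ...) {
  cat(sprintf("<sarco_outcome %s> cost $%.2f, QALYs %.4f\n",
              x$strategy, x$cost, x$qalys))
  invisible(x)
}
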