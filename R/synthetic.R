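# Synthetic inputs: the packaged base-case configuration, toy scenarios with
# closed-form outcomes, random scenario generation, and an individual-level
# microsimulation oracle for the cohort engine.

#' The base-case global parameter set
#'
#' All published model parameters with their uncertainty statements: Beta
#' distributions for probabilities, utilities, disutilities and discount
#' rates (discount rates as Beta rescaled to their published ranges), Gamma
#' for costs, Log-normal for the mortality hazard ratio and first-year
#' fracture relative risk. The age-60 background death probability, the
#' visit/laboratory cost, the willingness-to-pay threshold and the PPP
#' conversion factor carry no uncertainty and are fixed.
#'
#' @return A `sarco_params`.
#' @export
table2_parameter_set <- function() {
  parameter_set(
    values = list(
      discount_rate_costs = 0.05,
      discount_rate_outcomes = 0.05,
      q60_background = 0.0095,
      hr_sarcopenia_mortality = 1.6,
      rr_fracture_mortality_y1 = 6.57,
      p_fall = 0.155,
      p_fracture_given_fall = 0.33,
      utility_sarcopenic = 0.785,
      disutility_fracture_y1 = 0.25,
      disutility_post_fracture = 0.17,
      cost_fracture_y1 = 12588.214,
      cost_post_fracture = 2517.64,
      cost_visits_labs = 400.409,
      wtp = 25249.13,
      ppp_rial_per_dollar = 29704),
    dists = list(
      discount_rate_costs = make_dist("beta", 0.05, range = c(0.02, 0.10)),
      discount_rate_outcomes = make_dist("beta", 0.05, range = c(0.03, 0.08)),
      hr_sarcopenia_mortality = make_dist("lognormal", 1.6,
                                          ci95 = c(1.24, 2.06)),
      rr_fracture_mortality_y1 = make_dist("lognormal", 6.57,
                                           ci95 = c(5.54, 7.29)),
      p_fall = make_dist("beta", 0.155, sd = 0.041),
      p_fracture_given_fall = make_dist("beta", 0.33, sd = 0.06),
      utility_sarcopenic = make_dist("beta", 0.785, sd = 0.1962),
      disutility_fracture_y1 = make_dist("beta", 0.25, sd = 0.025),
      disutility_post_fracture = make_dist("beta", 0.17, sd = 0.017),
      cost_fracture_y1 = make_dist("gamma", 12588.214, sd = 3147.053),
      cost_post_fracture = make_dist("gamma", 2517.64, sd = 503)))
}

frr_dist <- function(mean, sd) make_dist("beta", mean, sd = sd,
                                         support = c(0, 100))

#' The eight base-case strategies
#'
#' Seven interventions plus the no-intervention comparator, each with its
#' mean annual cost (Gamma-distributed) and per-indicator percent fall-risk
#' reductions (Beta on `[0, 100]`). The vitamin-D-alone annual cost is not
#' published directly; it is derived as the P+D minus P cost difference
#' (129.276 $/yr, cross-validated by D+E minus E = 129.275), with a 20%
#' coefficient of variation for sampling (the study's stated fallback rule
#' assigns 10-30% of the mean as sd when no evidence exists).
#'
#' @return Named list of eight `sarco_strategy` objects.
#' @export
table2_strategies <- function() {
  s <- list(
    strategy_spec("None", annual_cost = 0, acceptance = 0.9,
                  dosage_note = "no intervention"),
    strategy_spec("E", annual_cost = 4268.785, frr_mm = 14, acceptance = 0.9,
                  dosage_note = "3 training sessions of 1.5 h per week",
                  dists = list(
                    annual_cost = make_dist("gamma", 4268.785, sd = 853.75),
                    frr_mm = frr_dist(14, 3.5))),
    strategy_spec("P", annual_cost = 5463.329, frr_mm = 3.64, frr_ms = 1.6,
                  frr_mp = 8.82, acceptance = 0.9,
                  dosage_note = "Whey protein 45 g/day",
                  dists = list(
                    annual_cost = make_dist("gamma", 5463.329, sd = 1515.555),
                    frr_mm = frr_dist(3.64, 0.91),
                    frr_ms = frr_dist(1.6, 0.4),
                    frr_mp = frr_dist(8.82, 2.205))),
    strategy_spec("D", annual_cost = 129.276, frr_mp = 27.08, acceptance = 0.9,
                  dosage_note = "Vitamin D 800 IU/day",
                  dists = list(
                    annual_cost = make_dist("gamma", 129.276, sd = 25.8552),
                    frr_mp = frr_dist(27.08, 6.77))),
    strategy_spec("WBV", annual_cost = 7126.312, frr_ms = 1.15,
                  frr_mp = 33.23, acceptance = 0.9,
                  dosage_note = "3 sessions per week",
                  dists = list(
                    annual_cost = make_dist("gamma", 7126.312, sd = 1790.565),
                    frr_ms = frr_dist(1.15, 0.2875),
                    frr_mp = frr_dist(33.23, 8.3075))),
    strategy_spec("P+D", annual_cost = 5592.605, frr_mm = 46.52,
                  frr_ms = 1.6, frr_mp = 20.1, acceptance = 0.9,
                  dosage_note = "Vitamin D 800 IU/day + Whey protein 45 g/day",
                  dists = list(
                    annual_cost = make_dist("gamma", 5592.605, sd = 1536.569),
                    frr_mm = frr_dist(46.52, 11.63),
                    frr_ms = frr_dist(1.6, 0.4),
                    frr_mp = frr_dist(20.1, 5.025))),
    strategy_spec("D+E", annual_cost = 4398.06, frr_mm = 15.31,
                  frr_ms = 3.7, acceptance = 0.9,
                  dosage_note = "Vitamin D 800 IU/day + 3 training sessions of 1.5 h per week",
                  dists = list(
                    annual_cost = make_dist("gamma", 4398.06, sd = 1662.537),
                    frr_mm = frr_dist(15.31, 3.8275),
                    frr_ms = frr_dist(3.7, 0.925))),
    strategy_spec("P+D+E", annual_cost = 9861.39, frr_mm = 24.35,
                  frr_ms = 3.85, frr_mp = 37.33, acceptance = 0.9,
                  dosage_note = "Whey protein 45 g/day + Vitamin D 800 IU/day + 3 training sessions of 1.5 h per week",
                  dists = list(
                    annual_cost = make_dist("gamma", 9861.39, sd = 7477.532),
                    frr_mm = frr_dist(24.35, 6.0875),
                    frr_ms = frr_dist(3.85, 0.962),
                    frr_mp = frr_dist(37.33, 9.332))))
  names(s) <- vapply(s, `[[`, "", "name")
  s
}

#' Write the packaged base-case configuration to a file
#'
#' Regenerates the YAML configuration shipped at
#' `inst/extdata/table2.yaml` from [table2_parameter_set()] and
#' [table2_strategies()].
#'
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
make_table2_fixture <- function(path) {
  write_model_config(table2_parameter_set(), table2_strategies(), path)
}

#' The default synthetic background life table
#'
#' Gompertz table anchored at the published age-60 annual death probability
#' 0.0095, slope 0.085/yr, closed at age 110. Stands in for the national
#' life table, whose edition is not deposited.
#'
#' @return A `sarco_lifetable`.
#' @export
default_life_table <- function() gompertz_life_table()

#' Engineered scenarios with closed-form lifetime outcomes
#'
#' Returns a configuration together with analytically computed expected
#' outcomes (evaluated independently of the cohort engine):
#' \describe{
#'   \item{no-events}{no falls, no deaths until the forced terminal age
#'     (20-cycle horizon): discounted QALYs are the annuity
#'     `u * sum_{t=0}^{19} (1+r)^{-t}`; off-treatment cost is 0.}
#'   \item{constant-mortality}{flat annual death probability 0.2, no falls,
#'     no discounting (50-cycle horizon): QALYs are the truncated geometric
#'     series `u * (1 - 0.8^50) / 0.2`.}
#'   \item{one-cycle}{certain death after the first cycle: QALYs equal one
#'     year at the sarcopenic utility.}
#' }
#' All analytic values refer to the off-treatment arm of the comparator.
#'
#' @param kind One of `"no-events"`, `"constant-mortality"`, `"one-cycle"`.
#' @return List: `params`, `strategies`, `life_table`, `expected`
#'   (list with `cost`, `qalys`), `kind`.
#' @export
make_toy_scenario <- function(kind = c("no-events", "constant-mortality",
                                       "one-cycle")) {
  kind <- match.arg(kind)
  params <- table2_parameter_set()
  strategies <- table2_strategies()
  v <- unclass(params)
  if (kind == "no-events") {
    v$p_fall <- 0
    p <- structure(v, dists = attr(params, "dists"), class = "sarco_params")
    Tcyc <- 20L
    lt <- new_life_table(60:(60 + Tcyc - 1L), c(rep(0, Tcyc - 1L), 1))
    r <- p$discount_rate_outcomes
    qalys <- p$utility_sarcopenic * sum((1 + r)^-(0:(Tcyc - 1L)))
    expected <- list(cost = 0, qalys = qalys)
  } else if (kind == "constant-mortality") {
    v$p_fall <- 0
    v$discount_rate_costs <- 0
    v$discount_rate_outcomes <- 0
    v$hr_sarcopenia_mortality <- 1
    p <- structure(v, dists = attr(params, "dists"), class = "sarco_params")
    q <- 0.2
    Tcyc <- 50L
    lt <- new_life_table(60:(60 + Tcyc - 1L), c(rep(q, Tcyc - 1L), 1))
    # survivorship is geometric; the final cycle still rewards its survivors
    qalys <- p$utility_sarcopenic * (1 - (1 - q)^Tcyc) / q
    expected <- list(cost = 0, qalys = qalys)
  } else {
    p <- params
    lt <- new_life_table(60L, 1)
    expected <- list(cost = 0, qalys = params$utility_sarcopenic)
  }
  list(params = p, strategies = strategies, life_table = lt,
       expected = expected, kind = kind)
}

#' Generate a random valid model configuration
#'
#' Draws a random but invariant-respecting configuration from the current R
#' random number stream: probabilities in `[0, 0.5]`, log-uniform costs, a
#' random Gompertz life table, and 2 to 8 strategies always including the
#' `"None"` comparator. Used for property-style testing.
#'
#' @return List: `params`, `strategies`, `life_table`.
#' @export
random_scenario <- function() {
  u <- stats::runif(1, 0.3, 1)
  values <- list(
    discount_rate_costs = stats::runif(1, 0, 0.1),
    discount_rate_outcomes = stats::runif(1, 0, 0.1),
    q60_background = stats::runif(1, 0.001, 0.05),
    hr_sarcopenia_mortality = stats::runif(1, 1, 3),
    rr_fracture_mortality_y1 = stats::runif(1, 1, 8),
    p_fall = stats::runif(1, 0, 0.5),
    p_fracture_given_fall = stats::runif(1, 0, 0.5),
    utility_sarcopenic = u,
    disutility_fracture_y1 = stats::runif(1, 0, u),
    disutility_post_fracture = stats::runif(1, 0, u),
    cost_fracture_y1 = exp(stats::runif(1, log(100), log(50000))),
    cost_post_fracture = exp(stats::runif(1, log(10), log(10000))),
    cost_visits_labs = exp(stats::runif(1, log(10), log(1000))),
    wtp = exp(stats::runif(1, log(1000), log(100000))),
    ppp_rial_per_dollar = 29704)
  params <- parameter_set(values)
  n_extra <- sample(1:7, 1)
  strategies <- c(list(strategy_spec("None", annual_cost = 0)),
                  lapply(seq_len(n_extra), function(i) {
                    strategy_spec(paste0("S", i),
                                  annual_cost = exp(stats::runif(1, log(10), log(20000))),
                                  frr_mm = stats::runif(1, 0, 60),
                                  frr_ms = stats::runif(1, 0, 60),
                                  frr_mp = stats::runif(1, 0, 60),
                                  acceptance = stats::runif(1, 0.5, 1))
                  }))
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  lt <- gompertz_life_table(q_anchor = stats::runif(1, 0.003, 0.03),
                            anchor_age = 60,
                            slope = stats::runif(1, 0.02, 0.12),
                            max_age = sample(90:110, 1))
  list(params = params, strategies = strategies, life_table = lt)
}

#' Individual-level microsimulation oracle
#'
#' Estimates the expected discounted cost and QALYs of one arm by simulating
#' `n_paths` individual trajectories through the same per-cycle transition
#' probabilities and rewards as the cohort engine, sampling states rather
#' than propagating occupancy fractions. Serves as an independent
#' Monte-Carlo check on the cohort matrix arithmetic.
#'
#' @inheritParams run_arm
#' @param n_paths Number of simulated individuals.
#' @param seed Integer seed.
#' @return List: `cost`, `qalys` (means), `cost_se`, `qalys_se` (standard
#'   errors), `n_paths`.
#' @export
microsim_oracle <- function(strategy, arm, params, life_table,
                            n_paths = 10000L, seed = 1L, start_age = 60) {
  stopifnot(n_paths >= 1)
  arm <- match.arg(arm, ARMS)
  set.seed(seed)
  ages <- seq.int(start_age, life_table$age[nrow(life_table)])
  n <- length(ages)
  qx <- lt_qx(life_table, ages)
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
  dc <- (1 + params$discount_rate_costs)^-(0:(n - 1))
  do <- (1 + params$discount_rate_outcomes)^-(0:(n - 1))
  state <- rep(1L, n_paths)
  cost <- qaly <- numeric(n_paths)
  for (t in seq_len(n)) {
    alive <- state != 4L
    if (!any(alive)) break
    cost <- cost + state_cost[state] * dc[t]
    qaly <- qaly + state_util[state] * do[t]
    pd_s <- 1 - (1 - qx[t])^hr
    pd_f <- 1 - (1 - qx[t])^(hr * rr)
    u1 <- stats::runif(n_paths)
    u2 <- stats::runif(n_paths)
    new <- state
    sp <- alive & state != 2L                     # sarcopenic / post-fracture
    dies <- sp & u1 < pd_s
    fx <- sp & !dies & u2 < p_fx
    new[dies] <- 4L
    new[fx] <- 2L
    ft <- alive & state == 2L                     # fracture-year tunnel
    fdies <- ft & u1 < pd_f
    new[fdies] <- 4L
    new[ft & !fdies] <- 3L
    # survivors of sarcopenic stay 1, of post-fracture stay 3 (no change)
    state <- new
  }
  list(cost = mean(cost), qalys = mean(qaly),
       cost_se = stats::sd(cost) / sqrt(n_paths),
       qalys_se = stats::sd(qaly) / sqrt(n_paths),
       n_paths = n_paths)
}
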