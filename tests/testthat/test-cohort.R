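# The Markov cohort engine: transition rows, rewards, traces, decision-tree
# weighting, conservation/absorption invariants and the microsimulation check.

test_that("combined fall-risk reduction is the capped equal-weight sum", {
  none <- strategy_spec("None", 0)
  expect_equal(combined_fall_risk_reduction(none), 0)
  d <- strategy_spec("D", 129.276, frr_mp = 27.08)
  expect_equal(combined_fall_risk_reduction(d), 0.2708)
  pd <- strategy_spec("P+D", 5592.605, frr_mm = 46.52, frr_ms = 1.6,
                      frr_mp = 20.1)
  expect_equal(combined_fall_risk_reduction(pd), 0.6822)
  big <- strategy_spec("X", 1, frr_mm = 60, frr_ms = 60, frr_mp = 60)
  expect_equal(combined_fall_risk_reduction(big), 1)
})

test_that("transition rows match hand-computed probabilities and sum to one", {
  cfg <- fixture_config()
  lt <- default_life_table()
  d <- cfg$strategies[["D"]]

  dead <- build_transition_row("dead", 60, "off_treatment", d, cfg$params, lt)
  expect_equal(unname(dead), c(0, 0, 0, 1))

  # off-treatment sarcopenic at 60: death first, then fall * fracture
  p_die <- 1 - (1 - 0.0095)^1.6
  p_fx <- (1 - p_die) * 0.155 * 0.33
  row <- build_transition_row("sarcopenic", 60, "off_treatment", d,
                              cfg$params, lt)
  expect_equal(unname(row["dead"]), p_die, tolerance = 1e-12)
  expect_equal(unname(row["fracture_year"]), p_fx, tolerance = 1e-12)
  expect_equal(unname(row["sarcopenic"]), 1 - p_die - p_fx, tolerance = 1e-12)
  expect_equal(sum(row), 1, tolerance = 1e-15)

  # on-treatment: fall probability scaled by (1 - combined FRR)
  row_on <- build_transition_row("sarcopenic", 60, "on_treatment", d,
                                 cfg$params, lt)
  expect_equal(unname(row_on["fracture_year"]),
               (1 - p_die) * 0.155 * (1 - 0.2708) * 0.33, tolerance = 1e-12)

  # fracture-year tunnel: combined HR x RR mortality, survivors all move on
  row_fx <- build_transition_row("fracture_year", 60, "off_treatment", d,
                                 cfg$params, lt)
  p_die_fx <- 1 - (1 - 0.0095)^(1.6 * 6.57)
  expect_equal(unname(row_fx["dead"]), p_die_fx, tolerance = 1e-12)
  expect_equal(unname(row_fx["post_fracture"]), 1 - p_die_fx, tolerance = 1e-12)
  expect_equal(unname(row_fx["sarcopenic"]), 0)

  # post-fracture allows re-fracture at the same adjusted probabilities
  row_pf <- build_transition_row("post_fracture", 70, "on_treatment", d,
                                 cfg$params, lt)
  q70 <- lt$qx[lt$age == 70]
  pd70 <- 1 - (1 - q70)^1.6
  expect_equal(unname(row_pf["fracture_year"]),
               (1 - pd70) * 0.155 * (1 - 0.2708) * 0.33, tolerance = 1e-12)
  expect_equal(sum(row_pf), 1, tolerance = 1e-15)

  expect_error(build_transition_row("sarcopenic", 200, "off_treatment", d,
                                    cfg$params, lt), "outside")
})

test_that("cycle rewards price states and arms as configured", {
  cfg <- fixture_config()
  p <- cfg$params
  pr <- cfg$strategies[["P"]]
  expect_equal(cycle_rewards("dead", "off_treatment", pr, p),
               c(cost = 0, utility = 0))
  expect_equal(cycle_rewards("fracture_year", "off_treatment", pr, p),
               c(cost = 12588.214, utility = 0.785 - 0.25))
  expect_equal(cycle_rewards("post_fracture", "off_treatment", pr, p),
               c(cost = 2517.64, utility = 0.785 - 0.17))
  # on-treatment alive states accrue intervention + visit/lab costs
  expect_equal(cycle_rewards("sarcopenic", "on_treatment", pr, p),
               c(cost = 5463.329 + 400.409, utility = 0.785))
  expect_equal(cycle_rewards("sarcopenic", "off_treatment", pr, p),
               c(cost = 0, utility = 0.785))
})

test_that("engine reproduces closed-form annuities on toy scenarios", {
  toy <- make_toy_scenario("no-events")
  tr <- run_arm(toy$strategies[["None"]], "off_treatment", toy$params,
                toy$life_table)
  expect_equal(attr(tr, "total_qalys"), toy$expected$qalys, tolerance = 1e-10)
  expect_equal(attr(tr, "total_cost"), toy$expected$cost, tolerance = 1e-10)
  # the spec'd spot value of the 20-cycle 5% annuity at utility 0.785
  expect_equal(toy$expected$qalys, 10.271, tolerance = 1e-4)

  cm <- make_toy_scenario("constant-mortality")
  tr2 <- run_arm(cm$strategies[["None"]], "off_treatment", cm$params,
                 cm$life_table)
  expect_equal(attr(tr2, "total_qalys"), cm$expected$qalys, tolerance = 1e-10)

  oc <- make_toy_scenario("one-cycle")
  tr3 <- run_arm(oc$strategies[["None"]], "off_treatment", oc$params,
                 oc$life_table)
  expect_equal(attr(tr3, "total_qalys"), oc$expected$qalys, tolerance = 1e-12)
  expect_equal(tr3$dead[nrow(tr3)], 1)

  # zero discounting: QALYs equal utility-weighted life years
  cfg <- fixture_config()
  v <- unclass(cfg$params)
  v$discount_rate_costs <- 0
  v$discount_rate_outcomes <- 0
  p0 <- structure(v, dists = attr(cfg$params, "dists"),
                  class = "sarco_params")
  lt <- gompertz_life_table(max_age = 90)
  tr4 <- run_arm(cfg$strategies[["None"]], "off_treatment", p0, lt)
  occ <- as.data.frame(tr4)[seq_len(nrow(lt)), ]
  ly <- occ$sarcopenic * 0.785 + occ$fracture_year * (0.785 - 0.25) +
    occ$post_fracture * (0.785 - 0.17)
  expect_equal(attr(tr4, "total_qalys"), sum(ly), tolerance = 1e-10)
})

test_that("traces conserve occupancy and absorb into death", {
  cfg <- fixture_config()
  lt <- default_life_table()
  for (nm in c("None", "D", "P+D+E")) {
    for (arm in c("on_treatment", "off_treatment")) {
      if (nm == "None" && arm == "on_treatment") next
      tr <- run_arm(cfg$strategies[[nm]], arm, cfg$params, lt)
      occ <- tr$sarcopenic + tr$fracture_year + tr$post_fracture + tr$dead
      expect_true(all(abs(occ - 1) < 1e-9))
      expect_true(all(diff(tr$dead) >= -1e-12))
      expect_equal(tr$dead[nrow(tr)], 1, tolerance = 1e-12)
    }
  }
  # the same invariants on random scenarios
  set.seed(11)
  for (k in 1:5) {
    sc <- random_scenario()
    s <- sc$strategies[[length(sc$strategies)]]
    tr <- run_arm(s, "on_treatment", sc$params, sc$life_table)
    occ <- tr$sarcopenic + tr$fracture_year + tr$post_fracture + tr$dead
    expect_true(all(abs(occ - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_equal(tr$dead[nrow(tr)], 1, tolerance = 1e-12)
  }
})

test_that("decision-tree weighting and effect monotonicity hold", {
  cfg <- fixture_config()
  lt <- default_life_table()
  d <- cfg$strategies[["D"]]

  d1 <- d; d1$acceptance <- 1
  out1 <- run_strategy(d1, cfg$params, lt)
  on <- run_arm(d, "on_treatment", cfg$params, lt)
  expect_equal(out1$cost, attr(on, "total_cost"), tolerance = 1e-12)
  expect_equal(out1$qalys, attr(on, "total_qalys"), tolerance = 1e-12)

  d0 <- d; d0$acceptance <- 0
  out0 <- run_strategy(d0, cfg$params, lt)
  none <- run_strategy(cfg$strategies[["None"]], cfg$params, lt)
  expect_equal(out0$cost, none$cost, tolerance = 1e-12)
  expect_equal(out0$qalys, none$qalys, tolerance = 1e-12)

  # more fall-risk reduction never reduces QALYs (costs held fixed)
  qal <- vapply(seq(0, 60, by = 10), function(f) {
    s <- strategy_spec("X", annual_cost = d$annual_cost, frr_mp = f,
                       acceptance = 0.9)
    run_strategy(s, cfg$params, lt)$qalys
  }, 0)
  expect_true(all(diff(qal) > 0))

  # an active strategy has strictly fewer lifetime fractures than none
  tr_none <- run_arm(cfg$strategies[["None"]], "off_treatment", cfg$params, lt)
  tr_d <- run_arm(d, "on_treatment", cfg$params, lt)
  expect_lt(sum(tr_d$fracture_year), sum(tr_none$fracture_year))
})

test_that("cohort engine agrees with the microsimulation oracle", {
  cfg <- fixture_config()
  lt <- default_life_table()

  # degenerate check: no events, every path identical, SE zero
  toy <- make_toy_scenario("no-events")
  ms0 <- microsim_oracle(toy$strategies[["None"]], "off_treatment",
                         toy$params, toy$life_table, n_paths = 50, seed = 1)
  expect_equal(ms0$qalys_se, 0)
  expect_equal(ms0$qalys, toy$expected$qalys, tolerance = 1e-10)

  # base case off treatment within 3 Monte-Carlo standard errors
  eng <- run_arm(cfg$strategies[["None"]], "off_treatment", cfg$params, lt)
  ms <- microsim_oracle(cfg$strategies[["None"]], "off_treatment",
                        cfg$params, lt, n_paths = 40000, seed = 2024)
  expect_lt(abs(ms$qalys - attr(eng, "total_qalys")), 3 * ms$qalys_se)
  expect_lt(abs(ms$cost - attr(eng, "total_cost")), 3 * ms$cost_se)

  # and on three random scenarios, on-treatment
  set.seed(5)
  for (k in 1:3) {
    sc <- random_scenario()
    s <- sc$strategies[[length(sc$strategies)]]
    eng <- run_arm(s, "on_treatment", sc$params, sc$life_table)
    ms <- microsim_oracle(s, "on_treatment", sc$params, sc$life_table,
                          n_paths = 20000, seed = 100 + k)
    expect_lt(abs(ms$qalys - attr(eng, "total_qalys")),
              3 * max(ms$qalys_se, 1e-12))
    expect_lt(abs(ms$cost - attr(eng, "total_cost")),
              3 * max(ms$cost_se, 1e-12))
  }
})
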