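# Tornado, PSA, acceptability curves and value-of-information analysis.

test_that("tornado bars have closed-form behaviour on engineered ranges", {
  cfg <- fixture_config()
  lt <- gompertz_life_table(max_age = 85)  # shorter horizon, cheaper reruns

  # zero-width range -> zero-spread bar
  tb <- tornado(cfg$params, cfg$strategies, lt,
                parameters = "cost_fracture_y1",
                ranges = list(cost_fracture_y1 = c(12588.214, 12588.214)))
  expect_equal(tb$spread, 0)

  # the incremental NMB is exactly linear in the first-year fracture cost,
  # so the spread equals |slope| * (high - low) with the slope estimated
  # from two independent points
  tb2 <- tornado(cfg$params, cfg$strategies, lt,
                 parameters = "cost_fracture_y1",
                 ranges = list(cost_fracture_y1 = c(8000, 16000)))
  probe <- function(v) {
    t1 <- tornado(cfg$params, cfg$strategies, lt,
                  parameters = "cost_fracture_y1",
                  ranges = list(cost_fracture_y1 = c(v, v)))
    t1$nmb_low
  }
  slope <- (probe(11000) - probe(10000)) / 1000
  expect_equal(tb2$spread, abs(slope) * 8000, tolerance = 1e-9)
  # and the three points are collinear
  mid <- probe(12000)
  expect_equal(mid, (probe(8000) + probe(16000)) / 2, tolerance = 1e-6)

  # ranges outside the parameter support are rejected
  expect_error(tornado(cfg$params, cfg$strategies, lt,
                       parameters = "p_fall",
                       ranges = list(p_fall = c(-0.1, 0.4))),
               "support")
})

test_that("default tornado varies every uncertain global parameter, sorted by spread", {
  cfg <- fixture_config()
  lt <- gompertz_life_table(max_age = 85)
  tb <- tornado(cfg$params, cfg$strategies, lt)
  uncertain <- c("discount_rate_costs", "discount_rate_outcomes",
                 "hr_sarcopenia_mortality", "rr_fracture_mortality_y1",
                 "p_fall", "p_fracture_given_fall", "utility_sarcopenic",
                 "disutility_fracture_y1", "disutility_post_fracture",
                 "cost_fracture_y1", "cost_post_fracture")
  expect_setequal(tb$parameter, uncertain)
  expect_true(all(diff(tb$spread) <= 0))
  expect_true(all(tb$spread >= 0))
  # published CI / range endpoints are used where given
  hr <- tb[tb$parameter == "hr_sarcopenia_mortality", ]
  expect_equal(c(hr$low, hr$high), c(1.24, 2.06))
  dc <- tb[tb$parameter == "discount_rate_costs", ]
  expect_equal(c(dc$low, dc$high), c(0.02, 0.10))
})

test_that("PSA is seed-reproducible and degenerates to the base case", {
  cfg <- fixture_config()
  lt <- gompertz_life_table(max_age = 90)
  p1 <- run_psa(cfg$params, cfg$strategies, lt, n_iterations = 25, seed = 42)
  p2 <- run_psa(cfg$params, cfg$strategies, lt, n_iterations = 25, seed = 42)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qalys, p2$qalys)
  p3 <- run_psa(cfg$params, cfg$strategies, lt, n_iterations = 25, seed = 43)
  expect_false(identical(p1$cost, p3$cost))

  # all distributions replaced by point masses -> every draw equals base case
  fixed <- parameter_set(unclass(cfg$params))
  strat0 <- lapply(cfg$strategies, function(s) { s$dists <- list(); s })
  psa0 <- run_psa(fixed, strat0, lt, n_iterations = 3, seed = 1)
  base <- outcomes_table(run_all_strategies(cfg$params, cfg$strategies, lt))
  for (i in 1:3) {
    expect_equal(unname(psa0$cost[i, ]), base$cost, tolerance = 1e-12)
    expect_equal(unname(psa0$qalys[i, ]), base$qalys, tolerance = 1e-12)
  }

  expect_error(run_psa(cfg$params, cfg$strategies, lt, n_iterations = 0),
               ">= 1")
})

test_that("PSA means track base-case outcomes within a convexity margin", {
  cfg <- fixture_config()
  lt <- gompertz_life_table(max_age = 90)
  psa <- run_psa(cfg$params, cfg$strategies, lt, n_iterations = 400, seed = 9)
  base <- outcomes_table(run_all_strategies(cfg$params, cfg$strategies, lt))
  for (s in c("None", "D", "P+D")) {
    expect_lt(abs(mean(psa$cost[, s]) - base$cost[base$strategy == s]) /
                max(base$cost[base$strategy == s], 1), 0.10)
    expect_lt(abs(mean(psa$qalys[, s]) - base$qalys[base$strategy == s]) /
                base$qalys[base$strategy == s], 0.10)
  }
})

test_that("acceptability probabilities are well-formed and tie-aware", {
  # hand-built PSA objects exercise the decision arithmetic directly
  mk <- function(cost, qalys) {
    structure(list(n_iterations = nrow(cost), seed = 1,
                   strategies = colnames(cost), cost = cost, qalys = qalys,
                   draws = data.frame()),
              class = "sarco_psa")
  }
  # one strategy cheaper AND more effective in every draw
  cost <- cbind(a = c(1, 1), b = c(2, 2))
  q <- cbind(a = c(2, 2), b = c(1, 1))
  expect_equal(acceptability_at_wtp(mk(cost, q), 10),
               c(a = 1, b = 0))
  # two identical strategies split the ties equally
  cost2 <- cbind(a = c(1, 1), b = c(1, 1))
  q2 <- cbind(a = c(1, 1), b = c(1, 1))
  expect_equal(acceptability_at_wtp(mk(cost2, q2), 10), c(a = 0.5, b = 0.5))

  cfg <- fixture_config()
  lt <- gompertz_life_table(max_age = 90)
  psa <- run_psa(cfg$params, cfg$strategies, lt, n_iterations = 60, seed = 5)
  acc <- acceptability_at_wtp(psa, cfg$params$wtp)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_equal(sum(acc), 1, tolerance = 1e-12)

  cc <- ceac(psa, base_wtp = cfg$params$wtp)
  expect_equal(nrow(cc), 61L)
  probs <- as.matrix(cc[, -1])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)), tolerance = 1e-12)
  # consistency: the curve at the base threshold equals the spot value
  at <- which.min(abs(cc$wtp - cfg$params$wtp))
  expect_equal(unname(unlist(cc[at, -1])),
               unname(acceptability_at_wtp(psa, cc$wtp[at])),
               tolerance = 1e-12)
})

test_that("EVPI matches hand enumeration and its invariants", {
  mk <- function(cost, qalys) {
    structure(list(n_iterations = nrow(cost), seed = 1,
                   strategies = colnames(cost), cost = cost, qalys = qalys,
                   draws = data.frame()),
              class = "sarco_psa")
  }
  # two strategies, two equiprobable draws with NMBs {(10,0),(0,10)}:
  # EVPI = mean(10, 10) - max(5, 5) = 5 (costs encode the NMBs at wtp 0)
  psa <- mk(cbind(a = c(-10, 0), b = c(0, -10)),
            cbind(a = c(0, 0), b = c(0, 0)))
  e <- evpi(psa, 0)
  expect_equal(e$evpi, 5)

  # a universal winner has zero value of information
  psa2 <- mk(cbind(a = c(1, 2), b = c(5, 7)), cbind(a = c(3, 3), b = c(3, 3)))
  expect_equal(evpi(psa2, 10)$evpi, 0)
  expect_equal(evpi(psa2, 10)$optimal_strategy, "a")

  # non-negativity on random draw matrices
  set.seed(22)
  for (k in 1:50) {
    n <- sample(2:20, 1); s <- sample(2:6, 1)
    psa3 <- mk(matrix(stats::runif(n * s, 0, 100), n, s,
                      dimnames = list(NULL, paste0("s", 1:s))),
               matrix(stats::runif(n * s, 0, 10), n, s,
                      dimnames = list(NULL, paste0("s", 1:s))))
    for (w in c(0, 10, 50)) expect_gte(evpi(psa3, w)$evpi, -1e-12)
  }

  # degenerate PSA (point masses): EVPI identically zero along the curve
  cfg <- fixture_config()
  lt <- gompertz_life_table(max_age = 90)
  fixed <- parameter_set(unclass(cfg$params))
  strat0 <- lapply(cfg$strategies, function(s) { s$dists <- list(); s })
  psa0 <- run_psa(fixed, strat0, lt, n_iterations = 4, seed = 2)
  curve <- evpi_curve(psa0, c(0, 25249.13, 50000))
  expect_equal(curve$evpi, rep(0, 3), tolerance = 1e-9)

  # on a real PSA the EVPI rises with the threshold beyond it
  psa4 <- run_psa(cfg$params, cfg$strategies, lt, n_iterations = 120, seed = 8)
  cv <- evpi_curve(psa4, c(25249.13, 2 * 25249.13))
  expect_gte(cv$evpi[2], cv$evpi[1])
  expect_true(all(cv$evpi >= 0))
})
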