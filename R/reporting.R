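# Reporting layer: run configuration, manifests, and bit-stable CSV outputs
# for each analysis stage. A thin command-line dispatcher over these
# functions ships at inst/cli/sarco-cea.R.

say <- function(quiet, ...) if (!quiet) message(...)

resolve_inputs <- function(config, lifetable = NULL) {
  cfg <- load_model_config(config)
  lt <- if (is.null(lifetable)) default_life_table()
        else read_life_table(lifetable)
  list(params = cfg$params, strategies = cfg$strategies, life_table = lt)
}

write_manifest <- function(out_dir, command, config, extra = list()) {
  manifest <- c(list(command = command, config = config,
                     package_version = as.character(utils::packageVersion("sarcocea")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

prepare_out <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  invisible(out_dir)
}

#' Base-case cost-utility analysis to CSV
#'
#' Runs every strategy at base-case parameter values, writes the full
#' common-baseline CEA table (`cea_full.csv`), the frontier-only table
#' (`cea_frontier.csv`) and a run manifest, and logs the cost-effective
#' strategy at the configured threshold.
#'
#' @param config Path to a YAML model configuration.
#' @param out_dir Output directory (created if missing).
#' @param lifetable Optional life-table CSV; default is the packaged
#'   synthetic Gompertz table.
#' @param wtp Threshold override; defaults to the configured value.
#' @param discount_costs,discount_outcomes Optional discount-rate overrides.
#' @param start_age Cohort entry age.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the `sarco_cea` table and the decision.
#' @export
cmd_basecase <- function(config, out_dir, lifetable = NULL, wtp = NULL,
                         discount_costs = NULL, discount_outcomes = NULL,
                         start_age = 60, quiet = FALSE) {
  inp <- resolve_inputs(config, lifetable)
  if (!length(inp$strategies)) stop("cmd_basecase: empty strategy list")
  p <- inp$params
  if (!is.null(discount_costs)) p$discount_rate_costs <- discount_costs
  if (!is.null(discount_outcomes)) p$discount_rate_outcomes <- discount_outcomes
  if (is.null(wtp)) wtp <- p$wtp
  prepare_out(out_dir)
  say(quiet, "running ", length(inp$strategies), " strategies...")
  outcomes <- run_all_strategies(p, inp$strategies, inp$life_table, start_age)
  cea <- efficiency_frontier(outcomes)
  write_cea_tables(cea, file.path(out_dir, "cea_full.csv"),
                   file.path(out_dir, "cea_frontier.csv"))
  decision <- decide_cost_effective(cea, wtp)
  say(quiet, sprintf("cost-effective strategy at WTP %.2f: %s", wtp, decision))
  write_manifest(out_dir, "basecase", config,
                 list(wtp = wtp, start_age = start_age,
                      discount_costs = p$discount_rate_costs,
                      discount_outcomes = p$discount_rate_outcomes))
  invisible(list(cea = cea, decision = decision, wtp = wtp))
}

#' Probabilistic sensitivity analysis to CSV
#'
#' Runs the Monte-Carlo PSA and writes the per-draw cost/QALY matrices
#' (`psa_draws.csv`), the acceptability at the threshold
#' (`acceptability.csv`), the acceptability curve (`ceac.csv`), the
#' incremental scatter of the top frontier pair (`psa_scatter.csv`) and a
#' manifest. Outputs are byte-identical across reruns with the same
#' configuration and seed.
#'
#' @inheritParams cmd_basecase
#' @param iterations Number of Monte-Carlo repetitions (>= 1).
#' @param seed Integer seed.
#' @param scatter_pair Two strategy names for the incremental scatter.
#' @return Invisibly, the `sarco_psa`.
#' @export
cmd_psa <- function(config, out_dir, lifetable = NULL, iterations = 1000,
                    seed = 1L, wtp = NULL, scatter_pair = c("P+D", "D"),
                    start_age = 60, quiet = FALSE) {
  if (!is.numeric(iterations) || iterations < 1)
    stop("cmd_psa: iterations must be >= 1")
  inp <- resolve_inputs(config, lifetable)
  if (is.null(wtp)) wtp <- inp$params$wtp
  prepare_out(out_dir)
  say(quiet, "PSA: ", iterations, " iterations, seed ", seed)
  psa <- run_psa(inp$params, inp$strategies, inp$life_table,
                 n_iterations = iterations, seed = seed, start_age = start_age)
  draws <- data.frame(draw = seq_len(psa$n_iterations), psa$draws,
                      stats::setNames(as.data.frame(psa$cost),
                                      paste0("cost.", psa$strategies)),
                      stats::setNames(as.data.frame(psa$qalys),
                                      paste0("qalys.", psa$strategies)),
                      check.names = FALSE)
  utils::write.csv(draws, file.path(out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  acc <- acceptability_at_wtp(psa, wtp)
  utils::write.csv(data.frame(strategy = names(acc),
                              probability = as.numeric(acc)),
                   file.path(out_dir, "acceptability.csv"), row.names = FALSE)
  cc <- ceac(psa, base_wtp = wtp)
  utils::write.csv(as.data.frame(cc), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  if (all(scatter_pair %in% psa$strategies))
    utils::write.csv(psa_scatter(psa, scatter_pair),
                     file.path(out_dir, "psa_scatter.csv"), row.names = FALSE)
  write_manifest(out_dir, "psa", config,
                 list(seed = seed, iterations = iterations, wtp = wtp,
                      start_age = start_age))
  invisible(psa)
}

#' Deterministic (tornado) sensitivity analysis to CSV
#'
#' @inheritParams cmd_basecase
#' @param pair Two strategy names whose incremental net monetary benefit is
#'   the tornado outcome.
#' @return Invisibly, the `sarco_tornado`.
#' @export
cmd_dsa <- function(config, out_dir, lifetable = NULL, wtp = NULL,
                    pair = c("P+D", "D"), start_age = 60, quiet = FALSE) {
  inp <- resolve_inputs(config, lifetable)
  if (is.null(wtp)) wtp <- inp$params$wtp
  prepare_out(out_dir)
  say(quiet, "tornado on incremental NMB of ", pair[1], " vs ", pair[2])
  tb <- tornado(inp$params, inp$strategies, inp$life_table, pair = pair,
                wtp = wtp, start_age = start_age)
  utils::write.csv(as.data.frame(tb), file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "dsa", config,
                 list(wtp = wtp, pair = pair, start_age = start_age))
  invisible(tb)
}

#' Expected value of perfect information to CSV
#'
#' Runs the PSA, writes the per-person EVPI at the configured threshold
#' (`evpi.csv`) and the EVPI curve over a threshold grid
#' (`evpi_curve.csv`), plus a manifest.
#'
#' @inheritParams cmd_psa
#' @param wtp_grid Threshold grid for the curve; default
#'   `seq(0, 3 * wtp, length.out = 61)`.
#' @return Invisibly, a list with the `sarco_evpi` and the curve.
#' @export
cmd_evpi <- function(config, out_dir, lifetable = NULL, iterations = 1000,
                     seed = 1L, wtp = NULL, wtp_grid = NULL, start_age = 60,
                     quiet = FALSE) {
  if (!is.numeric(iterations) || iterations < 1)
    stop("cmd_evpi: iterations must be >= 1")
  inp <- resolve_inputs(config, lifetable)
  if (is.null(wtp)) wtp <- inp$params$wtp
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 3 * wtp, length.out = 61L)
  prepare_out(out_dir)
  say(quiet, "EVPI: ", iterations, " PSA iterations, seed ", seed)
  psa <- run_psa(inp$params, inp$strategies, inp$life_table,
                 n_iterations = iterations, seed = seed, start_age = start_age)
  e <- evpi(psa, wtp)
  utils::write.csv(data.frame(wtp = e$wtp, evpi = e$evpi,
                              avg_incremental_cost_perfect_info =
                                e$avg_incremental_cost_perfect_info,
                              avg_incremental_eff_perfect_info =
                                e$avg_incremental_eff_perfect_info,
                              optimal_strategy = e$optimal_strategy),
                   file.path(out_dir, "evpi.csv"), row.names = FALSE)
  utils::write.csv(evpi_curve(psa, wtp_grid),
                   file.path(out_dir, "evpi_curve.csv"), row.names = FALSE)
  say(quiet, sprintf("EVPI at WTP %.2f: $%.2f per person", wtp, e$evpi))
  write_manifest(out_dir, "evpi", config,
                 list(seed = seed, iterations = iterations, wtp = wtp,
                      start_age = start_age))
  invisible(list(evpi = e, curve = evpi_curve(psa, wtp_grid), psa = psa))
}
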