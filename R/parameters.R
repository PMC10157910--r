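# Model parameters: global parameter set, strategy specifications, YAML IO,
# and joint probabilistic sampling.

PARAM_NAMES <- c(
  "discount_rate_costs", "discount_rate_outcomes", "q60_background",
  "hr_sarcopenia_mortality", "rr_fracture_mortality_y1",
  "p_fall", "p_fracture_given_fall",
  "utility_sarcopenic", "disutility_fracture_y1", "disutility_post_fracture",
  "cost_fracture_y1", "cost_post_fracture", "cost_visits_labs",
  "wtp", "ppp_rial_per_dollar"
)

STRATEGY_NAMES <- c("None", "E", "P", "D", "WBV", "P+D", "D+E", "P+D+E")

#' Construct and validate the global parameter set
#'
#' Holds all strategy-independent model parameters: annual discount rates for
#' costs and outcomes, the background annual death probability at age 60, the
#' sarcopenia mortality hazard ratio, the first-year fracture mortality
#' relative risk, annual fall probability, fracture probability conditional on
#' a fall, health-state utility and fracture disutilities, fracture-related
#' costs, annual visit/laboratory cost accrued on treatment, the
#' willingness-to-pay threshold and the PPP conversion factor (metadata only).
#'
#' @param values Named list/vector of base-case values; must contain exactly
#'   the names listed above (see `sarcocea:::PARAM_NAMES`).
#' @param dists Named list of [make_dist()] descriptors, one per parameter
#'   (parameters without uncertainty use family `"fixed"`). Missing entries
#'   default to fixed at the base value.
#' @return An object of class `sarco_params`: the named base values, with the
#'   distribution descriptors stored in `attr(, "dists")`.
#' @export
parameter_set <- function(values, dists = list()) {
  values <- as.list(values)
  missing <- setdiff(PARAM_NAMES, names(values))
  if (length(missing))
    stop("parameter_set: missing parameter(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(values), PARAM_NAMES)
  if (length(unknown))
    stop("parameter_set: unknown parameter(s): ", paste(unknown, collapse = ", "))
  values <- values[PARAM_NAMES]
  for (nm in PARAM_NAMES) {
    v <- values[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter_set: '", nm, "' must be a single finite number")
  }
  for (nm in c("q60_background", "p_fall", "p_fracture_given_fall"))
    if (values[[nm]] < 0 || values[[nm]] > 1)
      stop("parameter_set: probability '", nm, "' outside [0, 1]")
  for (nm in c("utility_sarcopenic"))
    if (values[[nm]] < 0 || values[[nm]] > 1)
      stop("parameter_set: utility '", nm, "' outside [0, 1]")
  for (nm in c("disutility_fracture_y1", "disutility_post_fracture")) {
    if (values[[nm]] < 0)
      stop("parameter_set: disutility '", nm, "' must be >= 0")
    if (values[[nm]] > values$utility_sarcopenic)
      stop("parameter_set: disutility '", nm, "' exceeds utility_sarcopenic")
  }
  for (nm in c("cost_fracture_y1", "cost_post_fracture", "cost_visits_labs", "wtp"))
    if (values[[nm]] < 0)
      stop("parameter_set: cost '", nm, "' must be >= 0")
  for (nm in c("hr_sarcopenia_mortality", "rr_fracture_mortality_y1"))
    if (values[[nm]] <= 0)
      stop("parameter_set: '", nm, "' must be > 0")
  for (nm in c("discount_rate_costs", "discount_rate_outcomes"))
    if (values[[nm]] < 0 || values[[nm]] >= 1)
      stop("parameter_set: discount rate '", nm, "' outside [0, 1)")
  unknown <- setdiff(names(dists), PARAM_NAMES)
  if (length(unknown))
    stop("parameter_set: dists for unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  full <- lapply(PARAM_NAMES, function(nm) {
    if (!is.null(dists[[nm]])) {
      d <- dists[[nm]]
      stopifnot(inherits(d, "sarco_dist"))
      d
    } else {
      make_dist("fixed", mean = values[[nm]])
    }
  })
  names(full) <- PARAM_NAMES
  structure(values, dists = full, class = "sarco_params")
}

#' Construct and validate one intervention strategy
#'
#' A strategy is described by its mean annual intervention cost and by the
#' percent fall-risk reductions it achieves through each of the three
#' sarcopenia indicators: muscle mass (`frr_mm`), muscle strength (`frr_ms`)
#' and physical performance (`frr_mp`). Indicators with no published effect
#' contribute 0. `acceptance` is the probability that a patient accepts and
#' adheres to the intervention (decision-tree split); the comparator strategy
#' `"None"` ignores it and runs off treatment.
#'
#' @param name Strategy label, e.g. `"D"` or `"P+D"`.
#' @param annual_cost Mean annual intervention cost ($/yr, >= 0).
#' @param frr_mm,frr_ms,frr_mp Percent fall-risk reduction in `[0, 100]`.
#' @param acceptance Acceptance/adherence probability in `[0, 1]`.
#' @param dosage_note Free-text dosage and duration description.
#' @param dists Named list of [make_dist()] descriptors for any of
#'   `annual_cost`, `frr_mm`, `frr_ms`, `frr_mp`; missing entries are fixed.
#' @return An object of class `sarco_strategy`.
#' @export
strategy_spec <- function(name, annual_cost = 0, frr_mm = 0, frr_ms = 0,
                          frr_mp = 0, acceptance = 0.9, dosage_note = "",
                          dists = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("strategy_spec: 'name' must be a non-empty string")
  if (!is.numeric(annual_cost) || annual_cost < 0)
    stop("strategy_spec: annual_cost must be >= 0")
  for (nm in c("frr_mm", "frr_ms", "frr_mp")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 100)
      stop("strategy_spec: '", nm, "' must lie in [0, 100] (percent)")
  }
  if (!is.numeric(acceptance) || acceptance < 0 || acceptance > 1)
    stop("strategy_spec: acceptance must lie in [0, 1]")
  allowed <- c("annual_cost", "frr_mm", "frr_ms", "frr_mp")
  unknown <- setdiff(names(dists), allowed)
  if (length(unknown))
    stop("strategy_spec: dists for unknown field(s): ",
         paste(unknown, collapse = ", "))
  for (d in dists) stopifnot(inherits(d, "sarco_dist"))
  structure(list(name = name, annual_cost = annual_cost,
                 frr_mm = frr_mm, frr_ms = frr_ms, frr_mp = frr_mp,
                 acceptance = acceptance, dosage_note = dosage_note,
                 dists = dists),
            class = "sarco_strategy")
}

# YAML configuration --------------------------------------------------------

dist_from_config <- function(entry, what, default_support = NULL) {
  allowed <- c("value", "distribution", "sd", "ci95", "range", "support")
  unknown <- setdiff(names(entry), allowed)
  if (length(unknown))
    stop("config: unknown key(s) in '", what, "': ", paste(unknown, collapse = ", "))
  if (is.null(entry$value))
    stop("config: '", what, "' has no 'value'")
  family <- if (is.null(entry$distribution)) "fixed" else entry$distribution
  if (!family %in% c("fixed", "beta", "gamma", "lognormal"))
    stop("config: '", what, "' has unknown distribution '", family, "'")
  support <- entry$support
  if (is.null(support) && family == "beta" && is.null(entry$range))
    support <- default_support
  make_dist(family, mean = entry$value,
            sd = if (is.null(entry$sd)) NULL else entry$sd,
            ci95 = if (is.null(entry$ci95)) NULL else as.numeric(entry$ci95),
            range = if (is.null(entry$range)) NULL else as.numeric(entry$range),
            support = if (is.null(support)) NULL else as.numeric(support))
}

dist_to_config <- function(d) {
  out <- list(value = d$mean)
  if (d$family != "fixed") out$distribution <- d$family
  if (!is.null(d$sd)) out$sd <- d$sd
  if (!is.null(d$ci95)) out$ci95 <- as.numeric(d$ci95)
  if (!is.null(d$range)) out$range <- as.numeric(d$range)
  if (!is.null(d$support)) out$support <- as.numeric(d$support)
  out
}

#' Load a model configuration from YAML
#'
#' The configuration carries a `parameters` block (one entry per global
#' parameter with `value`, optional `distribution` and its `sd` / `ci95` /
#' `range` / `support`) and a `strategies` list. Unknown keys anywhere are
#' rejected, all invariants are checked, and a zero-cost comparator strategy
#' named `"None"` must be present. The packaged base-case configuration is at
#' `system.file("extdata", "table2.yaml", package = "sarcocea")`.
#'
#' @param path Path to a YAML (or JSON, parsed by yaml) configuration file.
#' @return List with elements `params` (a `sarco_params`) and `strategies`
#'   (list of `sarco_strategy`).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("load_model_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("parameters", "strategies"))
  if (length(unknown))
    stop("config: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$parameters) || is.null(cfg$strategies))
    stop("config: needs 'parameters' and 'strategies' blocks")

  pdists <- lapply(names(cfg$parameters), function(nm)
    dist_from_config(cfg$parameters[[nm]], paste0("parameters$", nm)))
  names(pdists) <- names(cfg$parameters)
  values <- lapply(pdists, function(d) d$mean)
  params <- parameter_set(values, dists = pdists)

  if (!length(cfg$strategies)) stop("config: empty strategy list")
  strategies <- lapply(cfg$strategies, function(s) {
    allowed <- c("name", "dosage_note", "acceptance",
                 "annual_cost", "frr_mm", "frr_ms", "frr_mp")
    unknown <- setdiff(names(s), allowed)
    if (length(unknown))
      stop("config: unknown strategy key(s): ", paste(unknown, collapse = ", "))
    if (is.null(s$name)) stop("config: strategy without a name")
    dists <- list()
    vals <- list(annual_cost = 0, frr_mm = 0, frr_ms = 0, frr_mp = 0)
    for (f in c("annual_cost", "frr_mm", "frr_ms", "frr_mp")) {
      if (!is.null(s[[f]])) {
        sup <- if (startsWith(f, "frr_")) c(0, 100) else NULL
        d <- dist_from_config(s[[f]], paste0(s$name, "$", f), default_support = sup)
        vals[[f]] <- d$mean
        if (d$family != "fixed") dists[[f]] <- d
      }
    }
    strategy_spec(name = s$name, annual_cost = vals$annual_cost,
                  frr_mm = vals$frr_mm, frr_ms = vals$frr_ms,
                  frr_mp = vals$frr_mp,
                  acceptance = if (is.null(s$acceptance)) 0.9 else s$acceptance,
                  dosage_note = if (is.null(s$dosage_note)) "" else s$dosage_note,
                  dists = dists)
  })
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  if (anyDuplicated(names(strategies)))
    stop("config: duplicated strategy names")
  if (!"None" %in% names(strategies))
    stop("config: a comparator strategy named 'None' is required")
  none <- strategies[["None"]]
  if (none$annual_cost != 0 || combined_fall_risk_reduction(none) != 0)
    stop("config: the 'None' strategy must have zero cost and zero effect")
  list(params = params, strategies = strategies)
}

#' Write a model configuration to YAML
#'
#' Inverse of [load_model_config()]: a write-then-read round trip reproduces
#' identical objects.
#'
#' @param params A `sarco_params`.
#' @param strategies List of `sarco_strategy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, strategies, path) {
  stopifnot(inherits(params, "sarco_params"))
  dists <- attr(params, "dists")
  pblock <- lapply(PARAM_NAMES, function(nm) dist_to_config(dists[[nm]]))
  names(pblock) <- PARAM_NAMES
  sblock <- lapply(strategies, function(s) {
    stopifnot(inherits(s, "sarco_strategy"))
    out <- list(name = s$name)
    if (nzchar(s$dosage_note)) out$dosage_note <- s$dosage_note
    out$acceptance <- s$acceptance
    for (f in c("annual_cost", "frr_mm", "frr_ms", "frr_mp")) {
      d <- s$dists[[f]]
      if (!is.null(d)) out[[f]] <- dist_to_config(d)
      else if (s[[f]] != 0) out[[f]] <- list(value = s[[f]])
    }
    if (is.null(out$annual_cost)) out$annual_cost <- list(value = 0)
    out
  })
  yaml::write_yaml(list(parameters = pblock, strategies = unname(sblock)), path,
                   precision = 15L)
  invisible(path)
}

# Sampling ------------------------------------------------------------------

#' Draw one joint realization of all uncertain parameters
#'
#' Samples every global parameter and every strategy-level cost / fall-risk
#' reduction from its declared distribution using the current R random number
#' stream (seed it with `set.seed()` for reproducibility). Parameters with a
#' `fixed` descriptor pass through unchanged. The draw order is fixed
#' (global parameters in declaration order, then strategies in list order,
#' each sampling cost then frr_mm/ms/mp), so a given seed yields a
#' bitwise-identical draw.
#'
#' @param params A `sarco_params`.
#' @param strategies List of `sarco_strategy`.
#' @param draw_index Optional integer recorded on the draw.
#' @return List of class `sarco_draw` with elements `params` (a
#'   `sarco_params` of realized values), `strategies` (realized strategies)
#'   and `draw_index`.
#' @export
sample_parameters <- function(params, strategies, draw_index = NA_integer_) {
  stopifnot(inherits(params, "sarco_params"))
  dists <- attr(params, "dists")
  vals <- lapply(PARAM_NAMES, function(nm) sample_dist(dists[[nm]], 1L))
  names(vals) <- PARAM_NAMES
  # keep the realized parameter set valid for downstream invariant checks
  vals$disutility_fracture_y1 <- min(vals$disutility_fracture_y1,
                                     vals$utility_sarcopenic)
  vals$disutility_post_fracture <- min(vals$disutility_post_fracture,
                                       vals$utility_sarcopenic)
  p <- structure(vals, dists = dists, class = "sarco_params")
  strat <- lapply(strategies, function(s) {
    r <- s
    for (f in c("annual_cost", "frr_mm", "frr_ms", "frr_mp")) {
      d <- s$dists[[f]]
      if (!is.null(d) && d$family != "fixed") r[[f]] <- sample_dist(d, 1L)
    }
    r$dists <- list()
    r
  })
  names(strat) <- names(strategies)
  structure(list(params = p, strategies = strat, draw_index = draw_index),
            class = "sarco_draw")
}

#' @export
print.sarco_params <- function(x, ...) {
  cat("<sarco_params>\n")
  for (nm in PARAM_NAMES)
    cat(sprintf("  %-26s %12.6g  [%s]\n", nm, x[[nm]],
                attr(x, "dists")[[nm]]$family))
  invisible(x)
}

#' @export
print.sarco_strategy <- function(x, ...) {
  cat(sprintf("<sarco_strategy %s> cost %.3f $/yr, FRR (mm/ms/mp) %.2f/%.2f/%.2f %%, acceptance %.2f\n",
              x$name, x$annual_cost, x$frr_mm, x$frr_ms, x$frr_mp, x$acceptance))
  invisible(x)
}
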