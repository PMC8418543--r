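# One-at-a-time sensitivity sweeps, plant-capacity rescaling and seeded
# Monte-Carlo scenario ensembles.

#' Run the full pipeline on one scenario
#'
#' Mass balance -> schedule -> capital -> operating cost -> economics.
#'
#' @param scenario a `bmn_scenario`
#' @return list with elements `scenario`, `batch`, `schedule`, `capital`,
#'   `operating`, `economics`
#' @examples
#' res <- evaluate_scenario(builtin_fixture("base_single"))
#' res$economics$unit_production_cost_usd_kg
#' @export
evaluate_scenario <- function(scenario) {
  assert_valid(scenario)
  batch <- simulate_batch(scenario)
  schedule <- build_schedule(scenario, batch)
  capital <- capital_investment(scenario)
  operating <- operating_cost_summary(scenario, batch, schedule, capital)
  economics <- economic_summary(scenario, schedule, capital, operating)
  list(scenario = scenario, batch = batch, schedule = schedule,
       capital = capital, operating = operating, economics = economics)
}

#' One-at-a-time parameter sweep
#'
#' Re-runs the full pipeline for each value of a single scenario parameter
#' (dotted path into the scenario; the special parameter `"capacity"`
#' rescales the whole plant via [capacity_rescale()]).  The base-case row is
#' appended and flagged.  A value that violates the scenario invariants is
#' recorded as a row-level error and the sweep continues.
#'
#' @param base a `bmn_scenario`
#' @param parameter dotted parameter path, e.g.
#'   `"fermentation.magnetite_yield_mg_l"`, or `"capacity"`
#' @param values numeric vector (>= 1 value)
#' @return data frame with one row per value: `parameter`, `value`,
#'   `unit_cost_usd_kg`, `operating_cost_usd_yr`, `msp_usd_kg`,
#'   `annual_product_kg`, `is_base`, `error`
#' @examples
#' oat_sweep(builtin_fixture("base_single"),
#'           "fermentation.magnetite_yield_mg_l", c(80, 250))
#' @export
oat_sweep <- function(base, parameter, values) {
  stopifnot(length(values) >= 1)
  base_value <- if (identical(parameter, "capacity")) 1
    else scenario_get(base, parameter)
  vals <- c(values, base_value)
  is_base <- c(rep(FALSE, length(values)), TRUE)
  rows <- lapply(seq_along(vals), function(i) {
    out <- data.frame(parameter = parameter, value = vals[i],
                      unit_cost_usd_kg = NA_real_,
                      operating_cost_usd_yr = NA_real_,
                      msp_usd_kg = NA_real_, annual_product_kg = NA_real_,
                      is_base = is_base[i], error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      s <- if (identical(parameter, "capacity"))
        capacity_rescale(base, vals[i])
      else scenario_set(base, parameter, vals[i])
      evaluate_scenario(s)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      out$unit_cost_usd_kg <- res$economics$unit_production_cost_usd_kg
      out$operating_cost_usd_yr <- res$operating$total_usd_per_yr
      out$msp_usd_kg <- res$economics$msp_usd_kg
      out$annual_product_kg <- res$schedule$annual_product_kg
    }
    out
  })
  do.call(rbind, rows)
}

#' Rescale plant capacity
#'
#' Scales the fermentation train (vessel, initial and final working
#' volumes) by `factor`, resizes every equipment item to the new duty (its
#' purchase cost then follows the item's power law), and scales operator
#' hours per batch sub-linearly (`factor^labor_scale_exponent`).  Recipe
#' times, efficiencies and prices are unchanged, so annual product scales
#' linearly while capital and labor scale with economies of scale.
#'
#' @param base a `bmn_scenario`
#' @param factor capacity multiplier (> 0)
#' @return a rescaled `bmn_scenario`
#' @export
capacity_rescale <- function(base, factor) {
  if (!is.numeric(factor) || factor <= 0)
    stop("capacity factor must be positive", call. = FALSE)
  s <- base
  for (p in c("fermentation.vessel_volume_m3",
              "fermentation.initial_volume_m3",
              "fermentation.final_working_volume_m3"))
    s <- scenario_set(s, p, scenario_get(s, p) * factor)
  s$equipment <- lapply(s$equipment, function(it) {
    it$size <- it$size * factor
    it
  })
  lexp <- s$cost_factors$labor_scale_exponent
  s$schedule$labor_hours_per_batch <-
    lapply(s$schedule$labor_hours_per_batch, function(h) h * factor^lexp)
  s
}

rtriangular <- function(n, min, mode, max) {
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Default ensemble perturbations
#'
#' Triangular distributions over the one-at-a-time sweep ranges, with the
#' mode at the base-case value: magnetite yield 80-350 mg/L, growth rate
#' 0.06-0.12 1/h, MSC capture 0.65-0.95, lactic acid 0.5-2.5 USD/kg, urea
#' 0.05-0.75 USD/kg, exchange rate 4.0-6.5 BRL/USD.
#'
#' @param base a `bmn_scenario` (supplies the modes)
#' @return named list of perturbation specs
#' @export
default_perturbations <- function(base) {
  tri <- function(path, min, max)
    list(dist = "triangular", min = min,
         mode = scenario_get(base, path), max = max)
  list(
    "fermentation.magnetite_yield_mg_l" =
      tri("fermentation.magnetite_yield_mg_l", 80, 350),
    "fermentation.mu_per_h" = tri("fermentation.mu_per_h", 0.06, 0.12),
    "downstream.msc_efficiency" = tri("downstream.msc_efficiency", 0.65, 0.95),
    "prices.materials.lactic_acid.price" =
      tri("prices.materials.lactic_acid.price", 0.5, 2.5),
    "prices.materials.urea.price" = tri("prices.materials.urea.price",
                                        0.05, 0.75),
    "prices.exchange_rate_brl_per_usd" =
      tri("prices.exchange_rate_brl_per_usd", 4.0, 6.5))
}

#' Generate a randomized scenario ensemble
#'
#' Draws `draws` scenarios around the base case, perturbing each listed
#' parameter independently from its stated distribution (triangular by
#' default; a zero-width distribution reproduces the base value).  Draws
#' violating scenario invariants are rejection-resampled; the resample
#' count is reported in the `"rejected"` attribute.  Deterministic given
#' `seed`.
#'
#' @param base a `bmn_scenario`
#' @param perturbations named list of specs
#'   (`list(dist = "triangular", min, mode, max)`), keyed by parameter path
#' @param draws number of scenarios (>= 1)
#' @param seed integer seed
#' @return list of `bmn_scenario` (attributes: `seed`, `rejected`)
#' @export
scenario_ensemble <- function(base, perturbations = default_perturbations(base),
                              draws = 100, seed = 42) {
  stopifnot(draws >= 1)
  for (sp in perturbations)
    if (!identical(sp$dist, "triangular"))
      stop("unknown distribution family '", sp$dist, "'", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rejected <- 0L
  draw_one <- function() {
    repeat {
      s <- base
      for (path in names(perturbations)) {
        sp <- perturbations[[path]]
        val <- if (sp$max == sp$min) sp$mode
          else rtriangular(1, sp$min, sp$mode, sp$max)
        s <- scenario_set(s, path, val)
      }
      v <- validate_scenario(s)
      if (!any(v$level == "error")) return(s)
      rejected <<- rejected + 1L
    }
  }
  out <- lapply(seq_len(draws), function(i) draw_one())
  attr(out, "seed") <- seed
  attr(out, "rejected") <- rejected
  out
}

#' Monte-Carlo summary of an ensemble
#'
#' Evaluates every ensemble member and summarises unit production cost and
#' MSP as P5/P50/P95 percentiles (linear interpolation).
#'
#' @param ensemble list of scenarios from [scenario_ensemble()]
#' @return data frame (`metric`, `p5`, `p50`, `p95`) with attributes `seed`
#'   and `draws`
#' @export
monte_carlo_summary <- function(ensemble) {
  if (!length(ensemble)) stop("empty ensemble", call. = FALSE)
  res <- lapply(ensemble, evaluate_scenario)
  unit <- vapply(res, function(r) r$economics$unit_production_cost_usd_kg, 0)
  msp <- vapply(res, function(r) r$economics$msp_usd_kg, 0)
  q <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE,
                                   type = 7)
  out <- data.frame(metric = c("unit_cost_usd_kg", "msp_usd_kg"),
                    rbind(q(unit), q(msp)), stringsAsFactors = FALSE)
  names(out)[2:4] <- c("p5", "p50", "p95")
  attr(out, "seed") <- attr(ensemble, "seed")
  attr(out, "draws") <- length(ensemble)
  out
}
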