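# Report-based scenario validation.  Hard invariant breaches are errors;
# soft ones (e.g. working volume above the stated 80% cap, which the
# calibrated fixtures deliberately exceed) are warnings.

violation <- function(level, path, message)
  data.frame(level = level, path = path, message = message,
             stringsAsFactors = FALSE)

no_violations <- function()
  data.frame(level = character(), path = character(), message = character(),
             stringsAsFactors = FALSE)

#' Validate a scenario
#'
#' Checks every type invariant of the scenario data model: strict positivity
#' of volumes, times, rates and prices; efficiencies and fractions in (0, 1];
#' mode-dependent required fields (`harvest_fraction`, `stage2_yield_mg_l`
#' for semicontinuous operation); schedule consistency (cycle time not above
#' batch time); a price entry for every material the process model demands;
#' and the finance block (tax rate in [0, 1), ordered price grid).  Fermenter
#' working volume above `max_working_fraction` of the vessel is a
#' **warning**, not an error.
#'
#' @param s a `bmn_scenario`
#' @return data frame of violations (columns `level`, `path`, `message`);
#'   zero rows of level `"error"` means the scenario is usable
#' @examples
#' v <- validate_scenario(builtin_fixture("base_single"))
#' subset(v, level == "warning")
#' @export
validate_scenario <- function(s) {
  v <- no_violations()
  add <- function(level, path, msg) v <<- rbind(v, violation(level, path, msg))

  pos <- function(path) {
    val <- tryCatch(scenario_get(s, path), error = function(e) NULL)
    if (is.null(val) || !is.numeric(val) || any(val <= 0))
      add("error", path, "must be strictly positive")
  }
  frac <- function(path, open_top = FALSE) {
    val <- tryCatch(scenario_get(s, path), error = function(e) NULL)
    if (is.null(val)) { add("error", path, "missing"); return(invisible()) }
    hi_ok <- if (open_top) val < 1 else val <= 1
    if (!is.numeric(val) || val <= 0 || !hi_ok)
      add("error", path, sprintf("fraction out of range (0,1%s]: %g",
                                 if (open_top) ")" else "", val))
  }

  if (!identical(s$mode, "single_stage") &&
      !identical(s$mode, "semicontinuous"))
    add("error", "mode", "must be 'single_stage' or 'semicontinuous'")

  for (p in c("fermentation.duration_h", "fermentation.mu_per_h",
              "fermentation.aeration_vvm", "fermentation.magnetite_yield_mg_l",
              "fermentation.vessel_volume_m3", "fermentation.initial_volume_m3",
              "fermentation.final_working_volume_m3",
              "fermentation.initial_biomass_g_l", "fermentation.max_biomass_g_l",
              "fermentation.inoculum_expansion_factor",
              "fermentation.inoculum_stages",
              "downstream.homogenizer_passes", "downstream.msc_flowrate_bv_h",
              "downstream.urea_concentration_mol_l",
              "downstream.product_concentration_mg_ml",
              "downstream.urea_kg_per_m3_processed",
              "schedule.annual_operating_time_h", "schedule.batch_time_h",
              "schedule.cycle_time_h", "prices.exchange_rate_brl_per_usd",
              "cost_factors.installation_multiplier",
              "cost_factors.depreciation_life_yr", "cost_factors.labor_rate",
              "finance.target_payback_yr"))
    pos(p)

  for (p in c("downstream.per_pass_lysis_fraction", "downstream.msc_efficiency",
              "downstream.centrifuge_efficiency",
              "fermentation.max_working_fraction"))
    frac(p)

  tax <- s$finance$income_tax_rate
  if (!is.numeric(tax) || tax < 0 || tax >= 1)
    add("error", "finance.income_tax_rate", "must lie in [0, 1)")
  grid <- s$finance$price_grid_usd_kg
  if (length(grid) != 2L || grid[1] >= grid[2])
    add("error", "finance.price_grid_usd_kg", "lower bound must be below upper")

  fp <- s$fermentation
  if (is.numeric(fp$final_working_volume_m3) &&
      is.numeric(fp$vessel_volume_m3)) {
    if (fp$final_working_volume_m3 > fp$vessel_volume_m3)
      add("error", "fermentation.final_working_volume_m3",
          "exceeds vessel volume")
    else if (is.numeric(fp$max_working_fraction) &&
             fp$final_working_volume_m3 >
             fp$max_working_fraction * fp$vessel_volume_m3)
      add("warning", "fermentation.final_working_volume_m3",
          sprintf("working volume %.2f m3 exceeds %.0f%% of the %.4g m3 vessel",
                  fp$final_working_volume_m3, 100 * fp$max_working_fraction,
                  fp$vessel_volume_m3))
  }
  if (is.numeric(fp$inoculum_expansion_factor) &&
      fp$inoculum_expansion_factor <= 1)
    add("error", "fermentation.inoculum_expansion_factor", "must exceed 1")

  if (identical(s$mode, "semicontinuous")) {
    if (is.null(fp$harvest_fraction))
      add("error", "fermentation.harvest_fraction",
          "required for semicontinuous mode")
    else if (fp$harvest_fraction <= 0 || fp$harvest_fraction >= 1)
      add("error", "fermentation.harvest_fraction", "must lie in (0, 1)")
    if (is.null(fp$stage2_yield_mg_l))
      add("error", "fermentation.stage2_yield_mg_l",
          "required for semicontinuous mode")
    else if (fp$stage2_yield_mg_l >= fp$magnetite_yield_mg_l)
      add("error", "fermentation.stage2_yield_mg_l",
          "must be below the stage-1 yield")
  }

  if (is.numeric(s$schedule$cycle_time_h) &&
      is.numeric(s$schedule$batch_time_h) &&
      s$schedule$cycle_time_h > s$schedule$batch_time_h)
    add("error", "schedule.cycle_time_h", "exceeds batch time")
  if (is.numeric(s$schedule$annual_operating_time_h) &&
      is.numeric(s$schedule$batch_time_h) &&
      s$schedule$annual_operating_time_h < s$schedule$batch_time_h)
    add("error", "schedule.annual_operating_time_h", "below one batch time")

  # every material the demand model references must be priced
  needed <- c(names(s$materials$medium_recipe), s$materials$iron_source,
              "urea", "sucrose", "buffer_salts", "wash_water",
              "cleaning_agents")
  for (m in needed) {
    entry <- s$prices$materials[[m]]
    if (is.null(entry) || !is.numeric(entry$price) || entry$price <= 0)
      add("error", paste0("prices.materials.", m),
          "missing or non-positive price for a demanded material")
  }
  for (m in names(s$prices$materials)) {
    cur <- s$prices$materials[[m]]$currency %||% "USD"
    if (!cur %in% c("USD", "BRL"))
      add("error", paste0("prices.materials.", m, ".currency"),
          "currency must be USD or BRL")
  }

  v
}

assert_valid <- function(s) {
  v <- validate_scenario(s)
  err <- v[v$level == "error", , drop = FALSE]
  if (nrow(err))
    stop("invalid scenario:\n", paste0("  - ", err$path, ": ", err$message,
                                       collapse = "\n"), call. = FALSE)
  invisible(s)
}
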