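# Factored capital estimation and annual operating cost assembly.
#
# Capital: equipment purchase costs (power-law scaled from base sizes) times
# an installation multiplier give direct fixed capital (DFC, "total plant
# cost"); working capital and startup are fractions of DFC.  Operating:
# direct costs (materials, labor, utilities, QC) are built from the mass
# balance and schedule; indirect costs (maintenance, straight-line
# depreciation, taxes/insurance/overhead) are fractions of DFC.  All USD;
# BRL-denominated entries are converted at the scenario exchange rate.

#' Power-law equipment cost scaling
#'
#' `base_cost * (size / base_size)^exponent`, the standard six-tenths-rule
#' style correlation used when resizing equipment.
#'
#' @param base_cost purchase cost (USD) at `base_size`
#' @param base_size,size equipment size metric (same units)
#' @param exponent scale exponent in (0, 1]
#' @return scaled purchase cost (USD)
#' @examples
#' scale_equipment_cost(500000, 29, 58, 0.6)
#' @export
scale_equipment_cost <- function(base_cost, base_size, size, exponent) {
  if (base_size <= 0 || size <= 0)
    stop("equipment sizes must be positive", call. = FALSE)
  if (exponent <= 0 || exponent > 1)
    stop("scale exponent must lie in (0, 1]", call. = FALSE)
  base_cost * (size / base_size)^exponent
}

# equipment register -> data frame with current purchase costs
equipment_costs <- function(scenario) {
  items <- scenario$equipment
  if (!length(items)) stop("equipment list is empty", call. = FALSE)
  purchase <- vapply(items, function(it)
    scale_equipment_cost(it$base_cost_usd, it$base_size, it$size,
                         it$scale_exponent), 0)
  data.frame(name = vapply(items, `[[`, "", "name"),
             section = vapply(items, `[[`, "", "section"),
             size = vapply(items, `[[`, 0, "size"),
             size_unit = vapply(items, `[[`, "", "size_unit"),
             purchase_cost_usd = purchase,
             stringsAsFactors = FALSE)
}

#' Factored capital investment
#'
#' @param scenario a `bmn_scenario`
#' @return a `bmn_capital`: equipment total, direct fixed capital (total
#'   plant cost), working capital, startup cost, total investment and the
#'   per-item equipment table
#' @examples
#' capital_investment(builtin_fixture("base_single"))
#' @export
capital_investment <- function(scenario) {
  eq <- equipment_costs(scenario)
  cf <- scenario$cost_factors
  equipment_total <- sum(eq$purchase_cost_usd)
  dfc <- cf$installation_multiplier * equipment_total
  working <- cf$working_capital_fraction * dfc
  startup <- cf$startup_fraction * dfc
  structure(list(
    equipment = eq,
    equipment_total_usd = equipment_total,
    equipment_by_section = tapply(eq$purchase_cost_usd, eq$section, sum),
    total_plant_cost_usd = dfc,
    working_capital_usd = working,
    startup_cost_usd = startup,
    total_investment_usd = dfc + working + startup), class = "bmn_capital")
}

#' Annual materials cost with section attribution
#'
#' Prices every entry of an annual demand table.  Prices are USD per native
#' unit (kg or m3); BRL entries are converted at the scenario exchange rate.
#' A demanded material without a price entry is an error naming the
#' material.
#'
#' @param demand data frame (`material`, `amount`, `unit`, `section`), e.g.
#'   a per-batch demand from [batch_material_demand()] scaled by the batch
#'   count
#' @param prices the `prices` block of a scenario
#' @return list with `total_usd`, `by_section`, `by_material` and the
#'   priced table
#' @export
materials_cost <- function(demand, prices) {
  rate <- prices$exchange_rate_brl_per_usd
  unit_price <- vapply(demand$material, function(m) {
    entry <- prices$materials[[m]]
    if (is.null(entry))
      stop("no price entry for material '", m, "'", call. = FALSE)
    price_usd(entry, rate)
  }, 0)
  priced <- demand
  priced$unit_price_usd <- unit_price
  priced$cost_usd <- priced$amount * unit_price
  list(total_usd = sum(priced$cost_usd),
       by_section = tapply(priced$cost_usd, priced$section, sum),
       by_material = tapply(priced$cost_usd, priced$material, sum),
       table = priced)
}

#' Annual labor and QC cost
#'
#' Labor hours from the schedule at the (possibly BRL-denominated) labor
#' rate; QC/QA is a fixed fraction of labor.
#'
#' @param schedule a `bmn_schedule`
#' @param cf the `cost_factors` block of a scenario
#' @param exchange_rate BRL per USD, used when the labor rate is BRL
#' @return list with `labor_usd`, `qc_usd`, `by_section`
#' @export
labor_cost <- function(schedule, cf, exchange_rate) {
  rate <- price_usd(list(price = cf$labor_rate,
                         currency = cf$labor_rate_currency %||% "USD"),
                    exchange_rate)
  by_section <- schedule$annual_labor_hours_by_section * rate
  labor <- sum(by_section)
  list(labor_usd = labor, qc_usd = cf$qc_fraction_of_labor * labor,
       by_section = by_section)
}

#' Assemble the annual operating cost summary
#'
#' Direct costs: materials, labor, utilities and QC.  Indirect costs:
#' maintenance, straight-line depreciation
#' (`DFC x (1 - salvage) / depreciation_life`) and aggregated
#' taxes/insurance/overhead, all fractions of direct fixed capital.  Every
#' cost is attributed to a plant section (inoculum, fermentation,
#' downstream): materials by consumption, labor and QC by section hours,
#' utilities by medium volume handled, indirect costs by the section share
#' of equipment purchase cost.
#'
#' @param scenario a `bmn_scenario`
#' @param batch a `bmn_batch`
#' @param schedule a `bmn_schedule`
#' @param capital a `bmn_capital`
#' @return a `bmn_opcost` with `direct`, `indirect`, `total_usd_per_yr`,
#'   `by_section` and the annual materials table
#' @export
operating_cost_summary <- function(scenario, batch, schedule, capital) {
  cf <- scenario$cost_factors
  n <- schedule$batches_per_year

  demand <- batch$material_demand
  demand$amount <- demand$amount * n
  mat <- materials_cost(demand, scenario$prices)
  lab <- labor_cost(schedule, cf, scenario$prices$exchange_rate_brl_per_usd)

  medium_m3 <- n * sum(batch$media_volume_m3)
  utilities <- cf$utilities_cost_per_m3_medium * medium_m3

  dfc <- capital$total_plant_cost_usd
  maintenance <- cf$maintenance_fraction * dfc
  depreciation <- dfc * (1 - cf$salvage_fraction) / cf$depreciation_life_yr
  taxes_overhead <- cf$tax_insurance_overhead_fraction * dfc

  direct <- c(materials = mat$total_usd, labor = lab$labor_usd,
              utilities = utilities, qc = lab$qc_usd)
  indirect <- c(maintenance = maintenance, depreciation = depreciation,
                taxes_overhead = taxes_overhead)
  total <- sum(direct) + sum(indirect)

  sections <- c("inoculum", "fermentation", "downstream")
  sec <- stats::setNames(numeric(3), sections)
  pick <- function(x, s) if (s %in% names(x)) x[[s]] else 0
  eq_share <- capital$equipment_by_section / capital$equipment_total_usd
  med_share <- n * batch$media_volume_m3 / medium_m3
  for (s in sections) {
    sec[s] <- pick(mat$by_section, s) +
      (1 + cf$qc_fraction_of_labor) * pick(lab$by_section, s) +
      utilities * pick(med_share, s) +
      sum(indirect) * pick(eq_share, s)
  }

  structure(list(
    direct = direct, indirect = indirect,
    direct_usd = sum(direct), indirect_usd = sum(indirect),
    total_usd_per_yr = total,
    indirect_share = sum(indirect) / total,
    by_section = sec,
    by_section_share = sec / total,
    materials = mat), class = "bmn_opcost")
}

#' @export
print.bmn_opcost <- function(x, ...) {
  cat(sprintf("<bmn_opcost> %.3f MUSD/yr (direct %.3f, indirect %.3f; indirect share %.3f)\n",
              x$total_usd_per_yr / 1e6, x$direct_usd / 1e6,
              x$indirect_usd / 1e6, x$indirect_share))
  sh <- round(100 * x$by_section_share, 1)
  cat("  sections:", paste(names(sh), sh, sep = " ", collapse = "% | "),
      "%\n")
  invisible(x)
}
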