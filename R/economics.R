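# Plant economics: unit production cost, after-tax cash flow, payback-vs-
# price curve and the minimum selling price (MSP) at a fixed target payback.
#
# Payback convention: total capital investment divided by annual net
# (after-tax) profit, with no depreciation add-back and net profit =
# (revenue - operating cost) x (1 - income tax rate).  This convention,
# with a 40% income tax, reproduces the base-case MSPs from the printed
# capital and operating totals; the tax rate is an ordinary config value.

#' Unit production cost
#'
#' Total annual operating cost divided by annual recovered product.
#'
#' @param operating_cost annual operating cost (USD/yr) or a `bmn_opcost`
#' @param annual_product recovered product (kg/yr), > 0
#' @return USD per kg
#' @export
unit_production_cost <- function(operating_cost, annual_product) {
  if (inherits(operating_cost, "bmn_opcost"))
    operating_cost <- operating_cost$total_usd_per_yr
  if (annual_product <= 0)
    stop("annual product must be positive", call. = FALSE)
  operating_cost / annual_product
}

#' Investment payback time at a selling price
#'
#' `total investment / ((price x product - operating cost) x (1 - tax))`.
#' Prices at or below break-even return `Inf` (the investment is never
#' recovered), not an error.
#'
#' @param total_investment USD
#' @param operating_cost USD/yr
#' @param annual_product kg/yr
#' @param price selling price (USD/kg); may be a vector
#' @param tax_rate income tax rate in [0, 1)
#' @return payback time in years (vectorised over `price`)
#' @examples
#' payback_time(5e6, 2e6, 1000, 3000, 0)  # 5 years
#' @export
payback_time <- function(total_investment, operating_cost, annual_product,
                         price, tax_rate = 0) {
  net <- (price * annual_product - operating_cost) * (1 - tax_rate)
  ifelse(net > 0, total_investment / net, Inf)
}

#' Minimum selling price at a fixed payback time
#'
#' Solves `payback(price) = target_payback` by bisection on the configured
#' price grid (relative tolerance 1e-6).  The payback curve is strictly
#' decreasing in price above break-even, so the root is unique.
#'
#' @inheritParams payback_time
#' @param target_payback years
#' @param grid length-2 numeric bracket (USD/kg)
#' @param tol relative tolerance on the price
#' @param extend when `TRUE` the bracket is widened automatically if the
#'   root lies outside `grid` (down to just above break-even, or upward by
#'   doubling); when `FALSE` (default) an out-of-bracket root is an error
#'   advising grid expansion
#' @return MSP in USD/kg
#' @export
minimum_selling_price <- function(total_investment, operating_cost,
                                  annual_product, target_payback,
                                  grid = c(30000, 120000), tax_rate = 0,
                                  tol = 1e-6, extend = FALSE) {
  if (target_payback <= 0)
    stop("target payback must be positive", call. = FALSE)
  f <- function(p) payback_time(total_investment, operating_cost,
                                annual_product, p, tax_rate) - target_payback
  lo <- grid[1]; hi <- grid[2]
  if (f(hi) > 0) {
    if (!extend)
      stop("payback still exceeds the target at the upper grid bound; ",
           "expand the price grid", call. = FALSE)
    while (f(hi) > 0) hi <- hi * 2
  }
  if (f(lo) < 0) {
    if (!extend)
      stop("payback is below the target at the lower grid bound; ",
           "expand the price grid", call. = FALSE)
    # just above break-even the payback is arbitrarily long
    lo <- (operating_cost / annual_product) * (1 + 1e-12)
  }
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Payback-versus-price curve
#'
#' @inheritParams minimum_selling_price
#' @param n number of grid points
#' @return data frame (`price_usd_kg`, `payback_yr`)
#' @export
payback_curve <- function(total_investment, operating_cost, annual_product,
                          grid = c(30000, 120000), tax_rate = 0, n = 91) {
  price <- seq(grid[1], grid[2], length.out = n)
  data.frame(price_usd_kg = price,
             payback_yr = payback_time(total_investment, operating_cost,
                                       annual_product, price, tax_rate))
}

#' Full economic summary for a scenario result
#'
#' @param scenario a `bmn_scenario`
#' @param schedule a `bmn_schedule`
#' @param capital a `bmn_capital`
#' @param operating a `bmn_opcost`
#' @param price optional selling price (USD/kg); defaults to the solved MSP
#' @return a `bmn_econ`: unit production cost, revenue/profit/cash flow at
#'   `price`, payback, MSP and the payback curve
#' @export
economic_summary <- function(scenario, schedule, capital, operating,
                             price = NULL) {
  fin <- scenario$finance
  product <- schedule$annual_product_kg
  aoc <- operating$total_usd_per_yr
  inv <- capital$total_investment_usd
  msp <- minimum_selling_price(inv, aoc, product, fin$target_payback_yr,
                               grid = fin$price_grid_usd_kg,
                               tax_rate = fin$income_tax_rate,
                               extend = TRUE)
  if (is.null(price)) price <- msp
  revenue <- price * product
  gross <- revenue - aoc
  tax <- max(gross, 0) * fin$income_tax_rate
  net <- gross - tax
  structure(list(
    unit_production_cost_usd_kg = unit_production_cost(aoc, product),
    selling_price_usd_kg = price,
    revenue_usd_yr = revenue,
    gross_profit_usd_yr = gross,
    income_tax_usd_yr = tax,
    net_profit_usd_yr = net,
    payback_yr = payback_time(inv, aoc, product, price,
                              fin$income_tax_rate),
    msp_usd_kg = msp,
    payback_curve = payback_curve(inv, aoc, product,
                                  grid = fin$price_grid_usd_kg,
                                  tax_rate = fin$income_tax_rate)),
    class = "bmn_econ")
}

#' Annual after-tax cash flow
#'
#' The cash-flow figure the payback calculation divides into the capital
#' investment.
#'
#' @param econ a `bmn_econ`
#' @return USD per year
#' @export
annual_cash_flow <- function(econ) econ$net_profit_usd_yr

#' Reference comparison with chemical magnetite synthesis
#'
#' Static published reference constants for chemically synthesised
#' magnetite nanoparticles (co-precipitation, bare particles; hydrothermal,
#' carbon-coated), alongside the biogenic results, for reporting.
#'
#' @param econ optional `bmn_econ` whose unit cost is included
#' @param materials_usd_kg optional material cost per kg for the biogenic row
#' @return data frame of production / material / equipment costs
#' @export
reference_comparison <- function(econ = NULL, materials_usd_kg = NA) {
  ref <- data.frame(
    process = c("co_precipitation", "hydrothermal"),
    production_cost_usd_kg = c(210, 4192),
    material_cost_usd_kg = c(78, 1361),
    equipment_cost_kusd = c(1036, 2027),
    stringsAsFactors = FALSE)
  if (!is.null(econ)) {
    ref <- rbind(data.frame(
      process = "biogenic_bmn",
      production_cost_usd_kg = econ$unit_production_cost_usd_kg,
      material_cost_usd_kg = materials_usd_kg,
      equipment_cost_kusd = NA_real_,
      stringsAsFactors = FALSE), ref)
  }
  ref
}

#' @export
print.bmn_econ <- function(x, ...) {
  cat(sprintf("<bmn_econ> unit cost %.0f USD/kg | MSP %.0f USD/kg | payback %.2f yr at %.0f USD/kg\n",
              x$unit_production_cost_usd_kg, x$msp_usd_kg, x$payback_yr,
              x$selling_price_usd_kg))
  invisible(x)
}
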