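test_that("equipment cost scaling follows the power law", {
  expect_equal(scale_equipment_cost(5e5, 29, 29, 0.6), 5e5)
  # doubling the size at exponent 0.6: 500000 * 2^0.6
  expect_equal(scale_equipment_cost(5e5, 29, 58, 0.6), 757858.28,
               tolerance = 1e-6)
  # exponent 1 is linear
  expect_equal(scale_equipment_cost(1000, 2, 7, 1), 3500)
  expect_error(scale_equipment_cost(1000, 0, 1, 0.6), "positive")
})

test_that("factored capital reproduces the base-case capital summary", {
  cap1 <- res_single$capital
  expect_equal(cap1$equipment_total_usd / 1e6, 8.898, tolerance = 1e-6)
  expect_equal(cap1$total_plant_cost_usd / 1e6, 43.03, tolerance = 1e-4)
  expect_equal(cap1$total_investment_usd / 1e6, 52.11, tolerance = 1e-4)
  ferm_item <- cap1$equipment$purchase_cost_usd[
    cap1$equipment$name == "main_bioreactor"]
  expect_equal(ferm_item / cap1$equipment_total_usd, 0.306, tolerance = 1e-3)

  cap2 <- res_semi$capital
  expect_equal(cap2$equipment_total_usd / 1e6, 12.888, tolerance = 1e-6)
  expect_equal(cap2$total_investment_usd / 1e6, 79.86, tolerance = 1e-4)
  expect_equal(cap2$equipment$purchase_cost_usd[
    cap2$equipment$name == "main_bioreactor"] / cap2$equipment_total_usd,
    0.382, tolerance = 1e-3)
  # ordering invariant
  expect_gte(cap1$total_investment_usd, cap1$total_plant_cost_usd)
  expect_gte(cap1$total_plant_cost_usd, cap1$equipment_total_usd)
})

test_that("degenerate cost factors collapse investment to equipment cost", {
  s <- fx_single
  s$cost_factors$installation_multiplier <- 1
  s$cost_factors$working_capital_fraction <- 0
  s$cost_factors$startup_fraction <- 0
  cap <- capital_investment(s)
  expect_equal(cap$total_investment_usd, cap$equipment_total_usd)
  s$equipment <- list()
  expect_error(capital_investment(s), "empty")
})

test_that("materials cost prices every demand and attributes sections", {
  mat <- res_single$operating$materials
  tab <- mat$table
  lactic_ferm <- sum(tab$cost_usd[tab$material == "lactic_acid" &
                                    tab$section == "fermentation"])
  expect_gt(lactic_ferm / mat$by_section[["fermentation"]], 0.60)
  expect_lt(lactic_ferm / mat$by_section[["fermentation"]], 0.68)
  urea <- sum(tab$cost_usd[tab$material == "urea"])
  expect_gt(urea / mat$by_section[["downstream"]], 0.83)
  expect_lt(urea / mat$by_section[["downstream"]], 0.91)
  expect_equal(mat$total_usd, sum(mat$by_section))

  bad <- data.frame(material = "unobtainium", amount = 1, unit = "kg",
                    section = "fermentation")
  expect_error(materials_cost(bad, fx_single$prices), "unobtainium")
  none <- materials_cost(data.frame(material = "urea", amount = 0,
                                    unit = "kg", section = "downstream"),
                         fx_single$prices)
  expect_equal(none$total_usd, 0)
})

test_that("materials cost is homogeneous of degree one in prices", {
  s <- fx_single
  for (m in names(s$prices$materials))
    s$prices$materials[[m]]$price <- 3 * s$prices$materials[[m]]$price
  scaled <- evaluate_scenario(s)
  expect_equal(scaled$operating$materials$total_usd,
               3 * res_single$operating$materials$total_usd,
               tolerance = 1e-12)
  # physical balances unchanged
  expect_equal(scaled$batch$magnetite_recovered_kg,
               res_single$batch$magnetite_recovered_kg)
})

test_that("BRL-denominated prices convert at the exchange rate", {
  s <- fx_single
  s$prices$materials$urea <- list(price = 0.40 * 5.20, per = "kg",
                                  currency = "BRL")
  same <- evaluate_scenario(s)
  expect_equal(same$operating$materials$total_usd,
               res_single$operating$materials$total_usd, tolerance = 1e-12)
  s2 <- scenario_set(s, "prices.exchange_rate_brl_per_usd", 10.4)
  halved <- evaluate_scenario(s2)
  urea_cost <- function(r) sum(r$operating$materials$table$cost_usd[
    r$operating$materials$table$material == "urea"])
  expect_equal(urea_cost(halved), urea_cost(same) / 2, tolerance = 1e-12)
})

test_that("single-stage labor cost runs ~9% above semicontinuous", {
  l1 <- labor_cost(res_single$schedule, fx_single$cost_factors, 5.20)
  l2 <- labor_cost(res_semi$schedule, fx_semi$cost_factors, 5.20)
  expect_equal(l1$labor_usd / l2$labor_usd, 1.09, tolerance = 0.005)
  expect_equal(l1$qc_usd, 0.15 * l1$labor_usd)
  # linearity in the rate
  cf <- fx_single$cost_factors
  cf$labor_rate <- 2 * cf$labor_rate
  expect_equal(labor_cost(res_single$schedule, cf, 5.20)$labor_usd,
               2 * l1$labor_usd)
})

test_that("operating cost is additive and its indirect share sits in 0.76-0.79", {
  for (r in list(res_single, res_semi)) {
    op <- r$operating
    expect_equal(op$total_usd_per_yr, sum(op$direct) + sum(op$indirect))
    expect_equal(sum(op$by_section), op$total_usd_per_yr, tolerance = 1e-9)
    expect_gt(op$indirect_share, 0.76)
    expect_lt(op$indirect_share, 0.79)
  }
})

test_that("fermentation carries about half the operating cost, more when semicontinuous", {
  sh1 <- res_single$operating$by_section_share[["fermentation"]]
  sh2 <- res_semi$operating$by_section_share[["fermentation"]]
  expect_gt(sh1, 0.45); expect_lt(sh1, 0.55)
  expect_gt(sh2 - sh1, 0.04); expect_lt(sh2 - sh1, 0.10)
  dn1 <- res_single$operating$by_section_share[["downstream"]]
  dn2 <- res_semi$operating$by_section_share[["downstream"]]
  expect_gt(min(dn1, dn2), 0.22); expect_lt(max(dn1, dn2), 0.29)
})

test_that("zero cost factors and zero direct inputs give zero indirect cost", {
  s <- fx_single
  s$cost_factors$maintenance_fraction <- 0
  s$cost_factors$tax_insurance_overhead_fraction <- 0
  s$cost_factors$salvage_fraction <- 1   # no depreciable base
  r <- evaluate_scenario(s)
  expect_equal(sum(r$operating$indirect), 0)
})
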