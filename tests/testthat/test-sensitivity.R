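unit_at <- function(sweep, value) {
  sweep$unit_cost_usd_kg[!sweep$is_base & abs(sweep$value - value) < 1e-12]
}

test_that("a sweep over the base value reproduces the base case", {
  sw <- oat_sweep(fx_single, "fermentation.magnetite_yield_mg_l",
                  c(250, 250))
  expect_equal(sw$unit_cost_usd_kg,
               rep(res_single$economics$unit_production_cost_usd_kg, 3))
  expect_identical(sw$is_base, c(FALSE, FALSE, TRUE))
})

test_that("invalid sweep values are row-level errors, not sweep failures", {
  sw <- oat_sweep(fx_single, "downstream.msc_efficiency", c(-0.5, 0.85))
  expect_false(is.na(sw$error[1]))
  expect_true(is.na(sw$error[2]))
  expect_equal(sw$unit_cost_usd_kg[2],
               res_single$economics$unit_production_cost_usd_kg)
})

test_that("unit cost falls strictly with yield and with each downstream efficiency", {
  sw <- oat_sweep(fx_single, "fermentation.magnetite_yield_mg_l",
                  seq(80, 350, 45))
  expect_true(all(diff(sw$unit_cost_usd_kg[!sw$is_base]) < 0))
  sw2 <- oat_sweep(fx_single, "downstream.msc_efficiency",
                   seq(0.65, 0.95, 0.05))
  expect_true(all(diff(sw2$unit_cost_usd_kg[!sw2$is_base]) < 0))
  sw3 <- oat_sweep(fx_single, "downstream.centrifuge_efficiency",
                   seq(0.6, 1, 0.1))
  expect_true(all(diff(sw3$unit_cost_usd_kg[!sw3$is_base]) < 0))
})

test_that("halving the magnetite yield about doubles unit cost and MSP", {
  sw <- oat_sweep(fx_single, "fermentation.magnetite_yield_mg_l", 125)
  base_unit <- res_single$economics$unit_production_cost_usd_kg
  ratio <- unit_at(sw, 125) / base_unit
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
  msp_ratio <- sw$msp_usd_kg[1] / res_single$economics$msp_usd_kg
  expect_gt(msp_ratio, 1.8); expect_lt(msp_ratio, 2.2)
})

test_that("a 30% lower growth rate raises costs by about a factor 2.5", {
  sw <- oat_sweep(fx_single, "fermentation.mu_per_h", 0.07)
  ratio <- unit_at(sw, 0.07) /
    res_single$economics$unit_production_cost_usd_kg
  expect_gt(ratio, 2.2); expect_lt(ratio, 2.8)
})

test_that("the urea price sweep moves per-kg operating cost within a narrow band", {
  sw <- oat_sweep(fx_single, "prices.materials.urea.price", c(0.05, 0.75))
  perkg <- sw$operating_cost_usd_yr[!sw$is_base] /
    sw$annual_product_kg[!sw$is_base]
  expect_gt(min(perkg), 9700)
  expect_lt(max(perkg), 12000)
})

test_that("USD-denominated scenarios are invariant to the exchange rate", {
  s <- fx_single
  # move the only BRL-denominated item (labor) to USD at the base parity
  s$cost_factors$labor_rate <- 130 / 5.20
  s$cost_factors$labor_rate_currency <- "USD"
  sw <- oat_sweep(s, "prices.exchange_rate_brl_per_usd", c(4.0, 5.2, 6.5))
  expect_equal(diff(range(sw$unit_cost_usd_kg)), 0, tolerance = 1e-9)
  # with BRL labor, a weaker real lowers the USD cost
  sw2 <- oat_sweep(fx_single, "prices.exchange_rate_brl_per_usd",
                   c(4.0, 6.5))
  expect_gt(unit_at(sw2, 4.0), unit_at(sw2, 6.5))
})

test_that("capacity rescaling keeps the scenario at factor 1 and shows scale economies", {
  expect_equal(unclass(capacity_rescale(fx_single, 1)), unclass(fx_single))
  sw <- oat_sweep(fx_single, "capacity", 2)
  base_unit <- res_single$economics$unit_production_cost_usd_kg
  drop <- 1 - unit_at(sw, 2) / base_unit
  expect_gt(drop, 0.12); expect_lt(drop, 0.30)
  expect_equal(sw$annual_product_kg[1], 1280, tolerance = 1e-6)
  half <- oat_sweep(fx_single, "capacity", 0.5)
  expect_gt(unit_at(half, 0.5), base_unit)
  expect_error(capacity_rescale(fx_single, -1), "positive")
})

test_that("scenario ensembles are seed-reproducible, bitwise", {
  e1 <- scenario_ensemble(fx_single, draws = 30, seed = 42)
  e2 <- scenario_ensemble(fx_single, draws = 30, seed = 42)
  expect_identical(lapply(e1, unclass), lapply(e2, unclass))
  s1 <- monte_carlo_summary(e1)
  s2 <- monte_carlo_summary(e2)
  expect_identical(s1$p50, s2$p50)
  e3 <- scenario_ensemble(fx_single, draws = 30, seed = 43)
  expect_false(identical(lapply(e1, unclass), lapply(e3, unclass)))
})

test_that("zero-width perturbations reproduce the base scenario", {
  pert <- list("fermentation.magnetite_yield_mg_l" =
                 list(dist = "triangular", min = 250, mode = 250, max = 250))
  e <- scenario_ensemble(fx_single, pert, draws = 3, seed = 1)
  for (s in e) expect_equal(unclass(s), unclass(fx_single))
  expect_error(scenario_ensemble(fx_single,
    list("fermentation.mu_per_h" = list(dist = "gauss", min = 0, mode = 1,
                                        max = 2))), "unknown distribution")
})

test_that("triangular draws centre on the base-case mode", {
  e <- scenario_ensemble(fx_single, draws = 400, seed = 42)
  yields <- vapply(e, function(s) s$fermentation$magnetite_yield_mg_l, 0)
  expect_gt(min(yields), 80); expect_lt(max(yields), 350)
  # mean of triangular(80, 250, 350) = (80 + 250 + 350) / 3
  expect_equal(mean(yields), (80 + 250 + 350) / 3, tolerance = 0.05)
})

test_that("Monte-Carlo percentiles behave at the edges", {
  pert <- default_perturbations(fx_single)["fermentation.magnetite_yield_mg_l"]
  e <- scenario_ensemble(fx_single, pert, draws = 1, seed = 7)
  mc <- monte_carlo_summary(e)
  expect_equal(mc$p5, mc$p50)
  expect_equal(mc$p50, mc$p95)
  expect_identical(attr(mc, "draws"), 1L)
  # symmetric perturbation of a monotone response brackets the base value
  pert2 <- list("downstream.msc_efficiency" =
                  list(dist = "triangular", min = 0.75, mode = 0.85,
                       max = 0.95))
  mc2 <- monte_carlo_summary(scenario_ensemble(fx_single, pert2,
                                               draws = 200, seed = 42))
  base_unit <- res_single$economics$unit_production_cost_usd_kg
  expect_gt(mc2$p95[1], base_unit)
  expect_lt(mc2$p5[1], base_unit)
  expect_error(monte_carlo_summary(list()), "empty")
})
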