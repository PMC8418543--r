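test_that("inoculum train is a geometric series below the initial charge", {
  expect_equal(simulate_inoculum_train(fx_single$fermentation),
               c(0.015, 0.15, 1.5))
  fp <- list(initial_volume_m3 = 10, inoculum_expansion_factor = 10,
             inoculum_stages = 1)
  expect_equal(simulate_inoculum_train(fp), 1.0)
  fp$inoculum_expansion_factor <- 1.0
  expect_error(simulate_inoculum_train(fp), "exceed 1")
})

test_that("fed-batch growth is exponential, capped by the final density", {
  fp <- fx_single$fermentation
  # base case reaches the substrate-determined cap within 42 h
  expect_gt(fp$initial_biomass_g_l * exp(fp$mu_per_h * fp$duration_h),
            fp$max_biomass_g_l)
  b <- simulate_fed_batch(fx_single)
  V <- fp$final_working_volume_m3
  expect_equal(b$biomass_kg,
               (fp$max_biomass_g_l - fp$initial_biomass_g_l) * V)
  expect_equal(b$magnetite_produced_kg, 250 / 1000 * V)
  expect_equal(b$feed_volume_m3, V - fp$initial_volume_m3)

  # below the cap the amplification is exactly exp(mu t): e^4.2 = 66.69
  s <- scenario_set(fx_single, "fermentation.initial_biomass_g_l", 0.01)
  b2 <- simulate_fed_batch(s)
  amp <- exp(0.10 * 42)
  expect_equal(b2$biomass_kg / (0.01 * V), amp - 1, tolerance = 1e-12)
  expect_equal(b2$density_factor, 0.01 * amp / 5.0)
})

test_that("vanishing growth rate collapses biomass and magnetite", {
  s <- scenario_set(fx_single, "fermentation.mu_per_h", 1e-9)
  b <- simulate_fed_batch(s)
  expect_lt(b$biomass_kg, 1e-5)
  expect_equal(b$density_factor, 0.111 / 5.0, tolerance = 1e-6)
})

test_that("fed-batch rejects impossible volumes and rates", {
  expect_error(simulate_fed_batch(
    scenario_set(fx_single, "fermentation.final_working_volume_m3", 30)),
    "vessel")
  expect_error(simulate_fed_batch(
    scenario_set(fx_single, "fermentation.mu_per_h", -0.1)), "positive")
})

test_that("semicontinuous mass balance matches the two-harvest algebra", {
  b <- simulate_semicontinuous(fx_semi)
  V <- fx_semi$fermentation$final_working_volume_m3
  h <- 0.9
  # hand oracle: harvest1 = h*V*y1; harvest2 = (1-h)*V*y1 + V*y2 (both
  # stages reach the density cap at base conditions)
  expect_equal(b$harvests[[1]]$magnetite_kg, h * V * 0.250)
  expect_equal(b$harvests[[2]]$magnetite_kg, (1 - h) * V * 0.250 + V * 0.110)
  expect_equal(b$magnetite_produced_kg, V * 0.360, tolerance = 1e-12)
  expect_equal(b$ferm_medium_m3, 1.9 * V)
  expect_error(simulate_semicontinuous(
    scenario_set(fx_semi, "fermentation.harvest_fraction", 1.5)), "0, 1")
})

test_that("equal yields and near-total harvest give twice the single-stage output", {
  s <- scenario_set(fx_semi, "fermentation.stage2_yield_mg_l", 250)
  s <- scenario_set(s, "fermentation.harvest_fraction", 0.98)
  # 2% retained broth still regrows to the density cap within the recipe
  b <- simulate_semicontinuous(s)
  V <- s$fermentation$final_working_volume_m3
  expect_equal(b$magnetite_produced_kg, 2 * V * 0.250, tolerance = 1e-12)
})

test_that("downstream cascade recovers the product of stage efficiencies", {
  b <- simulate_batch(fx_single)
  lysed <- 1 - (1 - 0.7)^4
  expect_equal(b$lysed_fraction, lysed)
  expect_equal(b$overall_recovery, lysed * 0.85 * 0.90 * 0.85,
               tolerance = 1e-12)
  # composition: overall recovery equals the product of stage recoveries
  # taken from the stream table itself
  st <- b$stream_table
  stagewise <- prod(st$magnetite_captured_kg / st$magnetite_in_kg)
  expect_equal(b$magnetite_recovered_kg,
               b$magnetite_produced_kg * stagewise, tolerance = 1e-12)
  expect_lte(b$magnetite_recovered_kg, b$magnetite_produced_kg)
})

test_that("magnetite is conserved at every downstream stage", {
  for (b in list(res_single$batch, res_semi$batch)) {
    st <- b$stream_table
    resid <- abs(st$magnetite_in_kg - st$magnetite_captured_kg -
                   st$magnetite_waste_kg) / st$magnetite_in_kg
    expect_lt(max(resid), 1e-9)
  }
})

test_that("a lossless cascade returns everything it is fed", {
  s <- scenario_set(fx_single, "downstream.per_pass_lysis_fraction", 1)
  s <- scenario_set(s, "downstream.msc_efficiency", 1)
  s <- scenario_set(s, "downstream.centrifuge_efficiency", 1)
  b <- simulate_batch(s)
  expect_equal(b$magnetite_recovered_kg, b$magnetite_produced_kg,
               tolerance = 1e-12)
})

test_that("zero efficiencies and empty streams are modelling errors", {
  expect_error(run_downstream(simulate_fed_batch(fx_single),
    utils::modifyList(fx_single$downstream, list(msc_efficiency = 0))),
    "modelling mistake")
  empty <- list(harvests = list(list(magnetite_kg = 0, volume_m3 = 1)))
  expect_error(run_downstream(empty, fx_single$downstream), "positive")
})

test_that("recovered mass is monotone in each efficiency and in yield", {
  paths <- c("downstream.msc_efficiency", "downstream.centrifuge_efficiency",
             "downstream.per_pass_lysis_fraction",
             "fermentation.magnetite_yield_mg_l")
  grids <- list(seq(0.5, 1, 0.1), seq(0.5, 1, 0.1), seq(0.3, 1, 0.1),
                seq(50, 350, 50))
  for (k in seq_along(paths)) {
    rec <- vapply(grids[[k]], function(v)
      simulate_batch(scenario_set(fx_single, paths[k],
                                  v))$magnetite_recovered_kg, 0)
    expect_true(all(diff(rec) > -1e-12), info = paths[k])
  }
})

test_that("material demand is aggregated with section attribution", {
  d <- batch_material_demand(res_single$batch)
  expect_true(all(d$amount >= 0))
  expect_setequal(unique(d$section),
                  c("inoculum", "fermentation", "downstream"))
  # volume-driven demands scale with the working volume
  small <- scenario_set(fx_single, "fermentation.final_working_volume_m3",
                        1e-6)
  small <- scenario_set(small, "fermentation.initial_volume_m3", 5e-7)
  ds <- batch_material_demand(simulate_batch(small))
  urea <- function(x) x$amount[x$material == "urea"]
  expect_lt(sum(urea(ds)), 1e-3)
})
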