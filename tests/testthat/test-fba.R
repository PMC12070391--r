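test_that("FBA reproduces the hand-solved optimum of the tiny chain", {
  # unique optimum: import saturates at 10, so v = (-10, 10, 10), z = 10
  f <- solve_fba(tiny_chain_model())
  expect_identical(f$status, "optimal")
  expect_equal(f$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(f$fluxes), c(-10, 10, 10), tolerance = 1e-9)
})

test_that("FBA reproduces the analytic optimum of the toy plant model", {
  # photon cap 100 -> light reaction 12.5; NADPH couples fixation 1:1 to the
  # light reaction; balances give sugar = B*(1 + 0.5 + 2/3), so the biomass
  # optimum is 12.5 * 6/13 = 75/13
  fx <- make_toy_plant_gem()
  f <- solve_fba(fx$model, parsimonious = TRUE)
  expect_equal(f$objective_value, 75 / 13, tolerance = 1e-8)
  expect_equal(f$fluxes[["R_RuBisCO"]], 12.5, tolerance = 1e-8)
  expect_equal(f$fluxes[["T_Photon"]], 100, tolerance = 1e-8)
  # and the diel transformation preserves it (day does all the fixing)
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  fd <- solve_fba(res$model, parsimonious = TRUE)
  expect_equal(fd$objective_value, 75 / 13, tolerance = 1e-8)
})

test_that("optimal flux distributions satisfy bounds and mass balance", {
  fx <- make_toy_plant_gem()
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  for (f in list(solve_fba(res$model), solve_fba(res$model, parsimonious = TRUE))) {
    expect_identical(f$status, "optimal")
    S <- stoichiometric_matrix(res$model)
    expect_lt(max(abs(S %*% f$fluxes)), 1e-6)
    b <- model_bounds(res$model, cap_infinite = TRUE)
    expect_lt(max(pmax(b[, 1] - f$fluxes, f$fluxes - b[, 2])), 1e-6)
  }
})

test_that("parsimonious post-processing keeps the optimum, trims total flux", {
  fx <- make_toy_plant_gem()
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  plain <- solve_fba(res$model)
  pars <- solve_fba(res$model, parsimonious = TRUE)
  expect_equal(pars$objective_value, plain$objective_value, tolerance = 1e-7)
  expect_lte(sum(abs(pars$fluxes)), sum(abs(plain$fluxes)) + 1e-6)
})

test_that("forced-zero objectives and infeasible models are detected", {
  m <- tiny_chain_model()
  m$reactions[["SINK_A"]]$upper_bound <- 0
  expect_equal(solve_fba(m)$objective_value, 0, tolerance = 1e-12)

  infeas <- metabolic_model(
    "bad",
    compartments = list(compartment("c")),
    metabolites = list(metabolite("A_c", "c")),
    reactions = list(reaction("MAKE_A", c(A_c = 1), 1, 1)),
    objective = c(MAKE_A = 1))
  expect_identical(solve_fba(infeas)$status, "infeasible")

  noobj <- tiny_chain_model()
  noobj$objective <- numeric()
  expect_error(solve_fba(noobj), "objective")
})

test_that("quantum yield matches the stoichiometric construction exactly", {
  fx <- make_toy_plant_gem(qy_target = 0.125)
  f <- solve_fba(fx$model, parsimonious = TRUE)
  expect_equal(quantum_yield(f, "R_RuBisCO", "T_Photon"), 0.125,
               tolerance = 1e-9)
  fx2 <- make_toy_plant_gem(qy_target = 0.1)
  f2 <- solve_fba(fx2$model, parsimonious = TRUE)
  expect_equal(quantum_yield(f2, "R_RuBisCO", "T_Photon"), 0.1,
               tolerance = 1e-9)
})

test_that("quantum yield is invariant under uniform bound scaling", {
  fx <- make_toy_plant_gem()
  qy1 <- quantum_yield(solve_fba(fx$model, parsimonious = TRUE),
                       "R_RuBisCO", "T_Photon")
  scaled <- fx$model
  for (rid in names(scaled$reactions)) {
    scaled$reactions[[rid]]$lower_bound <- 2.5 * scaled$reactions[[rid]]$lower_bound
    scaled$reactions[[rid]]$upper_bound <- 2.5 * scaled$reactions[[rid]]$upper_bound
  }
  scaled$default_bound <- 2.5 * scaled$default_bound
  qy2 <- quantum_yield(solve_fba(scaled, parsimonious = TRUE),
                       "R_RuBisCO", "T_Photon")
  expect_equal(qy1, qy2, tolerance = 1e-9)
})

test_that("quantum yield guards its preconditions", {
  f0 <- structure(list(fluxes = c(RUB = 0, PHO = 5), objective_value = 1,
                       status = "optimal"), class = "flux_distribution")
  expect_equal(quantum_yield(f0, "RUB", "PHO"), 0)
  fbad <- f0; fbad$fluxes[["PHO"]] <- 0
  expect_error(quantum_yield(fbad, "RUB", "PHO"), "undefined")
  finf <- f0; finf$status <- "infeasible"
  expect_error(quantum_yield(finf, "RUB", "PHO"), "optimal")
  expect_error(quantum_yield(f0, "NOPE", "PHO"), "NOPE")
})

test_that("storage pool directions are forced by the fixture's construction", {
  fx <- make_toy_plant_gem()
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  f <- solve_fba(res$model, parsimonious = TRUE)
  rep <- storage_pool_report(res$model, f)
  rep <- rep[order(rep$metabolite), ]
  by_met <- stats::setNames(rep$net_direction, rep$metabolite)
  # night biomass can only draw carbon from the pool
  expect_identical(unname(by_met[["Sucrose_c"]]), "day_to_night")
  # ferredoxin-dependent assimilation is day-only, so excess night nitrate
  # uptake (forced by the 3:2 coupling) must cross to the day phase
  expect_identical(unname(by_met[["NO3_c"]]), "night_to_day")
  expect_identical(unname(by_met[["Ala_c"]]), "day_to_night")
  # steady state equates the two pool-side fluxes
  expect_equal(rep$day_to_pool_flux, rep$pool_to_night_flux, tolerance = 1e-8)
})

test_that("storage pool report classifies inactivity and missing pools", {
  fx <- make_toy_plant_gem()
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  zero <- structure(list(
    fluxes = stats::setNames(numeric(length(res$model$reactions)),
                             names(res$model$reactions)),
    objective_value = 0, status = "optimal"), class = "flux_distribution")
  rep <- storage_pool_report(res$model, zero)
  expect_true(all(rep$net_direction == "inactive"))

  f <- solve_fba(fx$model)
  expect_error(storage_pool_report(fx$model, f), "no storage pool")
})

test_that("relaxing the nitrate ratio never lowers the optimum", {
  fx <- make_toy_plant_gem()
  with_ratio <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  cfg_nr <- fx$config
  cfg_nr$ratio <- NULL
  without <- run_pipeline(fx$model, cfg_nr, quiet = TRUE)
  expect_gte(solve_fba(without$model)$objective_value,
             solve_fba(with_ratio$model)$objective_value - 1e-8)
})

test_that("any optimal diel solution honours the ratio and photon blocks", {
  fx <- make_toy_plant_gem()
  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  for (pars in c(FALSE, TRUE)) {
    f <- solve_fba(res$model, parsimonious = pars)
    expect_lt(abs(2 * f$fluxes[["T_NO3_Day"]] - 3 * f$fluxes[["T_NO3_Night"]]),
              1e-6)
    expect_lt(abs(f$fluxes[["T_Photon_Night"]]), 1e-6)
    # night-phase light-dependent chain is dark-silent
    expect_lt(abs(f$fluxes[["R_Light_Night"]]), 1e-6)
    expect_lt(abs(f$fluxes[["R_RuBisCO_Night"]]), 1e-6)
  }
})
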