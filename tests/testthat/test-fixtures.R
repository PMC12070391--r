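test_that("generated fixtures are valid and deterministic", {
  for (two in c(FALSE, TRUE)) {
    fx <- make_toy_plant_gem(include_two_tissues = two)
    expect_identical(validate_model(fx$model), character())
    p1 <- withr::local_tempfile(fileext = ".xml")
    p2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(fx$model, p1)
    write_sbml(make_toy_plant_gem(include_two_tissues = two)$model, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("generators reproduce the committed snapshot files", {
  for (case in list(list(two = FALSE, file = "toy_plant_gem.xml"),
                    list(two = TRUE, file = "toy_two_tissue_gem.xml"))) {
    snap <- system.file("extdata", case$file, package = "dielgem")
    p <- withr::local_tempfile(fileext = ".xml")
    write_sbml(make_toy_plant_gem(include_two_tissues = case$two)$model, p)
    expect_identical(readLines(p), readLines(snap))
  }
})

test_that("the toy model stays feasible after every pipeline step", {
  fx <- make_toy_plant_gem()
  dup <- duplicate_phases(fx$model, fx$config)
  m <- dup$model
  expect_gt(solve_fba(m)$objective_value, 0)
  m <- create_storage_pool(m, dup$phase_map, fx$config)
  expect_gt(solve_fba(m)$objective_value, 0)
  m <- block_night_photon_uptake(m, dup$phase_map, fx$config)
  expect_gt(solve_fba(m)$objective_value, 0)
  m <- apply_nitrate_ratio(m, dup$phase_map, fx$config)
  expect_gt(solve_fba(m)$objective_value, 0)
  m <- merge_biomass(m, dup$phase_map, fx$config)
  expect_gt(solve_fba(m)$objective_value, 0)
})

test_that("unreachable quantum yield targets are refused", {
  expect_error(make_toy_plant_gem(qy_target = 0.3), "unreachable")
  expect_error(make_toy_plant_gem(qy_target = 0), "0, 1")
  expect_error(make_toy_plant_gem(qy_target = 1.2), "0, 1")
  # reachable targets build the advertised stoichiometry
  fx <- make_toy_plant_gem(qy_target = 0.05)
  expect_equal(unname(fx$model$reactions[["R_Light"]]$stoichiometry["Photon_c"]),
               -20)
})

test_that("the two-tissue fixture exercises every multi-tissue branch", {
  fx <- make_toy_plant_gem(include_two_tissues = TRUE)
  expect_length(fx$config$photon_reaction_ids, 2L)
  expect_length(fx$config$nitrate_reaction_ids, 2L)
  expect_length(fx$config$biomass_reaction_ids, 2L)
  expect_identical(fx$config$tissue_names, c("Leaf", "Root"))
  # roots are dark: their photon uptake is closed in the source model
  expect_equal(fx$model$reactions[["T_Photon_Root"]]$upper_bound, 0)
  expect_gt(solve_fba(fx$model)$objective_value, 0)

  res <- run_pipeline(fx$model, fx$config, quiet = TRUE)
  expect_true(all(c("sp_Leaf", "sp_Root") %in% names(res$model$compartments)))
  expect_length(res$model$constraints, 2L)
  expect_length(grep("_Total$", names(res$model$reactions)), 2L)
  f <- solve_fba(res$model, parsimonious = TRUE)
  expect_gt(f$objective_value, 0)
  expect_lt(abs(f$fluxes[["T_Photon_Leaf_Night"]]), 1e-9)
  for (t in c("Leaf", "Root"))
    expect_lt(abs(2 * f$fluxes[[paste0("T_NO3_", t, "_Day")]] -
                    3 * f$fluxes[[paste0("T_NO3_", t, "_Night")]]), 1e-6)
})

test_that("filler padding hits the requested reaction count and pathways", {
  fx <- make_toy_plant_gem(n_filler_reactions = 8)
  fil <- grep("^R_Fil", names(fx$model$reactions), value = TRUE)
  expect_length(fil, 8L)
  pw <- unique(vapply(fx$model$reactions[fil], `[[`, "", "pathway"))
  expect_gte(length(pw), 3L)
  none <- make_toy_plant_gem(n_filler_reactions = 0)
  expect_length(grep("^R_Fil", names(none$model$reactions)), 0L)
  expect_gt(solve_fba(none$model)$objective_value, 0)
})

test_that("null pair generation honours effect size and bounds", {
  np <- make_null_sample_pairs(4, 25, seed = 3, effect_size = 10)
  expect_equal(dim(np$samples$samples), c(8L, 25L))
  day_means <- rowMeans(np$samples$samples[1:4, ])
  night_means <- rowMeans(np$samples$samples[5:8, ])
  expect_true(all(night_means - day_means > 5))
  expect_error(make_null_sample_pairs(0, 10, seed = 1))
  expect_error(make_null_sample_pairs(3, 1, seed = 1))
})
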