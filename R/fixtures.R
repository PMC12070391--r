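# Synthetic photoautotroph models for development and testing. The toy GEM
# is engineered, not fitted: NADPH couples carbon fixation 1:1 to the light
# reaction so the quantum yield is analytic; nitrate reduction consumes
# light-generated reduced ferredoxin so amino-acid synthesis is impossible in
# the dark and pooled nitrate is forced to flow night -> day; night biomass
# can only draw carbon from the storage pool, forcing sugar day -> night.

FILLER_PATHWAYS <- c("steroid biosynthesis", "flavonoid biosynthesis",
                     "ascorbate and aldarate metabolism",
                     "glyoxylate and dicarboxylate metabolism",
                     "fatty acid biosynthesis")

#' Generate a small synthetic plant genome-scale model
#'
#' Builds a feasible photoautotroph toy model together with the matching
#' [pipeline_config()]: photon supply and uptake, CO2 / nitrate / water /
#' phosphate exchanges, a light reaction turning `ceil(1/qy_target)` photons
#' into NADPH, ATP and reduced ferredoxin, RuBisCO carboxylation, sucrose /
#' starch interconversion, ferredoxin-dependent amino-acid synthesis,
#' respiration, ATP maintenance, a biomass reaction, and pathway-labelled
#' filler reactions. The storage set is sucrose, starch, nitrate and the
#' amino acid. The model solves with positive biomass both before and after
#' the diel transformation.
#'
#' @param n_filler_reactions Number of padding reactions (a linear chain from
#'   sucrose to CO2) carrying pathway labels from a roster of >= 3 pathways.
#' @param include_starch_cycle Include the sucrose/starch interconversion?
#' @param include_two_tissues Build the two-tissue (leaf/root) variant with
#'   per-tissue storage pools, two photon uptakes (the root's bounded to
#'   zero) and two nitrate uptakes?
#' @param qy_target Analytic quantum yield the light/fixation stoichiometry
#'   is built to produce; must equal `1/ceiling(1/qy_target)` exactly.
#' @param photon_supply Cap on total photon supply (makes light limiting).
#' @param seed Seed for the filler pathway assignment.
#' @return A list with `model` (a [metabolic_model()]) and `config` (a
#'   [pipeline_config()] naming all special reactions).
#' @export
make_toy_plant_gem <- function(n_filler_reactions = 6,
                               include_starch_cycle = TRUE,
                               include_two_tissues = FALSE,
                               qy_target = 0.125,
                               photon_supply = 100,
                               seed = 1) {
  if (!(qy_target > 0 && qy_target <= 1))
    stop("qy_target must lie in (0, 1]", call. = FALSE)
  np <- ceiling(1 / qy_target)
  if (abs(1 / np - qy_target) > 1e-12)
    stop("qy_target ", qy_target, " is unreachable with an integer photon ",
         "coefficient (nearest achievable: 1/", np, ")", call. = FALSE)
  if (include_two_tissues)
    return(make_two_tissue_gem(np, photon_supply, n_filler_reactions, seed))

  comps <- list(compartment("e", "extracellular"),
                compartment("c", "cytosol"),
                compartment("p", "plastid"))
  mets <- list(
    metabolite("Photon_e", "e", "photon"),
    metabolite("Photon_c", "c", "photon"),
    metabolite("CO2_e", "e", "carbon dioxide", formula = "CO2"),
    metabolite("CO2_c", "c", "carbon dioxide", formula = "CO2"),
    metabolite("NO3_e", "e", "nitrate", formula = "NO3"),
    metabolite("NO3_c", "c", "nitrate", formula = "NO3"),
    metabolite("H2O_e", "e", "water", formula = "H2O"),
    metabolite("H2O_c", "c", "water", formula = "H2O"),
    metabolite("Pi_e", "e", "phosphate"),
    metabolite("Pi_c", "c", "phosphate"),
    metabolite("NADPH_c", "c", "NADPH"),
    metabolite("ATP_c", "c", "ATP"),
    metabolite("Fdred_c", "c", "reduced ferredoxin"),
    metabolite("Sucrose_c", "c", "sucrose"),
    metabolite("Starch_p", "p", "starch"),
    metabolite("Ala_c", "c", "alanine")
  )
  sto <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  rxns <- list(
    reaction("EX_Photon", sto(Photon_e = -1), -photon_supply, 0,
             name = "photon exchange", pathway = "exchange"),
    reaction("EX_CO2", sto(CO2_e = -1), -1000, 1000,
             name = "CO2 exchange", pathway = "exchange"),
    reaction("EX_NO3", sto(NO3_e = -1), -1000, 1000,
             name = "nitrate exchange", pathway = "exchange"),
    reaction("EX_H2O", sto(H2O_e = -1), -1000, 1000,
             name = "water exchange", pathway = "exchange"),
    reaction("EX_Pi", sto(Pi_e = -1), -1000, 1000,
             name = "phosphate exchange", pathway = "exchange"),
    reaction("T_Photon", sto(Photon_e = -1, Photon_c = 1), 0, 1000,
             name = "photon uptake", pathway = "light reactions"),
    reaction("T_CO2", sto(CO2_e = -1, CO2_c = 1), -1000, 1000,
             name = "CO2 transport", pathway = "transport"),
    reaction("T_NO3", sto(NO3_e = -1, NO3_c = 1), 0, 1000,
             name = "nitrate uptake", pathway = "transport"),
    reaction("T_H2O", sto(H2O_e = -1, H2O_c = 1), -1000, 1000,
             name = "water transport", pathway = "transport"),
    reaction("T_Pi", sto(Pi_e = -1, Pi_c = 1), -1000, 1000,
             name = "phosphate transport", pathway = "transport"),
    reaction("R_Light",
             sto(Photon_c = -np, NADPH_c = 2, ATP_c = 3, Fdred_c = 1),
             0, 1000, name = "light reactions", pathway = "light reactions"),
    reaction("R_RuBisCO",
             sto(CO2_c = -1, H2O_c = -1, NADPH_c = -2, ATP_c = -3,
                 Sucrose_c = 1),
             0, 1000, name = "RuBisCO carboxylation",
             pathway = "carbon fixation", gpr = "rbcL and rbcS"),
    reaction("R_FdOx", sto(Fdred_c = -1), 0, 1000,
             name = "ferredoxin oxidase", pathway = "light reactions"),
    reaction("R_Resp", sto(Sucrose_c = -1, ATP_c = 3, CO2_c = 1), 0, 1000,
             name = "respiration", pathway = "glycolysis/gluconeogenesis"),
    reaction("R_AlaSyn",
             sto(NO3_c = -1, Sucrose_c = -1, Fdred_c = -1, Ala_c = 1),
             0, 1000, name = "alanine synthesis",
             pathway = "amino acid biosynthesis"),
    reaction("R_NGAM", sto(ATP_c = -1), 0, 1000,
             name = "ATP maintenance", pathway = "maintenance"),
    reaction("R_Biomass",
             sto(Sucrose_c = -1, Ala_c = -0.5, ATP_c = -2, Pi_c = -0.1),
             0, 1000, name = "biomass assembly", pathway = "biomass")
  )
  if (include_starch_cycle) {
    rxns <- c(rxns, list(
      reaction("R_StarchSyn", sto(Sucrose_c = -1, Starch_p = 1), 0, 1000,
               name = "starch synthesis",
               pathway = "starch and sucrose metabolism"),
      reaction("R_StarchDeg", sto(Starch_p = -1, Sucrose_c = 1), 0, 1000,
               name = "starch degradation",
               pathway = "starch and sucrose metabolism")))
  } else {
    mets <- Filter(function(m) m$id != "Starch_p", mets)
  }
  if (n_filler_reactions > 0) {
    pw <- run_with_seed(seed, sample(rep_len(FILLER_PATHWAYS,
                                             n_filler_reactions)))
    prev <- "Sucrose_c"
    for (i in seq_len(n_filler_reactions)) {
      nxt <- if (i == n_filler_reactions) "CO2_c" else {
        fid <- sprintf("Fil%d_c", i)
        mets <- c(mets, list(metabolite(fid, "c", sprintf("filler %d", i))))
        fid
      }
      rxns <- c(rxns, list(
        reaction(sprintf("R_Fil%d", i),
                 stats::setNames(c(-1, 1), c(prev, nxt)), 0, 1000,
                 name = sprintf("filler reaction %d", i), pathway = pw[[i]])))
      prev <- nxt
    }
  }
  model <- metabolic_model("toy_plant_gem", comps, mets, rxns,
                           objective = c(R_Biomass = 1))
  assert_valid_model(model)
  storage <- c("Sucrose_c",
               if (include_starch_cycle) "Starch_p",
               "NO3_c", "Ala_c")
  config <- pipeline_config(
    photon_reaction_ids = "T_Photon",
    storage_metabolite_ids = storage,
    nitrate_reaction_ids = "T_NO3",
    biomass_reaction_ids = "R_Biomass")
  list(model = model, config = config)
}

# two-tissue (leaf/root) variant: shared boundary, tissue compartments, an
# apoplast for inter-tissue transfer, and tissue-tagged metabolite ids so
# the pipeline's substring tissue matching applies.
make_two_tissue_gem <- function(np, photon_supply, n_filler_reactions, seed) {
  comps <- list(compartment("e", "extracellular"),
                compartment("ap", "apoplast"),
                compartment("Leaf_c", "leaf cytosol"),
                compartment("Root_c", "root cytosol"))
  mets <- list(
    metabolite("Photon_e", "e", "photon"),
    metabolite("CO2_e", "e", "carbon dioxide"),
    metabolite("NO3_e", "e", "nitrate"),
    metabolite("Sucrose_ap", "ap", "sucrose (apoplast)"),
    metabolite("NO3_ap", "ap", "nitrate (apoplast)"),
    metabolite("Photon_Leaf_c", "Leaf_c", "photon (leaf)"),
    metabolite("Photon_Root_c", "Root_c", "photon (root)"),
    metabolite("CO2_Leaf_c", "Leaf_c", "carbon dioxide (leaf)"),
    metabolite("NADPH_Leaf_c", "Leaf_c", "NADPH (leaf)"),
    metabolite("ATP_Leaf_c", "Leaf_c", "ATP (leaf)"),
    metabolite("Fdred_Leaf_c", "Leaf_c", "reduced ferredoxin (leaf)"),
    metabolite("Sucrose_Leaf_c", "Leaf_c", "sucrose (leaf)"),
    metabolite("NO3_Leaf_c", "Leaf_c", "nitrate (leaf)"),
    metabolite("Ala_Leaf_c", "Leaf_c", "alanine (leaf)"),
    metabolite("ATP_Root_c", "Root_c", "ATP (root)"),
    metabolite("Sucrose_Root_c", "Root_c", "sucrose (root)"),
    metabolite("NO3_Root_c", "Root_c", "nitrate (root)"),
    metabolite("Ala_Root_c", "Root_c", "alanine (root)")
  )
  sto <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  rxns <- list(
    reaction("EX_Photon", sto(Photon_e = -1), -photon_supply, 0,
             pathway = "exchange"),
    reaction("EX_CO2", sto(CO2_e = -1), -1000, 1000, pathway = "exchange"),
    reaction("EX_NO3", sto(NO3_e = -1), -1000, 1000, pathway = "exchange"),
    reaction("T_Photon_Leaf", sto(Photon_e = -1, Photon_Leaf_c = 1), 0, 1000,
             name = "leaf photon uptake", pathway = "light reactions"),
    # roots see no light: uptake present but closed
    reaction("T_Photon_Root", sto(Photon_e = -1, Photon_Root_c = 1), 0, 0,
             name = "root photon uptake", pathway = "light reactions"),
    reaction("T_CO2_Leaf", sto(CO2_e = -1, CO2_Leaf_c = 1), -1000, 1000,
             pathway = "transport"),
    reaction("T_NO3_Leaf", sto(NO3_e = -1, NO3_Leaf_c = 1), 0, 1000,
             name = "leaf nitrate uptake", pathway = "transport"),
    reaction("T_NO3_Root", sto(NO3_e = -1, NO3_Root_c = 1), 0, 1000,
             name = "root nitrate uptake", pathway = "transport"),
    reaction("R_Light_Leaf",
             sto(Photon_Leaf_c = -np, NADPH_Leaf_c = 2, ATP_Leaf_c = 3,
                 Fdred_Leaf_c = 1), 0, 1000, pathway = "light reactions"),
    reaction("R_RuBisCO_Leaf",
             sto(CO2_Leaf_c = -1, NADPH_Leaf_c = -2, ATP_Leaf_c = -3,
                 Sucrose_Leaf_c = 1), 0, 1000, pathway = "carbon fixation"),
    reaction("R_FdOx_Leaf", sto(Fdred_Leaf_c = -1), 0, 1000,
             pathway = "light reactions"),
    reaction("R_Resp_Leaf", sto(Sucrose_Leaf_c = -1, ATP_Leaf_c = 3,
                                CO2_Leaf_c = 1), 0, 1000,
             pathway = "glycolysis/gluconeogenesis"),
    reaction("R_AlaSyn_Leaf",
             sto(NO3_Leaf_c = -1, Sucrose_Leaf_c = -1, Fdred_Leaf_c = -1,
                 Ala_Leaf_c = 1), 0, 1000,
             pathway = "amino acid biosynthesis"),
    reaction("R_Biomass_Leaf",
             sto(Sucrose_Leaf_c = -1, Ala_Leaf_c = -0.5, ATP_Leaf_c = -2),
             0, 1000, name = "leaf biomass", pathway = "biomass"),
    # root: heterotrophic, ATP-dependent nitrate assimilation
    reaction("R_Resp_Root", sto(Sucrose_Root_c = -1, ATP_Root_c = 3),
             0, 1000, pathway = "glycolysis/gluconeogenesis"),
    reaction("R_AlaSyn_Root",
             sto(NO3_Root_c = -1, Sucrose_Root_c = -1, ATP_Root_c = -1,
                 Ala_Root_c = 1), 0, 1000,
             pathway = "amino acid biosynthesis"),
    reaction("R_Biomass_Root",
             sto(Sucrose_Root_c = -1, Ala_Root_c = -0.5, ATP_Root_c = -1),
             0, 1000, name = "root biomass", pathway = "biomass"),
    # inter-tissue transfer through the apoplast
    reaction("T_Suc_Leaf_ap", sto(Sucrose_Leaf_c = -1, Sucrose_ap = 1),
             -1000, 1000, pathway = "transport"),
    reaction("T_Suc_Root_ap", sto(Sucrose_ap = -1, Sucrose_Root_c = 1),
             -1000, 1000, pathway = "transport"),
    reaction("T_NO3_Root_ap", sto(NO3_Root_c = -1, NO3_ap = 1),
             -1000, 1000, pathway = "transport"),
    reaction("T_NO3_Leaf_ap", sto(NO3_ap = -1, NO3_Leaf_c = 1),
             -1000, 1000, pathway = "transport")
  )
  if (n_filler_reactions > 0) {
    pw <- run_with_seed(seed, sample(rep_len(FILLER_PATHWAYS,
                                             n_filler_reactions)))
    prev <- "Sucrose_Leaf_c"
    for (i in seq_len(n_filler_reactions)) {
      nxt <- if (i == n_filler_reactions) "CO2_Leaf_c" else {
        fid <- sprintf("Fil%d_Leaf_c", i)
        mets <- c(mets, list(metabolite(fid, "Leaf_c",
                                        sprintf("filler %d (leaf)", i))))
        fid
      }
      rxns <- c(rxns, list(
        reaction(sprintf("R_Fil%d_Leaf", i),
                 stats::setNames(c(-1, 1), c(prev, nxt)), 0, 1000,
                 pathway = pw[[i]])))
      prev <- nxt
    }
  }
  model <- metabolic_model("toy_two_tissue_gem", comps, mets, rxns,
                           objective = c(R_Biomass_Leaf = 1,
                                         R_Biomass_Root = 1))
  assert_valid_model(model)
  config <- pipeline_config(
    photon_reaction_ids = c("T_Photon_Leaf", "T_Photon_Root"),
    storage_metabolite_ids = c("Sucrose_Leaf_c", "NO3_Leaf_c", "Ala_Leaf_c",
                               "Sucrose_Root_c", "NO3_Root_c", "Ala_Root_c"),
    nitrate_reaction_ids = c("T_NO3_Leaf", "T_NO3_Root"),
    biomass_reaction_ids = c("R_Biomass_Leaf", "R_Biomass_Root"),
    tissue_names = c("Leaf", "Root"))
  list(model = model, config = config)
}

#' Generate synthetic day/night sample pairs
#'
#' Builds a synthetic `sample_matrix` plus matching phase map for calibrating
#' the differential flux test: each pair has a day row drawn from
#' `N(0, sd^2)` and a night row from `N(effect_size * sd, sd^2)`. With
#' `effect_size = 0` the pairs are exchangeable (the null); large effect
#' sizes separate the rows completely.
#'
#' @param n_pairs Number of day/night row pairs (>= 1).
#' @param n_samples Samples per row (>= 2).
#' @param seed Integer seed.
#' @param effect_size Shift of the night rows, in units of `sd`.
#' @param sd Common standard deviation of the rows.
#' @return A list with `samples` (a `sample_matrix`-compatible object) and
#'   `phase_map` pairing `pair_<i>_Day` with `pair_<i>_Night`.
#' @export
make_null_sample_pairs <- function(n_pairs, n_samples, seed,
                                   effect_size = 0, sd = 1) {
  stopifnot(n_pairs >= 1, n_samples >= 2)
  orig <- sprintf("pair_%d", seq_len(n_pairs))
  day_ids <- paste0(orig, "_Day")
  night_ids <- paste0(orig, "_Night")
  M <- run_with_seed(seed, {
    rbind(matrix(stats::rnorm(n_pairs * n_samples, 0, sd),
                 n_pairs, n_samples),
          matrix(stats::rnorm(n_pairs * n_samples, effect_size * sd, sd),
                 n_pairs, n_samples))
  })
  rownames(M) <- c(day_ids, night_ids)
  samples <- structure(list(reaction_ids = rownames(M), samples = M,
                            seed = seed), class = "sample_matrix")
  phase_map <- structure(list(
    compartments = list(day = character(), night = character()),
    metabolites = list(day = character(), night = character()),
    reactions = list(day = stats::setNames(day_ids, orig),
                     night = stats::setNames(night_ids, orig))
  ), class = "phase_map")
  list(samples = samples, phase_map = phase_map)
}
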