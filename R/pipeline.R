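#' Configuration for the diel transformation pipeline
#'
#' Collects every user choice the five-step transformation needs: the phase
#' suffix convention, which metabolites may cross between phases through the
#' storage pool, and which reactions are photon uptakes, nitrate uptakes and
#' biomass assemblies. All reaction/metabolite ids refer to the
#' *pre-duplication* (non-diel) model.
#'
#' @param photon_reaction_ids Character vector of photon uptake reaction ids
#'   (non-empty; a photoautotroph model must photosynthesize). These are the
#'   reactions whose night copies are blocked in step 3.
#' @param storage_metabolite_ids Metabolite ids to place in the storage pool
#'   (e.g. sugars, starch, nitrate, amino acids, carboxylic acids).
#' @param nitrate_reaction_ids Nitrate uptake reaction ids (step 4); each must
#'   be oriented so that positive flux means uptake.
#' @param biomass_reaction_ids Biomass reaction ids (step 5); may be empty,
#'   in which case only four steps run.
#' @param day_suffix,night_suffix Suffixes appended to every id and name of
#'   the two phases. Must differ and be non-empty.
#' @param tissue_names Tissue names for multi-tissue models (empty = generic
#'   model). Tissues are matched case-insensitively as substrings of
#'   metabolite and compartment ids unless `tissue_storage` is given.
#' @param tissue_storage Optional named list, tissue name -> character vector
#'   of storage metabolite ids, overriding substring matching.
#' @param ratio Day:night nitrate uptake ratio as a positive pair `c(p, q)`
#'   (default `c(3, 2)`, the empirical 3:2 proportion), or `NULL` to skip
#'   step 4 entirely.
#' @param merge_biomass Run step 5 (merge phase biomasses into a total
#'   biomass objective)?
#' @param biomass_weights Weights `c(w_day, w_night)` of the phase biomass
#'   stoichiometries in the merged total reaction; must be positive and sum
#'   to 1. Default an even 0.5/0.5 split.
#' @param storage_bound Magnitude of the reversible storage-pool exchange
#'   bounds (default 1000, the conventional "unbounded" value).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(photon_reaction_ids,
                            storage_metabolite_ids = character(),
                            nitrate_reaction_ids = character(),
                            biomass_reaction_ids = character(),
                            day_suffix = "_Day", night_suffix = "_Night",
                            tissue_names = character(),
                            tissue_storage = NULL,
                            ratio = c(3, 2),
                            merge_biomass = length(biomass_reaction_ids) > 0,
                            biomass_weights = c(0.5, 0.5),
                            storage_bound = 1000) {
  if (!nzchar(day_suffix) || !nzchar(night_suffix))
    stop("phase suffixes must be non-empty", call. = FALSE)
  if (identical(day_suffix, night_suffix))
    stop("day_suffix and night_suffix must differ", call. = FALSE)
  if (length(photon_reaction_ids) == 0L)
    stop("photon_reaction_ids must be non-empty", call. = FALSE)
  if (!is.null(ratio)) {
    if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
      stop("ratio must be a pair of positive numbers (p, q), or NULL",
           call. = FALSE)
  }
  if (length(biomass_weights) != 2L || any(biomass_weights <= 0) ||
      abs(sum(biomass_weights) - 1) > 1e-12)
    stop("biomass_weights must be two positive values summing to 1",
         call. = FALSE)
  structure(list(
    day_suffix = day_suffix, night_suffix = night_suffix,
    storage_metabolite_ids = storage_metabolite_ids,
    photon_reaction_ids = photon_reaction_ids,
    nitrate_reaction_ids = nitrate_reaction_ids,
    biomass_reaction_ids = biomass_reaction_ids,
    tissue_names = tissue_names, tissue_storage = tissue_storage,
    ratio = ratio, merge_biomass = merge_biomass,
    biomass_weights = biomass_weights, storage_bound = storage_bound
  ), class = "pipeline_config")
}

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Step 1: duplicate the model into day and night phases
#'
#' Every compartment, metabolite and reaction is copied twice, with the phase
#' suffix appended to both id and display name; all internal references
#' (metabolite compartments, reaction stoichiometries) are rewritten within
#' the same phase. The objective becomes the duplicated objective reactions
#' of both phases at the original weights. Running this on an
#' already-duplicated model errors on the suffix collision rather than
#' silently quadrupling.
#'
#' @param model A valid [metabolic_model()].
#' @param config A [pipeline_config()].
#' @return A list with elements `model` (the duplicated model) and
#'   `phase_map` (original -> day/night id correspondence for compartments,
#'   metabolites and reactions).
#' @export
duplicate_phases <- function(model, config) {
  assert_valid_model(model)
  if (length(model$reactions) == 0L)
    stop("cannot duplicate an empty model (no reactions)", call. = FALSE)
  all_ids <- c(names(model$compartments), names(model$metabolites),
               names(model$reactions))
  for (suf in c(config$day_suffix, config$night_suffix)) {
    hit <- all_ids[endsWith(all_ids, suf)]
    if (length(hit))
      stop("id '", hit[[1]], "' already ends in phase suffix '", suf,
           "'; refusing to duplicate (is this already a diel model?)",
           call. = FALSE)
  }
  sufs <- c(day = sanitize_sid(config$day_suffix),
            night = sanitize_sid(config$night_suffix))
  phase_ids <- function(ids, phase) stats::setNames(paste0(ids, sufs[[phase]]), ids)

  phase_map <- list(
    compartments = lapply(c(day = "day", night = "night"), function(p)
      phase_ids(names(model$compartments), p)),
    metabolites = lapply(c(day = "day", night = "night"), function(p)
      phase_ids(names(model$metabolites), p)),
    reactions = lapply(c(day = "day", night = "night"), function(p)
      phase_ids(names(model$reactions), p))
  )
  class(phase_map) <- "phase_map"

  name_suffix <- c(day = config$day_suffix, night = config$night_suffix)
  comps <- list(); mets <- list(); rxns <- list()
  for (p in c("day", "night")) {
    for (cp in model$compartments)
      comps[[length(comps) + 1L]] <- compartment(
        phase_map$compartments[[p]][[cp$id]],
        name = paste0(cp$name, name_suffix[[p]]))
    for (mt in model$metabolites)
      mets[[length(mets) + 1L]] <- metabolite(
        phase_map$metabolites[[p]][[mt$id]],
        compartment = phase_map$compartments[[p]][[mt$compartment]],
        name = paste0(mt$name, name_suffix[[p]]), formula = mt$formula)
    for (r in model$reactions) {
      sto <- r$stoichiometry
      names(sto) <- unname(phase_map$metabolites[[p]][names(sto)])
      rxns[[length(rxns) + 1L]] <- reaction(
        phase_map$reactions[[p]][[r$id]], sto, r$lower_bound, r$upper_bound,
        name = paste0(r$name, name_suffix[[p]]), gpr = r$gpr,
        pathway = r$pathway)
    }
  }
  objective <- numeric()
  for (rid in names(model$objective)) {
    objective[[phase_map$reactions$day[[rid]]]] <- model$objective[[rid]]
    objective[[phase_map$reactions$night[[rid]]]] <- model$objective[[rid]]
  }
  out <- metabolic_model(paste0(model$id, "_diel"), comps, mets, rxns,
                         objective = objective,
                         default_bound = model$default_bound)
  list(model = out, phase_map = phase_map)
}

#' Step 2: create the storage pool
#'
#' Adds a storage-pool compartment (one per tissue for multi-tissue models)
#' holding a pool copy `<met>_sp` of every storage metabolite, connected to
#' both phases by reversible exchange reactions `SP_<met><day_suffix>`
#' (positive flux = day deposits into the pool) and `SP_<met><night_suffix>`
#' (positive flux = the pool feeds the night phase). At steady state the two
#' fluxes are equal, so a positive common value moves material day -> night
#' and a negative one night -> day.
#'
#' @param model The phase-duplicated model from [duplicate_phases()].
#' @param phase_map The phase map from [duplicate_phases()].
#' @param config A [pipeline_config()]; `storage_metabolite_ids` are
#'   pre-duplication ids. For multi-tissue models every tissue must match at
#'   least one storage metabolite.
#' @return The model with pool compartment(s), metabolites and exchange
#'   reactions added.
#' @export
create_storage_pool <- function(model, phase_map, config) {
  sto_ids <- config$storage_metabolite_ids
  if (length(sto_ids) == 0L) return(model)
  unknown <- setdiff(sto_ids, names(phase_map$metabolites$day))
  if (length(unknown))
    stop("unknown storage metabolite id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  tissues <- config$tissue_names
  if (length(tissues)) {
    if (!is.null(config$tissue_storage)) {
      missing_t <- setdiff(tissues, names(config$tissue_storage))
      if (length(missing_t))
        stop("tissue_storage lacks entries for tissue(s): ",
             paste(missing_t, collapse = ", "), call. = FALSE)
      assignment <- config$tissue_storage[tissues]
    } else {
      tiss_of <- vapply(sto_ids, function(m) {
        # tissue resolution uses the pre-duplication model topology, which is
        # recoverable from phase_map + the duplicated model's day entries
        comp_day <- model$metabolites[[phase_map$metabolites$day[[m]]]]$compartment
        hay <- tolower(c(m, comp_day))
        hit <- tissues[vapply(tissues, function(tn)
          any(grepl(tolower(tn), hay, fixed = TRUE)), TRUE)]
        if (length(hit)) hit[[1]] else NA_character_
      }, "")
      assignment <- split(sto_ids, factor(tiss_of, levels = tissues))
      empty <- tissues[vapply(assignment, length, 0L) == 0L]
      if (length(empty))
        stop("tissue(s) match no storage metabolite: ",
             paste(empty, collapse = ", "), call. = FALSE)
      orphan <- sto_ids[is.na(tiss_of)]
      if (length(orphan))
        stop("storage metabolite(s) match no tissue: ",
             paste(orphan, collapse = ", "), call. = FALSE)
    }
  } else {
    assignment <- list(sp = sto_ids)
  }

  for (tn in names(assignment)) {
    pool_comp <- if (length(tissues)) paste0("sp_", sanitize_sid(tn)) else "sp"
    pool_name <- if (length(tissues)) paste("storage pool", tn) else "storage pool"
    if (pool_comp %in% names(model$compartments))
      stop("storage pool compartment '", pool_comp, "' already exists",
           call. = FALSE)
    model$compartments[[pool_comp]] <- compartment(pool_comp, name = pool_name)
    for (m in assignment[[tn]]) {
      pool_met <- paste0(m, "_sp")
      day_rxn <- paste0("SP_", m, sanitize_sid(config$day_suffix))
      night_rxn <- paste0("SP_", m, sanitize_sid(config$night_suffix))
      clash <- intersect(c(pool_met, day_rxn, night_rxn),
                         c(names(model$metabolites), names(model$reactions)))
      if (length(clash))
        stop("storage pool id collision: ", paste(clash, collapse = ", "),
             call. = FALSE)
      model$metabolites[[pool_met]] <- metabolite(
        pool_met, pool_comp,
        name = paste(model$metabolites[[phase_map$metabolites$day[[m]]]]$name,
                     "(storage pool)"))
      b <- config$storage_bound
      sto_day <- stats::setNames(c(-1, 1),
                                 c(phase_map$metabolites$day[[m]], pool_met))
      sto_night <- stats::setNames(c(-1, 1),
                                   c(pool_met, phase_map$metabolites$night[[m]]))
      model$reactions[[day_rxn]] <- reaction(
        day_rxn, sto_day, -b, b,
        name = paste0("storage exchange ", m, config$day_suffix),
        pathway = "storage pool exchange")
      model$reactions[[night_rxn]] <- reaction(
        night_rxn, sto_night, -b, b,
        name = paste0("storage exchange ", m, config$night_suffix),
        pathway = "storage pool exchange")
    }
  }
  model
}

#' Step 3: block photon uptake during the night
#'
#' Sets lower and upper bounds of every night-phase photon uptake reaction to
#' zero. Day copies are untouched. Multi-tissue models may list several
#' photon uptake reactions; all are blocked.
#'
#' @inheritParams create_storage_pool
#' @return The model with night photon uptake bounds fixed to zero.
#' @export
block_night_photon_uptake <- function(model, phase_map, config) {
  for (pid in config$photon_reaction_ids) {
    nid <- phase_map$reactions$night[pid]
    if (is.na(nid) || !(nid %in% names(model$reactions)))
      stop("photon reaction '", pid, "' has no night-phase copy", call. = FALSE)
    r <- model$reactions[[nid]]
    r$lower_bound <- 0
    r$upper_bound <- 0
    model$reactions[[nid]] <- r
  }
  model
}

#' Step 4: constrain the day:night nitrate uptake ratio
#'
#' For each nitrate uptake reaction adds the linear coupling constraint
#' `q * v_day - p * v_night = 0`, pinning the day:night uptake proportion to
#' p:q (default 3:2) while leaving the absolute uptake free. Skipped entirely
#' when `config$ratio` is `NULL`.
#'
#' Each nitrate reaction must be oriented so positive flux is uptake: its
#' upper bound must be positive and it must either consume a boundary
#' (extracellular) species or produce an internal one.
#'
#' @inheritParams create_storage_pool
#' @return The model, with one coupling constraint per nitrate reaction.
#' @export
apply_nitrate_ratio <- function(model, phase_map, config) {
  if (is.null(config$ratio)) return(model)
  p <- config$ratio[[1]]; q <- config$ratio[[2]]
  if (p <= 0 || q <= 0)
    stop("nitrate ratio components must be positive", call. = FALSE)
  for (rid in config$nitrate_reaction_ids) {
    did <- phase_map$reactions$day[rid]
    nid <- phase_map$reactions$night[rid]
    if (is.na(did) || is.na(nid) || !(did %in% names(model$reactions)) ||
        !(nid %in% names(model$reactions)))
      stop("nitrate reaction '", rid, "' has no day/night copies", call. = FALSE)
    r <- model$reactions[[did]]
    if (r$upper_bound <= 0)
      stop("nitrate reaction '", rid, "' is oriented as export ",
           "(upper_bound <= 0); re-orient it so positive flux is uptake",
           call. = FALSE)
    if (!any(r$stoichiometry > 0) && !any(r$stoichiometry < 0))
      stop("nitrate reaction '", rid, "' has no stoichiometry", call. = FALSE)
    cid <- paste0("ratio_", rid)
    model$constraints[[cid]] <- linear_constraint(
      cid, stats::setNames(c(q, -p), c(did, nid)), 0, 0)
  }
  model
}

#' Step 5: merge the day and night biomass reactions
#'
#' For each original biomass reaction adds a total-biomass reaction whose
#' stoichiometry is the weighted coefficient-wise sum of its day and night
#' copies (weights `config$biomass_weights`, default 0.5/0.5), fixes both
#' individual phase biomass reactions to zero flux, and resets the objective
#' to weight 1 on the total-biomass reaction(s) only.
#'
#' @inheritParams create_storage_pool
#' @return The model with merged biomass objective.
#' @export
merge_biomass <- function(model, phase_map, config) {
  if (!isTRUE(config$merge_biomass) || length(config$biomass_reaction_ids) == 0L)
    stop("biomass merging requested without biomass reactions ",
         "(set merge_biomass = TRUE and provide biomass_reaction_ids)",
         call. = FALSE)
  w <- config$biomass_weights
  objective <- numeric()
  for (bid in config$biomass_reaction_ids) {
    did <- phase_map$reactions$day[bid]
    nid <- phase_map$reactions$night[bid]
    if (is.na(did) || is.na(nid) || !(did %in% names(model$reactions)) ||
        !(nid %in% names(model$reactions)))
      stop("biomass reaction '", bid, "' has no day/night copies", call. = FALSE)
    rd <- model$reactions[[did]]; rn <- model$reactions[[nid]]
    sto <- w[[1]] * rd$stoichiometry
    for (m in names(rn$stoichiometry)) {
      sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) +
        w[[2]] * rn$stoichiometry[[m]]
    }
    sto <- sto[sto != 0]
    tid <- paste0(bid, "_Total")
    if (tid %in% names(model$reactions))
      stop("total biomass id collision: '", tid, "'", call. = FALSE)
    model$reactions[[tid]] <- reaction(
      tid, sto, 0, model$default_bound,
      name = paste(rd$name, "+", rn$name, "(total)"), pathway = rd$pathway)
    for (pid in c(did, nid)) {
      r <- model$reactions[[pid]]
      r$lower_bound <- 0; r$upper_bound <- 0
      model$reactions[[pid]] <- r
    }
    objective[[tid]] <- 1
  }
  model$objective <- objective
  model
}

#' Run the full diel transformation pipeline
#'
#' Applies the transformation steps in their fixed order: (1) phase
#' duplication, (2) storage pool creation, (3) night photon blocking,
#' (4) nitrate day:night ratio (only when `config$ratio` is set), and
#' (5) biomass merging (only when `config$merge_biomass` and biomass ids are
#' given — a model without a biomass reaction needs only four steps).
#'
#' @param model A valid non-diel [metabolic_model()].
#' @param config A [pipeline_config()].
#' @param quiet Suppress the per-step log messages?
#' @return A list of class `diel_pipeline_result` with elements `model`,
#'   `phase_map`, and `report` (per-step entity counts).
#' @export
run_pipeline <- function(model, config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- function(m) c(compartments = length(m$compartments),
                          metabolites = length(m$metabolites),
                          reactions = length(m$reactions),
                          constraints = length(m$constraints))
  report <- list()
  say <- function(step, m) {
    report[[step]] <<- as.list(counts(m))
    if (!quiet) message(sprintf(
      "[%s] %d compartments, %d metabolites, %d reactions, %d constraints",
      step, length(m$compartments), length(m$metabolites),
      length(m$reactions), length(m$constraints)))
  }
  run_step <- function(step, fn) {
    tryCatch(fn(), error = function(e)
      stop("step '", step, "': ", conditionMessage(e), call. = FALSE))
  }

  dup <- run_step("duplicate_phases",
                  function() duplicate_phases(model, config))
  m <- dup$model; pm <- dup$phase_map
  say("duplicate_phases", m)
  m <- run_step("create_storage_pool",
                function() create_storage_pool(m, pm, config))
  say("create_storage_pool", m)
  m <- run_step("block_night_photon_uptake",
                function() block_night_photon_uptake(m, pm, config))
  say("block_night_photon_uptake", m)
  if (!is.null(config$ratio) && length(config$nitrate_reaction_ids)) {
    m <- run_step("apply_nitrate_ratio",
                  function() apply_nitrate_ratio(m, pm, config))
    say("apply_nitrate_ratio", m)
  }
  if (isTRUE(config$merge_biomass) && length(config$biomass_reaction_ids)) {
    m <- run_step("merge_biomass", function() merge_biomass(m, pm, config))
    say("merge_biomass", m)
  }
  assert_valid_model(m)
  structure(list(model = m, phase_map = pm, report = report),
            class = "diel_pipeline_result")
}

#' @export
print.diel_pipeline_result <- function(x, ...) {
  cat("<diel_pipeline_result>\n")
  for (step in names(x$report)) {
    ct <- x$report[[step]]
    cat(sprintf("  %-26s %4d cmp %4d met %4d rxn %3d cstr\n", step,
                ct$compartments, ct$metabolites, ct$reactions, ct$constraints))
  }
  invisible(x)
}
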