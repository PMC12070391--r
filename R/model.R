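#' Construct a metabolite
#'
#' Metabolites are the nodes of the stoichiometric network. The `compartment`
#' must name a compartment present in the model the metabolite is placed in.
#'
#' @param id Unique identifier (opaque, case-sensitive string).
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Identifier of the compartment the metabolite lives in.
#' @param formula Optional chemical formula string.
#' @return A `dg_metabolite` object.
#' @export
metabolite <- function(id, compartment, name = id, formula = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(compartment), length(compartment) == 1L)
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula),
            class = "dg_metabolite")
}

#' Construct a compartment
#'
#' @param id Unique identifier.
#' @param name Human-readable name; defaults to `id`.
#' @return A `dg_compartment` object.
#' @export
compartment <- function(id, name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name), class = "dg_compartment")
}

#' Construct a reaction
#'
#' Stoichiometry follows the usual constraint-based convention: negative
#' coefficients are consumed, positive coefficients produced. Bounds are in
#' flux units (conventionally mmol gDW^-1 h^-1).
#'
#' @param id Unique identifier.
#' @param stoichiometry Named numeric vector, names are metabolite ids.
#' @param lower_bound,upper_bound Flux bounds, `lower_bound <= upper_bound`.
#' @param name Human-readable name; defaults to `id`.
#' @param gpr Optional gene-protein-reaction rule (opaque boolean string).
#' @param pathway Optional pathway / subsystem label used by enrichment.
#' @return A `dg_reaction` object.
#' @export
reaction <- function(id, stoichiometry, lower_bound, upper_bound,
                     name = id, gpr = NULL, pathway = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(stoichiometry), !is.null(names(stoichiometry)),
            all(nzchar(names(stoichiometry))),
            is.numeric(lower_bound), is.numeric(upper_bound))
  stoichiometry <- stats::setNames(as.numeric(stoichiometry),
                                   names(stoichiometry))
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, pathway = pathway),
            class = "dg_reaction")
}

#' Construct a linear coupling constraint
#'
#' A linear constraint `lower <= sum(coefficients * v) <= upper` over reaction
#' fluxes, in addition to mass balance and bounds. The day:night nitrate
#' uptake ratio p:q is encoded this way as `q * v_day - p * v_night = 0`.
#'
#' @param id Unique identifier.
#' @param coefficients Named numeric vector, names are reaction ids.
#' @param lower,upper Constraint bounds, `lower <= upper`.
#' @return A `dg_constraint` object.
#' @export
linear_constraint <- function(id, coefficients, lower, upper) {
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(id = id,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                names(coefficients)),
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "dg_constraint")
}

#' Construct a constraint-based metabolic model
#'
#' The central container: compartments, metabolites, reactions, a linear
#' objective over reactions, and optional extra linear coupling constraints.
#' Components are stored as lists keyed by id.
#'
#' @param id Model identifier.
#' @param compartments List of [compartment()] objects.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective Named numeric vector of objective weights over reaction ids.
#' @param constraints List of [linear_constraint()] objects.
#' @param default_bound Magnitude used to cap infinite bounds when solving or
#'   sampling; the conventional "unbounded" value of published GEMs.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(id, compartments = list(), metabolites = list(),
                            reactions = list(), objective = numeric(),
                            constraints = list(), default_bound = 1000) {
  name_by_id <- function(xs) stats::setNames(xs, vapply(xs, `[[`, "", "id"))
  m <- structure(list(
    id = id,
    compartments = name_by_id(compartments),
    metabolites = name_by_id(metabolites),
    reactions = name_by_id(reactions),
    objective = stats::setNames(as.numeric(objective), names(objective)),
    constraints = name_by_id(constraints),
    default_bound = default_bound
  ), class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model> %s: %d compartments, %d metabolites, %d reactions, %d coupling constraints\n",
    x$id, length(x$compartments), length(x$metabolites), length(x$reactions),
    length(x$constraints)))
  if (length(x$objective))
    cat("  objective:", paste(sprintf("%g*%s", x$objective, names(x$objective)),
                              collapse = " + "), "\n")
  invisible(x)
}

#' Validate a metabolic model
#'
#' Checks every structural invariant of the model container and returns a
#' character vector of human-readable violations, empty when the model is
#' consistent. This function never throws on well-typed input.
#'
#' Checked rules: unique ids per namespace; metabolite compartments exist;
#' reactions have non-empty stoichiometry over existing metabolites and
#' ordered bounds; objective and coupling constraints refer only to existing
#' reactions; coupling constraint bounds are ordered.
#'
#' @param model A [metabolic_model()].
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_model <- function(model) {
  v <- character()
  note <- function(...) v <<- c(v, sprintf(...))

  for (space in c("compartments", "metabolites", "reactions", "constraints")) {
    ids <- names(model[[space]])
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) note("duplicate id '%s' in %s", d, space)
  }
  comp_ids <- names(model$compartments)
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)

  for (m in model$metabolites)
    if (!(m$compartment %in% comp_ids))
      note("metabolite '%s': unknown compartment '%s'", m$id, m$compartment)

  for (r in model$reactions) {
    if (length(r$stoichiometry) == 0L)
      note("reaction '%s': empty stoichiometry", r$id)
    if (!is.finite(r$lower_bound) && r$lower_bound > 0 ||
        !is.finite(r$upper_bound) && r$upper_bound < 0 ||
        r$lower_bound > r$upper_bound)
      note("reaction '%s': lower_bound (%g) > upper_bound (%g)",
           r$id, r$lower_bound, r$upper_bound)
    missing <- setdiff(names(r$stoichiometry), met_ids)
    for (mm in missing)
      note("reaction '%s': unknown metabolite '%s'", r$id, mm)
  }

  bad_obj <- setdiff(names(model$objective), rxn_ids)
  for (b in bad_obj) note("objective: unknown reaction '%s'", b)

  for (cn in model$constraints) {
    if (cn$lower > cn$upper)
      note("constraint '%s': lower (%g) > upper (%g)", cn$id, cn$lower, cn$upper)
    missing <- setdiff(names(cn$coefficients), rxn_ids)
    for (mm in missing)
      note("constraint '%s': unknown reaction '%s'", cn$id, mm)
  }
  v
}

#' Assert that a model is valid, stopping with all violations otherwise
#' @param model A [metabolic_model()].
#' @return The model, invisibly.
#' @export
assert_valid_model <- function(model) {
  v <- validate_model(model)
  if (length(v))
    stop("invalid model '", model$id, "':\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model A [metabolic_model()].
#' @return A dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Reaction flux bounds of a model
#'
#' @param model A [metabolic_model()].
#' @param cap_infinite Replace infinite bounds by `+/- model$default_bound`.
#' @return A two-column matrix (`lower`, `upper`) with reaction-id rownames.
#' @export
model_bounds <- function(model, cap_infinite = FALSE) {
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  if (cap_infinite) {
    lb <- pmax(lb, -model$default_bound)
    ub <- pmin(ub, model$default_bound)
  }
  cbind(lower = lb, upper = ub)
}

# internal: replace a reaction (keyed list assignment preserving class)
set_reaction <- function(model, rxn) {
  model$reactions[[rxn$id]] <- rxn
  model
}
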