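# SBML Level 3 Version 1 + FBC v2 serialization.
#
# Bounds are FBC flux-bound parameters (shared per distinct value), the
# objective is an FBC objective, pathway labels are written as
# "SUBSYSTEM: <label>" notes and read from either the groups package or such
# notes, GPRs are carried in "GENE_ASSOCIATION: <rule>" notes. Cross-reaction
# coupling constraints have no native SBML FBC representation and are stored
# in a model-level annotation block under the urn:dielgem:coupling namespace
# (schema: <dgc:couplingConstraints><dgc:constraint id lower upper>
# <dgc:coefficient reaction value/>...</dgc:constraint>...), re-hydrated on
# read so a diel model stays a single self-describing file.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"
DGC_NS <- "urn:dielgem:coupling"

num_attr <- function(x) sprintf("%.17g", x)

is_valid_sid <- function(id) grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)

#' Write a model to an SBML Level 3 FBC v2 file
#'
#' The model must pass [validate_model()]; violations abort the write. All
#' ids must already be valid SBML SIds (identifiers are treated as opaque and
#' are never mangled). Coupling constraints are serialized in a model-level
#' annotation so that [read_sbml()] reproduces the model field by field.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  assert_valid_model(model)
  bad <- Filter(Negate(is_valid_sid),
                c(names(model$compartments), names(model$metabolites),
                  names(model$reactions)))
  if (length(bad))
    stop("ids are not valid SBML SIds: ", paste(bad, collapse = ", "),
         call. = FALSE)

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS, "xmlns:dgc" = DGC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = model$id,
                               "fbc:strict" = "false")

  if (length(model$constraints)) {
    ann <- xml2::xml_add_child(mnode, "annotation")
    cc <- xml2::xml_add_child(ann, "dgc:couplingConstraints")
    for (cn in model$constraints) {
      cnode <- xml2::xml_add_child(cc, "dgc:constraint", id = cn$id,
                                   lower = num_attr(cn$lower),
                                   upper = num_attr(cn$upper))
      for (rid in names(cn$coefficients))
        xml2::xml_add_child(cnode, "dgc:coefficient", reaction = rid,
                            value = num_attr(cn$coefficients[[rid]]))
    }
  }

  locomp <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in model$compartments)
    xml2::xml_add_child(locomp, "compartment", id = cp$id, name = cp$name,
                        constant = "true")

  losp <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (mt in model$metabolites) {
    attrs <- list(id = mt$id, name = mt$name, compartment = mt$compartment,
                  hasOnlySubstanceUnits = "false", boundaryCondition = "false",
                  constant = "false")
    if (!is.null(mt$formula)) attrs[["fbc:chemicalFormula"]] <- mt$formula
    do.call(xml2::xml_add_child, c(list(losp, "species"), attrs))
  }

  # shared flux-bound parameters, one per distinct value
  bvals <- unique(unlist(lapply(model$reactions,
                                function(r) c(r$lower_bound, r$upper_bound))))
  bids <- stats::setNames(sprintf("fb_%d", seq_along(bvals)), num_attr(bvals))
  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_along(bvals))
    xml2::xml_add_child(lop, "parameter", id = bids[[i]],
                        value = num_attr(bvals[[i]]), constant = "true",
                        sboTerm = "SBO:0000625")

  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  for (r in model$reactions) {
    rnode <- xml2::xml_add_child(
      lor, "reaction", id = r$id, name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bids[[num_attr(r$lower_bound)]],
      "fbc:upperFluxBound" = bids[[num_attr(r$upper_bound)]])
    notes <- character()
    if (!is.null(r$pathway)) notes <- c(notes, paste0("SUBSYSTEM: ", r$pathway))
    if (!is.null(r$gpr)) notes <- c(notes, paste0("GENE_ASSOCIATION: ", r$gpr))
    if (length(notes)) {
      nn <- xml2::xml_add_child(rnode, "notes")
      body <- xml2::xml_add_child(nn, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      for (txt in notes) xml2::xml_add_child(body, "p", txt)
    }
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rnode, "listOfReactants")
      for (sid in names(reac))
        xml2::xml_add_child(lr, "speciesReference", species = sid,
                            stoichiometry = num_attr(-reac[[sid]]),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rnode, "listOfProducts")
      for (sid in names(prod))
        xml2::xml_add_child(lp, "speciesReference", species = sid,
                            stoichiometry = num_attr(prod[[sid]]),
                            constant = "true")
    }
  }

  loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  if (length(model$objective)) {
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective))
      xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = rid,
                          "fbc:coefficient" = num_attr(model$objective[[rid]]))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from an SBML Level 3 FBC file
#'
#' Requires FBC flux-bound parameters on every reaction (kinetic laws are not
#' supported). Pathway labels are taken from the SBML groups package when
#' present, otherwise from reaction notes matching "SUBSYSTEM: <label>"; GPR
#' strings from "GENE_ASSOCIATION: <rule>" notes or `fbc:geneProductAssociation`
#' are kept opaque. Coupling constraints written by [write_sbml()] are
#' re-hydrated from the model annotation.
#'
#' @param path Path to an SBML Level 3 file with the FBC package.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed SBML in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS, g = GROUPS_NS, dgc = DGC_NS)
  mnode <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mnode, "xml_missing"))
    stop("malformed SBML: no <model> element under <sbml>", call. = FALSE)

  attr1 <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }

  comps <- lapply(xml2::xml_find_all(mnode, "./s:listOfCompartments/s:compartment", ns),
                  function(n) compartment(attr1(n, "id"),
                                          name = attr1(n, "name", attr1(n, "id"))))

  mets <- lapply(xml2::xml_find_all(mnode, "./s:listOfSpecies/s:species", ns),
                 function(n) {
                   f <- xml2::xml_attr(n, "chemicalFormula")
                   metabolite(attr1(n, "id"), attr1(n, "compartment"),
                              name = attr1(n, "name", attr1(n, "id")),
                              formula = if (is.na(f)) NULL else f)
                 })
  met_ids <- vapply(mets, `[[`, "", "id")

  pnodes <- xml2::xml_find_all(mnode, "./s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                          xml2::xml_attr(pnodes, "id"))

  # pathway labels from the groups package (member idRef -> group name)
  group_pathway <- character()
  for (gnode in xml2::xml_find_all(mnode, ".//g:group", ns)) {
    gname <- attr1(gnode, "name", attr1(gnode, "id"))
    refs <- xml2::xml_attr(xml2::xml_find_all(gnode, ".//g:member", ns), "idRef")
    group_pathway[refs[!is.na(refs)]] <- gname
  }

  note_field <- function(rnode, key) {
    txt <- xml2::xml_text(xml2::xml_find_all(rnode, ".//s:notes//*[not(*)]", ns))
    hit <- grep(paste0("^\\s*", key, ":\\s*"), txt, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^\\s*", key, ":\\s*"), "", hit[[1]])
  }

  rxns <- lapply(xml2::xml_find_all(mnode, "./s:listOfReactions/s:reaction", ns),
                 function(rnode) {
    rid <- attr1(rnode, "id")
    lb_id <- xml2::xml_attr(rnode, "lowerFluxBound")
    ub_id <- xml2::xml_attr(rnode, "upperFluxBound")
    if (is.na(lb_id) || is.na(ub_id) ||
        !(lb_id %in% names(pars)) || !(ub_id %in% names(pars)))
      stop("reaction '", rid, "' lacks FBC flux-bound parameters; ",
           "bounds are required (SBML L3 + FBC)", call. = FALSE)
    sto <- numeric()
    for (sr in xml2::xml_find_all(rnode, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- attr1(sr, "species")
      sto[sp] <- (if (sp %in% names(sto)) sto[[sp]] else 0) -
        as.numeric(attr1(sr, "stoichiometry", "1"))
    }
    for (sr in xml2::xml_find_all(rnode, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- attr1(sr, "species")
      sto[sp] <- (if (sp %in% names(sto)) sto[[sp]] else 0) +
        as.numeric(attr1(sr, "stoichiometry", "1"))
    }
    undecl <- setdiff(names(sto), met_ids)
    if (length(undecl))
      stop("parse error: reaction '", rid, "' references undeclared species: ",
           paste(undecl, collapse = ", "), call. = FALSE)
    pw <- if (rid %in% names(group_pathway)) group_pathway[[rid]]
          else note_field(rnode, "SUBSYSTEM")
    reaction(rid, sto, pars[[lb_id]], pars[[ub_id]],
             name = attr1(rnode, "name", rid),
             gpr = note_field(rnode, "GENE_ASSOCIATION"), pathway = pw)
  })

  fo <- xml2::xml_find_all(
    mnode, "./fbc:listOfObjectives/fbc:objective[1]/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                               xml2::xml_attr(fo, "reaction"))

  constraints <- lapply(
    xml2::xml_find_all(mnode, "./s:annotation/dgc:couplingConstraints/dgc:constraint", ns),
    function(cnode) {
      co <- xml2::xml_find_all(cnode, "./dgc:coefficient", ns)
      linear_constraint(
        attr1(cnode, "id"),
        stats::setNames(as.numeric(xml2::xml_attr(co, "value")),
                        xml2::xml_attr(co, "reaction")),
        as.numeric(attr1(cnode, "lower")), as.numeric(attr1(cnode, "upper")))
    })

  model <- metabolic_model(attr1(mnode, "id", "model"),
                           compartments = comps, metabolites = mets,
                           reactions = rxns, objective = objective,
                           constraints = constraints)
  assert_valid_model(model)
  model
}

#' Export a model as JSON (debugging / fixture diffing)
#'
#' A plain JSON rendering of the full model structure. [model_from_json()]
#' inverts it.
#'
#' @param model A [metabolic_model()].
#' @param path Optional file path; when given, JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL) {
  strip <- function(x) { x[!vapply(x, is.null, TRUE)] }
  obj <- list(
    id = model$id,
    default_bound = model$default_bound,
    compartments = lapply(unname(model$compartments), strip),
    metabolites = lapply(unname(model$metabolites), strip),
    reactions = lapply(unname(model$reactions), function(r)
      strip(list(id = r$id, name = r$name,
                 stoichiometry = as.list(r$stoichiometry),
                 lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                 gpr = r$gpr, pathway = r$pathway))),
    objective = as.list(model$objective),
    constraints = lapply(unname(model$constraints), function(cn)
      list(id = cn$id, coefficients = as.list(cn$coefficients),
           lower = cn$lower, upper = cn$upper))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Rebuild a model from its JSON export
#' @param json JSON string or path to a JSON file written by [model_to_json()].
#' @return A [metabolic_model()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  metabolic_model(
    obj$id,
    compartments = lapply(obj$compartments, function(x)
      compartment(x$id, name = x$name)),
    metabolites = lapply(obj$metabolites, function(x)
      metabolite(x$id, x$compartment, name = x$name, formula = x$formula)),
    reactions = lapply(obj$reactions, function(x)
      reaction(x$id, unlist(x$stoichiometry), x$lower_bound, x$upper_bound,
               name = x$name, gpr = x$gpr, pathway = x$pathway)),
    objective = unlist(obj$objective) %||% numeric(),
    constraints = lapply(obj$constraints, function(x)
      linear_constraint(x$id, unlist(x$coefficients), x$lower, x$upper)),
    default_bound = obj$default_bound %||% 1000
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
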