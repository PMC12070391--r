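# Linear programming plumbing over the in-package bounded-variable simplex:
#   max/min c'v  s.t.  A_eq v = b_eq,  A_le v <= b_le,  lb <= v <= ub
# Inequalities get slack variables in [0, Inf); lower bounds must be finite
# (callers cap infinities at the model default bound first).
solve_lp <- function(cvec, lb, ub, A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL, maximize = TRUE) {
  n <- length(cvec)
  stopifnot(length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)))
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric() }
  if (is.null(A_le)) { A_le <- matrix(0, 0, n); b_le <- numeric() }
  ns <- nrow(A_le)
  A <- rbind(cbind(A_eq, matrix(0, nrow(A_eq), ns)),
             cbind(A_le, diag(1, ns)))
  b <- c(b_eq, b_le)
  res <- bounded_simplex(A, b, c(cvec, numeric(ns)),
                         lb = c(lb, numeric(ns)),
                         ub = c(ub, rep(Inf, ns)), maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, solution = rep(NA_real_, n),
                objective = NA_real_))
  v <- res$solution[seq_len(n)]
  list(status = "optimal", solution = v, objective = sum(cvec * v))
}

# internal: assemble equality / inequality rows for a model's coupling
# constraints (rows over the reaction vector in model reaction order)
coupling_rows <- function(model) {
  rxn_ids <- names(model$reactions)
  n <- length(rxn_ids)
  A_eq <- NULL; b_eq <- numeric(); A_le <- NULL; b_le <- numeric()
  for (cn in model$constraints) {
    row <- numeric(n); names(row) <- rxn_ids
    row[names(cn$coefficients)] <- cn$coefficients
    if (cn$lower == cn$upper) {
      A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, cn$lower)
    } else {
      if (is.finite(cn$upper)) { A_le <- rbind(A_le, row); b_le <- c(b_le, cn$upper) }
      if (is.finite(cn$lower)) { A_le <- rbind(A_le, -row); b_le <- c(b_le, -cn$lower) }
    }
  }
  list(A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le)
}

#' Solve a model by flux balance analysis
#'
#' Maximizes the model objective subject to steady-state mass balance
#' `S v = 0`, flux bounds, and any linear coupling constraints. With
#' `parsimonious = TRUE` a second LP minimizes the total absolute flux
#' `sum(|v|)` while holding the objective at its optimum, which removes most
#' of the degeneracy of the optimal face and makes reported flux directions
#' meaningful.
#'
#' Infinite bounds are capped at `model$default_bound` before solving, so the
#' LP is always bounded; `status` is `"optimal"` or `"infeasible"`.
#'
#' @param model A valid [metabolic_model()] with a non-empty objective.
#' @param parsimonious Run the total-flux minimization at the fixed optimum?
#' @return A `flux_distribution`: list with `fluxes` (named by reaction id),
#'   `objective_value`, and `status`.
#' @export
solve_fba <- function(model, parsimonious = FALSE) {
  assert_valid_model(model)
  if (length(model$objective) == 0L)
    stop("model has an empty objective; set model$objective first",
         call. = FALSE)
  rxn_ids <- names(model$reactions)
  n <- length(rxn_ids)
  S <- stoichiometric_matrix(model)
  bounds <- model_bounds(model, cap_infinite = TRUE)
  cvec <- numeric(n); names(cvec) <- rxn_ids
  cvec[names(model$objective)] <- model$objective
  cp <- coupling_rows(model)
  A_eq <- rbind(S, cp$A_eq)
  b_eq <- c(numeric(nrow(S)), cp$b_eq)

  fit <- solve_lp(cvec, bounds[, "lower"], bounds[, "upper"],
                  A_eq = A_eq, b_eq = b_eq,
                  A_le = cp$A_le, b_le = cp$b_le, maximize = TRUE)
  if (fit$status != "optimal")
    return(structure(list(fluxes = stats::setNames(fit$solution, rxn_ids),
                          objective_value = NA_real_, status = fit$status),
                     class = "flux_distribution"))
  zopt <- fit$objective
  clamp <- function(v) pmin(pmax(v, bounds[, "lower"]), bounds[, "upper"])
  v <- clamp(fit$solution)

  if (parsimonious) {
    # v = pos - neg, pos/neg >= 0; minimize sum(pos + neg) at c'v >= z* - tol
    lbv <- bounds[, "lower"]; ubv <- bounds[, "upper"]
    lb2 <- c(pmax(lbv, 0), pmax(-ubv, 0))
    ub2 <- c(pmax(ubv, 0), pmax(-lbv, 0))
    split2 <- function(A) cbind(A, -A)
    A_eq2 <- split2(A_eq)
    A_le2 <- rbind(if (!is.null(cp$A_le)) split2(cp$A_le),
                   matrix(c(-cvec, cvec), 1))
    b_le2 <- c(cp$b_le, -(zopt - 1e-9))
    fit2 <- solve_lp(c(rep(1, n), rep(1, n)), lb2, ub2,
                     A_eq = A_eq2, b_eq = b_eq,
                     A_le = A_le2, b_le = b_le2, maximize = FALSE)
    if (fit2$status == "optimal") {
      v <- clamp(fit2$solution[seq_len(n)] - fit2$solution[n + seq_len(n)])
      zopt <- sum(cvec * v)
    }
  }
  structure(list(fluxes = stats::setNames(v, rxn_ids),
                 objective_value = zopt, status = "optimal"),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status = %s, objective = %s, %d reactions\n",
              x$status,
              if (is.na(x$objective_value)) "NA" else
                format(x$objective_value, digits = 6),
              length(x$fluxes)))
  invisible(x)
}

#' Quantum yield of CO2 fixation
#'
#' The quantum yield (QY, mol CO2 fixed per mol photons absorbed) of a solved
#' model is the flux of the RuBisCO carboxylation reaction divided by the
#' flux of the photon uptake reaction. For diel models pass the day-phase
#' reaction ids. Both reactions are expected in the positive-flux-is-uptake /
#' positive-flux-is-fixation orientation.
#'
#' @param flux An optimal `flux_distribution` from [solve_fba()].
#' @param rubisco_carboxylation_id Reaction id of RuBisCO carboxylation.
#' @param photon_uptake_id Reaction id of photon uptake.
#' @param tol Photon fluxes at or below this magnitude leave QY undefined.
#' @return The dimensionless quantum yield.
#' @export
quantum_yield <- function(flux, rubisco_carboxylation_id, photon_uptake_id,
                          tol = 1e-6) {
  if (!identical(flux$status, "optimal"))
    stop("quantum yield requires an optimal flux distribution (status = ",
         flux$status, ")", call. = FALSE)
  for (rid in c(rubisco_carboxylation_id, photon_uptake_id))
    if (!(rid %in% names(flux$fluxes)))
      stop("reaction '", rid, "' not in the flux distribution", call. = FALSE)
  v_photon <- flux$fluxes[[photon_uptake_id]]
  if (abs(v_photon) <= tol)
    stop("photon uptake flux is ~0 (", format(v_photon),
         "); quantum yield is undefined", call. = FALSE)
  flux$fluxes[[rubisco_carboxylation_id]] / v_photon
}

#' Storage-pool flux report
#'
#' For every pooled metabolite reports the flux of its day-side exchange
#' (positive = the day phase deposits into the pool) and its night-side
#' exchange (positive = the pool feeds the night phase), and classifies the
#' net direction. Steady state makes the two fluxes equal, so the direction
#' is `day_to_night` when they are positive, `night_to_day` when negative,
#' and `inactive` when both magnitudes are at most `tol`.
#'
#' Pool exchange reactions are identified by the pipeline's naming scheme
#' (`SP_<metabolite><suffix>`).
#'
#' @param model A diel model produced by [run_pipeline()].
#' @param flux An optimal `flux_distribution` for `model`.
#' @param day_suffix,night_suffix The phase suffixes used by the pipeline.
#' @param tol Activity threshold on flux magnitude.
#' @return A data.frame with columns `metabolite`, `day_to_pool_flux`,
#'   `pool_to_night_flux`, `net_direction`.
#' @export
storage_pool_report <- function(model, flux, day_suffix = "_Day",
                                night_suffix = "_Night", tol = 1e-6) {
  if (!identical(flux$status, "optimal"))
    stop("storage pool report requires an optimal flux distribution",
         call. = FALSE)
  ds <- sanitize_sid(day_suffix); ns <- sanitize_sid(night_suffix)
  ids <- names(model$reactions)
  day_ids <- ids[startsWith(ids, "SP_") & endsWith(ids, ds)]
  mets <- substr(day_ids, 4L, nchar(day_ids) - nchar(ds))
  night_ids <- paste0("SP_", mets, ns)
  keep <- night_ids %in% ids
  mets <- mets[keep]; day_ids <- day_ids[keep]; night_ids <- night_ids[keep]
  if (length(mets) == 0L)
    stop("model has no storage pool (no SP_* exchange reaction pairs found)",
         call. = FALSE)
  d <- unname(flux$fluxes[day_ids])
  n <- unname(flux$fluxes[night_ids])
  dir <- ifelse(abs(d) <= tol & abs(n) <= tol, "inactive",
                ifelse(d > 0, "day_to_night", "night_to_day"))
  data.frame(metabolite = mets, day_to_pool_flux = d, pool_to_night_flux = n,
             net_direction = dir, row.names = NULL,
             stringsAsFactors = FALSE)
}
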