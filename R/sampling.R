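# Artificial-centering hit-and-run (ACHR) sampling of the flux polytope
# {v : S v = 0, coupling constraints, lb <= v <= ub}.
#
# Two reductions make every emitted sample valid to machine precision.
# First, the walk runs in the null space of the equality system (mass
# balance, equality couplings, fixed reactions), so S v = 0 holds exactly.
# Second, diel polytopes are usually not full-dimensional even inside that
# null space — blocking night photon uptake pins whole night pathways to
# zero through one-sided bounds — so warmup vertices from flux variability
# (plus seeded random objectives) are used to identify the affine hull of
# the feasible set, and the chain moves only inside that hull, with the
# warmup vertices seeding the ACHR direction pool.

run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Sample flux distributions with an ACHR walk
#'
#' Draws `n` near-uniform samples from the feasible flux polytope of the
#' model (steady-state mass balance, flux bounds, coupling constraints).
#' Infinite bounds are capped at `model$default_bound` before sampling so the
#' polytope is bounded. Warmup points are the flux-variability extreme
#' points of every non-fixed reaction plus a few random-objective vertices;
#' the artificial-centering walk then emits every `thinning`-th step after
#' `warmup` initial steps.
#'
#' @param model A valid, feasible [metabolic_model()].
#' @param n Number of samples (>= 2).
#' @param seed Integer seed; the full run is reproducible given the seed.
#' @param thinning Keep every `thinning`-th step (default 100).
#' @param warmup Number of walk steps before the first kept sample.
#' @return A `sample_matrix`: list with `reaction_ids`, `samples` (reactions
#'   x n matrix with reaction-id rownames), and `seed`.
#' @export
sample_fluxes <- function(model, n, seed, thinning = 100, warmup = 500) {
  assert_valid_model(model)
  stopifnot(n >= 2, thinning >= 1)
  rxn_ids <- names(model$reactions)
  nr <- length(rxn_ids)
  S <- stoichiometric_matrix(model)
  bounds <- model_bounds(model, cap_infinite = TRUE)
  lb <- bounds[, "lower"]; ub <- bounds[, "upper"]
  cp <- coupling_rows(model)

  # equality system: mass balance, equality couplings, fixed reactions
  fixed <- (ub - lb) <= 1e-12
  E <- rbind(S, cp$A_eq,
             if (any(fixed)) diag(nr)[fixed, , drop = FALSE])
  b <- c(numeric(nrow(S)), cp$b_eq, if (any(fixed)) (lb[fixed] + ub[fixed]) / 2)
  A_eq <- rbind(S, cp$A_eq)
  b_eq <- c(numeric(nrow(S)), cp$b_eq)

  sv <- svd(E, nu = min(dim(E)), nv = ncol(E))
  tol_rank <- max(dim(E)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol_rank)
  if (r > 0) {
    v0 <- sv$v[, seq_len(r), drop = FALSE] %*%
      ((t(sv$u[, seq_len(r), drop = FALSE]) %*% b) / sv$d[seq_len(r)])
    v0 <- as.vector(v0)
    if (max(abs(E %*% v0 - b)) > 1e-7)
      stop("model is infeasible: equality constraints are inconsistent",
           call. = FALSE)
  } else v0 <- numeric(nr)
  d <- nr - r
  N <- if (d > 0) sv$v[, (r + 1):nr, drop = FALSE] else matrix(0, nr, 0)

  emit <- function(V) {
    rownames(V) <- rxn_ids
    structure(list(reaction_ids = rxn_ids, samples = V, seed = seed),
              class = "sample_matrix")
  }
  point_only <- function() {
    if (any(v0 < lb - 1e-6 | v0 > ub + 1e-6))
      stop("model is infeasible: the unique steady state violates bounds",
           call. = FALSE)
    emit(matrix(v0, nr, n))
  }
  if (d == 0L) return(point_only())

  # warmup vertices: flux variability over the non-fixed reactions, plus
  # seeded random objectives (guards against FVA vertices not spanning the
  # affine hull)
  free_idx <- which(!fixed)
  rand_obj <- run_with_seed(seed, matrix(stats::rnorm(nr * min(d, 20)), nr))
  objs <- cbind(diag(nr)[, free_idx, drop = FALSE],
                -diag(nr)[, free_idx, drop = FALSE], rand_obj)
  W <- matrix(NA_real_, nr, ncol(objs))
  for (k in seq_len(ncol(objs))) {
    fit <- solve_lp(objs[, k], lb, ub, A_eq = A_eq, b_eq = b_eq,
                    A_le = cp$A_le, b_le = cp$b_le, maximize = TRUE)
    if (fit$status != "optimal")
      stop("model is infeasible; cannot sample", call. = FALSE)
    W[, k] <- fit$solution
  }
  Z <- crossprod(N, W - v0)            # warmup points in null-space coords
  z_c <- rowMeans(Z)
  Zc <- Z - z_c
  svz <- svd(Zc, nu = d, nv = 0)
  scale_z <- max(svz$d)
  if (scale_z <= 1e-9) return(point_only())
  d2 <- sum(svz$d > 1e-9 * max(1, scale_z))
  Q <- svz$u[, seq_len(d2), drop = FALSE]    # affine hull basis

  # inequalities in hull coordinates y (z = z_c + Q y):  Ay y <= by
  free <- !fixed
  Az <- rbind(N[free, , drop = FALSE], -N[free, , drop = FALSE],
              if (!is.null(cp$A_le)) cp$A_le %*% N)
  bz <- c(ub[free] - v0[free], v0[free] - lb[free],
          if (!is.null(cp$A_le)) cp$b_le - as.vector(cp$A_le %*% v0))
  Ay <- Az %*% Q
  by <- bz - as.vector(Az %*% z_c)
  rn <- sqrt(rowSums(Ay^2))
  keep <- rn > 1e-9 * max(1, max(rn))
  # dropped rows are constant on the hull; they hold at the warmup center
  by[!keep & by < 0] <- 0
  Ay <- Ay[keep, , drop = FALSE]; by <- by[keep]

  Y <- crossprod(Q, Zc)                # warmup points in hull coords
  run_with_seed(seed + 1L, {
    n_store <- max(2L * n, ncol(Y), 200L)
    store <- matrix(0, d2, n_store)
    store[, seq_len(ncol(Y))] <- Y
    n_seen <- ncol(Y)
    center <- rowMeans(Y)
    y <- center
    add_point <- function(yp) {
      n_seen <<- n_seen + 1L
      center <<- center + (yp - center) / n_seen
      store[, (n_seen - 1L) %% n_store + 1L] <<- yp
    }
    step <- function(y, u) {
      nu <- sqrt(sum(u^2))
      if (nu < 1e-12) return(y)
      u <- u / nu
      au <- as.vector(Ay %*% u)
      s <- by - as.vector(Ay %*% y)
      s[s < 0] <- 0
      pos <- au > 1e-10; neg <- au < -1e-10
      tmax <- if (any(pos)) min(s[pos] / au[pos]) else Inf
      tmin <- if (any(neg)) max(-s[neg] / (-au[neg])) else -Inf
      if (!is.finite(tmax)) tmax <- 1e6
      if (!is.finite(tmin)) tmin <- -1e6
      if (tmax <= tmin) return(y)
      y + stats::runif(1, tmin, tmax) * u
    }
    Ykept <- matrix(0, d2, n)
    total <- warmup + n * thinning
    k_out <- 0L
    for (i in seq_len(total)) {
      pick <- store[, sample.int(min(n_seen, n_store), 1L)]
      u <- pick - center
      if (sqrt(sum(u^2)) < 1e-10) u <- stats::rnorm(d2)
      y <- step(y, u)
      add_point(y)
      if (i > warmup && (i - warmup) %% thinning == 0L) {
        k_out <- k_out + 1L
        Ykept[, k_out] <- y
      }
    }
    emit(v0 + N %*% (z_c + Q %*% Ykept))
  })
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> %d reactions x %d samples (seed %s)\n",
              nrow(x$samples), ncol(x$samples), format(x$seed)))
  invisible(x)
}
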