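# Bounded-variable primal simplex with Bland's anti-cycling rule.
#
#   max c'x   s.t.  A x = b,  lb <= x <= ub
#
# lb must be finite; ub may be +Inf. A two-phase scheme gets a feasible basis
# from artificial variables. The basis system is re-solved densely each
# iteration, which is entirely adequate for the model sizes this package
# targets (hundreds of reactions); Bland's rule trades speed for guaranteed
# termination on the heavily degenerate LPs that diel transformations
# produce (many bounds fixed at zero).

simplex_core <- function(A, b, cvec, lb, ub, basis, at_ub, x,
                         tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    nonbasic <- setdiff(seq_len(ncol(A)), basis)
    x[basis] <- solve(B, b - A[, nonbasic, drop = FALSE] %*% x[nonbasic])
    y <- solve(t(B), cvec[basis])
    d <- cvec - as.vector(crossprod(A, y))
    cand <- nonbasic[(!at_ub[nonbasic] & d[nonbasic] > tol) |
                       (at_ub[nonbasic] & d[nonbasic] < -tol)]
    if (length(cand) == 0L)
      return(list(status = "optimal", x = x, basis = basis, at_ub = at_ub))
    j <- min(cand)                       # Bland: smallest entering index
    dir <- if (at_ub[j]) -1 else 1
    w <- solve(B, A[, j])
    g <- -dir * w                        # basic change per unit step
    t_basic <- rep(Inf, m)
    up <- g > tol
    t_basic[up] <- (ub[basis[up]] - x[basis[up]]) / g[up]
    dn <- g < -tol
    t_basic[dn] <- (lb[basis[dn]] - x[basis[dn]]) / g[dn]
    t_basic[t_basic < 0] <- 0            # numerical guard on degenerate steps
    t_own <- ub[j] - lb[j]
    t_step <- min(t_own, t_basic)
    if (!is.finite(t_step))
      return(list(status = "unbounded", x = x, basis = basis, at_ub = at_ub))
    x[j] <- x[j] + dir * t_step
    x[basis] <- x[basis] + t_step * g
    if (t_own <= min(t_basic)) {
      at_ub[j] <- !at_ub[j]              # bound flip, basis unchanged
      x[j] <- if (at_ub[j]) ub[j] else lb[j]
    } else {
      hit <- which(abs(t_basic - t_step) <= tol * (1 + abs(t_step)))
      leave_pos <- hit[which.min(basis[hit])]   # Bland: smallest leaving index
      lv <- basis[leave_pos]
      at_ub[lv] <- g[leave_pos] > 0
      x[lv] <- if (at_ub[lv]) ub[lv] else lb[lv]
      basis[leave_pos] <- j
    }
  }
  stop("simplex iteration limit reached (", max_iter, ")", call. = FALSE)
}

# max c'x s.t. A x = b, lb <= x <= ub; lb finite, ub may be Inf.
bounded_simplex <- function(A, b, cvec, lb, ub, maximize = TRUE,
                            tol = 1e-9) {
  if (!maximize) {
    res <- bounded_simplex(A, b, -cvec, lb, ub, TRUE, tol)
    res$objective <- -res$objective
    return(res)
  }
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(is.finite(lb)), all(ub >= lb))
  if (m == 0L) {
    x <- ifelse(cvec > 0, ub, lb)
    if (any(!is.finite(x)))
      return(list(status = "unbounded", solution = NULL, objective = Inf))
    return(list(status = "optimal", solution = x,
                objective = sum(cvec * x)))
  }
  # phase 1: start all structurals at lb, artificials absorb the residual
  x0 <- lb
  r <- as.vector(b - A %*% x0)
  Aa <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  art <- n + seq_len(m)
  xa <- c(x0, abs(r))
  lba <- c(lb, numeric(m)); uba <- c(ub, rep(Inf, m))
  c1 <- c(numeric(n), rep(-1, m))
  at_ub <- rep(FALSE, n + m)
  p1 <- simplex_core(Aa, b, c1, lba, uba, basis = art, at_ub = at_ub, x = xa,
                     tol = tol)
  feas_tol <- 1e-7 * max(1, max(abs(b)))
  if (p1$status != "optimal" || sum(p1$x[art]) > feas_tol)
    return(list(status = "infeasible", solution = NULL, objective = NA_real_))
  # phase 2: artificials pinned to zero, true objective
  uba[art] <- 0
  xa <- p1$x; xa[art] <- 0
  c2 <- c(cvec, numeric(m))
  p2 <- simplex_core(Aa, b, c2, lba, uba, basis = p1$basis,
                     at_ub = p1$at_ub, x = xa, tol = tol)
  if (p2$status != "optimal")
    return(list(status = "unbounded", solution = NULL, objective = Inf))
  x <- p2$x[seq_len(n)]
  list(status = "optimal", solution = x, objective = sum(cvec * x))
}
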