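#' Solve a bounded-variable linear program
#'
#' Solves `max/min obj' x` subject to `A x = rhs` and `lb <= x <= ub` with a
#' two-phase primal simplex method supporting explicit variable bounds.
#' This is the solver behind all flux-balance computations in the package
#' (FBA, FVA, consistency testing, FASTCORE extraction). Problems of the
#' sizes handled here (tens to a few hundred variables) solve in
#' milliseconds; the implementation favours numerical care over speed:
#' Dantzig pricing with a Bland's-rule fallback against cycling, and a
#' basis refactorisation on every iteration.
#'
#' Lower bounds must be finite; upper bounds may be `Inf`. Equality rows
#' only — encode inequalities with explicit slack variables.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or a `Matrix` sparse matrix.
#' @param rhs right-hand side (length m).
#' @param lb,ub variable bounds (length n); `lb` finite, `ub` may be `Inf`.
#' @param sense `"max"` or `"min"`.
#' @param tol numerical tolerance on reduced costs and feasibility.
#' @return a list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"singular"`), `objective` (the optimum, `NA` unless
#'   optimal) and `x` (an optimal point, `NA` unless optimal).
#' @examples
#' # max v3 s.t. a toy flux balance: uptake <= 10, 2 ATP per carbon
#' S <- matrix(c(-1, 0, -1, 2, 0, -1), nrow = 2)
#' lp_solve(c(0, 0, 1), S, c(0, 0), lb = c(-10, 0, 0), ub = rep(1000, 3))
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) {
    stop("lp_solve: lower bounds must be finite")
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NA))
  }
  cc <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  if (m == 0L) {
    # bounds-only problem: optimum at a bound, by sign of the cost
    x <- ifelse(cc >= 0, lb, ub)
    if (any(!is.finite(x))) {
      return(list(status = "unbounded", objective = NA_real_, x = NA))
    }
    val <- sum(cc * x)
    return(list(status = "optimal",
                objective = if (sense == "max") -val else val, x = x))
  }

  # ---- phase 1: artificial variables with unit costs -----------------------
  # nonbasic structural variables start at the finite bound nearest zero
  start <- ifelse(is.finite(ub) & abs(ub) < abs(lb), ub, lb)
  resid <- as.numeric(rhs - A %*% start)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Aall <- cbind(A, diag(art_sign, m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  x <- c(start, abs(resid))
  at_upper <- ifelse(is.finite(ub) & abs(ub) < abs(lb), TRUE, FALSE)
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)

  st <- simplex_core(c(rep(0, n), rep(1, m)), Aall, lball, uball,
                     basis, x, at_upper, tol)
  if (st$status != "optimal") {
    return(list(status = if (st$status == "unbounded") "singular" else st$status,
                objective = NA_real_, x = NA))
  }
  if (sum(st$x[n + seq_len(m)]) > 1e-7 * max(1, max(abs(rhs)))) {
    return(list(status = "infeasible", objective = NA_real_, x = NA))
  }

  # ---- phase 2: pin artificials at zero, optimise the true objective -------
  uball2 <- uball
  uball2[n + seq_len(m)] <- 0
  x2 <- st$x
  x2[n + seq_len(m)] <- 0
  st2 <- simplex_core(c(cc, rep(0, m)), Aall, lball, uball2,
                      st$basis, x2, st$at_upper, tol)
  if (st2$status != "optimal") {
    return(list(status = st2$status, objective = NA_real_, x = NA))
  }
  xopt <- st2$x[seq_len(n)]
  val <- sum(cc * xopt)
  list(status = "optimal",
       objective = if (sense == "max") -val else val,
       x = xopt)
}

# Bounded-variable primal simplex core (minimisation). Iterates from a
# basic solution until no eligible entering variable remains. Pricing is
# Dantzig's rule; after `bland_after` iterations it switches to Bland's
# rule, which guarantees finite termination under degeneracy.
simplex_core <- function(cost, A, lb, ub, basis, x, at_upper, tol,
                         max_iter = NULL, bland_after = NULL) {
  m <- nrow(A)
  nv <- ncol(A)
  if (is.null(max_iter)) max_iter <- 200L + 40L * nv
  if (is.null(bland_after)) bland_after <- 100L + 10L * nv
  is_basic <- rep(FALSE, nv)
  is_basic[basis] <- TRUE

  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]),
                  error = function(e) NULL)
    if (is.null(y)) {
      return(list(status = "singular", x = x, basis = basis,
                  at_upper = at_upper))
    }
    d <- cost - as.numeric(crossprod(A, y))
    nonbasic <- which(!is_basic)
    viol_lo <- !at_upper[nonbasic] & d[nonbasic] < -tol
    viol_hi <- at_upper[nonbasic] & d[nonbasic] > tol
    eligible <- nonbasic[viol_lo | viol_hi]
    if (length(eligible) == 0L) {
      return(list(status = "optimal", x = x, basis = basis,
                  at_upper = at_upper))
    }
    if (iter > bland_after) {
      e <- eligible[1L] # Bland: smallest index
    } else {
      e <- eligible[which.max(abs(d[eligible]))]
    }
    delta <- if (at_upper[e]) -1 else 1

    w <- tryCatch(solve(B, A[, e]), error = function(e) NULL)
    if (is.null(w)) {
      return(list(status = "singular", x = x, basis = basis,
                  at_upper = at_upper))
    }
    g <- -delta * w # change of basic variables per unit step

    # ratio test: keep basic variables inside their bounds, and the
    # entering variable inside its own span
    t_best <- ub[e] - lb[e] # bound flip distance (may be Inf)
    leave <- 0L
    leave_to_upper <- FALSE
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (g[i] > tol) {
        if (is.finite(ub[bi])) {
          ti <- (ub[bi] - x[bi]) / g[i]
          if (ti < t_best - 1e-12) {
            t_best <- ti; leave <- i; leave_to_upper <- TRUE
          }
        }
      } else if (g[i] < -tol) {
        ti <- (x[bi] - lb[bi]) / (-g[i])
        if (ti < t_best - 1e-12) {
          t_best <- ti; leave <- i; leave_to_upper <- FALSE
        }
      }
    }
    if (!is.finite(t_best)) {
      return(list(status = "unbounded", x = x, basis = basis,
                  at_upper = at_upper))
    }
    t_best <- max(t_best, 0)

    # update the solution
    x[e] <- x[e] + delta * t_best
    x[basis] <- x[basis] + g * t_best
    if (leave == 0L) {
      # entering variable travelled to its opposite bound: no basis change
      at_upper[e] <- !at_upper[e]
    } else {
      out <- basis[leave]
      x[out] <- if (leave_to_upper) ub[out] else lb[out]
      at_upper[out] <- leave_to_upper
      is_basic[out] <- FALSE
      basis[leave] <- e
      is_basic[e] <- TRUE
    }
  }
  list(status = "iteration_limit", x = x, basis = basis, at_upper = at_upper)
}
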