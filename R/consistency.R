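# Flux-consistency testing. A reaction is flux-consistent if some
# steady-state flux vector within bounds gives it |v| >= tol. Blocked
# (inconsistent) reactions carry zero flux in every feasible state, so
# removing them leaves the feasible space of the others untouched; the
# consistent set is therefore well-defined in a single pass.

# LP-7 of the FASTCORE family: find a flux vector maximising the number of
# reactions in J that carry flux >= eps in the forward direction.
# Variables: v (fluxes), z_j in [0, eps] with z_j <= v_j for j in J
# (encoded v_j - z_j - s_j = 0, s_j >= 0); maximise sum z.
lp7 <- function(S, lb, ub, J, eps) {
  n <- length(lb)
  m <- nrow(S)
  k <- length(J)
  if (k == 0) return(numeric(n))
  A <- matrix(0, m + k, n + 2 * k)
  A[seq_len(m), seq_len(n)] <- as.matrix(S)
  for (t in seq_len(k)) {
    A[m + t, J[t]] <- 1        # v_j
    A[m + t, n + t] <- -1      # -z_j
    A[m + t, n + k + t] <- -1  # -s_j
  }
  obj <- c(rep(0, n), rep(1, k), rep(0, k))
  lbb <- c(lb, rep(0, k), rep(0, k))
  ubb <- c(ub, rep(eps, k), rep(Inf, k))
  res <- lp_solve(obj, A, rep(0, m + k), lbb, ubb, sense = "max")
  if (res$status != "optimal") {
    return(NULL)
  }
  res$x[seq_len(n)]
}

supp_of <- function(v, eps) which(abs(v) >= 0.99 * eps)

#' Find the flux-consistent subnetwork of a model
#'
#' Returns the maximal set of reactions that can each carry a flux of
#' magnitude at least `tol` in some steady-state solution within the
#' model's bounds. The default method iterates support-maximising LPs over
#' shrinking candidate sets with direction flipping for reversible
#' reactions (the FASTCC scheme), testing many reactions per LP; the
#' `"per-reaction"` method solves two LPs (max and min flux) per reaction
#' and serves as the exhaustive reference on small networks.
#'
#' @param model a `metabolic_model`.
#' @param tol flux threshold (> 0, default 1e-4 mmol/gDW/h).
#' @param method `"fastcc"` (default) or `"per-reaction"`.
#' @return character vector of consistent reaction ids, in model order. An
#'   infeasible model (bounds admit no steady state at all) yields an
#'   empty set with a warning.
#' @export
find_consistent_subnetwork <- function(model, tol = 1e-4,
                                       method = c("fastcc", "per-reaction")) {
  method <- match.arg(method)
  stopifnot(tol > 0)
  ids <- model$reactions$id
  n <- length(ids)
  if (n == 0) return(character())
  S <- model$S
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  # feasibility probe: can any steady state exist at all?
  probe <- lp_solve(rep(0, n), S, rep(0, nrow(S)), lb, ub, sense = "max")
  if (probe$status != "optimal") {
    warning("model admits no steady-state flux distribution; ",
            "returning empty consistent set")
    return(character())
  }

  keep <- if (method == "per-reaction") {
    consistent_per_reaction(S, lb, ub, tol)
  } else {
    consistent_fastcc(S, lb, ub, tol)
  }
  ids[sort(keep)]
}

consistent_per_reaction <- function(S, lb, ub, tol) {
  n <- length(lb)
  m <- nrow(S)
  found <- logical(n)
  for (j in seq_len(n)) {
    if (found[j]) next
    obj <- numeric(n)
    obj[j] <- 1
    hi <- lp_solve(obj, S, rep(0, m), lb, ub, sense = "max")
    if (hi$status == "optimal") {
      if (hi$objective >= 0.99 * tol) {
        found[supp_of(hi$x, tol)] <- TRUE
        next
      }
      if (lb[j] < 0) {
        lo <- lp_solve(obj, S, rep(0, m), lb, ub, sense = "min")
        if (lo$status == "optimal" && lo$objective <= -0.99 * tol) {
          found[supp_of(lo$x, tol)] <- TRUE
        }
      }
    }
  }
  which(found)
}

consistent_fastcc <- function(S, lb, ub, tol) {
  n <- length(lb)
  N <- seq_len(n)
  irrev <- which(lb >= 0)

  # flipping substitutes v_j -> -v_j: negate the column and swap the bounds
  flip <- function(idx) {
    S[, idx] <<- -S[, idx]
    tmp <- lb[idx]
    lb[idx] <<- -ub[idx]
    ub[idx] <<- -tmp
  }

  v <- lp7(S, lb, ub, intersect(N, irrev), tol)
  A <- if (is.null(v)) integer() else supp_of(v, tol)
  inc_i <- setdiff(intersect(N, irrev), A)
  J <- setdiff(setdiff(N, A), inc_i)

  singleton <- FALSE
  flipped <- FALSE
  guard <- 0L
  while (length(J) > 0 && guard < 10L * n + 100L) {
    guard <- guard + 1L
    Ji <- if (singleton) J[1] else J
    v <- lp7(S, lb, ub, Ji, tol)
    if (!is.null(v)) A <- union(A, supp_of(v, tol))
    if (length(intersect(J, A)) > 0) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      ji_rev <- setdiff(Ji, irrev)
      if (flipped || length(ji_rev) == 0) {
        flipped <- FALSE
        if (singleton) {
          J <- setdiff(J, Ji) # blocked
        } else {
          singleton <- TRUE
        }
      } else {
        flip(ji_rev)
        flipped <- TRUE
      }
    }
  }
  sort(A)
}
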