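#' Core reactions implied by gene expression calls
#'
#' The core is the set of reactions whose GPR evaluates to `expressed`
#' under the given calls (AND = min, OR = max over
#' `unexpressed < unknown < expressed`). Reactions with an empty GPR, an
#' `unknown` evaluation, or an `unexpressed` evaluation are non-core: they
#' are not forced into the context model, but they are also not forced out
#' — the extraction keeps any of them needed to sustain core fluxes.
#'
#' @param model a `metabolic_model`.
#' @param calls a `gene_calls` object or named call vector.
#' @return character vector of core reaction ids.
#' @export
reaction_core_from_calls <- function(model, calls) {
  cv <- as_call_vector(calls)
  model_genes_used <- genes_of_reactions(model)
  unmeasured <- setdiff(model_genes_used, names(cv))
  if (length(unmeasured) > 0) {
    message(length(unmeasured), " model gene(s) absent from the call set; ",
            "treated as unknown")
  }
  status <- vapply(model$reactions$gpr, function(g) {
    evaluate_gpr(g, cv)
  }, character(1), USE.NAMES = FALSE)
  model$reactions$id[status == "expressed"]
}

# LP-9 of the FASTCORE family: among flux vectors carrying every reaction
# in K at >= eps (forward), minimise the L1 weight of the penalty set P.
# Variables: v, plus z_p >= |v_p| for p in P; minimise sum z.
lp9 <- function(S, lb, ub, K, P, eps) {
  n <- length(lb)
  m <- nrow(S)
  np <- length(P)
  lbk <- lb
  lbk[K] <- pmax(lbk[K], eps)
  ubk <- ub
  if (any(lbk[K] > ubk[K])) return(NULL) # core cannot reach eps forward
  if (np == 0) {
    res <- lp_solve(rep(0, n), S, rep(0, m), lbk, ubk, sense = "min")
    if (res$status != "optimal") return(NULL)
    return(res$x)
  }
  # rows: S v = 0 ; v_p - z_p + s1 = 0 (z >= v) ; v_p + z_p - s2 = 0 (z >= -v)
  A <- matrix(0, m + 2 * np, n + 3 * np)
  A[seq_len(m), seq_len(n)] <- as.matrix(S)
  for (t in seq_len(np)) {
    A[m + t, P[t]] <- 1
    A[m + t, n + t] <- -1
    A[m + t, n + np + t] <- 1
    A[m + np + t, P[t]] <- 1
    A[m + np + t, n + t] <- 1
    A[m + np + t, n + 2 * np + t] <- -1
  }
  big <- max(abs(lb), abs(ub), 1) * 2
  obj <- c(rep(0, n), rep(1, np), rep(0, 2 * np))
  lbb <- c(lbk, rep(0, 3 * np))
  ubb <- c(ubk, rep(big, np), rep(2 * big, 2 * np))
  res <- lp_solve(obj, A, rep(0, m + 2 * np), lbb, ubb, sense = "min")
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

# one sparse-support search step of FASTCORE: activate (part of) J, then
# minimise the penalty weight outside the core.
find_sparse_mode <- function(S, lb, ub, J, P, singleton, eps) {
  if (length(J) == 0) return(integer())
  Js <- if (singleton) J[1] else J
  v <- lp7(S, lb, ub, Js, eps)
  if (is.null(v)) return(integer())
  K <- Js[v[Js] >= 0.99 * eps]
  if (length(K) == 0) return(integer())
  v <- lp9(S, lb, ub, K, P, eps)
  if (is.null(v)) return(integer())
  supp_of(v, eps)
}

#' Extract a context-specific model around a core reaction set
#'
#' FASTCORE-family extraction: returns the smallest (in practice minimal;
#' exactly minimal on the package's small reference networks) flux-
#' consistent subnetwork that contains every core reaction, adding only
#' the non-core reactions needed to let each core reaction carry a flux of
#' at least `tol`. Core reactions that are not flux-consistent in the full
#' model cannot be supported and are dropped from the core with a warning
#' (or raise an error with `strict = TRUE`). The search alternates a
#' support-maximising LP over the unsatisfied core with an L1-penalised LP
#' over non-core reactions, flipping directions for reversible reactions;
#' ties are resolved deterministically by reaction order, so the result is
#' reproducible.
#'
#' @param model a `metabolic_model` (media already applied, if any).
#' @param core character vector of core reaction ids.
#' @param tol flux threshold (default 1e-4).
#' @param consistent optional precomputed result of
#'   [find_consistent_subnetwork()] for `model`, to avoid recomputation.
#' @param strict error (instead of warn-and-drop) on unsupportable core
#'   reactions.
#' @return a `context_model`: list with `parent` (the input model),
#'   `retained` (reaction ids) and `derivation` (core, dropped core,
#'   tolerance).
#' @export
extract_context_model <- function(model, core, tol = 1e-4,
                                  consistent = NULL, strict = FALSE) {
  stopifnot(tol > 0)
  ids <- model$reactions$id
  missing <- setdiff(core, ids)
  if (length(missing) > 0) {
    stop("core contains unknown reaction id(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(consistent)) {
    consistent <- find_consistent_subnetwork(model, tol = tol)
  }
  dropped <- setdiff(core, consistent)
  if (length(dropped) > 0) {
    msg <- paste0("core reaction(s) not flux-consistent in the full model: ",
                  paste(dropped, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; dropped from core")
    core <- intersect(core, consistent)
  }

  # work on the consistent subnetwork only
  sub_idx <- which(ids %in% consistent)
  sub_ids <- ids[sub_idx]
  S <- model$S[, sub_idx, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  S <- S[used, , drop = FALSE]
  lb <- model$reactions$lower_bound[sub_idx]
  ub <- model$reactions$upper_bound[sub_idx]
  core_idx <- which(sub_ids %in% core)

  retained <- if (length(core_idx) == 0) {
    integer()
  } else {
    repair_extraction(S, lb, ub, fastcore(S, lb, ub, core_idx, tol),
                      core_idx, tol)
  }
  structure(list(parent = model,
                 retained = sub_ids[sort(retained)],
                 derivation = list(core = core, dropped_core = dropped,
                                   tol = tol)),
            class = "context_model")
}

fastcore <- function(S, lb, ub, C, eps) {
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

  flipped <- FALSE
  singleton <- FALSE
  J <- intersect(C, irrev)
  P <- setdiff(N, C)
  supp <- find_sparse_mode(S, lb, ub, J, P, singleton, eps)
  if (!all(J %in% supp)) {
    stop("inconsistent irreversible core reaction(s): ",
         paste(setdiff(J, supp), collapse = ", "))
  }
  A <- supp
  J <- setdiff(C, A)
  guard <- 0L
  while (length(J) > 0) {
    guard <- guard + 1L
    if (guard > 10L * n + 100L) {
      stop("FASTCORE did not converge")
    }
    P <- setdiff(P, A)
    supp <- find_sparse_mode(S, lb, ub, J, P, singleton, eps)
    A <- union(A, supp)
    if (length(intersect(J, A)) > 0) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      ji_rev <- setdiff(if (singleton) J[1] else J, irrev)
      if (flipped || length(ji_rev) == 0) {
        if (singleton) {
          stop("core reaction unsupportable even by the full model: ",
               J[1])
        }
        flipped <- FALSE
        singleton <- TRUE
      } else {
        flip(ji_rev)
        flipped <- TRUE
      }
    }
  }
  sort(A)
}

# which members of A can reach |flux| >= tol inside the subnetwork A?
consistent_in_sub <- function(S, lb, ub, A, tol) {
  Ssub <- S[, A, drop = FALSE]
  used <- Matrix::rowSums(Ssub != 0) > 0
  Ssub <- as.matrix(Ssub[used, , drop = FALSE])
  ok <- logical(length(A))
  for (k in seq_along(A)) {
    if (ok[k]) next
    obj <- numeric(length(A))
    obj[k] <- 1
    hi <- lp_solve(obj, Ssub, rep(0, nrow(Ssub)), lb[A], ub[A], "max")
    if (hi$status == "optimal") {
      if (hi$objective >= 0.99 * tol) {
        ok[abs(hi$x) >= 0.99 * tol] <- TRUE
        next
      }
      if (lb[A[k]] < 0) {
        lo <- lp_solve(obj, Ssub, rep(0, nrow(Ssub)), lb[A], ub[A], "min")
        if (lo$status == "optimal" && lo$objective <= -0.99 * tol) {
          ok[abs(lo$x) >= 0.99 * tol] <- TRUE
        }
      }
    }
  }
  ok
}

# full-support witness flux for reaction r at |v_r| >= tol on the whole
# (consistent) network
witness_support <- function(S, lb, ub, r, tol) {
  n <- length(lb)
  obj <- numeric(n)
  obj[r] <- 1
  Sd <- as.matrix(S)
  hi <- lp_solve(obj, Sd, rep(0, nrow(Sd)), lb, ub, "max")
  if (hi$status == "optimal" && hi$objective >= 0.99 * tol) {
    return(which(abs(hi$x) > 1e-9))
  }
  lo <- lp_solve(obj, Sd, rep(0, nrow(Sd)), lb, ub, "min")
  if (lo$status == "optimal" && lo$objective <= -0.99 * tol) {
    return(which(abs(lo$x) > 1e-9))
  }
  NULL
}

# FASTCORE's union of L1-sparse mode supports can, on unusual topologies,
# omit carriers whose flux in the mode fell below the support threshold,
# leaving the retained set inconsistent as a standalone subnetwork. This
# pass enforces the contract by construction: blocked non-core reactions
# are dropped, blocked core reactions are re-supported by the full support
# of a witness flux vector, and if that tug-of-war does not settle, the
# whole consistent subnetwork (always a valid, if non-minimal, answer) is
# the fallback. On well-behaved networks the first check passes and this
# is a no-op.
repair_extraction <- function(S, lb, ub, A, core_idx, tol,
                              max_iter = 15L) {
  for (iter in seq_len(max_iter)) {
    ok <- consistent_in_sub(S, lb, ub, A, tol)
    if (all(ok)) return(sort(A))
    blocked <- A[!ok]
    bad_core <- intersect(blocked, core_idx)
    if (length(bad_core) == 0) {
      A <- A[ok]
    } else {
      for (r in bad_core) {
        w <- witness_support(S, lb, ub, r, tol)
        if (is.null(w)) {
          stop("core reaction unsupportable even by the full model: ", r)
        }
        A <- union(A, w)
      }
    }
  }
  # fallback: the full consistent subnetwork, pruned of blocked non-core
  A <- seq_len(ncol(S))
  for (iter in seq_len(max_iter)) {
    ok <- consistent_in_sub(S, lb, ub, A, tol)
    if (all(ok)) return(sort(A))
    if (any(!ok[match(core_idx, A)])) {
      stop("core reaction(s) cannot be made flux-consistent: ",
           paste(intersect(A[!ok], core_idx), collapse = ", "))
    }
    A <- A[ok]
  }
  sort(A)
}

#' @export
print.context_model <- function(x, ...) {
  cat("context_model:", length(x$retained), "of",
      nrow(x$parent$reactions), "reactions retained (core:",
      length(x$derivation$core), ")\n")
  invisible(x)
}

#' Materialise a context model as a stand-alone metabolic model
#' @param cm a `context_model`.
#' @param name model name (default: parent name + `"_context"`).
#' @return a `metabolic_model` restricted to the retained reactions.
#' @export
context_as_model <- function(cm, name = paste0(cm$parent$name, "_context")) {
  subset_model(cm$parent, cm$retained, name = name)
}

#' Build one condition-specific model from calls and media
#'
#' The per-cell-line orchestration: constrain the reference model by the
#' media, find its flux-consistent subnetwork, derive the core from the
#' gene calls (intersected with the consistent set), optionally force a
#' protected reaction list (e.g. the ATP demand objective) into the core,
#' and extract the context model.
#'
#' @param model the reference `metabolic_model`.
#' @param calls a `gene_calls` object for this cell line.
#' @param media media composition (see [apply_media()]), or `NULL` to
#'   leave exchange bounds as they are.
#' @param tol flux threshold.
#' @param protected reaction ids always added to the core (dropped with a
#'   warning if not flux-consistent under the media).
#' @return a `context_model`; `derivation` records media, tolerance,
#'   protected list and call provenance.
#' @export
build_condition_model <- function(model, calls, media = NULL, tol = 1e-4,
                                  protected = character()) {
  constrained <- if (!is.null(media)) apply_media(model, media) else model
  consistent <- find_consistent_subnetwork(constrained, tol = tol)
  core <- reaction_core_from_calls(constrained, calls)
  core <- intersect(core, consistent)
  if (length(protected) > 0) {
    lost <- setdiff(protected, consistent)
    if (length(lost) > 0) {
      warning("protected reaction(s) not flux-consistent under media: ",
              paste(lost, collapse = ", "))
    }
    core <- union(core, intersect(protected, consistent))
  }
  cm <- extract_context_model(constrained, core, tol = tol,
                              consistent = consistent)
  cm$derivation$media <- media
  cm$derivation$protected <- protected
  cm$derivation$calls_provenance <-
    if (inherits(calls, "gene_calls")) calls$provenance else list()
  cm
}
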