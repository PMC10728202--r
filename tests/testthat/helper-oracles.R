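# Independent oracles: scipy/HiGHS linear programming through `python`,
# brute-force subnetwork enumeration, and a from-scratch interval overlap
# computation for the similarity index.

# solve a batch of steady-state LPs with scipy (HiGHS). problems: list of
# lists with S, lb, ub, obj, sense, optional ineq = list(coef, rhs).
scipy_solve_batch <- function(problems) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2("python",
                    c(shQuote(test_path("oracle-lp.py")), shQuote(fin),
                      shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python LP oracle failed")
  vals <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
         numeric(1))
}

# FVA by brute force: one scipy LP per reaction and direction, with the
# objective-optimality row added explicitly.
scipy_fva <- function(model, objective = NULL, gamma = 1,
                      reactions = reaction_ids(model)) {
  S <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(lb)
  base <- list(S = S, lb = lb, ub = ub)
  problems <- list()
  ineq <- NULL
  if (!is.null(objective)) {
    coef <- numeric(n)
    coef[match(objective, model$reactions$id)] <- 1
    opt <- scipy_solve_batch(list(c(base, list(obj = coef, sense = "max"))))
    ineq <- list(coef = coef, rhs = gamma * opt)
  }
  idx <- match(reactions, model$reactions$id)
  for (j in idx) {
    obj <- numeric(n)
    obj[j] <- 1
    for (sense in c("min", "max")) {
      problems[[length(problems) + 1]] <-
        c(base, list(obj = obj, sense = sense, ineq = ineq))
    }
  }
  vals <- scipy_solve_batch(problems)
  data.frame(reaction = reactions,
             vmin = vals[seq(1, length(vals), 2)],
             vmax = vals[seq(2, length(vals), 2)],
             stringsAsFactors = FALSE)
}

# is `keep` a flux-consistent subnetwork (every member can reach |v| >= tol
# inside it)?
subnetwork_is_consistent <- function(model, keep, tol = 1e-4) {
  if (length(keep) == 0) return(TRUE)
  sub <- subset_model(model, keep)
  cons <- suppressWarnings(
    find_consistent_subnetwork(sub, tol = tol, method = "per-reaction"))
  setequal(cons, keep)
}

# exhaustive minimum: smallest consistent subnetwork containing the core,
# found by enumerating supersets of the core in order of cardinality
brute_min_subnetwork <- function(model, core, tol = 1e-4) {
  ids <- reaction_ids(model)
  others <- setdiff(ids, core)
  for (k in 0:length(others)) {
    combos <- if (k == 0) list(character()) else
      utils::combn(others, k, simplify = FALSE)
    for (extra in combos) {
      cand <- c(core, extra)
      if (subnetwork_is_consistent(model, cand, tol)) {
        return(cand)
      }
    }
  }
  NULL
}

# similarity index recomputed from first principles: intersect and span of
# two closed intervals
si_oracle <- function(a, b, eps = 0) {
  lo <- sort(c(a, b))
  span <- lo[4] - lo[1]
  inter_lo <- max(a[1], b[1])
  inter_hi <- min(a[2], b[2])
  overlap <- inter_hi - inter_lo # negative when disjoint
  if (span + eps <= 0) return(1)
  max(0, (overlap + eps) / (span + eps))
}
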