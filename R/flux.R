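#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction subject to steady
#' state (`S v = 0`) and the model's bounds. The usual objective in this
#' package is an ATP demand (hydrolysis sink) reaction, mimicking a state
#' of high energetic load.
#'
#' @param model a `metabolic_model`.
#' @param objective a reaction id.
#' @param sense `"max"` (default) or `"min"`.
#' @return list with `objective_value`, `fluxes` (a named optimal flux
#'   vector) and `status`.
#' @export
fba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  j <- match(objective, model$reactions$id)
  if (is.na(j)) stop("objective reaction not in model: ", objective)
  n <- nrow(model$reactions)
  obj <- numeric(n)
  obj[j] <- 1
  res <- lp_solve(obj, model$S, rep(0, length(model$metabolites)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  sense = sense)
  if (res$status != "optimal") {
    stop("FBA failed (", res$status, ") for objective ", objective)
  }
  list(objective_value = res$objective,
       fluxes = stats::setNames(res$x, model$reactions$id),
       status = res$status)
}

# steady-state LP with an optional objective-optimality row:
#   obj_coef' v >= gamma * opt   (written obj_coef' v - s = gamma*opt, s >= 0)
fva_lp <- function(model, target_j, sense, extra = NULL) {
  n <- nrow(model$reactions)
  m <- length(model$metabolites)
  obj <- numeric(n)
  obj[target_j] <- 1
  A <- as.matrix(model$S)
  rhs <- rep(0, m)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(extra)) {
    A <- rbind(cbind(A, 0), c(extra$coef, -1))
    rhs <- c(rhs, extra$rhs)
    obj <- c(obj, 0)
    lb <- c(lb, 0)
    ub <- c(ub, Inf)
  }
  lp_solve(obj, A, rhs, lb, ub, sense = sense)
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimum and maximum steady-state flux
#' compatible with the bounds and, when an objective is given, with
#' retaining at least a fraction `gamma` of the FBA optimum of that
#' objective. `gamma = 1` fixes the objective at its optimum; lowering
#' `gamma` relaxes it, so ranges at smaller `gamma` always contain ranges
#' at larger `gamma`.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimise first, or `NULL` for
#'   unconstrained variability.
#' @param gamma optimality fraction in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @return a `flux_range_set`: list with `model_id`, `objective`, `gamma`,
#'   `optimum` and `ranges` (data frame `reaction`, `vmin`, `vmax`).
#' @export
fva <- function(model, objective = NULL, gamma = 1, reactions = NULL) {
  stopifnot(gamma > 0, gamma <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  missing <- setdiff(reactions, model$reactions$id)
  if (length(missing) > 0) {
    stop("unknown reaction(s) in FVA request: ",
         paste(missing, collapse = ", "))
  }
  extra <- NULL
  optimum <- NA_real_
  if (!is.null(objective)) {
    sol <- fba(model, objective)
    optimum <- sol$objective_value
    coef <- numeric(nrow(model$reactions))
    coef[match(objective, model$reactions$id)] <- 1
    extra <- list(coef = coef, rhs = gamma * optimum)
  }
  idx <- match(reactions, model$reactions$id)
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    lo <- fva_lp(model, idx[k], "min", extra)
    hi <- fva_lp(model, idx[k], "max", extra)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA failed for reaction ", reactions[k])
    }
    vmin[k] <- lo$objective
    vmax[k] <- hi$objective
  }
  # clamp solver jitter: ranges are intervals by construction
  swap <- vmin > vmax
  if (any(swap)) {
    mid <- (vmin[swap] + vmax[swap]) / 2
    vmin[swap] <- mid
    vmax[swap] <- mid
  }
  structure(list(model_id = model$name, objective = objective,
                 gamma = gamma, optimum = optimum,
                 ranges = data.frame(reaction = reactions,
                                     vmin = vmin, vmax = vmax,
                                     stringsAsFactors = FALSE)),
            class = "flux_range_set")
}

#' @export
print.flux_range_set <- function(x, ...) {
  cat("flux_range_set:", x$model_id, "-", nrow(x$ranges), "reactions")
  if (!is.null(x$objective)) {
    cat(" | objective", x$objective, "at gamma =", x$gamma,
        "(optimum", format(x$optimum, digits = 6), ")")
  }
  cat("\n")
  invisible(x)
}

#' Write / read a flux range set as TSV
#' @param frs a `flux_range_set`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_flux_ranges <- function(frs, path) {
  utils::write.table(frs$ranges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# interval similarity: max(0, (overlap + eps) / (union + eps)), the
# flux-range similarity index. Identical point ranges (union width 0 with
# eps = 0) are defined as SI = 1 by continuity.
si_interval <- function(v1min, v1max, v2min, v2max, eps = 0) {
  num <- pmin(v1max, v2max) - pmax(v1min, v2min) + eps
  den <- pmax(v1max, v2max) - pmin(v1min, v2min) + eps
  out <- ifelse(den <= 0, 1, pmax(0, num / den))
  as.numeric(out)
}

#' Flux-range similarity index (SI)
#'
#' Compares the FVA range of one reaction between two models:
#' `SI = max(0, (min(v1max, v2max) - max(v1min, v2min) + eps) /
#' (max(v1max, v2max) - min(v1min, v2min) + eps))`, i.e. the signed
#' overlap of the two ranges over the width of their union. SI is 1 when
#' the ranges are identical (highest similarity in flux variability) and 0
#' when they do not overlap at all (complete mismatch). `eps` defaults to
#' 0, the convention when SI is computed only for reactions shared between
#' the models; identical point ranges then score 1 by continuity.
#'
#' @param r1,r2 flux ranges: either numeric `c(vmin, vmax)`, or one-row
#'   data frames / lists with fields `reaction`, `vmin`, `vmax` (in which
#'   case the reaction ids must agree).
#' @param eps non-negative continuity constant.
#' @return SI in \[0, 1\].
#' @examples
#' similarity_index(c(0, 5), c(0, 5)) # 1: identical variability
#' similarity_index(c(0, 1), c(2, 3)) # 0: complete mismatch
#' similarity_index(c(0, 2), c(1, 3)) # overlap 1 / union 3
#' @export
similarity_index <- function(r1, r2, eps = 0) {
  stopifnot(eps >= 0)
  as_range <- function(r) {
    if (is.numeric(r) && length(r) == 2) {
      return(list(reaction = NA_character_, vmin = r[1], vmax = r[2]))
    }
    stopifnot(!is.null(r$vmin), !is.null(r$vmax))
    list(reaction = if (is.null(r$reaction)) NA_character_ else
           as.character(r$reaction),
         vmin = as.numeric(r$vmin), vmax = as.numeric(r$vmax))
  }
  a <- as_range(r1)
  b <- as_range(r2)
  if (!is.na(a$reaction) && !is.na(b$reaction) &&
      !identical(a$reaction, b$reaction)) {
    stop("similarity_index: ranges refer to different reactions: ",
         a$reaction, " vs ", b$reaction)
  }
  if (a$vmin > a$vmax || b$vmin > b$vmax) {
    stop("similarity_index: vmin must not exceed vmax")
  }
  si_interval(a$vmin, a$vmax, b$vmin, b$vmax, eps)
}

#' Per-subsystem similarity between two flux range sets
#'
#' SI is computed per reaction for the reactions present in both range
#' sets (shared reactions), then summarised per subsystem. With
#' `aggregation = "mean"` (default) the subsystem value is the unweighted
#' mean of its shared reactions' SI; with `"pooled"` the subsystem's
#' ranges are first pooled into one interval per model (min of vmin, max
#' of vmax) and SI is computed once on the pooled intervals. Subsystems
#' with no shared reaction get `NA`, not 0: no comparison is possible.
#'
#' @param fva_a,fva_b `flux_range_set` objects computed with the same
#'   objective role and `gamma`.
#' @param subsystem_map named character vector (reaction id -> subsystem
#'   label), e.g. [reaction_subsystems()] of the reference model.
#' @param eps continuity constant for [similarity_index()].
#' @param aggregation `"mean"` or `"pooled"`.
#' @param subsystems optional subset of subsystem labels to report.
#' @return data frame `subsystem`, `si`, `n_shared`.
#' @export
subsystem_similarity <- function(fva_a, fva_b, subsystem_map, eps = 0,
                                 aggregation = c("mean", "pooled"),
                                 subsystems = NULL) {
  aggregation <- match.arg(aggregation)
  if (!is.null(fva_a$gamma) && !is.null(fva_b$gamma) &&
      fva_a$gamma != fva_b$gamma) {
    stop("flux range sets were computed at different gamma")
  }
  shared <- intersect(fva_a$ranges$reaction, fva_b$ranges$reaction)
  ss <- unname(subsystem_map[shared])
  ss[is.na(ss) | ss == ""] <- "(unassigned)"
  if (is.null(subsystems)) {
    subsystems <- sort(unique(
      ifelse(subsystem_map == "", "(unassigned)", subsystem_map)))
  }
  a <- fva_a$ranges[match(shared, fva_a$ranges$reaction), ]
  b <- fva_b$ranges[match(shared, fva_b$ranges$reaction), ]
  si <- vapply(subsystems, function(lab) {
    sel <- ss == lab
    if (!any(sel)) return(NA_real_)
    if (aggregation == "mean") {
      mean(si_interval(a$vmin[sel], a$vmax[sel],
                       b$vmin[sel], b$vmax[sel], eps))
    } else {
      si_interval(min(a$vmin[sel]), max(a$vmax[sel]),
                  min(b$vmin[sel]), max(b$vmax[sel]), eps)
    }
  }, numeric(1))
  n_shared <- vapply(subsystems, function(lab) sum(ss == lab), integer(1))
  data.frame(subsystem = subsystems, si = unname(si),
             n_shared = unname(n_shared), stringsAsFactors = FALSE)
}

#' Pairwise similarity table across condition groups
#'
#' Computes the per-subsystem SI for every cross-group model pair and
#' every within-group pair, plus the cross-group aggregate: the arithmetic
#' mean over all cross pairs (with two models per group these are the four
#' cross comparisons and one within-group comparison per condition). A
#' group with fewer than two models gets no within-group column (noted in
#' the `notes` attribute).
#'
#' @param range_sets named list of `flux_range_set` objects (one per
#'   model).
#' @param groups named character vector: model id -> condition label.
#' @param subsystem_map reaction id -> subsystem label.
#' @param eps,aggregation,subsystems passed to [subsystem_similarity()].
#' @return a `similarity_table`: data frame with one row per subsystem,
#'   one column per pair (`<m1>.vs.<m2>`), `mean_cross`, and one
#'   `within_<group>` column per group with >= 2 models. Attributes:
#'   `cross_pairs`, `within_pairs`, `notes`.
#' @export
group_comparison <- function(range_sets, groups, subsystem_map, eps = 0,
                             aggregation = c("mean", "pooled"),
                             subsystems = NULL) {
  aggregation <- match.arg(aggregation)
  ids <- names(range_sets)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  groups <- groups[ids]
  labs <- unique(groups)
  if (length(labs) != 2) stop("group_comparison expects exactly two groups")
  if (!any(table(groups) >= 1)) stop("each group needs >= 1 model")

  pair_si <- function(m1, m2) {
    subsystem_similarity(range_sets[[m1]], range_sets[[m2]], subsystem_map,
                         eps = eps, aggregation = aggregation,
                         subsystems = subsystems)
  }
  a_ids <- ids[groups == labs[1]]
  b_ids <- ids[groups == labs[2]]
  cross <- expand.grid(a = a_ids, b = b_ids, stringsAsFactors = FALSE)
  within <- lapply(labs, function(g) {
    gm <- ids[groups == g]
    if (length(gm) < 2) return(NULL)
    cb <- utils::combn(gm, 2)
    data.frame(a = cb[1, ], b = cb[2, ], stringsAsFactors = FALSE)
  })
  names(within) <- labs

  base <- pair_si(cross$a[1], cross$b[1])
  out <- data.frame(subsystem = base$subsystem, stringsAsFactors = FALSE)
  cross_cols <- character(nrow(cross))
  for (k in seq_len(nrow(cross))) {
    col <- paste0(cross$a[k], ".vs.", cross$b[k])
    cross_cols[k] <- col
    out[[col]] <- pair_si(cross$a[k], cross$b[k])$si
  }
  out$mean_cross <- rowMeans(out[, cross_cols, drop = FALSE])
  notes <- character()
  within_pairs <- list()
  for (g in labs) {
    wp <- within[[g]]
    if (is.null(wp)) {
      notes <- c(notes, paste0("group '", g,
                               "' has < 2 models; within-group column omitted"))
      next
    }
    cols <- numeric(nrow(out))
    for (k in seq_len(nrow(wp))) {
      cols <- cols + pair_si(wp$a[k], wp$b[k])$si / nrow(wp)
    }
    out[[paste0("within_", g)]] <- cols
    within_pairs[[g]] <- paste0(wp$a, ".vs.", wp$b)
  }
  for (n in notes) message(n)
  structure(out, class = c("similarity_table", "data.frame"),
            cross_pairs = cross_cols, within_pairs = within_pairs,
            notes = notes)
}
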