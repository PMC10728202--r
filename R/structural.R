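#' Element set of a context model
#'
#' The genes, reactions or metabolites of the retained subnetwork:
#' reactions are the retained ids, genes those appearing in retained
#' reactions' GPRs, metabolites those with a nonzero coefficient in a
#' retained reaction.
#'
#' @param cm a `context_model`.
#' @param kind `"reactions"`, `"genes"` or `"metabolites"`.
#' @return character vector of element ids.
#' @export
element_set <- function(cm, kind = c("reactions", "genes", "metabolites")) {
  kind <- match.arg(kind)
  stopifnot(inherits(cm, "context_model"))
  switch(kind,
         reactions = cm$retained,
         genes = genes_of_reactions(cm$parent, cm$retained),
         metabolites = metabolites_of_reactions(cm$parent, cm$retained))
}

same_parent <- function(models) {
  ref <- reaction_ids(models[[1]]$parent)
  all(vapply(models, function(m) {
    identical(reaction_ids(m$parent), ref)
  }, logical(1)))
}

#' Elements shared by all models of one condition
#'
#' Intersection across a condition's context models of their element sets
#' (the `intersect`-across-models step of the structural comparison).
#'
#' @param models list of `context_model`s of one condition (>= 1), all
#'   derived from the same reference model.
#' @param kind element kind, see [element_set()].
#' @return character vector.
#' @export
condition_shared <- function(models, kind = c("reactions", "genes",
                                              "metabolites")) {
  kind <- match.arg(kind)
  stopifnot(length(models) >= 1)
  if (!same_parent(models)) {
    stop("context models derive from different reference models")
  }
  Reduce(intersect, lapply(models, element_set, kind = kind))
}

#' Elements unique to one condition
#'
#' Starting from a condition's shared element set, removes the elements
#' found in the other condition's models. Two comparison modes exist
#' because the source analyses phrase them differently:
#'
#' * `"vs-union"` (default): subtract the union over the other condition's
#'   models — an element is unique only if absent from *every* model of
#'   the other condition ("present only in the control models but not in
#'   patient-derived models").
#' * `"vs-shared"`: subtract only the other condition's shared set (the
#'   literal `setdiff` of the two shared sets).
#'
#' `vs-union` unique sets are always a subset of `vs-shared` ones; the two
#' differ exactly for elements present in some but not all models of the
#' other condition.
#'
#' @param shared_a character vector: the focal condition's shared set.
#' @param models_b list of the other condition's `context_model`s.
#' @param kind element kind.
#' @param mode `"vs-union"` or `"vs-shared"`.
#' @return character vector of unique elements.
#' @export
condition_unique <- function(shared_a, models_b,
                             kind = c("reactions", "genes", "metabolites"),
                             mode = c("vs-union", "vs-shared")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  sets_b <- lapply(models_b, element_set, kind = kind)
  comparand <- if (mode == "vs-union") {
    Reduce(union, sets_b, character())
  } else {
    if (length(sets_b) == 0) character() else Reduce(intersect, sets_b)
  }
  setdiff(shared_a, comparand)
}

#' Full structural comparison of two condition groups
#'
#' For each element kind, the shared set per condition and the unique set
#' per condition (see [condition_unique()] for the mode semantics).
#'
#' @param models_a,models_b lists of `context_model`s for the two
#'   conditions.
#' @param mode comparison mode, see [condition_unique()].
#' @return a `structural_diff`: per kind, a list with `shared_a`,
#'   `shared_b`, `unique_a`, `unique_b`; plus `mode`.
#' @export
structural_diff <- function(models_a, models_b,
                            mode = c("vs-union", "vs-shared")) {
  mode <- match.arg(mode)
  if (!same_parent(c(models_a, models_b))) {
    stop("context models derive from different reference models")
  }
  kinds <- c("genes", "reactions", "metabolites")
  out <- lapply(kinds, function(kind) {
    sa <- condition_shared(models_a, kind)
    sb <- condition_shared(models_b, kind)
    list(shared_a = sa, shared_b = sb,
         unique_a = condition_unique(sa, models_b, kind, mode),
         unique_b = condition_unique(sb, models_a, kind, mode))
  })
  names(out) <- kinds
  structure(c(out, list(mode = mode)), class = "structural_diff")
}

#' Venn-style counts of a structural comparison
#' @param diff a `structural_diff`.
#' @return data frame: per kind, counts of the two shared sets, the two
#'   unique sets, and of the common intersection.
#' @export
venn_counts <- function(diff) {
  kinds <- c("genes", "reactions", "metabolites")
  do.call(rbind, lapply(kinds, function(kind) {
    d <- diff[[kind]]
    data.frame(kind = kind,
               shared_a = length(d$shared_a),
               shared_b = length(d$shared_b),
               common = length(intersect(d$shared_a, d$shared_b)),
               unique_a = length(d$unique_a),
               unique_b = length(d$unique_b),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.structural_diff <- function(x, ...) {
  cat("structural_diff (mode:", x$mode, ")\n")
  print(venn_counts(x))
  invisible(x)
}

#' Attribute condition-unique reactions to subsystems
#'
#' Pools the unique reactions of the two conditions per subsystem and
#' expresses the pooled count as a percentage of the subsystem's total
#' size in the reference model. Reactions without a subsystem label are
#' pooled under `"(unassigned)"`. Rows are sorted by pooled count
#' descending, ties by label.
#'
#' @param unique_a,unique_b character vectors of condition-unique reaction
#'   ids.
#' @param reference the reference `metabolic_model` (for subsystem labels
#'   and sizes).
#' @return data frame `subsystem`, `n_unique_a`, `n_unique_b`, `pooled`,
#'   `size`, `percent_different`, with the full reference subsystem size
#'   table in the `reference_sizes` attribute.
#' @export
subsystem_attribution <- function(unique_a, unique_b, reference) {
  subs <- reaction_subsystems(reference)
  missing <- setdiff(c(unique_a, unique_b), names(subs))
  if (length(missing) > 0) {
    stop("unique reaction(s) absent from reference: ",
         paste(missing, collapse = ", "))
  }
  lab <- function(ids) {
    x <- unname(subs[ids])
    ifelse(x == "", "(unassigned)", x)
  }
  all_labs <- ifelse(subs == "", "(unassigned)", subs)
  sizes <- table(all_labs)
  labels <- sort(unique(c(lab(unique_a), lab(unique_b))))
  na <- vapply(labels, function(l) sum(lab(unique_a) == l), integer(1))
  nb <- vapply(labels, function(l) sum(lab(unique_b) == l), integer(1))
  out <- data.frame(subsystem = labels,
                    n_unique_a = unname(na),
                    n_unique_b = unname(nb),
                    pooled = unname(na + nb),
                    size = as.integer(sizes[labels]),
                    stringsAsFactors = FALSE)
  out$percent_different <- 100 * out$pooled / out$size
  out <- out[order(-out$pooled, out$subsystem), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_sizes") <-
    stats::setNames(as.integer(sizes), names(sizes))
  out
}

#' Select subsystems for flux variability analysis
#'
#' A subsystem qualifies if its total size in the reference model is
#' strictly larger than `min_size` reactions *and* strictly more than
#' `min_percent` percent of its reactions differ between the conditions.
#' Central-energy subsystems can be forced in regardless (they are checked
#' against the reference and skipped with a warning when absent), and
#' subsystems absent from all models of either condition are excluded —
#' no flux comparison is possible for them. The `"(unassigned)"` bucket
#' never qualifies: it is not a subsystem.
#'
#' @param table result of [subsystem_attribution()].
#' @param min_size size threshold (strict `>`), default 20.
#' @param min_percent percent-different threshold (strict `>`), default 20.
#' @param forced labels to include regardless of thresholds.
#' @param absent_in labels absent from at least one condition's models:
#'   a character vector, or a list of character vectors (one per
#'   condition, the union is excluded).
#' @return character vector of selected subsystem labels, sorted.
#' @export
select_subsystems <- function(table, min_size = 20, min_percent = 20,
                              forced = character(), absent_in = NULL) {
  stopifnot(min_size > 0, min_percent > 0)
  sel <- table$subsystem[table$size > min_size &
                           table$percent_different > min_percent]
  reference <- names(attr(table, "reference_sizes"))
  if (is.null(reference)) reference <- table$subsystem
  if (length(forced) > 0) {
    unknown <- setdiff(forced, reference)
    if (length(unknown) > 0) {
      warning("forced subsystem(s) absent from reference, skipped: ",
              paste(unknown, collapse = ", "))
    }
    sel <- union(sel, intersect(forced, reference))
  }
  if (!is.null(absent_in)) {
    sel <- setdiff(sel, unique(unlist(absent_in)))
  }
  sort(setdiff(sel, "(unassigned)"))
}
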