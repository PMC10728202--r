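DEFAULT_BOUND <- 1000

#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric matrix plus
#' per-reaction bounds, gene-protein-reaction (GPR) rules and subsystem
#' labels. Reversibility is encoded purely in the bounds (a reaction with
#' a negative lower bound can run backwards). Bounds absent or infinite in
#' the input are canonicalised to +/- 1000 mmol/gDW/h, the COBRA
#' convention. A reaction is an exchange if it has exactly one nonzero
#' stoichiometric entry; exchanges model uptake (negative flux) and
#' secretion (positive flux) across the system boundary.
#'
#' @param reactions a data frame with columns `id`, `lower_bound`,
#'   `upper_bound`, and optionally `gpr` (rule strings, `""` for none) and
#'   `subsystem` (`""` for none).
#' @param metabolites character vector of metabolite identifiers; a
#'   compartment tag in the style `"glc[c]"` is preserved verbatim as part
#'   of the identity.
#' @param S stoichiometric coefficients, metabolites x reactions: a matrix
#'   or `Matrix` sparse matrix; dimnames optional (positions are matched
#'   to `metabolites` and `reactions$id`).
#' @param genes optional character vector of gene identifiers; defaults to
#'   the union of all GPR genes. Must be a superset of the GPR genes.
#' @param name free-text model name.
#' @return an object of class `metabolic_model` with elements `name`,
#'   `reactions` (data frame, including a derived `is_exchange` column),
#'   `metabolites`, `S` (sparse `dgCMatrix`) and `genes`.
#' @export
metabolic_model <- function(reactions, metabolites, S, genes = NULL,
                            name = "model") {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "lower_bound", "upper_bound") %in% names(reactions)))
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  reactions$id <- as.character(reactions$id)

  # canonicalise bounds: missing or infinite -> +/- DEFAULT_BOUND
  lbv <- as.numeric(reactions$lower_bound)
  ubv <- as.numeric(reactions$upper_bound)
  lbv[is.na(lbv) | lbv == -Inf] <- -DEFAULT_BOUND
  ubv[is.na(ubv) | ubv == Inf] <- DEFAULT_BOUND
  reactions$lower_bound <- pmax(lbv, -DEFAULT_BOUND)
  reactions$upper_bound <- pmin(ubv, DEFAULT_BOUND)

  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites, reactions$id)
  reactions$is_exchange <- Matrix::colSums(S != 0) == 1L

  gpr_gene_set <- unique(unlist(lapply(reactions$gpr, gpr_genes)))
  if (is.null(genes)) genes <- gpr_gene_set
  genes <- as.character(genes)

  m <- structure(list(name = name, reactions = reactions,
                      metabolites = as.character(metabolites),
                      S = S, genes = genes),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks identifier uniqueness, stoichiometry/identifier agreement, bound
#' ordering and finiteness, and that every GPR leaf gene is declared.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction id: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
  }
  if (anyDuplicated(model$metabolites)) {
    stop("duplicate metabolite id: ",
         paste(unique(model$metabolites[duplicated(model$metabolites)]),
               collapse = ", "))
  }
  if (!identical(dim(model$S),
                 c(length(model$metabolites), nrow(rx)))) {
    stop("stoichiometry dimensions do not match metabolite/reaction lists")
  }
  if (any(rx$lower_bound > rx$upper_bound)) {
    bad <- rx$id[rx$lower_bound > rx$upper_bound]
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(!is.finite(rx$lower_bound)) || any(!is.finite(rx$upper_bound))) {
    stop("non-finite bounds after canonicalization")
  }
  gg <- unique(unlist(lapply(rx$gpr, gpr_genes)))
  missing <- setdiff(gg, model$genes)
  if (length(missing) > 0) {
    stop("GPR references undeclared gene(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", x$name, "\n")
  cat("  ", nrow(x$reactions), "reactions (",
      sum(x$reactions$is_exchange), "exchanges ),",
      length(x$metabolites), "metabolites,",
      length(x$genes), "genes\n")
  ss <- setdiff(unique(x$reactions$subsystem), "")
  cat("  ", length(ss), "subsystems\n")
  invisible(x)
}

#' Reaction identifiers of a model
#' @param model a `metabolic_model`.
#' @return character vector.
#' @export
reaction_ids <- function(model) model$reactions$id

#' Exchange reaction identifiers of a model
#' @param model a `metabolic_model`.
#' @return character vector of reactions with exactly one nonzero
#'   stoichiometric entry.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$is_exchange]
}

#' Subsystem label per reaction
#' @param model a `metabolic_model`.
#' @return named character vector (reaction id -> subsystem; `""` if
#'   unassigned).
#' @export
reaction_subsystems <- function(model) {
  stats::setNames(model$reactions$subsystem, model$reactions$id)
}

# single metabolite of an exchange reaction
exchange_metabolite <- function(model, rxn_id) {
  j <- match(rxn_id, model$reactions$id)
  nz <- which(model$S[, j] != 0)
  if (length(nz) != 1L) {
    stop(rxn_id, " is not an exchange reaction")
  }
  model$metabolites[nz]
}

#' Restrict a model to a subset of reactions
#'
#' Keeps the given reactions, drops metabolites no longer touched by any
#' retained reaction, and restricts the gene set to genes appearing in
#' retained GPRs.
#'
#' @param model a `metabolic_model`.
#' @param keep character vector of reaction ids to retain.
#' @param name name for the submodel.
#' @return a `metabolic_model`.
#' @export
subset_model <- function(model, keep, name = paste0(model$name, "_sub")) {
  keep <- as.character(keep)
  missing <- setdiff(keep, model$reactions$id)
  if (length(missing) > 0) {
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  }
  jj <- model$reactions$id %in% keep
  S <- model$S[, jj, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  rx <- model$reactions[jj, setdiff(names(model$reactions), "is_exchange"),
                        drop = FALSE]
  rownames(rx) <- NULL
  metabolic_model(rx, model$metabolites[used],
                  S[used, , drop = FALSE],
                  genes = unique(unlist(lapply(rx$gpr, gpr_genes))),
                  name = name)
}

#' Genes used by a set of reactions
#' @param model a `metabolic_model`.
#' @param rxn_ids reaction ids (default all).
#' @return character vector of genes appearing in those reactions' GPRs.
#' @export
genes_of_reactions <- function(model, rxn_ids = reaction_ids(model)) {
  jj <- model$reactions$id %in% rxn_ids
  unique(unlist(lapply(model$reactions$gpr[jj], gpr_genes)))
}

#' Metabolites touched by a set of reactions
#' @param model a `metabolic_model`.
#' @param rxn_ids reaction ids (default all).
#' @return character vector of metabolites with a nonzero coefficient in
#'   at least one of the reactions.
#' @export
metabolites_of_reactions <- function(model, rxn_ids = reaction_ids(model)) {
  jj <- model$reactions$id %in% rxn_ids
  model$metabolites[Matrix::rowSums(model$S[, jj, drop = FALSE] != 0) > 0]
}
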