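#' Read a metabolic model from file
#'
#' Supports SBML Level 3 with the FBC version 2 extension (bounds as flux
#' parameters, GPRs as gene product associations, subsystems from the
#' groups extension or from a `SUBSYSTEM:` line in reaction notes) and a
#' JSON dialect compatible with the cobrapy JSON schema (see
#' [write_metabolic_model()] for the fields emitted).
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"sbml"` or `"json"`.
#' @return a `metabolic_model`.
#' @export
read_metabolic_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "json",
                     stop("cannot infer model format from extension: ", path))
  }
  switch(format,
         sbml = read_model_sbml(path),
         json = read_model_json(path))
}

#' Write a metabolic model to file
#'
#' The emitted file re-reads to a structurally identical model (same ids,
#' bounds, GPR strings, subsystem labels). In JSON, the schema mirrors
#' cobrapy: top-level `name`, `metabolites` (id, compartment), `genes`,
#' and `reactions` (id, lower_bound, upper_bound, gene_reaction_rule,
#' subsystem, metabolites as an id -> coefficient map). In SBML, bounds
#' are FBC flux parameters, GPRs FBC gene product associations, and
#' subsystems SBML groups; empty subsystems and GPRs are omitted.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_metabolic_model <- function(model, path,
                                  format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xml = , sbml = "sbml",
                     json = "json",
                     stop("cannot infer model format from extension: ", path))
  }
  switch(format,
         sbml = write_model_sbml(model, path),
         json = write_model_json(model, path))
  invisible(path)
}

met_compartment <- function(id) {
  m <- regmatches(id, regexec("\\[([^][]+)\\]$", id))[[1]]
  if (length(m) == 2) m[2] else "c"
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON model '", path, "': ",
                         conditionMessage(e))
                  })
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("malformed JSON model: missing element '", field, "'")
    }
  }
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id),
                    character(1))
  rx <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = as.character(r$id),
               lower_bound = if (is.null(r$lower_bound)) NA_real_ else
                 as.numeric(r$lower_bound),
               upper_bound = if (is.null(r$upper_bound)) NA_real_ else
                 as.numeric(r$upper_bound),
               gpr = if (is.null(r$gene_reaction_rule)) "" else
                 as.character(r$gene_reaction_rule),
               subsystem = if (is.null(r$subsystem)) "" else
                 as.character(r$subsystem),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(rx$id)) {
    stop("malformed JSON model: duplicate reaction id '",
         rx$id[duplicated(rx$id)][1], "'")
  }
  triplets <- do.call(rbind, lapply(seq_along(doc$reactions), function(j) {
    mets <- doc$reactions[[j]]$metabolites
    if (length(mets) == 0) return(NULL)
    i <- match(names(mets), met_ids)
    if (anyNA(i)) {
      stop("malformed JSON model: reaction '", doc$reactions[[j]]$id,
           "' references undeclared metabolite '",
           names(mets)[is.na(i)][1], "'")
    }
    cbind(i = i, j = j, x = as.numeric(unlist(mets)))
  }))
  S <- Matrix::sparseMatrix(i = triplets[, "i"], j = triplets[, "j"],
                            x = triplets[, "x"],
                            dims = c(length(met_ids), nrow(rx)))
  genes <- if (is.null(doc$genes)) NULL else
    vapply(doc$genes, function(g) {
      as.character(if (is.list(g)) g$id else g)
    }, character(1))
  metabolic_model(rx, met_ids, S, genes = genes,
                  name = if (is.null(doc$name)) "model" else doc$name)
}

write_model_json <- function(model, path) {
  rx <- model$reactions
  doc <- list(
    name = model$name,
    metabolites = lapply(model$metabolites, function(mid) {
      list(id = mid, compartment = met_compartment(mid))
    }),
    genes = lapply(model$genes, function(g) list(id = g)),
    reactions = lapply(seq_len(nrow(rx)), function(j) {
      nz <- which(model$S[, j] != 0)
      list(id = rx$id[j],
           lower_bound = rx$lower_bound[j],
           upper_bound = rx$upper_bound[j],
           gene_reaction_rule = rx$gpr[j],
           subsystem = rx$subsystem[j],
           metabolites = as.list(stats::setNames(
             as.numeric(model$S[nz, j]), model$metabolites[nz])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
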