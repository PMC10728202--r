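#' Read a media composition table
#'
#' Two-column tab-separated file: `metabolite_id` (an exchangeable
#' metabolite, compartment tag included) and `uptake` (maximum uptake rate
#' in mmol/gDW/h, >= 0).
#'
#' @param path file path.
#' @return named numeric vector of uptake rates.
#' @export
read_media <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "uptake") %in% names(df))) {
    stop("media file must have columns 'metabolite_id' and 'uptake': ", path)
  }
  as_media(stats::setNames(as.numeric(df$uptake), df$metabolite_id))
}

as_media <- function(media) {
  if (is.data.frame(media)) {
    media <- stats::setNames(as.numeric(media$uptake), media$metabolite_id)
  }
  if (length(media) > 0) {
    stopifnot(!is.null(names(media)))
    if (any(media < 0)) stop("media uptake rates must be >= 0")
  }
  media
}

#' Constrain a model by a media composition
#'
#' Exchange reactions whose metabolite appears in the media get their
#' lower bound set to minus the stated uptake rate; the uptake direction
#' of every other exchange is closed (lower bound 0). Secretion (upper)
#' bounds and non-exchange reactions are untouched, so the operation is
#' idempotent. A media entry naming a metabolite with no exchange reaction
#' is skipped with a warning.
#'
#' @param model a `metabolic_model`.
#' @param media named numeric vector (metabolite id -> max uptake rate) or
#'   a data frame with columns `metabolite_id`, `uptake`.
#' @return the constrained `metabolic_model`.
#' @export
apply_media <- function(model, media) {
  media <- as_media(media)
  ex <- which(model$reactions$is_exchange)
  ex_met <- vapply(model$reactions$id[ex], exchange_metabolite,
                   character(1), model = model)
  unmatched <- setdiff(names(media), ex_met)
  if (length(unmatched) > 0) {
    warning("media metabolite(s) with no exchange reaction, skipped: ",
            paste(unmatched, collapse = ", "))
  }
  lb <- model$reactions$lower_bound
  for (k in seq_along(ex)) {
    j <- ex[k]
    up <- media[ex_met[k]]
    lb[j] <- if (!is.na(up)) -up else max(0, lb[j])
  }
  model$reactions$lower_bound <- pmin(lb, model$reactions$upper_bound)
  validate_model(model)
  model
}
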