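#' Read a TPM expression table
#'
#' Tab-separated, first column transcript-or-gene identifiers, remaining
#' columns one per sequencing run (technical replicate). Values are TPM
#' and must be non-negative.
#'
#' @param path file path.
#' @return numeric matrix with identifier rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (anyDuplicated(colnames(mat))) stop("duplicate sample columns in ", path)
  if (any(mat < 0, na.rm = TRUE)) stop("negative TPM values in ", path)
  mat
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample` (the cell line / biological sample),
#' `condition` (group label) and `replicate` (technical replicate tag). The
#' expression matrix is expected to carry one column per row of the design,
#' named `<sample>_<replicate>`; an optional `column` field overrides that
#' naming.
#'
#' @param path file path.
#' @return data frame with columns `sample`, `condition`, `replicate`,
#'   `column`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(df))) {
    stop("design file must have columns ", paste(need, collapse = ", "),
         ": ", path)
  }
  if (is.null(df$column)) {
    df$column <- paste(df$sample, df$replicate, sep = "_")
  }
  df
}

check_columns <- function(em, columns) {
  missing <- setdiff(columns, colnames(em))
  if (length(missing) > 0) {
    stop("unknown sample column(s): ", paste(missing, collapse = ", "))
  }
}

#' Drop genes with zero expression across all technical replicates
#'
#' Removes rows whose TPM is exactly 0 in every one of the given replicate
#' columns (one cell line's technical replicates); all other rows pass
#' through unchanged. This is applied per cell line, before replicate
#' aggregation.
#'
#' @param em expression matrix (rows identifiers, columns replicates).
#' @param columns the replicate columns of one cell line.
#' @return the filtered matrix.
#' @export
filter_zero_genes <- function(em, columns = colnames(em)) {
  if (length(columns) == 0) stop("replicate group must be non-empty")
  check_columns(em, columns)
  keep <- rowSums(em[, columns, drop = FALSE] != 0) > 0
  em[keep, , drop = FALSE]
}

#' Median TPM across technical replicates
#'
#' One value per row: the median over the given replicate columns. Even
#' replicate counts use the midpoint of the two central values.
#'
#' @param em expression matrix.
#' @param columns the replicate columns of one cell line.
#' @return named numeric vector (row identifier -> median TPM).
#' @export
aggregate_replicates <- function(em, columns = colnames(em)) {
  if (length(columns) == 0) stop("replicate group must be non-empty")
  check_columns(em, columns)
  apply(em[, columns, drop = FALSE], 1, stats::median)
}

#' Collapse transcript isoforms to genes
#'
#' Per gene, the isoform with the highest median value is taken. Ties are
#' broken deterministically by the lexicographically smallest transcript
#' identifier. Transcripts absent from the map pass through as their own
#' gene (recorded in the `unmapped` attribute).
#'
#' @param profile named numeric vector (transcript -> median TPM).
#' @param isoform_map data frame with columns `transcript`, `gene`, or
#'   `NULL` for an identity map.
#' @return named numeric vector (gene -> TPM), with attributes
#'   `chosen_isoform` (named character: the winning transcript per gene)
#'   and `unmapped` (transcripts that passed through).
#' @export
collapse_isoforms <- function(profile, isoform_map = NULL) {
  tx <- names(profile)
  if (is.null(isoform_map)) {
    gene <- tx
    unmapped <- character()
  } else {
    stopifnot(all(c("transcript", "gene") %in% names(isoform_map)))
    gene <- isoform_map$gene[match(tx, isoform_map$transcript)]
    unmapped <- tx[is.na(gene)]
    gene[is.na(gene)] <- tx[is.na(gene)]
  }
  ord <- order(gene, -profile, tx, method = "radix")
  first <- !duplicated(gene[ord])
  sel <- ord[first]
  out <- stats::setNames(profile[sel], gene[sel])
  attr(out, "chosen_isoform") <- stats::setNames(tx[sel], gene[sel])
  attr(out, "unmapped") <- unmapped
  out
}

#' Discretize an expression profile into gene calls
#'
#' Turns per-gene TPM values into `expressed`/`unexpressed` calls, the
#' input the context-extraction step consumes.
#'
#' * `percentile` (default): a gene is expressed iff its value is at least
#'   the `p`-th percentile of the profile's nonzero values (type-7
#'   quantile). With `p = 50` this calls the upper half of detected genes
#'   expressed; all-equal nonzero profiles are entirely expressed since
#'   every value equals the threshold.
#' * `mixture`: a two-component Gaussian mixture is fit to log2(TPM + 1)
#'   of the nonzero values ([mclust::Mclust], deterministic); a gene is
#'   expressed iff its posterior probability for the higher-mean component
#'   is at least 0.5. A degenerate fit (fewer than two distinct values, or
#'   a failed fit) falls back to the percentile rule with a warning.
#'
#' Zero-TPM genes are always unexpressed.
#'
#' @param profile named numeric vector (gene -> TPM).
#' @param method `"percentile"` or `"mixture"`.
#' @param p percentile on nonzero values (percentile method), in (0, 100].
#' @return a `gene_calls` object: list with `calls` (named character,
#'   values `"expressed"`/`"unexpressed"`) and `provenance` (method,
#'   parameters, threshold).
#' @export
discretize_expression <- function(profile,
                                  method = c("percentile", "mixture"),
                                  p = 50) {
  method <- match.arg(method)
  if (length(profile) == 0) stop("profile must be non-empty")
  nz <- profile[profile > 0]
  prov <- list(method = method, p = p)

  if (method == "mixture") {
    x <- log2(nz + 1)
    # Mclust() resolves mclustBIC in the caller's frame; provide it when
    # the namespace is imported rather than attached
    mclustBIC <- mclust::mclustBIC
    fit <- if (length(unique(x)) >= 2) {
      tryCatch(mclust::Mclust(x, G = 2, verbose = FALSE),
               error = function(e) NULL)
    } else {
      NULL
    }
    if (is.null(fit)) {
      warning("degenerate mixture fit; falling back to percentile rule")
      method <- "percentile"
      prov$fallback <- "percentile"
    } else {
      high <- which.max(fit$parameters$mean)
      post <- fit$z[, high]
      expressed_nz <- post >= 0.5
      calls <- stats::setNames(rep("unexpressed", length(profile)),
                               names(profile))
      calls[names(nz)[expressed_nz]] <- "expressed"
      prov$component_means <- as.numeric(fit$parameters$mean)
      return(new_gene_calls(calls, prov))
    }
  }

  thr <- if (length(nz) > 0) {
    stats::quantile(nz, probs = p / 100, type = 7, names = FALSE)
  } else {
    Inf
  }
  calls <- ifelse(profile >= thr & profile > 0, "expressed", "unexpressed")
  prov$threshold <- thr
  new_gene_calls(stats::setNames(calls, names(profile)), prov)
}

new_gene_calls <- function(calls, provenance) {
  structure(list(calls = calls, provenance = provenance),
            class = "gene_calls")
}

#' Construct a gene call set directly
#'
#' Convenience constructor, mainly for tests and scripted analyses where
#' calls are known rather than derived from a TPM profile.
#'
#' @param calls named character vector with values
#'   `"expressed"`/`"unexpressed"`.
#' @param provenance free-form list recording how the calls were made.
#' @return a `gene_calls` object.
#' @export
gene_calls <- function(calls, provenance = list(method = "manual")) {
  new_gene_calls(as_call_vector(calls), provenance)
}

#' @export
print.gene_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c("expressed", "unexpressed")))
  cat("gene_calls:", tab["expressed"], "expressed,",
      tab["unexpressed"], "unexpressed (method:",
      x$provenance$method, ")\n")
  invisible(x)
}

#' Per-cell-line gene calls from a TPM table
#'
#' Runs the full preparation pipeline for one cell line, in the required
#' order: drop genes with all-zero technical replicates, take the median
#' across replicates, collapse isoforms to genes, then discretize.
#'
#' @param em expression matrix (see [read_expression_matrix()]).
#' @param columns the cell line's replicate columns.
#' @param isoform_map optional transcript -> gene map (see
#'   [collapse_isoforms()]).
#' @param method,p passed to [discretize_expression()].
#' @return a `gene_calls` object.
#' @export
calls_for_sample <- function(em, columns, isoform_map = NULL,
                             method = "percentile", p = 50) {
  em <- filter_zero_genes(em, columns)
  profile <- aggregate_replicates(em, columns)
  profile <- collapse_isoforms(profile, isoform_map)
  cs <- discretize_expression(profile, method = method, p = p)
  cs$provenance$columns <- columns
  cs
}
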