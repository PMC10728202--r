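#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a boolean rule string such as `"(g1 and g2) or g3"` into an
#' expression tree. `and`/`AND`/`&` denote enzyme complexes (all subunits
#' required), `or`/`OR`/`|` denote isozymes (any suffices). Gene
#' identifiers are any other whitespace-delimited tokens.
#'
#' @param text the rule as a character scalar; `""` or `NA` yield `NULL`
#'   (no gene association).
#' @return a tree: either `NULL`, a leaf `list(type = "gene", gene = id)`,
#'   or a node `list(type = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) ||
      !nzchar(trimws(text))) {
    return(NULL)
  }
  toks <- gpr_tokens(text)
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$pos <- 1L
  tree <- gpr_parse_or(env)
  if (env$pos <= length(env$toks)) {
    stop("malformed GPR rule near '", env$toks[env$pos], "': ", text)
  }
  tree
}

gpr_tokens <- function(text) {
  text <- gsub("&&|&", " and ", text)
  text <- gsub("\\|\\||\\|", " or ", text)
  text <- gsub("\\(", " ( ", text)
  text <- gsub("\\)", " ) ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(env) {
  if (env$pos > length(env$toks)) NA_character_ else env$toks[env$pos]
}

gpr_parse_or <- function(env) {
  args <- list(gpr_parse_and(env))
  while (!is.na(tk <- gpr_peek(env)) && tolower(tk) == "or") {
    env$pos <- env$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(env)
  }
  if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)
}

gpr_parse_and <- function(env) {
  args <- list(gpr_parse_atom(env))
  while (!is.na(tk <- gpr_peek(env)) && tolower(tk) == "and") {
    env$pos <- env$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(env)
  }
  if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
}

gpr_parse_atom <- function(env) {
  tk <- gpr_peek(env)
  if (is.na(tk)) stop("malformed GPR rule: unexpected end of input")
  if (tk == "(") {
    env$pos <- env$pos + 1L
    inner <- gpr_parse_or(env)
    if (!identical(gpr_peek(env), ")")) {
      stop("malformed GPR rule: unbalanced parenthesis")
    }
    env$pos <- env$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("malformed GPR rule: unexpected token '", tk, "'")
  }
  env$pos <- env$pos + 1L
  list(type = "gene", gene = tk)
}

#' Genes referenced by a GPR rule
#'
#' @param rule a rule string or a tree from [parse_gpr()].
#' @return character vector of gene identifiers (unique, in order of first
#'   appearance).
#' @export
gpr_genes <- function(rule) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(character())
  if (identical(rule$type, "gene")) return(rule$gene)
  unique(unlist(lapply(rule$args, gpr_genes)))
}

#' Render a GPR tree back to its rule string
#' @param rule a tree from [parse_gpr()] (or a string, returned as is).
#' @return character scalar; `""` for `NULL`.
#' @export
deparse_gpr <- function(rule) {
  if (is.character(rule)) return(rule)
  if (is.null(rule)) return("")
  if (identical(rule$type, "gene")) return(rule$gene)
  parts <- vapply(rule$args, function(a) {
    s <- deparse_gpr(a)
    if (!identical(a$type, "gene") && !identical(a$type, rule$type)) {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$type, " "))
}

#' Evaluate a GPR rule against gene expression calls
#'
#' Three-valued logic over `unexpressed < unknown < expressed`: an AND node
#' takes the minimum of its arguments (a complex is only as available as
#' its least-available subunit), an OR node the maximum (any isozyme
#' suffices). Genes absent from `calls` evaluate to `unknown`, so genes
#' that were never measured do not force a reaction out of the core. An
#' empty rule evaluates to `unknown`.
#'
#' @param rule a rule string or tree from [parse_gpr()].
#' @param calls a [gene_calls] object, or a named character vector with
#'   values `"expressed"`/`"unexpressed"`.
#' @return one of `"expressed"`, `"unexpressed"`, `"unknown"`.
#' @examples
#' evaluate_gpr("g1 and g2", c(g1 = "expressed", g2 = "unexpressed"))
#' evaluate_gpr("(g1 and g2) or g3",
#'              c(g1 = "expressed", g2 = "unexpressed", g3 = "expressed"))
#' @export
evaluate_gpr <- function(rule, calls) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  calls <- as_call_vector(calls)
  lv <- gpr_eval_num(rule, calls)
  c("unexpressed", "unknown", "expressed")[lv + 1L]
}

# numeric three-valued evaluation: 0 unexpressed, 1 unknown, 2 expressed
gpr_eval_num <- function(rule, calls) {
  if (is.null(rule)) return(1L)
  if (identical(rule$type, "gene")) {
    v <- calls[rule$gene]
    if (is.na(v)) return(1L)
    return(if (v == "expressed") 2L else 0L)
  }
  vals <- vapply(rule$args, gpr_eval_num, integer(1), calls = calls)
  if (identical(rule$type, "and")) min(vals) else max(vals)
}

as_call_vector <- function(calls) {
  if (inherits(calls, "gene_calls")) calls <- calls$calls
  if (is.null(calls)) calls <- character()
  bad <- setdiff(unique(calls), c("expressed", "unexpressed"))
  if (length(bad) > 0) {
    stop("gene calls must be 'expressed' or 'unexpressed', got: ",
         paste(bad, collapse = ", "))
  }
  calls
}
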