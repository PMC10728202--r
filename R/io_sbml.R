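# SBML Level 3 + FBC v2 reading and writing, via xml2.
#
# Arbitrary identifiers (e.g. "glc[c]") are not valid SBML SIds, so ids are
# written as M_/R_/G_ prefixed strings with every character outside
# [A-Za-z0-9_] encoded as __<codepoint>__ (decoded on read), which makes
# the round trip exact unless an id itself contains a literal __<digits>__
# run.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"

sbml_encode_id <- function(id, prefix) {
  chars <- strsplit(id, "")[[1]]
  enc <- vapply(chars, function(ch) {
    if (grepl("^[A-Za-z0-9_]$", ch)) ch else sprintf("__%d__", utf8ToInt(ch))
  }, character(1))
  paste0(prefix, paste(enc, collapse = ""))
}

sbml_decode_id <- function(sid, prefix) {
  s <- sub(paste0("^", prefix), "", sid)
  m <- gregexpr("__([0-9]+)__", s)
  regmatches(s, m) <- lapply(regmatches(s, m), function(hits) {
    vapply(hits, function(h) {
      intToUtf8(as.integer(sub("^__([0-9]+)__$", "\\1", h)))
    }, character(1))
  })
  s
}

# attribute lookup tolerant of namespace prefixes
sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | sub("^[^:]+:", "", names(at)) == name)
  if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
}

sbml_children_named <- function(node, local) {
  kids <- xml2::xml_children(node)
  kids[vapply(kids, function(k) {
    sub("^.*:", "", xml2::xml_name(k)) == local
  }, logical(1))]
}

sbml_find1 <- function(node, local) {
  hits <- xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
  if (length(hits) == 0) NULL else hits[[1]]
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML file '", path, "': ", conditionMessage(e))
  })
  model_node <- sbml_find1(doc, "model")
  if (is.null(model_node)) stop("malformed SBML: no <model> element")
  name <- sbml_attr(model_node, "name")
  if (is.na(name)) name <- sbml_decode_id(sbml_attr(model_node, "id"), "")

  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(
    vapply(params, function(p) as.numeric(sbml_attr(p, "value")), numeric(1)),
    vapply(params, function(p) sbml_attr(p, "id"), character(1)))

  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  met_sids <- vapply(species, function(s) sbml_attr(s, "id"), character(1))
  met_ids <- sbml_decode_id(met_sids, "M_")
  if (anyDuplicated(met_ids)) {
    stop("malformed SBML: duplicate metabolite id '",
         met_ids[duplicated(met_ids)][1], "'")
  }

  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gene_by_sid <- stats::setNames(
    vapply(gps, function(g) {
      lab <- sbml_attr(g, "label")
      if (!is.na(lab)) lab else sbml_decode_id(sbml_attr(g, "id"), "G_")
    }, character(1)),
    vapply(gps, function(g) sbml_attr(g, "id"), character(1)))

  rxn_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  n <- length(rxn_nodes)
  ids <- character(n); lbs <- ubs <- numeric(n)
  gprs <- subs <- character(n)
  trip <- list()
  for (j in seq_len(n)) {
    rn <- rxn_nodes[[j]]
    ids[j] <- sbml_decode_id(sbml_attr(rn, "id"), "R_")
    lb_ref <- sbml_attr(rn, "lowerFluxBound")
    ub_ref <- sbml_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(pval)) {
      lbs[j] <- pval[lb_ref]
    } else {
      rev <- identical(sbml_attr(rn, "reversible"), "true")
      lbs[j] <- if (rev) -DEFAULT_BOUND else 0
    }
    ubs[j] <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) {
      pval[ub_ref]
    } else {
      DEFAULT_BOUND
    }
    for (side in c("listOfReactants", "listOfProducts")) {
      node <- sbml_children_named(rn, side)
      if (length(node) == 1) {
        for (sr in sbml_children_named(node[[1]], "speciesReference")) {
          i <- match(sbml_attr(sr, "species"), met_sids)
          if (is.na(i)) {
            stop("malformed SBML: reaction '", ids[j],
                 "' references undeclared species '",
                 sbml_attr(sr, "species"), "'")
          }
          coef <- as.numeric(sbml_attr(sr, "stoichiometry"))
          if (is.na(coef)) coef <- 1
          sgn <- if (side == "listOfReactants") -1 else 1
          trip[[length(trip) + 1L]] <- c(i = i, j = j, x = sgn * coef)
        }
      }
    }
    gpa <- sbml_children_named(rn, "geneProductAssociation")
    gprs[j] <- if (length(gpa) == 1) {
      kids <- xml2::xml_children(gpa[[1]])
      if (length(kids) == 1) {
        deparse_gpr(sbml_read_gpa(kids[[1]], gene_by_sid))
      } else ""
    } else ""
    # subsystem fallback: notes "SUBSYSTEM: <label>" (groups read below win)
    notes <- sbml_children_named(rn, "notes")
    subs[j] <- if (length(notes) == 1) {
      txt <- xml2::xml_text(notes[[1]])
      mm <- regmatches(txt, regexec("SUBSYSTEM:\\s*([^\n]+)", txt))[[1]]
      if (length(mm) == 2) trimws(mm[2]) else ""
    } else ""
  }
  if (anyDuplicated(ids)) {
    stop("malformed SBML: duplicate reaction id '",
         ids[duplicated(ids)][1], "'")
  }

  # subsystems from the groups extension take priority over notes
  for (grp in xml2::xml_find_all(doc, ".//*[local-name()='group']")) {
    label <- sbml_attr(grp, "name")
    if (is.na(label)) next
    for (mem in xml2::xml_find_all(grp,
                                   ".//*[local-name()='member']")) {
      rid <- sbml_decode_id(sbml_attr(mem, "idRef"), "R_")
      k <- match(rid, ids)
      if (!is.na(k)) subs[k] <- label
    }
  }

  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                            dims = c(length(met_ids), n))
  rx <- data.frame(id = ids, lower_bound = lbs, upper_bound = ubs,
                   gpr = gprs, subsystem = subs, stringsAsFactors = FALSE)
  metabolic_model(rx, met_ids, S, name = name)
}

sbml_read_gpa <- function(node, gene_by_sid) {
  local <- sub("^.*:", "", xml2::xml_name(node))
  if (local == "geneProductRef") {
    sid <- sbml_attr(node, "geneProduct")
    g <- gene_by_sid[sid]
    if (is.na(g)) g <- sbml_decode_id(sid, "G_")
    return(list(type = "gene", gene = unname(g)))
  }
  if (local %in% c("and", "or")) {
    return(list(type = local,
                args = lapply(xml2::xml_children(node), sbml_read_gpa,
                              gene_by_sid = gene_by_sid)))
  }
  stop("malformed SBML: unexpected element in gene association: ", local)
}

write_model_sbml <- function(model, path) {
  rx <- model$reactions
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    "xmlns:groups" = SBML_GROUPS_NS,
    level = "3", version = "1",
    "fbc:required" = "false", "groups:required" = "false")
  mod <- xml2::xml_add_child(doc, "model",
                             id = sbml_encode_id(model$name, ""),
                             name = model$name, "fbc:strict" = "false")

  comps <- unique(vapply(model$metabolites, met_compartment, character(1)))
  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = sbml_encode_id(cp, "C_"),
                        constant = "true")
  }

  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (mid in model$metabolites) {
    xml2::xml_add_child(
      ls, "species", id = sbml_encode_id(mid, "M_"), name = mid,
      compartment = sbml_encode_id(met_compartment(mid), "C_"),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }

  bound_vals <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bound_vals)),
                         sprintf("%.17g", bound_vals))
  lp <- xml2::xml_add_child(mod, "listOfParameters")
  for (k in seq_along(bound_vals)) {
    xml2::xml_add_child(lp, "parameter", id = pid[[k]],
                        value = sprintf("%.17g", bound_vals[k]),
                        constant = "true", sboTerm = "SBO:0000626")
  }

  lr <- xml2::xml_add_child(mod, "listOfReactions")
  for (j in seq_len(nrow(rx))) {
    rn <- xml2::xml_add_child(
      lr, "reaction", id = sbml_encode_id(rx$id[j], "R_"), name = rx$id[j],
      reversible = if (rx$lower_bound[j] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = pid[[sprintf("%.17g", rx$lower_bound[j])]],
      "fbc:upperFluxBound" = pid[[sprintf("%.17g", rx$upper_bound[j])]])
    nz <- which(model$S[, j] != 0)
    coefs <- as.numeric(model$S[nz, j])
    for (side in c(-1, 1)) {
      sel <- if (side < 0) coefs < 0 else coefs > 0
      if (!any(sel)) next
      node <- xml2::xml_add_child(
        rn, if (side < 0) "listOfReactants" else "listOfProducts")
      for (k in which(sel)) {
        xml2::xml_add_child(
          node, "speciesReference",
          species = sbml_encode_id(model$metabolites[nz[k]], "M_"),
          stoichiometry = sprintf("%.17g", abs(coefs[k])),
          constant = "true")
      }
    }
    if (nzchar(rx$gpr[j])) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      sbml_write_gpa(gpa, parse_gpr(rx$gpr[j]))
    }
  }

  if (length(model$genes) > 0) {
    lg <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = sbml_encode_id(g, "G_"),
                          "fbc:label" = g)
    }
  }

  subsystems <- setdiff(unique(rx$subsystem), "")
  if (length(subsystems) > 0) {
    lgp <- xml2::xml_add_child(mod, "groups:listOfGroups")
    for (k in seq_along(subsystems)) {
      grp <- xml2::xml_add_child(lgp, "groups:group",
                                 "groups:id" = sprintf("g_subsystem_%d", k),
                                 "groups:kind" = "partonomy",
                                 "groups:name" = subsystems[k])
      lm <- xml2::xml_add_child(grp, "groups:listOfMembers")
      for (rid in rx$id[rx$subsystem == subsystems[k]]) {
        xml2::xml_add_child(lm, "groups:member",
                            "groups:idRef" = sbml_encode_id(rid, "R_"))
      }
    }
  }
  xml2::write_xml(doc, path)
}

sbml_write_gpa <- function(parent, tree) {
  if (identical(tree$type, "gene")) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_encode_id(tree$gene, "G_"))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", tree$type))
  for (a in tree$args) sbml_write_gpa(node, a)
  invisible(NULL)
}
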