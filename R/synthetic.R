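# run code under a local RNG state, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic study
#'
#' Parameters of the synthetic network-and-expression generator that
#' emulates the study layout the pipeline expects: a multi-subsystem
#' stoichiometric network with exchanges, an ATP demand sink and GPRs, and
#' a two-group TPM matrix with technical replicates, log-normal noise and
#' silenced subsystems planted in one group.
#'
#' The network is a carbon backbone (uptake exchange, transport, a central
#' energy reaction producing `objective_yield` ATP per carbon, an ATP
#' demand sink, a waste exchange) plus one branch module per subsystem:
#' a gateway from cytosolic carbon, a silenceable linear chain to waste,
#' and a small always-on leak (capacity `leak_capacity`) that keeps the
#' gateway flux-consistent even when the chain is silenced — so a silenced
#' subsystem loses its chain but keeps comparable reactions, as partially
#' inactivated pathways do in real context models.
#'
#' @param n_subsystems number of branch subsystems.
#' @param reactions_per_subsystem integer range `c(min, max)` of reactions
#'   per subsystem (gateway + chain + leak; minimum 3).
#' @param n_exchange total exchange reactions (>= 2); beyond the carbon
#'   uptake and waste secretion, extras are inert boundary metabolites
#'   (blocked, as in genome-scale reconstructions).
#' @param objective_yield ATP produced per carbon by the central reaction.
#' @param uptake_bound carbon uptake bound (mmol/gDW/h).
#' @param leak_capacity upper bound of each branch leak reaction.
#' @param conditions the two group labels.
#' @param models_per_group cell lines per condition.
#' @param replicates technical replicates per cell line.
#' @param perturbed named list: condition -> subsystem labels whose chain
#'   genes are silenced in that condition.
#' @param noise_sd log2-TPM standard deviation of line and replicate noise.
#' @param p_zero probability that a silenced gene's replicate reads
#'   exactly 0 (otherwise it reads near 0).
#' @param decoy_genes number of non-model background genes in the TPM
#'   table, or `"auto"` (= number of model genes) — they populate the low
#'   expression mode so percentile and mixture discretization both see a
#'   realistic bimodal profile.
#' @param isoform_fraction fraction of genes emitted as two transcript
#'   isoforms (exercises isoform collapsing; 0 keeps one row per gene).
#' @param gpr_mode `"single"` (one gene per reaction) or `"composite"`
#'   (chain reactions get two-gene AND/OR rules).
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subsystems = 6,
                           reactions_per_subsystem = c(4, 6),
                           n_exchange = 4,
                           objective_yield = 2,
                           uptake_bound = 10,
                           leak_capacity = 0.5,
                           conditions = c("CTRL", "PD"),
                           models_per_group = 2,
                           replicates = 3,
                           perturbed = list(PD = "subsystem_03"),
                           noise_sd = 0.5,
                           p_zero = 0.9,
                           decoy_genes = "auto",
                           isoform_fraction = 0,
                           gpr_mode = c("single", "composite"),
                           seed = 1) {
  gpr_mode <- match.arg(gpr_mode)
  stopifnot(n_subsystems >= 1, length(reactions_per_subsystem) == 2,
            reactions_per_subsystem[1] >= 3,
            reactions_per_subsystem[2] >= reactions_per_subsystem[1],
            n_exchange >= 2, objective_yield > 0, uptake_bound > 0,
            leak_capacity > 0, length(conditions) == 2,
            models_per_group >= 1, replicates >= 1,
            noise_sd >= 0, p_zero >= 0, p_zero <= 1,
            isoform_fraction >= 0, isoform_fraction <= 1)
  labels <- sprintf("subsystem_%02d", seq_len(n_subsystems))
  stopifnot(all(names(perturbed) %in% conditions),
            all(unlist(perturbed) %in% labels))
  structure(list(n_subsystems = n_subsystems,
                 reactions_per_subsystem = reactions_per_subsystem,
                 n_exchange = n_exchange,
                 objective_yield = objective_yield,
                 uptake_bound = uptake_bound,
                 leak_capacity = leak_capacity,
                 conditions = conditions,
                 models_per_group = models_per_group,
                 replicates = replicates,
                 perturbed = perturbed,
                 noise_sd = noise_sd,
                 p_zero = p_zero,
                 decoy_genes = decoy_genes,
                 isoform_fraction = isoform_fraction,
                 gpr_mode = gpr_mode,
                 subsystem_labels = labels,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic metabolic network with planted truth
#'
#' See [synthetic_spec()] for the network layout. Every branch is
#' flux-consistent under open media when its genes are expressed; the FBA
#' optimum for the ATP demand under the default media is
#' `objective_yield * uptake_bound` by construction.
#'
#' @param spec a `synthetic_spec`.
#' @param seed overrides `spec$seed`.
#' @return list with `model` (a `metabolic_model`), `truth` (per
#'   condition: `silenced_genes`, `lost_reactions`,
#'   `differential_subsystems`; plus `objective`, `media`,
#'   `chain_reactions` per subsystem) and `media` (named uptake vector).
#' @export
generate_network <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    rx <- list()
    smap <- list() # reaction id -> metabolite coefficient map
    add <- function(id, mets, lb, ub, gpr = "", subsystem = "") {
      rx[[length(rx) + 1L]] <<- data.frame(
        id = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
        subsystem = subsystem, stringsAsFactors = FALSE)
      smap[[id]] <<- mets
    }

    add("EX_carbon", c("carbon[e]" = -1), -spec$uptake_bound, DEFAULT_BOUND,
        subsystem = "exchange/demand")
    add("TRANS_carbon", c("carbon[e]" = -1, "carbon[c]" = 1),
        0, DEFAULT_BOUND, gpr = "g_TRANS", subsystem = "transport")
    add("CENTRAL", c("carbon[c]" = -1, "atp[c]" = spec$objective_yield),
        0, DEFAULT_BOUND, gpr = "g_CENTRAL",
        subsystem = "central energy metabolism")
    add("DM_atp", c("atp[c]" = -1), 0, DEFAULT_BOUND,
        subsystem = "exchange/demand")
    add("EX_waste", c("waste[e]" = -1), 0, DEFAULT_BOUND,
        subsystem = "exchange/demand")

    size_range <- seq(spec$reactions_per_subsystem[1],
                      spec$reactions_per_subsystem[2])
    sizes <- if (length(size_range) == 1) {
      rep(size_range, spec$n_subsystems)
    } else {
      sample(size_range, spec$n_subsystems, replace = TRUE)
    }
    chain_reactions <- list()
    chain_genes <- list()
    for (i in seq_len(spec$n_subsystems)) {
      lab <- spec$subsystem_labels[i]
      k <- sizes[i]
      n_chain <- k - 2L
      gw <- sprintf("GW_%02d", i)
      add(gw, stats::setNames(c(-1, 1),
                              c("carbon[c]", sprintf("x_%02d_1[c]", i))),
          0, DEFAULT_BOUND, gpr = sprintf("g_GW_%02d", i), subsystem = lab)
      ch_ids <- character(n_chain)
      ch_genes <- character(0)
      for (j in seq_len(n_chain)) {
        from <- sprintf("x_%02d_%d[c]", i, j)
        to <- if (j == n_chain) "waste[e]" else sprintf("x_%02d_%d[c]", i,
                                                        j + 1)
        gene1 <- sprintf("g_CH_%02d_%d", i, j)
        gpr <- gene1
        if (spec$gpr_mode == "composite") {
          gene2 <- sprintf("g_CHb_%02d_%d", i, j)
          op <- if (stats::runif(1) < 0.5) "and" else "or"
          gpr <- sprintf("%s %s %s", gene1, op, gene2)
          ch_genes <- c(ch_genes, gene2)
        }
        ch_genes <- c(ch_genes, gene1)
        ch_ids[j] <- sprintf("CH_%02d_%d", i, j)
        add(ch_ids[j], stats::setNames(c(-1, 1), c(from, to)),
            0, DEFAULT_BOUND, gpr = gpr, subsystem = lab)
      }
      add(sprintf("LK_%02d", i),
          stats::setNames(c(-1, 1), c(sprintf("x_%02d_1[c]", i),
                                      "waste[e]")),
          0, spec$leak_capacity, gpr = sprintf("g_LK_%02d", i),
          subsystem = lab)
      chain_reactions[[lab]] <- ch_ids
      chain_genes[[lab]] <- ch_genes
    }

    for (j in seq_len(spec$n_exchange - 2L)) {
      add(sprintf("EX_inert_%02d", j),
          stats::setNames(-1, sprintf("inert_%02d[e]", j)),
          0, DEFAULT_BOUND, subsystem = "exchange/demand")
    }

    rxdf <- do.call(rbind, rx)
    mets <- unique(unlist(lapply(smap, names)))
    S <- Matrix::sparseMatrix(
      i = match(unlist(lapply(smap, names)), mets),
      j = rep(seq_along(smap), lengths(smap)),
      x = unlist(smap),
      dims = c(length(mets), length(smap)))
    model <- metabolic_model(rxdf, mets, S, name = "synthetic_net")

    media <- c("carbon[e]" = spec$uptake_bound)
    truth <- list(objective = "DM_atp", media = media,
                  chain_reactions = chain_reactions,
                  per_condition = lapply(
                    stats::setNames(spec$conditions, spec$conditions),
                    function(cond) {
                      labs <- spec$perturbed[[cond]]
                      list(silenced_genes =
                             unique(unlist(chain_genes[labs])) %||%
                               character(),
                           lost_reactions =
                             unique(unlist(chain_reactions[labs])) %||%
                               character(),
                           differential_subsystems = labs %||% character())
                    }))
    list(model = model, truth = truth, media = media)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a two-group TPM matrix for a synthetic network
#'
#' One column per cell line and technical replicate
#' (`<line>_r<replicate>`). Expressed genes draw log-normal TPM around a
#' high mode (gene baseline log2 ~ N(6, 1); line and replicate noise with
#' sd `noise_sd`); decoy background genes draw around a low mode
#' (log2 ~ N(-0.5, 0.5)); a silenced gene's replicate reads exactly 0
#' with probability `p_zero` and near 0 otherwise. TPM scale is arbitrary
#' (no library-size model): only ranks and thresholds matter downstream.
#'
#' @param model the `metabolic_model` from [generate_network()].
#' @param spec the `synthetic_spec`.
#' @param truth the planted truth from [generate_network()].
#' @param seed overrides `spec$seed + 1`.
#' @return list with `tpm` (matrix, transcript rows), `design` (data
#'   frame `sample`, `condition`, `replicate`, `column`) and
#'   `isoform_map` (data frame `transcript`, `gene`, or `NULL` when every
#'   gene is a single transcript).
#' @export
generate_expression <- function(model, spec, truth, seed = spec$seed + 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    genes <- model$genes
    n_decoy <- if (identical(spec$decoy_genes, "auto")) {
      length(genes)
    } else {
      as.integer(spec$decoy_genes)
    }
    decoys <- if (n_decoy > 0) sprintf("decoy_%04d", seq_len(n_decoy)) else
      character()
    all_genes <- c(genes, decoys)
    base_mu <- c(stats::rnorm(length(genes), mean = 6, sd = 1),
                 stats::rnorm(length(decoys), mean = -0.5, sd = 0.5))
    names(base_mu) <- all_genes

    lines <- unlist(lapply(spec$conditions, function(cond) {
      stats::setNames(rep(cond, spec$models_per_group),
                      paste0(cond, seq_len(spec$models_per_group)))
    }))
    design <- do.call(rbind, lapply(names(lines), function(ln) {
      data.frame(sample = ln, condition = unname(lines[ln]),
                 replicate = paste0("r", seq_len(spec$replicates)),
                 stringsAsFactors = FALSE)
    }))
    design$column <- paste(design$sample, design$replicate, sep = "_")

    tpm <- matrix(0, nrow = length(all_genes), ncol = nrow(design),
                  dimnames = list(all_genes, design$column))
    for (ln in names(lines)) {
      cond <- lines[ln]
      silenced <- truth$per_condition[[cond]]$silenced_genes
      line_shift <- stats::rnorm(length(all_genes), 0, spec$noise_sd)
      for (r in seq_len(spec$replicates)) {
        col <- paste0(ln, "_r", r)
        lg <- base_mu + line_shift +
          stats::rnorm(length(all_genes), 0, spec$noise_sd)
        vals <- 2^lg
        sil <- all_genes %in% silenced
        if (any(sil)) {
          zero <- sil & stats::runif(length(all_genes)) < spec$p_zero
          near <- sil & !zero
          vals[zero] <- 0
          vals[near] <- 2^stats::rnorm(sum(near), -1, spec$noise_sd)
        }
        tpm[, col] <- vals
      }
    }

    isoform_map <- NULL
    if (spec$isoform_fraction > 0) {
      split_genes <- all_genes[stats::runif(length(all_genes)) <
                                 spec$isoform_fraction]
      tx_rows <- list()
      map <- list()
      for (g in all_genes) {
        if (g %in% split_genes) {
          t1 <- paste0(g, ".t1")
          t2 <- paste0(g, ".t2")
          # second isoform: attenuated copy of the first
          tx_rows[[t1]] <- tpm[g, ]
          tx_rows[[t2]] <- tpm[g, ] *
            stats::runif(ncol(tpm), 0.2, 0.8)
          map[[t1]] <- g
          map[[t2]] <- g
        } else {
          tx_rows[[g]] <- tpm[g, ]
          map[[g]] <- g
        }
      }
      tpm <- do.call(rbind, tx_rows)
      isoform_map <- data.frame(transcript = names(map),
                                gene = unlist(map),
                                stringsAsFactors = FALSE,
                                row.names = NULL)
    }
    list(tpm = tpm, design = design, isoform_map = isoform_map)
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates network and expression and writes exactly the files the
#' pipeline consumes: `model.json`, `tpm.tsv`, `design.tsv`,
#' `mapping.tsv` (when isoforms are emitted), `media.tsv` and
#' `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param spec a `synthetic_spec`.
#' @param seed overrides `spec$seed`.
#' @return named list of file paths (and the `truth` object, invisibly
#'   attached as an attribute).
#' @export
write_synthetic_bundle <- function(dir, spec = synthetic_spec(),
                                   seed = spec$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(spec, seed = seed)
  expr <- generate_expression(net$model, spec, net$truth, seed = seed + 1)

  paths <- list(model = file.path(dir, "model.json"),
                tpm = file.path(dir, "tpm.tsv"),
                design = file.path(dir, "design.tsv"),
                media = file.path(dir, "media.tsv"),
                truth = file.path(dir, "truth.json"))
  write_metabolic_model(net$model, paths$model, format = "json")
  tpm_df <- data.frame(transcript = rownames(expr$tpm), expr$tpm,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tpm_df, paths$tpm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$design, paths$design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(metabolite_id = names(net$media), uptake = net$media),
    paths$media, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(net$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(expr$isoform_map)) {
    paths$mapping <- file.path(dir, "mapping.tsv")
    utils::write.table(expr$isoform_map, paths$mapping, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  attr(paths, "truth") <- net$truth
  paths
}
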