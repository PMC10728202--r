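test_that("gene calls map to the reaction core through GPRs", {
  m <- toy_atp_model() # T: g_t ; C: g_c1 and g_c2 ; EX/DM: no GPR
  calls <- gene_calls(c(g_t = "expressed", g_c1 = "expressed",
                        g_c2 = "unexpressed"))
  expect_equal(reaction_core_from_calls(m, calls), "T")
  calls2 <- gene_calls(c(g_t = "expressed", g_c1 = "expressed",
                         g_c2 = "expressed"))
  expect_setequal(reaction_core_from_calls(m, calls2), c("T", "C"))
  # empty-GPR reactions are never core
  expect_false(any(c("EX_A", "DM") %in% reaction_core_from_calls(m, calls2)))
  # unmeasured genes are reported, not fatal
  expect_message(reaction_core_from_calls(m, gene_calls(c(g_t = "expressed"))),
                 "absent from the call set")
})

test_that("a single core reaction forces in its whole carrier chain", {
  m <- toy_chain_model()
  cm <- extract_context_model(m, core = "AB")
  expect_setequal(cm$retained, c("A_ex", "AB", "B_sink"))
  # exhaustive check: this is the unique minimal consistent superset
  expect_equal(length(brute_min_subnetwork(m, "AB")), 3)
})

test_that("an empty core yields an empty context model", {
  m <- toy_chain_model()
  cm <- extract_context_model(m, core = character())
  expect_equal(cm$retained, character())
})

test_that("one of two parallel routes is retained, matching the exhaustive minimum", {
  m <- parallel_routes_model()
  cm <- extract_context_model(m, core = "CORE")
  expect_true(all(c("EX_A", "T", "CORE", "EX_D") %in% cm$retained))
  best <- brute_min_subnetwork(m, "CORE")
  expect_equal(length(cm$retained), length(best)) # 5: the short route wins
  expect_true(subnetwork_is_consistent(m, cm$retained))
  # deterministic: same result on re-run
  expect_identical(cm$retained, extract_context_model(m, "CORE")$retained)
})

test_that("extraction matches the exhaustive minimum on all bundled networks", {
  cases <- list(list(m = toy_chain_model(), core = "AB"),
                list(m = toy_atp_model(), core = "C"),
                list(m = toy_atp_model(), core = c("T", "C")),
                list(m = parallel_routes_model(), core = "CORE"),
                list(m = parallel_routes_model(), core = c("P1b", "CORE")),
                list(m = reversible_backwards_model(), core = "R_rev"),
                list(m = dead_end_model(), core = "AB"))
  for (cs in cases) {
    cm <- extract_context_model(cs$m, cs$core)
    expect_true(all(cs$core %in% cm$retained))
    expect_true(subnetwork_is_consistent(cs$m, cm$retained),
                info = cs$m$name)
    best <- brute_min_subnetwork(cs$m, cs$core)
    expect_equal(length(cm$retained), length(best), info = cs$m$name)
  }
})

test_that("inconsistent core reactions are dropped with a warning (or error when strict)", {
  m <- dead_end_model()
  expect_warning(cm <- extract_context_model(m, core = c("AB", "CD")),
                 "not flux-consistent")
  expect_setequal(cm$retained, c("A_ex", "AB", "B_sink"))
  expect_equal(cm$derivation$dropped_core, "CD")
  expect_error(extract_context_model(m, core = "CD", strict = TRUE),
               "not flux-consistent")
  expect_error(extract_context_model(m, core = "nope"), "unknown reaction")
})

test_that("enlarging the core never shrinks the retained set below the previous core", {
  m <- parallel_routes_model()
  a <- extract_context_model(m, "CORE")$retained
  b <- extract_context_model(m, c("CORE", "P1a", "P1b"))$retained
  expect_true(all(c("CORE") %in% b))
  expect_gte(length(b), length(a))
  expect_true(all(c("P1a", "P1b") %in% b))
})

test_that("extraction output is consistent and core-containing on random networks", {
  for (seed in 1:15) {
    net <- random_model(sample(3:6, 1), sample(6:10, 1), seed = 4000 + seed)
    cons <- find_consistent_subnetwork(net)
    if (length(cons) == 0) next
    set.seed(seed)
    core <- sample(cons, min(length(cons), 2))
    cm <- suppressWarnings(
      extract_context_model(net, core, consistent = cons))
    expect_true(all(core %in% cm$retained))
    expect_true(subnetwork_is_consistent(net, cm$retained))
  }
})

test_that("the condition-model orchestrator honours media, calls and protection", {
  spec <- synthetic_spec(seed = 5)
  net <- generate_network(spec)
  # silence one subsystem entirely (all its genes, incl. gateway and leak)
  sil_lab <- "subsystem_02"
  sub_rxns <- reaction_ids(net$model)[
    net$model$reactions$subsystem == sil_lab]
  sil_genes <- genes_of_reactions(net$model, sub_rxns)
  cv <- stats::setNames(rep("expressed", length(net$model$genes)),
                        net$model$genes)
  cv[sil_genes] <- "unexpressed"
  cm <- build_condition_model(net$model, gene_calls(cv), net$media,
                              protected = "DM_atp")
  # >= 80% of the silenced subsystem's reactions are gone
  lost <- setdiff(sub_rxns, cm$retained)
  expect_gte(length(lost) / length(sub_rxns), 0.8)
  expect_true("DM_atp" %in% cm$retained) # protected objective
  # every-gene-expressed: context = the consistent subnetwork
  all_on <- gene_calls(stats::setNames(rep("expressed",
                                           length(net$model$genes)),
                                       net$model$genes))
  cm_all <- build_condition_model(net$model, all_on, net$media,
                                  protected = "DM_atp")
  constrained <- apply_media(net$model, net$media)
  expect_setequal(cm_all$retained, find_consistent_subnetwork(constrained))
  # closed media: nothing can run; context model is empty
  cm_closed <- suppressWarnings(
    build_condition_model(net$model, all_on,
                          stats::setNames(numeric(), character())))
  expect_lte(length(cm_closed$retained), 0)
})
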