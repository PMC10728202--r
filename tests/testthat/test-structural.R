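ctx <- function(model, keep) {
  structure(list(parent = model, retained = keep,
                 derivation = list(core = keep, dropped_core = character(),
                                   tol = 1e-4)),
            class = "context_model")
}

test_that("condition_shared intersects element sets across a condition's models", {
  m <- parallel_routes_model()
  a <- ctx(m, c("EX_A", "T", "P1a", "P1b", "CORE", "EX_D"))
  b <- ctx(m, c("EX_A", "T", "P2", "CORE", "EX_D"))
  expect_setequal(condition_shared(list(a, b), "reactions"),
                  c("EX_A", "T", "CORE", "EX_D"))
  expect_setequal(condition_shared(list(a), "reactions"), a$retained)
  expect_setequal(condition_shared(list(a, b), "genes"), "gc")
  expect_setequal(condition_shared(list(ctx(m, "P1a"), ctx(m, "P2")),
                                   "reactions"), character())
  m2 <- toy_chain_model()
  expect_error(condition_shared(list(a, ctx(m2, "AB"))),
               "different reference")
})

test_that("condition_unique implements both comparison modes", {
  m <- parallel_routes_model()
  models_b <- list(ctx(m, "T"), ctx(m, "P2"))
  # shared_A = {EX_A, T}; union(B) = {T, P2}; shared(B) = {}
  expect_setequal(condition_unique(c("EX_A", "T"), models_b, "reactions",
                                   mode = "vs-union"), "EX_A")
  expect_setequal(condition_unique(c("EX_A", "T"), models_b, "reactions",
                                   mode = "vs-shared"), c("EX_A", "T"))
  expect_equal(condition_unique(character(), models_b, "reactions"),
               character())
})

test_that("uniqueness algebra holds on randomized set families", {
  m <- parallel_routes_model()
  ids <- reaction_ids(m)
  set.seed(123)
  for (i in 1:500) {
    models_a <- lapply(1:2, function(k) {
      ctx(m, sample(ids, sample(2:6, 1)))
    })
    models_b <- lapply(1:2, function(k) {
      ctx(m, sample(ids, sample(2:6, 1)))
    })
    sa <- condition_shared(models_a, "reactions")
    sb <- condition_shared(models_b, "reactions")
    for (mode in c("vs-union", "vs-shared")) {
      ua <- condition_unique(sa, models_b, "reactions", mode)
      ub <- condition_unique(sb, models_a, "reactions", mode)
      # disjointness and containment in the own shared set
      expect_length(intersect(ua, ub), 0)
      expect_true(all(ua %in% sa))
      expect_true(all(ub %in% sb))
      # conservation: shared splits into unique and the removed part
      expect_equal(length(sa), length(ua) + length(setdiff(sa, ua)))
    }
    # vs-union unique sets are contained in vs-shared unique sets
    expect_true(all(
      condition_unique(sa, models_b, "reactions", "vs-union") %in%
        condition_unique(sa, models_b, "reactions", "vs-shared")))
  }
})

test_that("subsystem attribution pools, sizes and sorts correctly", {
  spec <- synthetic_spec(seed = 2)
  m <- generate_network(spec)$model
  smap <- reaction_subsystems(m)
  s3 <- names(smap)[smap == "subsystem_03"]
  s1 <- names(smap)[smap == "subsystem_01"]
  tab <- subsystem_attribution(s3[1:2], character(), m)
  expect_equal(tab$subsystem, "subsystem_03")
  expect_equal(tab$pooled, 2)
  expect_equal(tab$size, length(s3))
  expect_equal(tab$percent_different, 100 * 2 / length(s3))
  # counts conserve across rows
  tab2 <- subsystem_attribution(c(s3[1:3], s1[1]), s1[2], m)
  expect_equal(sum(tab2$pooled), 5)
  expect_equal(tab2$subsystem[1], "subsystem_03") # sorted by pooled desc
  # empty input, empty table
  expect_equal(nrow(subsystem_attribution(character(), character(), m)), 0)
  # unassigned reactions pool under "(unassigned)"
  m2 <- toy_chain_model()
  m2$reactions$subsystem <- ""
  tab3 <- subsystem_attribution("AB", character(), m2)
  expect_equal(tab3$subsystem, "(unassigned)")
  expect_error(subsystem_attribution("ghost", character(), m), "absent")
})

test_that("subsystem selection uses strict thresholds, forcing and absence", {
  tab <- data.frame(subsystem = c("big_diff", "big_border", "small_diff"),
                    n_unique_a = c(6, 5, 8), n_unique_b = 0,
                    pooled = c(6, 5, 8), size = c(25, 25, 15),
                    percent_different = c(24, 20, 8 / 15 * 100))
  attr(tab, "reference_sizes") <- c(big_diff = 25L, big_border = 25L,
                                    small_diff = 15L, glycolysis = 30L)
  # 25 reactions / 24% different: in ; 25 / exactly 20%: out (strict >)
  # 15 reactions / 53%: out (size gate), unless forced
  expect_equal(select_subsystems(tab), "big_diff")
  expect_setequal(select_subsystems(tab, forced = "small_diff"),
                  c("big_diff", "small_diff"))
  # forced central-energy labels join even with no unique reactions at all
  expect_setequal(select_subsystems(tab, forced = "glycolysis"),
                  c("big_diff", "glycolysis"))
  expect_warning(sel <- select_subsystems(tab, forced = "made_up"),
                 "absent from reference")
  expect_equal(sel, "big_diff")
  # subsystems absent from one condition's models are excluded
  expect_equal(select_subsystems(tab, absent_in = list("big_diff",
                                                       character())),
               character())
  # the unassigned bucket never qualifies
  tab2 <- rbind(tab, data.frame(subsystem = "(unassigned)", n_unique_a = 30,
                                n_unique_b = 0, pooled = 30, size = 40,
                                percent_different = 75))
  attr(tab2, "reference_sizes") <- attr(tab, "reference_sizes")
  expect_equal(select_subsystems(tab2), "big_diff")
})

test_that("structural_diff on context models produces coherent venn counts", {
  spec <- synthetic_spec(seed = 4)
  net <- generate_network(spec)
  cons <- find_consistent_subnetwork(apply_media(net$model, net$media))
  lost <- net$truth$chain_reactions[["subsystem_03"]]
  full <- ctx(net$model, cons)
  reduced <- ctx(net$model, setdiff(cons, lost))
  d <- structural_diff(list(full, full), list(reduced, reduced))
  expect_setequal(d$reactions$unique_a, lost)
  expect_equal(d$reactions$unique_b, character())
  vc <- venn_counts(d)
  expect_equal(vc$unique_a[vc$kind == "reactions"], length(lost))
  # unique sets are disjoint and inside their shared sets, for every kind
  for (kind in c("genes", "reactions", "metabolites")) {
    expect_length(intersect(d[[kind]]$unique_a, d[[kind]]$unique_b), 0)
    expect_true(all(d[[kind]]$unique_a %in% d[[kind]]$shared_a))
  }
})
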