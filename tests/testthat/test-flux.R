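test_that("FBA reproduces the hand-computed ATP optimum", {
  m <- toy_atp_model(uptake = 10, yield = 2)
  sol <- fba(m, "DM")
  expect_equal(sol$objective_value, 20)
  expect_equal(unname(sol$fluxes["EX_A"]), -10)
  # closed media: optimum 0
  closed <- apply_media(m, stats::setNames(numeric(), character()))
  expect_equal(fba(closed, "DM")$objective_value, 0)
  # blocked objective: optimum 0
  m2 <- m
  m2$reactions$upper_bound[m2$reactions$id == "C"] <- 0
  expect_equal(fba(m2, "DM")$objective_value, 0)
  expect_error(fba(m, "nope"), "not in model")
})

test_that("FVA collapses to a point on an obligatory path at gamma = 1", {
  m <- toy_atp_model()
  frs <- fva(m, objective = "DM", gamma = 1)
  expect_equal(frs$ranges$vmin, frs$ranges$vmax, tolerance = 1e-8)
  expect_equal(frs$ranges$vmax[frs$ranges$reaction == "DM"], 20)
  # the FBA-optimal vector lies inside every range
  opt <- fba(m, "DM")$fluxes
  expect_true(all(opt >= frs$ranges$vmin - 1e-8 &
                    opt <= frs$ranges$vmax + 1e-8))
})

test_that("two equal-yield parallel routes each span [0, full flux] at gamma 1", {
  m <- parallel_routes_model()
  # force total flow: make CORE the objective; both routes can carry it
  frs <- fva(m, objective = "CORE", gamma = 1)
  r <- frs$ranges
  expect_equal(r$vmax[r$reaction == "CORE"], 10)
  for (rid in c("P1a", "P1b", "P2")) {
    expect_equal(r$vmin[r$reaction == rid], 0, tolerance = 1e-8)
    expect_equal(r$vmax[r$reaction == rid], 10, tolerance = 1e-8)
  }
})

test_that("FVA bounds match the brute-force HiGHS oracle on every bundled network", {
  for (m in all_fixture_models()) {
    objective <- utils::tail(setdiff(reaction_ids(m),
                                     exchange_reactions(m)), 1)
    for (gamma in c(1, 0.9)) {
      mine <- fva(m, objective = objective, gamma = gamma)$ranges
      oracle <- scipy_fva(m, objective = objective, gamma = gamma)
      expect_equal(mine$vmin, oracle$vmin, tolerance = 1e-6,
                   info = paste(m$name, gamma))
      expect_equal(mine$vmax, oracle$vmax, tolerance = 1e-6,
                   info = paste(m$name, gamma))
    }
  }
})

test_that("ranges nest as the optimality requirement relaxes", {
  m <- toy_atp_model()
  tight <- fva(m, objective = "DM", gamma = 1)$ranges
  loose <- fva(m, objective = "DM", gamma = 0.9)$ranges
  free <- fva(m, objective = "DM", gamma = 1e-9)$ranges
  expect_true(all(loose$vmin <= tight$vmin + 1e-9))
  expect_true(all(loose$vmax >= tight$vmax - 1e-9))
  expect_true(all(free$vmin <= loose$vmin + 1e-9))
  expect_true(all(free$vmax >= loose$vmax - 1e-9))
})

test_that("similarity index reproduces its analytic endpoints and oracle", {
  expect_equal(similarity_index(c(0, 5), c(0, 5)), 1)
  expect_equal(similarity_index(c(0, 1), c(2, 3)), 0)
  expect_equal(similarity_index(c(0, 2), c(1, 3)), 1 / 3)
  # identical point ranges with eps = 0: defined as 1 by continuity
  expect_equal(similarity_index(c(1, 1), c(1, 1)), 1)
  # id mismatch is a usage error
  expect_error(similarity_index(list(reaction = "a", vmin = 0, vmax = 1),
                                list(reaction = "b", vmin = 0, vmax = 1)),
               "different reactions")
  expect_error(similarity_index(c(2, 1), c(0, 1)), "vmin")

  set.seed(99)
  for (i in 1:300) {
    a <- sort(stats::rnorm(2, sd = 10))
    b <- sort(stats::rnorm(2, sd = 10))
    eps <- sample(c(0, 0.1), 1)
    si <- similarity_index(a, b, eps)
    expect_equal(si, si_oracle(a, b, eps), tolerance = 1e-12)
    expect_gte(si, 0)
    expect_lte(si, 1)
    # symmetry and translation invariance
    expect_equal(si, similarity_index(b, a, eps))
    expect_equal(si, similarity_index(a + 7, b + 7, eps), tolerance = 1e-9)
    expect_equal(similarity_index(a, a, eps), 1)
  }
})

fake_frs <- function(id, df, gamma = 1) {
  structure(list(model_id = id, objective = "obj", gamma = gamma,
                 optimum = NA_real_, ranges = df),
            class = "flux_range_set")
}

test_that("subsystem similarity averages shared reactions and NA-flags empty ones", {
  ra <- data.frame(reaction = c("r1", "r2", "r3"),
                   vmin = c(0, 0, 0), vmax = c(5, 1, 2))
  rb <- data.frame(reaction = c("r1", "r2", "r4"),
                   vmin = c(0, 2, 0), vmax = c(5, 3, 2))
  smap <- c(r1 = "S1", r2 = "S1", r3 = "S2", r4 = "S3")
  out <- subsystem_similarity(fake_frs("A", ra), fake_frs("B", rb), smap)
  # S1: shared r1 (SI 1) and r2 (SI 0) -> 0.5 ; S2, S3: no shared -> NA
  expect_equal(out$si[out$subsystem == "S1"], 0.5)
  expect_true(is.na(out$si[out$subsystem == "S2"]))
  expect_true(is.na(out$si[out$subsystem == "S3"]))
  # identical sets: every subsystem with shared reactions scores 1
  same <- subsystem_similarity(fake_frs("A", ra), fake_frs("A", ra), smap)
  expect_true(all(same$si[!is.na(same$si)] == 1))
  # pooled aggregation: S1 pooled ranges A [0,5] vs B [0,5] -> 1
  pooled <- subsystem_similarity(fake_frs("A", ra), fake_frs("B", rb), smap,
                                 aggregation = "pooled")
  expect_equal(pooled$si[pooled$subsystem == "S1"], 1)
  expect_error(
    subsystem_similarity(fake_frs("A", ra, gamma = 1),
                         fake_frs("B", rb, gamma = 0.5), smap),
    "different gamma")
})

test_that("group comparison emits all pairs plus the cross-group mean", {
  rng <- function(lo, hi) data.frame(reaction = c("r1", "r2"),
                                     vmin = lo, vmax = hi)
  sets <- list(C1 = fake_frs("C1", rng(0, 10)),
               C2 = fake_frs("C2", rng(0, 8)),
               P1 = fake_frs("P1", rng(0, 4)),
               P2 = fake_frs("P2", rng(0, 2)))
  groups <- c(C1 = "CTRL", C2 = "CTRL", P1 = "PD", P2 = "PD")
  smap <- c(r1 = "S1", r2 = "S1")
  tab <- group_comparison(sets, groups, smap)
  expect_setequal(attr(tab, "cross_pairs"),
                  c("C1.vs.P1", "C1.vs.P2", "C2.vs.P1", "C2.vs.P2"))
  expect_equal(tab$mean_cross,
               unname(rowMeans(tab[, attr(tab, "cross_pairs")])))
  expect_equal(tab$C1.vs.P1, 0.4) # overlap 4 / union 10
  expect_equal(tab$within_CTRL, 0.8)
  # identical models everywhere: all ones
  same <- group_comparison(list(C1 = sets$C1, C2 = sets$C1,
                                P1 = sets$C1, P2 = sets$C1),
                           groups, smap)
  cols <- setdiff(names(same), "subsystem")
  expect_true(all(as.matrix(same[, cols]) == 1))
  # a one-model group loses its within column, with a note
  expect_message(
    solo <- group_comparison(sets[c("C1", "P1", "P2")],
                             groups, smap),
    "within-group column omitted")
  expect_false("within_CTRL" %in% names(solo))
})

test_that("a planted flux restriction lowers cross-group SI below within-group SI", {
  spec <- synthetic_spec(seed = 8)
  net <- generate_network(spec)
  constrained <- apply_media(net$model, net$media)
  full_cons <- find_consistent_subnetwork(constrained)
  full <- subset_model(constrained, full_cons, name = "full")
  # patient-like models: subsystem_03's chain removed, leak kept
  lost <- net$truth$chain_reactions[["subsystem_03"]]
  reduced <- subset_model(constrained, setdiff(full_cons, lost),
                          name = "reduced")
  smap <- reaction_subsystems(net$model)
  scan <- intersect(reaction_ids(reduced),
                    names(smap)[smap == "subsystem_03"])
  sets <- list(
    C1 = fva(full, "DM_atp", gamma = 0.9, reactions = scan),
    C2 = fva(full, "DM_atp", gamma = 0.9, reactions = scan),
    P1 = fva(reduced, "DM_atp", gamma = 0.9, reactions = scan),
    P2 = fva(reduced, "DM_atp", gamma = 0.9, reactions = scan))
  tab <- group_comparison(sets, c(C1 = "CTRL", C2 = "CTRL",
                                  P1 = "PD", P2 = "PD"), smap,
                          subsystems = "subsystem_03")
  expect_lt(tab$mean_cross, tab$within_CTRL)
  expect_lt(tab$mean_cross, tab$within_PD)
})
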