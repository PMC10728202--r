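toy_tpm <- function() {
  m <- matrix(c(0, 0, 0,      # gA: all-zero -> filtered
                0, 0.1, 0,    # gB: one nonzero replicate -> kept
                1, 2, 3,      # gC
                1, 2, 10,     # gD
                100, 90, 110, # gE
                7, 7, 7),     # gF
              ncol = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC", "gD", "gE", "gF"),
                              c("s1_r1", "s1_r2", "s1_r3")))
  m
}

test_that("zero filtering removes exactly the all-zero rows", {
  em <- toy_tpm()
  out <- filter_zero_genes(em, colnames(em))
  expect_setequal(rownames(out), c("gB", "gC", "gD", "gE", "gF"))
  expect_equal(out["gC", ], em["gC", ]) # untouched values
  expect_error(filter_zero_genes(em, "nope"), "unknown sample")
  expect_error(filter_zero_genes(em, character()), "non-empty")
  empty <- em[0, , drop = FALSE]
  expect_equal(nrow(filter_zero_genes(empty)), 0)
})

test_that("replicate aggregation is the median, midpoint on even counts", {
  em <- toy_tpm()
  med <- aggregate_replicates(em, colnames(em))
  expect_equal(unname(med["gC"]), 2)
  expect_equal(unname(med["gF"]), 7)
  em4 <- cbind(em, s1_r4 = c(0, 0, 10, 3, 95, 7))
  expect_equal(unname(aggregate_replicates(em4)["gC"]), 2.5) # (2+3)/2
  one <- em[, 1, drop = FALSE]
  expect_equal(unname(aggregate_replicates(one)["gF"]), 7)
})

test_that("isoform collapse takes the highest median, ties to smallest id", {
  profile <- c(t1 = 4, t2 = 9, u1 = 5, u2 = 5, v1 = 3)
  map <- data.frame(transcript = c("t1", "t2", "u1", "u2"),
                    gene = c("G", "G", "U", "U"))
  out <- collapse_isoforms(profile, map)
  expect_equal(unname(out["G"]), 9)
  expect_equal(unname(out["U"]), 5)
  expect_equal(attr(out, "chosen_isoform")[["U"]], "u1") # tie-break
  expect_equal(unname(out["v1"]), 3) # unmapped passes through
  expect_equal(attr(out, "unmapped"), "v1")
  # no map: identity
  expect_equal(as.numeric(collapse_isoforms(profile)), unname(profile))
})

test_that("percentile discretization thresholds on nonzero values", {
  # nonzero set {1, 100}: the type-7 median is 50.5
  cs <- discretize_expression(c(a = 0, b = 1, c = 100), "percentile", p = 50)
  expect_equal(cs$calls, c(a = "unexpressed", b = "unexpressed",
                           c = "expressed"))
  expect_equal(cs$provenance$threshold, 50.5)
  # all-equal nonzero profile: every value equals its percentile -> expressed
  cs2 <- discretize_expression(c(a = 5, b = 5, c = 5), "percentile")
  expect_true(all(cs2$calls == "expressed"))
  # boundary inclusive: value exactly at the threshold is expressed
  cs3 <- discretize_expression(c(a = 1, b = 2, c = 3), "percentile", p = 50)
  expect_equal(unname(cs3$calls["b"]), "expressed")
  expect_error(discretize_expression(numeric()), "non-empty")
})

test_that("percentile calls are monotone in a single replicate bump", {
  set.seed(42)
  em <- matrix(2^stats::rnorm(60, 4, 2), ncol = 3,
               dimnames = list(sprintf("g%02d", 1:20),
                               c("s_r1", "s_r2", "s_r3")))
  med <- aggregate_replicates(em)
  thr <- stats::quantile(med[med > 0], 0.5, type = 7, names = FALSE)
  base <- discretize_expression(med, "percentile")$calls
  for (g in sample(rownames(em), 5)) {
    em2 <- em
    em2[g, 2] <- em2[g, 2] * 10
    med2 <- aggregate_replicates(em2)
    # threshold from the unmodified background
    bumped <- ifelse(med2 >= thr & med2 > 0, "expressed", "unexpressed")
    if (base[g] == "expressed") expect_equal(unname(bumped[g]), "expressed")
  }
})

test_that("mixture discretization recovers a planted bimodal split", {
  spec <- synthetic_spec(seed = 3)
  net <- generate_network(spec)
  expr <- generate_expression(net$model, spec, net$truth)
  cols <- paste0("CTRL1_r", 1:3)
  med <- aggregate_replicates(filter_zero_genes(expr$tpm, cols), cols)
  cs <- discretize_expression(med, method = "mixture")
  planted <- ifelse(grepl("^decoy_", names(med)), "unexpressed", "expressed")
  agreement <- mean(cs$calls == planted)
  expect_gte(agreement, 0.95)
})

test_that("degenerate mixture input falls back to the percentile rule", {
  expect_warning(cs <- discretize_expression(c(a = 3, b = 3, c = 0),
                                             method = "mixture"),
                 "degenerate")
  expect_equal(cs$provenance$fallback, "percentile")
  expect_equal(unname(cs$calls), c("expressed", "expressed", "unexpressed"))
})

test_that("the per-line pipeline runs filter, median, collapse, discretize in order", {
  # worked 6-gene fixture: values chosen so any stage reordering would
  # change the outcome (e.g. discretizing before the zero filter shifts
  # the percentile threshold)
  em <- toy_tpm()
  map <- data.frame(transcript = c("gC", "gD"), gene = c("GCD", "GCD"))
  cs <- calls_for_sample(em, colnames(em), isoform_map = map)
  # medians: gB 0, GCD = max(2, 2) = 2, gE 100, gF 7; nonzero {2, 7, 100}
  # threshold (p50, type 7) = 7 -> expressed: gE and gF (boundary value)
  expect_equal(cs$calls[order(names(cs$calls))],
               c(GCD = "unexpressed", gB = "unexpressed",
                 gE = "expressed", gF = "expressed"))
  expect_equal(cs$provenance$threshold, 7)
  # identical inputs give identical calls
  expect_identical(cs, calls_for_sample(em, colnames(em), isoform_map = map))
})
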