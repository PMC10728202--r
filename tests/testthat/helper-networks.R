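# Fixture networks built in code. All are small enough for exhaustive
# oracles (<= 12 reactions).

# A_ex <-> A, A -> B, B_sink: 3 reactions, 2 metabolites, 2 exchanges
toy_chain_model <- function() {
  rx <- data.frame(id = c("A_ex", "AB", "B_sink"),
                   lower_bound = c(-10, 0, 0),
                   upper_bound = c(1000, 1000, 1000),
                   gpr = c("", "g1", ""),
                   subsystem = c("exchange", "conversion", "exchange"),
                   stringsAsFactors = FALSE)
  S <- matrix(0, 2, 3, dimnames = list(c("A[c]", "B[c]"), rx$id))
  S["A[c]", "A_ex"] <- -1
  S["A[c]", "AB"] <- -1
  S["B[c]", "AB"] <- 1
  S["B[c]", "B_sink"] <- -1
  metabolic_model(rx, rownames(S), S, name = "toy_chain")
}

# carbon backbone with 2 ATP per carbon: EX_A, transport, central, demand
toy_atp_model <- function(uptake = 10, yield = 2) {
  rx <- data.frame(id = c("EX_A", "T", "C", "DM"),
                   lower_bound = c(-uptake, 0, 0, 0),
                   upper_bound = 1000,
                   gpr = c("", "g_t", "g_c1 and g_c2", ""),
                   subsystem = c("exchange", "transport", "central",
                                 "exchange"),
                   stringsAsFactors = FALSE)
  S <- matrix(0, 3, 4, dimnames = list(c("A[e]", "A[c]", "atp[c]"), rx$id))
  S["A[e]", "EX_A"] <- -1
  S["A[e]", "T"] <- -1
  S["A[c]", "T"] <- 1
  S["A[c]", "C"] <- -1
  S["atp[c]", "C"] <- yield
  S["atp[c]", "DM"] <- -1
  metabolic_model(rx, rownames(S), S, name = "toy_atp")
}

# one core reaction sustainable through either a 2-step or a 1-step route
parallel_routes_model <- function() {
  rx <- data.frame(
    id = c("EX_A", "T", "P1a", "P1b", "P2", "CORE", "EX_D"),
    lower_bound = c(-10, 0, 0, 0, 0, 0, 0),
    upper_bound = 1000,
    gpr = c("", "", "g1a", "g1b", "g2", "gc", ""),
    subsystem = c("exchange", "transport", "route1", "route1", "route2",
                  "core", "exchange"),
    stringsAsFactors = FALSE)
  mets <- c("A[e]", "A[c]", "B[c]", "C[c]", "D[e]")
  S <- matrix(0, 5, 7, dimnames = list(mets, rx$id))
  S["A[e]", "EX_A"] <- -1
  S["A[e]", "T"] <- -1;  S["A[c]", "T"] <- 1
  S["A[c]", "P1a"] <- -1; S["B[c]", "P1a"] <- 1
  S["B[c]", "P1b"] <- -1; S["C[c]", "P1b"] <- 1
  S["A[c]", "P2"] <- -1;  S["C[c]", "P2"] <- 1
  S["C[c]", "CORE"] <- -1; S["D[e]", "CORE"] <- 1
  S["D[e]", "EX_D"] <- -1
  metabolic_model(rx, mets, S, name = "parallel_routes")
}

# a reversible reaction that can only ever run backwards: F <-> E written
# in the E -> F direction, but only E is supplied and only F is drained
reversible_backwards_model <- function() {
  rx <- data.frame(id = c("EX_E", "T_E", "R_rev", "SINK_F", "EX_G"),
                   lower_bound = c(-10, 0, -1000, 0, 0),
                   upper_bound = c(1000, 1000, 1000, 1000, 1000),
                   gpr = c("", "", "gr", "", ""),
                   subsystem = "",
                   stringsAsFactors = FALSE)
  mets <- c("E[e]", "E[c]", "F[c]", "G[e]")
  S <- matrix(0, 4, 5, dimnames = list(mets, rx$id))
  S["E[e]", "EX_E"] <- -1
  S["E[e]", "T_E"] <- -1; S["E[c]", "T_E"] <- 1
  S["F[c]", "R_rev"] <- -1; S["E[c]", "R_rev"] <- 1 # forward: F -> E
  S["F[c]", "SINK_F"] <- -1; S["G[e]", "SINK_F"] <- 1
  S["G[e]", "EX_G"] <- -1
  metabolic_model(rx, mets, S, name = "reversible_backwards")
}

# isolated C -> D with no boundary for either metabolite: dead end
dead_end_model <- function() {
  rx <- data.frame(id = c("A_ex", "AB", "B_sink", "CD"),
                   lower_bound = c(-10, 0, 0, 0), upper_bound = 1000,
                   gpr = "", subsystem = "",
                   stringsAsFactors = FALSE)
  mets <- c("A[c]", "B[c]", "C[c]", "D[c]")
  S <- matrix(0, 4, 4, dimnames = list(mets, rx$id))
  S["A[c]", "A_ex"] <- -1
  S["A[c]", "AB"] <- -1; S["B[c]", "AB"] <- 1
  S["B[c]", "B_sink"] <- -1
  S["C[c]", "CD"] <- -1; S["D[c]", "CD"] <- 1
  metabolic_model(rx, mets, S, name = "dead_end")
}

# random sparse network; seeds make cases reproducible
random_model <- function(m, n, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      k <- sample(1:2, 1)
      rows <- sample(seq_len(m), min(k + 1, m))
      S[rows, j] <- sample(c(-2, -1, 1, 2), length(rows), replace = TRUE)
    }
    lb <- ifelse(stats::runif(n) < 0.35,
                 -sample(c(5, 10, 1000), n, replace = TRUE), 0)
    ub <- sample(c(5, 10, 1000), n, replace = TRUE)
    rx <- data.frame(id = sprintf("r%02d", seq_len(n)), lower_bound = lb,
                     upper_bound = ub, stringsAsFactors = FALSE)
    mm <- try(metabolic_model(rx, sprintf("m%02d[c]", seq_len(m)), S,
                              name = paste0("rand", seed)),
              silent = TRUE)
    if (!inherits(mm, "try-error")) return(mm)
  }
}

all_fixture_models <- function() {
  list(toy_chain = toy_chain_model(),
       toy_atp = toy_atp_model(),
       parallel = parallel_routes_model(),
       reversible = reversible_backwards_model(),
       dead_end = dead_end_model())
}
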