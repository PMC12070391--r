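# Independent oracles and shared micro-fixtures.

# Hand-solvable three-reaction model: a single substrate A is imported
# (uptake capped at 10), transported and drained by the objective reaction.
# The unique optimum is v = (-10, 10, 10) with objective 10.
tiny_chain_model <- function() {
  metabolic_model(
    "tiny",
    compartments = list(compartment("e"), compartment("c")),
    metabolites = list(metabolite("A_e", "e"), metabolite("A_c", "c")),
    reactions = list(
      reaction("EX_A", c(A_e = -1), -10, 0),
      reaction("T_A", c(A_e = -1, A_c = 1), 0, 1000),
      reaction("SINK_A", c(A_c = -1), 0, 1000)),
    objective = c(SINK_A = 1))
}

# Exact upper-tail hypergeometric probability P(X >= k) by direct
# combinatorial summation (binomial coefficients are exact in doubles for
# N <= 25), independent of phyper.
hyper_tail_oracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- seq(max(k, max(0, n - (N - K))), hi)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Closed-form two-sided Mann-Whitney p-value (normal approximation with
# continuity correction, the wilcox.test(exact = FALSE) convention) for two
# fully separated samples of sizes n and m.
mw_p_separated <- function(n, m) {
  U <- n * m
  mu <- U / 2
  sigma <- sqrt(n * m * (n + m + 1) / 12)
  2 * stats::pnorm(-(U - mu - 0.5) / sigma)
}

# Field-by-field model equality (order-insensitive within id spaces).
expect_models_equal <- function(a, b) {
  expect_setequal(names(a$compartments), names(b$compartments))
  expect_setequal(names(a$metabolites), names(b$metabolites))
  expect_setequal(names(a$reactions), names(b$reactions))
  for (id in names(a$metabolites)) {
    expect_identical(a$metabolites[[id]]$compartment,
                     b$metabolites[[id]]$compartment)
    expect_identical(a$metabolites[[id]]$name, b$metabolites[[id]]$name)
  }
  for (id in names(a$reactions)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    ka <- sort(names(ra$stoichiometry))
    expect_identical(ra$stoichiometry[ka], rb$stoichiometry[ka])
    expect_equal(ra$lower_bound, rb$lower_bound)
    expect_equal(ra$upper_bound, rb$upper_bound)
    expect_identical(ra$pathway, rb$pathway)
    expect_identical(ra$gpr, rb$gpr)
    expect_identical(ra$name, rb$name)
  }
  ko <- sort(names(a$objective))
  expect_identical(ko, sort(names(b$objective)))
  expect_equal(a$objective[ko], b$objective[ko])
  expect_setequal(names(a$constraints), names(b$constraints))
  for (id in names(a$constraints)) {
    ca <- a$constraints[[id]]; cb <- b$constraints[[id]]
    kc <- sort(names(ca$coefficients))
    expect_equal(ca$coefficients[kc], cb$coefficients[kc])
    expect_equal(ca$lower, cb$lower)
    expect_equal(ca$upper, cb$upper)
  }
}

# A random valid little model (chain of k metabolites with entry and exit),
# for property-style duplication tests.
random_chain_model <- function(seed) {
  set.seed(seed)
  k <- sample(2:6, 1)
  n_comp <- sample(1:3, 1)
  comps <- lapply(seq_len(n_comp), function(i) compartment(sprintf("c%d", i)))
  mets <- lapply(seq_len(k), function(i)
    metabolite(sprintf("M%d", i), sprintf("c%d", sample(n_comp, 1))))
  rxns <- c(
    list(reaction("IN", c(M1 = 1), 0, round(stats::runif(1, 1, 50), 2))),
    lapply(seq_len(k - 1), function(i)
      reaction(sprintf("R%d", i),
               stats::setNames(c(-1, 1), c(sprintf("M%d", i),
                                           sprintf("M%d", i + 1))),
               0, 1000)),
    list(reaction("OUT", stats::setNames(-1, sprintf("M%d", k)), 0, 1000)))
  metabolic_model(sprintf("rand%d", seed), comps, mets, rxns,
                  objective = c(OUT = 1))
}
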