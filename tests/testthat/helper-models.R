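# Shared fixtures and comparators for the suite.

# tiny 5-reaction toy with one catalysed reversible reaction, used for the
# split-reversible net-flux oracle
toy_reversible_model <- function() {
  sp <- rbind(
    species("a", role = "balanced"),
    species("b", role = "balanced"),
    species("E", weight = 1, contributes_to_weight = TRUE),
    species("P", weight = 0.5, contributes_to_weight = TRUE))
  rx <- list(
    reaction("in_a", c(a = 1), lb = 0, ub = 10),
    reaction("a2b", c(a = -1, b = 1), reversible = TRUE, lb = -10, ub = 10),
    reaction("b2E", c(b = -1, E = 1), lb = 0, ub = 5),
    reaction("b2P", c(b = -1, P = 1), lb = 0, ub = 5),
    reaction("swap", c(a = -1, b = 1), reversible = TRUE, lb = -3, ub = 3))
  cap <- capacity_rule("a2b", "E", 2)
  cfba_model(sp, rx, capacity = cap)
}

# structural equality up to row order of the rule/segment tables
expect_same_model <- function(m1, m2) {
  expect_equal(m1$species, m2$species)
  expect_equal(names(m1$reactions), names(m2$reactions))
  for (id in names(m1$reactions)) {
    r1 <- m1$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_identical(r1$reversible, r2$reversible)
    expect_identical(r1$lb, r2$lb)
    expect_identical(r1$ub, r2$ub)
    expect_identical(sort(names(r1$stoichiometry)),
                     sort(names(r2$stoichiometry)))
    expect_identical(r1$stoichiometry[sort(names(r1$stoichiometry))],
                     r2$stoichiometry[sort(names(r2$stoichiometry))])
  }
  ord <- function(df, cols) df[do.call(order, df[cols]), , drop = FALSE]
  c1 <- ord(m1$capacity, "reaction_id"); rownames(c1) <- NULL
  c2 <- ord(m2$capacity, "reaction_id"); rownames(c2) <- NULL
  expect_identical(c1, c2)
  q1 <- ord(m1$quotas, c("species_id", "kind")); rownames(q1) <- NULL
  q2 <- ord(m2$quotas, c("species_id", "kind")); rownames(q2) <- NULL
  expect_identical(q1, q2)
  e1 <- ord(m1$environment, c("reaction_id", "t_start")); rownames(e1) <- NULL
  e2 <- ord(m2$environment, c("reaction_id", "t_start")); rownames(e2) <- NULL
  expect_identical(e1, e2)
  expect_identical(m1$initial_weight, m2$initial_weight)
  expect_identical(m1$exempt_storage_from_cycle, m2$exempt_storage_from_cycle)
}

# the parameterization used for randomized property loops
property_model <- function(s, with_quotas = s %% 3 == 0) {
  random_model(s, n_balanced = 1 + s %% 2, n_imbalanced = 2 + s %% 2,
               n_reactions = 4 + s %% 3, with_quotas = with_quotas)
}

# capacity-limited variant: weight rescaling is an exact symmetry of the
# program only when no finite nonzero flux bound pins the scale
uncap_bounds <- function(m) {
  for (id in names(m$reactions)) {
    m$reactions[[id]]$ub <- Inf
    m$reactions[[id]]$lb <- if (m$reactions[[id]]$reversible) -Inf else 0
  }
  m
}
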