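test_that("validate_model accepts the minimal-cell fixture and flags broken models", {
  mc <- minimal_cell_model()
  expect_identical(nrow(validate_model(mc$model)), 0L)

  # capacity rule whose catalyst is a balanced species
  bad_cap <- cfba_model(
    rbind(species("m", role = "balanced"),
          species("x", weight = 1, contributes_to_weight = TRUE)),
    list(reaction("r", c(m = -1, x = 1))),
    capacity = capacity_rule("r", "m", 1))
  d <- validate_model(bad_cap)
  expect_identical(sum(d$severity == "error"), 1L)
  expect_match(d$message[1], "imbalanced")

  # quota fraction outside [0, 1]
  bad_quota <- cfba_model(
    species("x", weight = 1, contributes_to_weight = TRUE),
    list(reaction("r", c(x = 1), ub = 1)),
    quotas = quota("x", "min", 1.3))
  d2 <- validate_model(bad_quota)
  expect_identical(sum(d2$severity == "error"), 1L)
  expect_match(d2$message[1], "\\[0, 1\\]")
})

test_that("validate_model catches dangling references, bad weights and bounds", {
  m <- cfba_model(
    rbind(species("m", role = "balanced"),
          species("x", weight = 1, contributes_to_weight = TRUE)),
    list(reaction("r", c(m = -1, ghost = 1)),          # unknown species
         reaction("r2", c(x = 1), lb = 2, ub = 1)),    # lb > ub
    environment = environment_profile("nope", 0, 1, 0, 1))
  d <- validate_model(m)
  expect_true(any(grepl("unknown species", d$message)))
  expect_true(any(grepl("lb exceeds ub", d$message)))
  expect_true(any(d$location == "environment:nope"))
  expect_error(assert_valid(m), "invalid cFBA model")

  # balanced species must not carry weight; zero-weight must not contribute
  sp <- species("m", role = "balanced")
  sp$weight <- 2
  d3 <- validate_model(cfba_model(
    rbind(sp, species("x", weight = 1, contributes_to_weight = TRUE)),
    list(reaction("r", c(x = 1), ub = 1))))
  expect_true(any(grepl("must not carry a weight", d3$message)))
})

test_that("split_reversible_catalysed splits only catalysed reversible reactions", {
  m <- toy_reversible_model()
  s <- split_reversible_catalysed(m)
  expect_setequal(names(s$reactions),
                  c("in_a", "a2b_fwd", "a2b_rev", "b2E", "b2P", "swap"))
  # bounds [-10, 10] become two [0, 10] columns, each carrying the rule
  expect_identical(s$reactions$a2b_fwd$lb, 0)
  expect_identical(s$reactions$a2b_fwd$ub, 10)
  expect_identical(s$reactions$a2b_rev$lb, 0)
  expect_identical(s$reactions$a2b_rev$ub, 10)
  expect_identical(s$reactions$a2b_rev$stoichiometry,
                   -s$reactions$a2b_fwd$stoichiometry)
  cap <- s$capacity[order(s$capacity$reaction_id), ]
  expect_identical(cap$reaction_id, c("a2b_fwd", "a2b_rev"))
  expect_identical(cap$kcat, c(2, 2))
  # uncatalysed reversible reaction untouched
  expect_true(s$reactions$swap$reversible)
  expect_identical(nrow(validate_model(s)), 0L)
})

test_that("splitting preserves net stoichiometric production (matrix oracle)", {
  m <- toy_reversible_model()
  s <- split_reversible_catalysed(m)
  S0 <- as.matrix(stoich_matrix(m))
  S1 <- as.matrix(stoich_matrix(s))
  set.seed(11)
  for (rep in 1:20) {
    v1 <- stats::runif(ncol(S1), 0, 5)        # any split flux vector
    v0 <- stats::setNames(numeric(ncol(S0)), colnames(S0))
    for (id in colnames(S0)) {
      v0[id] <- if (id %in% colnames(S1)) v1[match(id, colnames(S1))] else
        v1[match(paste0(id, "_fwd"), colnames(S1))] -
        v1[match(paste0(id, "_rev"), colnames(S1))]
    }
    expect_equal(as.numeric(S1 %*% v1), as.numeric(S0 %*% v0),
                 tolerance = 1e-12)
  }
})

test_that("split_reversible_catalysed is idempotent and identity without reversibles", {
  m <- toy_reversible_model()
  s1 <- split_reversible_catalysed(m)
  s2 <- split_reversible_catalysed(s1)
  expect_same_model(s1, s2)
  mc <- minimal_cell_model()$model       # no reversible reactions at all
  expect_same_model(mc, split_reversible_catalysed(mc))
})

test_that("bounds_at follows the half-open segment convention", {
  mc <- minimal_cell_model(minimal_cell_params(feed_end = 2, feed_ub = 10))
  expect_identical(bounds_at(mc$model, "uptake", 1.5), c(0, 10))
  expect_identical(bounds_at(mc$model, "uptake", 0), c(0, 10))
  expect_identical(bounds_at(mc$model, "uptake", 2.0), c(0, 0))  # default after feed
  expect_identical(bounds_at(mc$model, "store", 3.7), c(0, Inf)) # no profile
  expect_error(bounds_at(mc$model, "nope", 1), "unknown reaction")

  # adjacent segments: the right one wins at the shared node
  m <- cfba_model(
    species("x", weight = 1, contributes_to_weight = TRUE),
    list(reaction("r", c(x = 1), ub = 1)),
    environment = environment_profile("r", c(0, 2), c(2, 4), c(0, 0), c(5, 7)))
  expect_identical(bounds_at(m, "r", 2), c(0, 7))
  # total over the whole cycle
  for (t in seq(0, 3.99, by = 0.37))
    expect_length(bounds_at(m, "r", t), 2L)
})

test_that("weight vector covers contributing imbalanced species only", {
  mc <- minimal_cell_model()$model
  w <- weight_vector(mc)
  expect_named(w, c("storage", "enzymes", "biomass"))
  expect_identical(unname(w), c(0, 0, 1))  # lean-biomass accounting
  expect_true(all(w >= 0))
  for (s in 0:4) {
    m <- property_model(s)
    wv <- weight_vector(m)
    contrib <- m$species$contributes_to_weight[m$species$role == "imbalanced"]
    expect_identical(unname(wv > 0), contrib)
  }
})

test_that("time grids are validated and support non-uniform nodes", {
  g <- time_grid(0, 4, 8)
  expect_identical(g$n_steps, 8L)
  expect_equal(sum(g$dt), 4)
  gn <- time_grid(0, 1, 3, nodes = c(0, 0.5, 0.75, 1))
  expect_equal(gn$dt, c(0.5, 0.25, 0.25))
  expect_error(time_grid(1, 1, 4), "t0 < t_end")
  expect_error(time_grid(0, 1, 0), "n_steps")
  expect_error(time_grid(0, 1, 2, nodes = c(0, 0.6, 0.5, 1)), "increasing")
})
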