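test_that("build_lp emits the hand-derived constraint set for the N=1 self-replicator", {
  fx <- self_replicator(kcat = 1, n_steps = 1, t_end = 1)
  lp <- build_lp(fx$model, fx$grid, mu = 1.5)
  # 1 flux variable + 2 amount variables
  expect_identical(lp$n_var, 3L)
  expect_setequal(lp$label,
                  c("EQ1", "EQ2[E]", "DYN[E,k=0]", "CAP[make_E,k=0]",
                    "BOUND[make_E,k=0,lb]", "NONNEG[E,k=0]", "NONNEG[E,k=1]"))
  A <- as.matrix(lp$A)
  rownames(A) <- lp$label
  # variables: v[make_E,0], M[E,0], M[E,1]
  expect_equal(A["EQ1", ], c(0, 1, 0), ignore_attr = TRUE)          # w = 1
  expect_equal(lp$rhs[lp$label == "EQ1"], 1)
  expect_equal(A["EQ2[E]", ], c(0, -1.5, 1), ignore_attr = TRUE)    # M1 = mu M0
  expect_equal(A["DYN[E,k=0]", ], c(-1, -1, 1), ignore_attr = TRUE) # M1 = M0 + dt v
  expect_equal(A["CAP[make_E,k=0]", ], c(1, -1, 0), ignore_attr = TRUE)
  expect_identical(lp$sense[lp$label == "CAP[make_E,k=0]"], "<=")
})

test_that("build_lp validates its inputs", {
  fx <- self_replicator()
  expect_error(build_lp(fx$model, fx$grid, mu = 0), "mu must be > 0")
  expect_error(build_lp(fx$model, fx$grid, mu = -1), "mu must be > 0")
  m <- toy_reversible_model()
  expect_error(build_lp(m, time_grid(0, 1, 2), 1), "split_reversible_catalysed")
})

test_that("a reaction-free model is feasible exactly at mu = 1", {
  m <- cfba_model(
    species("x", weight = 2, contributes_to_weight = TRUE),
    list(reaction("frozen", c(x = 1), lb = 0, ub = 0)))
  g <- time_grid(0, 1, 3)
  opts <- solve_options()
  expect_true(is_feasible(build_lp(m, g, 1), opts)$feasible)
  expect_false(is_feasible(build_lp(m, g, 1 + 1e-4), opts)$feasible)
  expect_false(is_feasible(build_lp(m, g, 1 - 1e-4), opts)$feasible)
  traj <- maximize_mu(m, g)
  expect_equal(traj$mu_star, 1, tolerance = 2e-6)
})

test_that("QSS rows exist only for balanced metabolites", {
  mc <- minimal_cell_model()
  lp <- build_lp(mc$model, mc$grid, 2)
  qss <- lp$label[lp$tag == "QSS"]
  expect_length(qss, mc$grid$n_steps)
  expect_true(all(grepl("^QSS\\[intermediate,", qss)))
})

test_that("is_feasible matches the hand-solved self-replicator cases", {
  fx <- self_replicator(kcat = 1, n_steps = 1, t_end = 1)   # dt = 1
  opts <- solve_options()
  # mu = 1.5: v = 0.5 satisfies everything by hand
  r <- is_feasible(build_lp(fx$model, fx$grid, 1.5), opts)
  expect_true(r$feasible)
  expect_length(r$solution, 3L)
  # mu = 2.5: max achievable M1 = M0 (1 + kcat dt) = 2 < 2.5
  expect_false(is_feasible(build_lp(fx$model, fx$grid, 2.5), opts)$feasible)
  # zero flux and constant amounts at mu = 1 is always feasible without quotas
  expect_true(is_feasible(build_lp(fx$model, fx$grid, 1), opts)$feasible)
})

test_that("maximize_mu recovers closed-form optima and degenerate cases", {
  fx <- self_replicator(kcat = 1, n_steps = 1, t_end = 1)
  tr <- maximize_mu(fx$model, fx$grid)
  expect_equal(tr$mu_star, 2, tolerance = 1e-6)
  fx2 <- self_replicator(kcat = 1, n_steps = 2, t_end = 1)
  expect_equal(maximize_mu(fx2$model, fx2$grid)$mu_star, 2.25, tolerance = 1e-6)
  # no synthesis possible: capacity removed, production closed at ub = 0
  m0 <- cfba_model(
    species("E", weight = 1, contributes_to_weight = TRUE),
    list(reaction("make_E", c(E = 1), lb = 0, ub = 0)))
  expect_equal(maximize_mu(m0, time_grid(0, 1, 1))$mu_star, 1, tolerance = 1e-6)
})

test_that("maximize_mu reports unbounded growth instead of looping", {
  m <- cfba_model(
    species("E", weight = 1, contributes_to_weight = TRUE),
    list(reaction("make_E", c(E = 1), lb = 0, ub = Inf)))  # no capacity, no cap
  expect_error(
    maximize_mu(m, time_grid(0, 1, 1),
                solve_options(max_bracket_doublings = 5L)),
    "unbounded")
})

test_that("maximize_mu errors helpfully when even the lower bracket fails", {
  # two exact quotas that cannot hold simultaneously
  m <- cfba_model(
    rbind(species("a", weight = 1, contributes_to_weight = TRUE),
          species("b", weight = 1, contributes_to_weight = TRUE)),
    list(reaction("ra", c(a = 1), ub = 1), reaction("rb", c(b = 1), ub = 1)),
    quotas = rbind(quota("a", "exact", 0.8), quota("b", "exact", 0.8)))
  expect_error(maximize_mu(m, time_grid(0, 1, 1)), "infeasible at mu_lo")
})

test_that("extract_trajectory reshapes solutions and enforces invariants", {
  fx <- self_replicator(kcat = 1, n_steps = 1, t_end = 1)
  tr <- maximize_mu(fx$model, fx$grid)
  # unique optimum of the N = 1 program
  expect_equal(as.numeric(tr$amounts), c(1, 2), tolerance = 1e-5)
  expect_equal(as.numeric(tr$fluxes), 1, tolerance = 1e-5)
  expect_identical(dim(tr$amounts), c(1L, 2L))
  expect_identical(dim(tr$fluxes), c(1L, 1L))

  # zero-flux feasible point at mu = 1: constant amount columns
  opts <- solve_options()
  lp1 <- build_lp(fx$model, fx$grid, 1)
  sol <- is_feasible(lp1, opts)$solution
  tr1 <- extract_trajectory(sol, fx$model, fx$grid, 1, opts)
  expect_equal(tr1$amounts[, 1], tr1$amounts[, 2], tolerance = 1e-8)

  # a corrupted solution violates the cyclic-closure invariant
  bad <- sol
  bad[3] <- bad[3] + 1
  expect_error(extract_trajectory(bad, fx$model, fx$grid, 1, opts),
               "invariant violated")
})

test_that("bisection is deterministic for a fixed backend", {
  m <- property_model(5)
  g <- time_grid(0, 2, 3)
  t1 <- maximize_mu(m, g)
  t2 <- maximize_mu(m, g)
  expect_identical(t1$mu_star, t2$mu_star)
  expect_identical(t1$amounts, t2$amounts)
})
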