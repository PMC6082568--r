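test_that("solver reproduces the linear simplex and convex corner optima", {
  f4a <- solve_colony(figure_fixture("fig4a"))
  expect_equal(f4a$W_star, 4)
  expect_equal(f4a$set_kind, "connected_set")
  f1b <- solve_colony(figure_fixture("fig1b"))
  expect_equal(f1b$W_star, 4)
  expect_equal(f1b$set_kind, "isolated_points")
  expect_length(f1b$strategies, 3L)
  for (sp in f1b$specialization) {
    expect_equal(sp$n_germ, 1L)
    expect_equal(sp$n_soma, 2L)
  }
})

test_that("surface-regime optima of the worked example specialize as narrated", {
  ## moderately scarce resources: the cheap-fecundity second cell goes germ
  s29 <- solve_colony(we_ineq(29))
  expect_equal(s29$case$regime, "CASE_3P")
  expect_equal(s29$specialization[[1]]$labels,
               c("unspecialized", "germ", "unspecialized"))
  ## near-slack resources: a single interior point, no specialization;
  ## the optimal total fecundity solves C = 45 + 2T - 18T^2/11
  s35 <- solve_colony(we_ineq(35))
  expect_equal(s35$specialization[[1]]$labels, rep("unspecialized", 3))
  T35 <- s35$B_star
  expect_equal(45 + 2 * T35 - 18 * T35^2 / 11, 35, tolerance = 1e-6)
  expect_equal(s35$set_kind, "single_point")
  ## equality mode at C = 12: cells 1 and 3 germ, cell 2 unspecialized
  s12 <- solve_colony(we_eq(12))
  expect_equal(s12$case$regime, "CASE_3")
  expect_equal(s12$specialization[[1]]$labels,
               c("germ", "unspecialized", "germ"))
  ## linear identical surface model agrees with its closed form
  f4b <- solve_colony(figure_fixture("fig4b"))
  expect_equal(f4b$B_star, linear_identical_case3(figure_fixture("fig4b"))$B_star,
               tolerance = 1e-8)
})

test_that("the grid oracle honors budgets, modes, and emptiness", {
  ## level-set regime: oracle agrees with the closed form
  m2 <- figure_fixture("fig6a")
  o <- brute_force_oracle(m2, grid_n = 61, refine = 10)
  expect_equal(o$W, wstar_case2(m2), tolerance = 1e-3 * wstar_case2(m2))
  ## single linear cell without a binding budget: max of b(1-b) is 1/4
  m1 <- colony_model(tradeoff("linear", 1, 1), n = 1, alpha = 1, beta = 1,
                     k1 = 1, k2 = 1, C = 100)
  o1 <- brute_force_oracle(m1, grid_n = 201)
  expect_equal(o1$W, 0.25, tolerance = 1e-4)
  expect_equal(o1$strategy$b, 0.5, tolerance = 1e-2)
  ## empty equality-mode domain: no feasible grid point
  o0 <- brute_force_oracle(we_eq(8), grid_n = 41)
  expect_false(o0$feasible)
  expect_identical(o0$W, -Inf)
  expect_error(brute_force_oracle(we_eq(8), grid_n = 1e5), "grid")
})

test_that("level-set samples sit exactly on the target pair", {
  m <- we_ineq(15)
  cl <- classify_regime(m)
  ss <- sample_solution_set(m, n = 25, seed = 99)
  for (s in ss) {
    g <- group_levels(s)
    expect_equal(g[["B"]], cl$B_star, tolerance = 1e-7)
    expect_equal(g[["V"]], cl$V_star, tolerance = 1e-7)
    expect_true(is_feasible(s, m, tol = 1e-6))
  }
  expect_error(sample_solution_set(we_ineq(40)), "level-set")
})

test_that("optimal-set geometry of the illustration models is recovered", {
  ## convex level-set: three disconnected subsets
  f2a <- solve_colony(figure_fixture("fig2a"))
  expect_equal(f2a$set_kind, "connected_set")
  expect_equal(f2a$diagnostics$n_components, 3L)
  ## concave extreme sub-case: a three-point optimal set
  f6b <- solve_colony(figure_fixture("fig6b"))
  expect_equal(f6b$set_kind, "isolated_points")
  expect_length(f6b$strategies, 3L)
  bs <- do.call(rbind, lapply(f6b$strategies, `[[`, "b"))
  expect_equal(sort(colSums(bs)), rep(2, 3), tolerance = 1e-6)
})

test_that("solver dominates the refined grid oracle on random colonies", {
  for (cls in c("concave", "linear", "convex", "mixed")) {
    for (i in 1:3) {
      seed <- 700 + 10 * match(cls, c("concave", "linear", "convex", "mixed")) + i
      mode <- if (i %% 2 == 0) "equality" else "inequality"
      m <- random_colony(2 + (i %% 2), cls, seed = seed, mode = mode)
      s <- solve_colony(m)
      o <- brute_force_oracle(m, grid_n = if (m$N == 2) 401 else 61,
                              refine = 20)
      if (s$dead) {
        expect_false(o$feasible)
        next
      }
      expect_gte(s$W_star, o$W - 1e-3 * max(1, abs(o$W)))
      for (st in s$strategies[seq_len(min(3, length(s$strategies)))])
        expect_true(is_feasible(st, m, tol = 1e-5))
    }
  }
})

test_that("permuting identical cells leaves the optimum unchanged", {
  m <- figure_fixture("fig1a")
  W0 <- solve_colony(m)$W_star
  mp <- m; mp$cells <- m$cells[c(3, 1, 2)]
  expect_equal(solve_colony(mp)$W_star, W0)
  ## convex slack-regime strategies have at most one unspecialized cell
  for (nm in c("fig1a", "fig1b", "fig8a", "fig8b")) {
    sol <- solve_colony(figure_fixture(nm))
    for (sp in sol$specialization) expect_lte(sp$n_unspecialized, 1L)
  }
})

test_that("an empty domain yields a dead-colony report", {
  s <- solve_colony(we_eq(9))
  expect_true(s$dead)
  expect_length(s$strategies, 0L)
  expect_true(is.na(s$W_star))
})

test_that("solution methods print, summarize and tabulate", {
  sol <- solve_colony(we_ineq(29))
  expect_output(print(sol), "CASE_3P")
  expect_output(summary(sol), "strategies")
  expect_equal(unname(coef(sol)["W"]), sol$W_star)
  tab <- strategy_table(sol)
  expect_equal(nrow(tab), length(sol$strategies) * 3L)
  expect_named(tab, c("strategy", "cell", "b", "v", "label"))
})
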