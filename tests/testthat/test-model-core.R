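test_that("group levels are per-component sums", {
  expect_equal(group_levels(strategy(c(0, 0, 0), c(0, 0, 0))), c(B = 0, V = 0))
  expect_equal(group_levels(strategy(c(1, 1), c(2, 3))), c(B = 2, V = 5))
  ## three-cell example with binding trade-offs at b = (1/3, 1, 1/2):
  ## v = (6-3/9, 4-1, 5-1/2) = (17/3, 3, 9/2), totals (11/6, 79/6)
  m <- we_ineq()
  b <- c(1 / 3, 1, 1 / 2)
  v <- vapply(1:3, function(i) phi_at(m$cells[[i]], b[i]), numeric(1))
  expect_equal(v, c(17 / 3, 3, 9 / 2))
  expect_equal(group_levels(strategy(b, v)), c(B = 11 / 6, V = 79 / 6))
})

test_that("fitness is B^alpha V^beta, zero iff a component is zero", {
  m <- colony_model(tradeoff("linear", 1, 1), n = 2, alpha = 1, beta = 2,
                    k1 = 1, k2 = 1, C = 10)
  expect_equal(fitness(strategy(c(1, 1), c(1, 2)), m), 2 * 9)
  m1 <- colony_model(tradeoff("linear", 1, 1), n = 2, alpha = 1, beta = 1,
                     k1 = 1, k2 = 1, C = 10)
  expect_equal(fitness(strategy(c(1, 1), c(1, 2)), m1), 6)
  expect_equal(fitness(strategy(c(0, 0), c(1, 2)), m), 0)
  expect_equal(fitness(strategy(c(1, 1), c(0, 0)), m), 0)
  ## strictly increasing in B and V on the positive orthant
  set.seed(7)
  for (i in 1:20) {
    B <- runif(1, 0.1, 5); V <- runif(1, 0.1, 5)
    a <- runif(1, 0.2, 3); b <- runif(1, 0.2, 3)
    w0 <- colonyopt:::fitness_bv(B, V, a, b)
    expect_gt(colonyopt:::fitness_bv(B + 1e-4, V, a, b), w0)
    expect_gt(colonyopt:::fitness_bv(B, V + 1e-4, a, b), w0)
  }
})

test_that("resource usage is k1*B + k2*V", {
  m <- we_ineq()
  expect_equal(resource_usage(strategy(rep(0, 3), rep(0, 3)), m), 0)
  ## the resource-free optimum of the worked example uses ~36.055 units
  s <- strategy(c(3.02765, 0, 0), c(10, 0, 0))
  expect_equal(resource_usage(s, m), 36.055, tolerance = 1e-3)
  m1 <- colony_model(tradeoff("linear", 2, 1), n = 1, alpha = 1, beta = 1,
                     k1 = 1, k2 = 1, C = 5)
  expect_equal(resource_usage(strategy(1, 2), m1), 3)
})

test_that("feasibility covers box, trade-off mode, and budget", {
  mi <- we_ineq(C = 20)
  expect_true(is_feasible(strategy(rep(0, 3), rep(0, 3)), mi))
  ## one box bound violated by 10*tol
  bad <- strategy(c(sqrt(2) + 1e-5, 0, 0), c(0, 4, 5))
  expect_false(is_feasible(bad, mi, tol = 1e-6))
  ## below the empty-domain threshold no on-curve strategy is affordable
  me <- we_eq(C = 9)
  expect_gt(min_required_resource(me), 9)
  set.seed(11)
  L <- c(sqrt(2), 2, sqrt(2.5))
  for (i in 1:25) {
    b <- runif(3) * L
    v <- vapply(1:3, function(j) phi_at(me$cells[[j]], b[j]), numeric(1))
    expect_false(is_feasible(strategy(b, v), me))
  }
  ## equality mode rejects strategies off the curve
  off <- strategy(c(0.5, 0.5, 0.5), c(1, 1, 1))
  expect_false(is_feasible(off, me))
  expect_match(attr(is_feasible(off, me), "reason"), "curve")
})

test_that("cells are labeled germ at b_max, soma at v_max", {
  m <- we_ineq()
  L <- c(sqrt(2), 2, sqrt(2.5))
  allg <- classify_cells(strategy(L, rep(0, 3)), m)
  expect_equal(allg$labels, rep("germ", 3))
  mid <- classify_cells(strategy(L / 2, rep(1, 3)), m)
  expect_equal(mid$labels, rep("unspecialized", 3))
  expect_equal(mid$n_unspecialized + mid$n_germ + mid$n_soma, 3L)
  ## one aggregate cell in germ, two in soma (low alpha/beta convex optimum)
  f1b <- solve_colony(figure_fixture("fig1b"))
  for (sp in f1b$specialization) {
    expect_equal(sp$n_germ, 1L)
    expect_equal(sp$n_soma, 2L)
  }
})

test_that("labels are equivariant under permuting identical cells", {
  m <- figure_fixture("fig1a")
  s <- strategy(c(1, 0, 0.5), c(0, 1, 0.25))
  perm <- c(2, 3, 1)
  sp <- classify_cells(s, m)
  sp2 <- classify_cells(strategy(s$b[perm], s$v[perm]), m)
  expect_equal(sp2$labels, sp$labels[perm])
})

test_that("model validation enforces positive parameters", {
  tr <- tradeoff("linear", 1, 1)
  expect_error(colony_model(tr, n = 2, alpha = 0, beta = 1, k1 = 1, k2 = 1,
                            C = 1), "alpha")
  expect_error(colony_model(tr, n = 2, alpha = 1, beta = 1, k1 = -1, k2 = 1,
                            C = 1), "k1")
  expect_error(colony_model(tr, n = 21, alpha = 1, beta = 1, k1 = 1, k2 = 1,
                            C = 1), "20")
})
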