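test_that("level-set targets split the budget by exponent shares", {
  m <- colony_model(tradeoff("linear", 1, 1), n = 3, alpha = 1, beta = 1,
                    k1 = 1, k2 = 1, C = 4)
  expect_equal(setA_targets(m), c(B_star = 2, V_star = 2))
  m2 <- colony_model(tradeoff("linear", 1, 1), n = 3, alpha = 1, beta = 2,
                     k1 = 1, k2 = 2, C = 6)
  expect_equal(setA_targets(m2), c(B_star = 2, V_star = 2))
  m3 <- colony_model(tradeoff("linear", 1, 1), n = 3, alpha = 1, beta = 1,
                     k1 = 2, k2 = 3, C = 18)
  expect_equal(setA_targets(m3), c(B_star = 4.5, V_star = 3))
  ## agreement with a grid search over the budget line at random parameters
  set.seed(42)
  for (i in 1:10) {
    a <- runif(1, 0.3, 3); b <- runif(1, 0.3, 3)
    k1 <- runif(1, 0.5, 3); k2 <- runif(1, 0.5, 3); C <- runif(1, 2, 20)
    mm <- colony_model(tradeoff("linear", 1, 1), n = 1, alpha = a, beta = b,
                       k1 = k1, k2 = k2, C = C)
    g <- line_grid_max(a, b, k1, k2, C)
    tg <- setA_targets(mm)
    expect_equal(tg[["B_star"]], g$B, tolerance = 1e-3)
    expect_equal(tg[["V_star"]], g$V, tolerance = 1e-3)
  }
})

test_that("level-set optimal fitness matches its closed form and the line grid", {
  m <- colony_model(tradeoff("linear", 1, 1), n = 1, alpha = 1, beta = 1,
                    k1 = 1, k2 = 1, C = 2)
  expect_equal(wstar_case2(m), 1)
  m2 <- colony_model(tradeoff("linear", 1, 1), n = 1, alpha = 1, beta = 1,
                     k1 = 2, k2 = 3, C = 12)
  expect_equal(wstar_case2(m2), 6)
  expect_equal(line_grid_max(1, 1, 2, 3, 12)$W, 6, tolerance = 1e-6)
  ## identity: W* equals the fitness of the level-set targets
  set.seed(5)
  for (i in 1:10) {
    mm <- colony_model(tradeoff("linear", 1, 1), n = 1,
                       alpha = runif(1, 0.3, 3), beta = runif(1, 0.3, 3),
                       k1 = runif(1, 0.5, 3), k2 = runif(1, 0.5, 3),
                       C = runif(1, 1, 20))
    tg <- setA_targets(mm)
    expect_equal(wstar_case2(mm),
                 colonyopt:::fitness_bv(tg[["B_star"]], tg[["V_star"]],
                                        mm$alpha, mm$beta),
                 tolerance = 1e-9 * max(1, wstar_case2(mm)))
  }
})

test_that("sensitivity of W* to the fecundity exponent matches finite differences", {
  mk <- function(C) colony_model(tradeoff("linear", 1, 1), n = 1, alpha = 1,
                                 beta = 1, k1 = 1, k2 = 1, C = C)
  s4 <- wstar_alpha_sensitivity(mk(4))
  expect_true(s4$increasing)
  expect_equal(s4$derivative, wstar_case2(mk(4)) * log(2))
  expect_equal(wstar_alpha_sensitivity(mk(2))$derivative, 0)
  set.seed(9)
  for (i in 1:10) {
    a <- runif(1, 0.5, 2.5); b <- runif(1, 0.5, 2.5)
    k1 <- runif(1, 0.5, 2); k2 <- runif(1, 0.5, 2); C <- runif(1, 2, 15)
    f <- function(aa) {
      mm <- colony_model(tradeoff("linear", 1, 1), n = 1, alpha = aa, beta = b,
                         k1 = k1, k2 = k2, C = C)
      wstar_case2(mm)
    }
    h <- 1e-5
    fd <- (f(a + h) - f(a - h)) / (2 * h)
    an <- wstar_alpha_sensitivity(
      colony_model(tradeoff("linear", 1, 1), n = 1, alpha = a, beta = b,
                   k1 = k1, k2 = k2, C = C))$derivative
    expect_equal(an, fd, tolerance = 1e-6 * max(1, abs(an)))
  }
})

test_that("identical-linear slack-regime closed form matches the grid oracle", {
  m <- figure_fixture("fig4a") # phi = 1-b, N = 3, alpha 1, beta 2, C = 4
  r <- linear_identical_case1(m)
  expect_equal(r$B_star, 1)
  expect_equal(r$W_star, 4)
  expect_true(r$applicable)
  expect_equal(unname(r$condition_bounds["slack_threshold"]), 3)
  o <- brute_force_oracle(m, grid_n = 101, refine = 10)
  expect_equal(r$W_star, o$W, tolerance = 1e-6)
  ## equal exponents put the optimum at half the total fecundity
  ms <- colony_model(tradeoff("linear", 2, 1.5), n = 4, alpha = 1.3,
                     beta = 1.3, k1 = 1, k2 = 1, C = 100)
  expect_equal(linear_identical_case1(ms)$B_star, 4 * 1.5 / 2)
  ## boundary resource level is inclusive
  mb <- colony_model(tradeoff("linear", 1, 1), n = 3, alpha = 1, beta = 2,
                     k1 = 1, k2 = 1, C = 3)
  expect_true(linear_identical_case1(mb)$applicable)
  ## misuse guards
  expect_error(linear_identical_case1(we_ineq()), "linear")
  mh <- colony_model(list(tradeoff("linear", 1, 1), tradeoff("linear", 2, 1)),
                     alpha = 1, beta = 1, k1 = 1, k2 = 1, C = 4)
  expect_error(linear_identical_case1(mh), "identical")
})

test_that("identical-linear surface-regime closed form matches the grid oracle", {
  m <- figure_fixture("fig4b") # k2 = 2 squeezes the budget
  r <- linear_identical_case3(m)
  expect_equal(r$B_star, 2)
  expect_equal(r$W_star, 2)
  expect_true(r$applicable)
  o <- brute_force_oracle(m, grid_n = 101, refine = 10)
  expect_equal(r$W_star, o$W, tolerance = 1e-6)
  ## budget identity: V* is what remains of C after paying for B*
  expect_equal(r$W_star,
               r$B_star^m$alpha * ((m$C - m$k1 * r$B_star) / m$k2)^m$beta)
  ## below the survival bound the regime cannot occur
  mlow <- colony_model(tradeoff("linear", 1, 1), n = 3, alpha = 1, beta = 2,
                       k1 = 1, k2 = 2, C = 2.5)
  expect_false(linear_identical_case3(mlow)$applicable)
  ## degenerate cost ratio k1 = k2*gamma
  mdeg <- colony_model(tradeoff("linear", 1, 1), n = 3, alpha = 1, beta = 2,
                       k1 = 2, k2 = 2, C = 4)
  expect_error(linear_identical_case3(mdeg), "degenerate")
})

test_that("concave first-order condition solves the printed examples", {
  ## phi = 1-b^2, beta = 2: 2b * 3b = (1/2) * ... root b = sqrt(1/5)
  s <- concave_foc_solve(figure_fixture("fig5b"))
  expect_equal(s$b, rep(sqrt(0.2), 3), tolerance = 1e-9)
  expect_equal(attr(s, "elasticity"), -1 / 2, tolerance = 1e-9)
  ## equal exponents: 2b^2 = 1 - b^2
  ms <- colony_model(tradeoff("quadratic_concave", 1, 1), n = 3, alpha = 1,
                     beta = 1, k1 = 1, k2 = 1, C = 100)
  expect_equal(concave_foc_solve(ms)$b, rep(1 / sqrt(3), 3), tolerance = 1e-9)
  ## heterogeneous example: b* = lambda*(1/6, 1/2, 1/4), V(b*) = 10
  sw <- concave_foc_solve(we_ineq())
  lam <- sqrt(120 / 11)
  expect_equal(sw$b, lam * c(1 / 6, 1 / 2, 1 / 4), tolerance = 1e-9)
  expect_equal(sum(sw$v), 10, tolerance = 1e-9)
  expect_equal(attr(sw, "elasticity"), -1, tolerance = 1e-9)
  expect_error(concave_foc_solve(figure_fixture("fig1a")), "concave")
})

test_that("convex bang-bang enumeration finds all tied optima", {
  ## high alpha/beta: three optima, two germ + one soma, W = 2
  e1 <- convex_case1_enumerate(figure_fixture("fig1a"))
  expect_length(e1, 3L)
  expect_equal(attr(e1, "W_star"), 2)
  m <- figure_fixture("fig1a")
  for (s in e1) {
    sp <- classify_cells(s, m)
    expect_equal(sp$n_germ, 2L)
    expect_equal(sp$n_soma, 1L)
  }
  ## low alpha/beta flips the pattern, W = 4
  e2 <- convex_case1_enumerate(figure_fixture("fig1b"))
  expect_length(e2, 3L)
  expect_equal(attr(e2, "W_star"), 4)
  ## a lone convex cell: both corners give W = 0, the interior point wins
  m1 <- colony_model(tradeoff("quadratic_convex", 1, 1), n = 1, alpha = 1,
                     beta = 1, k1 = 1, k2 = 1, C = 100)
  e3 <- convex_case1_enumerate(m1)
  expect_equal(attr(e3, "W_star"), 4 / 27, tolerance = 1e-9)
  expect_equal(e3[[1]]$b, 1 / 3, tolerance = 1e-6)
  expect_error(convex_case1_enumerate(we_ineq()), "convex")
})

test_that("heterogeneous-linear optimum specializes by slope order", {
  ## slopes (1, 1, 1/3): the cheap-fecundity cell 3 goes germ, 1 and 2 soma
  m <- figure_fixture("fig8c")
  s <- linear_hetero_sorted(m)
  sp <- classify_cells(s, m)
  expect_equal(sp$labels, c("soma", "soma", "germ"))
  expect_equal(attr(s, "B_star"), 6)
  ## all slopes equal: reduces to the identical-cell simplex total
  me <- colony_model(tradeoff("linear", 2, 1), n = 3, alpha = 1, beta = 2,
                     k1 = 1, k2 = 1, C = 100)
  expect_equal(attr(linear_hetero_sorted(me), "B_star"),
               linear_identical_case1(me)$B_star, tolerance = 1e-9)
  expect_error(linear_hetero_sorted(we_ineq()), "linear")
})

test_that("exchange arguments hold on random strategies", {
  ## convex cells: pushing a fecundity pair apart never hurts the better of
  ## the two perturbed strategies
  set.seed(31)
  m <- random_colony(3, "convex", seed = 77)
  L <- vapply(m$cells, function(tr) tr$b_max, numeric(1))
  for (i in 1:25) {
    b <- runif(3, 0.05, 0.95) * L
    eps <- min(0.04 * min(L), min(b[1:2]), min(L[1:2] - b[1:2])) / 2
    W0 <- local({
      v <- vapply(1:3, function(j) phi_at(m$cells[[j]], b[j]), numeric(1))
      colonyopt:::fitness_bv(sum(b), sum(v), m$alpha, m$beta)
    })
    W_of <- function(bb) {
      v <- vapply(1:3, function(j) phi_at(m$cells[[j]], bb[j]), numeric(1))
      colonyopt:::fitness_bv(sum(bb), sum(v), m$alpha, m$beta)
    }
    b1 <- b + c(-eps, eps, 0); b2 <- b + c(eps, -eps, 0)
    expect_gte(max(W_of(b1), W_of(b2)), W0 - 1e-12)
  }
  ## linear cells: moving fecundity from a low-slope to a high-slope cell
  ## never increases fitness
  ml <- random_colony(3, "linear", seed = 78)
  gam <- vapply(ml$cells, function(tr) tr$v_max / tr$b_max, numeric(1))
  lo <- which.min(gam); hi <- which.max(gam)
  Ll <- vapply(ml$cells, function(tr) tr$b_max, numeric(1))
  W_of <- function(bb) {
    v <- vapply(seq_along(bb), function(j) phi_at(ml$cells[[j]], bb[j]),
                numeric(1))
    colonyopt:::fitness_bv(sum(bb), sum(v), ml$alpha, ml$beta)
  }
  for (i in 1:25) {
    b <- runif(3, 0.1, 0.9) * Ll
    eps <- min(0.05 * min(Ll), b[lo], Ll[hi] - b[hi]) / 2
    b_swap <- b; b_swap[lo] <- b[lo] - eps; b_swap[hi] <- b[hi] + eps
    expect_lte(W_of(b_swap), W_of(b) + 1e-12)
  }
})
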