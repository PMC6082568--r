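#' Level-set targets of the resource-bound optimum
#'
#' When only the resource budget binds, maximizing `B^alpha * V^beta` on the
#' line `k1*B + k2*V = C` splits the budget in proportion to the exponents:
#' `B* = C*alpha / (k1*(alpha+beta))` and `V* = C*beta / (k2*(alpha+beta))`.
#' The level-set regime's optimal set lives on this `(B*, V*)` pair.
#'
#' @param m a [colony_model()].
#' @return named numeric `c(B_star, V_star)`.
#' @export
setA_targets <- function(m) {
  ab <- m$alpha + m$beta
  c(B_star = m$C * m$alpha / (m$k1 * ab),
    V_star = m$C * m$beta / (m$k2 * ab))
}

#' Optimal fitness in the level-set regime
#'
#' Closed form for the maximal fitness when the resource budget is the only
#' binding constraint:
#' `W* = (alpha/k1)^alpha * (beta/k2)^beta * (C/(alpha+beta))^(alpha+beta)`.
#'
#' @param m a [colony_model()].
#' @return the optimal fitness (scalar).
#' @export
wstar_case2 <- function(m) {
  ab <- m$alpha + m$beta
  (m$alpha / m$k1)^m$alpha * (m$beta / m$k2)^m$beta * (m$C / ab)^ab
}

#' Sensitivity of the level-set optimum to the fecundity exponent
#'
#' In the level-set regime, `dW*/dalpha = W* * log(C*alpha/(k1*(alpha+beta)))`;
#' the optimum increases with the 'importance' of fecundity exactly when
#' `(k1/C)*(1 + beta/alpha) < 1`, i.e. when fecundity is relatively important
#' and cheap to produce.
#'
#' @param m a [colony_model()].
#' @return a list with `derivative` and logical `increasing`.
#' @export
wstar_alpha_sensitivity <- function(m) {
  arg <- m$C * m$alpha / (m$k1 * (m$alpha + m$beta))
  d <- wstar_case2(m) * log(arg)
  list(derivative = d, increasing = (m$k1 / m$C) * (1 + m$beta / m$alpha) < 1)
}

## checks that all cells are linear with equal (v_max, b_max)
check_identical_linear <- function(m) {
  cv <- curvature_vec(m)
  if (!all(cv == "linear"))
    stop("this closed form requires all cells to have linear trade-offs")
  v <- v_max_vec(m); L <- b_max_vec(m)
  if (diff(range(v)) > 1e-9 * max(v) || diff(range(L)) > 1e-9 * max(L))
    stop("this closed form requires identical cells")
  list(v = v[1], L = L[1], gamma = v[1] / L[1])
}

analytic_result <- function(B_star, V_star, alpha, beta, applicable,
                            condition_bounds = numeric()) {
  ## outside its validity range a closed form can produce negative levels;
  ## report them with W_star = NA rather than erroring
  W <- if (B_star >= 0 && V_star >= 0)
    fitness_bv(B_star, V_star, alpha, beta) else NA_real_
  structure(list(B_star = B_star, V_star = V_star, W_star = W,
                 applicable = applicable && !is.na(W),
                 condition_bounds = condition_bounds),
            class = "analytic_result")
}

#' @export
print.analytic_result <- function(x, ...) {
  cat(sprintf("analytic optimum: B* = %.6g, V* = %.6g, W* = %.6g (%s)\n",
              x$B_star, x$V_star, x$W_star,
              if (x$applicable) "applicable" else "NOT applicable"))
  if (length(x$condition_bounds)) {
    cat("  condition bounds:",
        paste(sprintf("%s = %.6g", names(x$condition_bounds),
                      x$condition_bounds), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Closed forms for identical linear trade-offs
#'
#' With `N` identical cells of slope `gamma = v_max/b_max`, the colony behaves
#' as a single cell. In the resource-slack regime the optimum is the simplex
#' `B(b*) = N*b_max / (1 + beta/alpha)` with fitness
#' `W* = (N/(alpha+beta))^(alpha+beta) * (alpha*b_max)^alpha * (beta*v_max)^beta`,
#' applicable iff
#' `C >= alpha/(alpha+beta)*k1*N*b_max + beta/(alpha+beta)*k2*N*v_max`
#' (boundary inclusive). In the resource-surface regime the optimum sits on
#' the budget plane: `B(b*) = (C - k2*N*v_max)/(k1 - k2*gamma)` with
#' `W* = B*^alpha * ((k1*N*v_max - gamma*C)/(k1 - k2*gamma))^beta`, applicable
#' iff `min(k1*N*b_max, k2*N*v_max) <= C <` the slack threshold; below the
#' left bound the colony cannot survive, and `k1 = k2*gamma` is degenerate
#' (the surface regime does not occur).
#'
#' @param m a [colony_model()] whose cells are all linear and identical.
#' @return an object of class `"analytic_result"` with fields `B_star`,
#'   `V_star`, `W_star`, `applicable` and `condition_bounds`.
#' @export
linear_identical_case1 <- function(m) {
  p <- check_identical_linear(m)
  ab <- m$alpha + m$beta
  B_star <- m$N * p$L / (1 + m$beta / m$alpha)
  V_star <- m$N * p$v - p$gamma * B_star
  thr <- m$alpha / ab * m$k1 * m$N * p$L + m$beta / ab * m$k2 * m$N * p$v
  res <- analytic_result(B_star, V_star, m$alpha, m$beta,
                         applicable = m$C >= thr,
                         condition_bounds = c(slack_threshold = thr))
  ## cross-check against the printed closed form for W*
  W_eq <- (m$N / ab)^ab * (m$alpha * p$L)^m$alpha * (m$beta * p$v)^m$beta
  stopifnot(abs(res$W_star - W_eq) <= 1e-9 * max(1, W_eq))
  res
}

#' @rdname linear_identical_case1
#' @export
linear_identical_case3 <- function(m) {
  p <- check_identical_linear(m)
  if (abs(m$k1 - m$k2 * p$gamma) <= 1e-12 * max(m$k1, m$k2 * p$gamma))
    stop("degenerate case k1 = k2*gamma: the resource-surface regime does not occur")
  ab <- m$alpha + m$beta
  B_star <- (m$C - m$k2 * m$N * p$v) / (m$k1 - m$k2 * p$gamma)
  V_star <- (m$k1 * m$N * p$v - p$gamma * m$C) / (m$k1 - m$k2 * p$gamma)
  thr_hi <- m$alpha / ab * m$k1 * m$N * p$L + m$beta / ab * m$k2 * m$N * p$v
  thr_lo <- min(m$k1 * m$N * p$L, m$k2 * m$N * p$v)
  analytic_result(B_star, V_star, m$alpha, m$beta,
                  applicable = (m$C >= thr_lo && m$C < thr_hi),
                  condition_bounds = c(survival_threshold = thr_lo,
                                       slack_threshold = thr_hi))
}

#' Interior first-order optimum for concave trade-offs
#'
#' For strictly concave trade-off curves the resource-free optimum satisfies
#' the marginal condition `phi_i'(b_i*) = -(alpha/beta) * V(b*)/B(b*)` for
#' every interior cell — equivalently, the elasticity of group viability with
#' respect to group fecundity equals `-alpha/beta` at the optimum. Cells whose
#' marginal condition cannot be met inside the box are clipped to the violated
#' bound (and are thereby specialized); the remaining cells still satisfy the
#' shared marginal condition. The common multiplier is found by monotone
#' bisection.
#'
#' @param m a [colony_model()] whose cells all have concave trade-offs.
#' @return a [strategy()] with attributes `mu` (the common slope magnitude),
#'   `elasticity` (computed over the interior cells) and `W_star`.
#' @export
concave_foc_solve <- function(m) {
  cv <- curvature_vec(m)
  if (!all(cv == "concave"))
    stop("concave_foc_solve requires all trade-offs to be strictly concave")
  L <- b_max_vec(m)
  b_of <- function(mu) vapply(seq_len(m$N),
                              function(i) invert_dphi(m$cells[[i]], -mu),
                              numeric(1))
  ## g(mu) = mu*B - (alpha/beta)*V is increasing; g(0+) < 0, g(mu_hi) > 0
  g <- function(mu) {
    b <- b_of(mu)
    mu * sum(b) - (m$alpha / m$beta) * sum(phi_vec(m, b))
  }
  mu_hi <- max(vapply(seq_len(m$N),
                      function(i) max(abs(dphi_at(m$cells[[i]], c(0, L[i])))),
                      numeric(1))) * (1 + 1e-9)
  lo <- 0; hi <- mu_hi
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-15 * max(1, mu_hi)) break
  }
  mu <- (lo + hi) / 2
  b <- b_of(mu)
  s <- on_curve_strategy(m, b)
  g2 <- group_levels(s)
  interior <- b > 1e-9 * L & b < L * (1 - 1e-9)
  elast <- if (any(interior)) {
    i <- which(interior)[1]
    dphi_at(m$cells[[i]], b[i]) * g2[["B"]] / g2[["V"]]
  } else NA_real_
  attr(s, "mu") <- mu
  attr(s, "elasticity") <- elast
  attr(s, "W_star") <- fitness(s, m)
  s
}

#' Bang-bang enumeration for convex trade-offs
#'
#' With strictly convex trade-off curves the resource-free optimum is
#' bang-bang: every cell sits at `b = b_max` (germ) or `b = 0` (soma, with
#' `v = v_max`), except possibly one interior cell. All assignments, plus a
#' 1-D optimization for the optional interior cell, are enumerated; every
#' strategy within relative tie tolerance `1e-9` of the best fitness is
#' returned (duplicated strategy vectors removed, permuted variants kept).
#'
#' @param m a [colony_model()] whose cells all have convex trade-offs.
#' @return list of [strategy()] objects, with attribute `W_star`.
#' @export
convex_case1_enumerate <- function(m) {
  cv <- curvature_vec(m)
  if (!all(cv == "convex"))
    stop("convex_case1_enumerate requires all trade-offs to be strictly convex")
  L <- b_max_vec(m)
  cand <- list()
  push <- function(b) cand[[length(cand) + 1L]] <<- b
  for (mask in 0:(2^m$N - 1L)) {
    germ <- bitwAnd(mask, 2^(seq_len(m$N) - 1L)) > 0
    b <- ifelse(germ, L, 0)
    push(b)
    for (j in which(!germ)) {
      ## one interior cell on top of the corner assignment
      objf <- function(t) {
        bt <- b; bt[j] <- t
        fitness_bv(sum(bt), sum_phi_all(m, bt), m$alpha, m$beta)
      }
      op <- stats::optimize(objf, c(0, L[j]), maximum = TRUE, tol = 1e-10)
      push({ bt <- b; bt[j] <- op$maximum; bt })
    }
  }
  W <- vapply(cand, function(b)
    fitness_bv(sum(b), sum_phi_all(m, b), m$alpha, m$beta), numeric(1))
  best <- max(W)
  keep <- unique_vectors(cand[W >= best * (1 - 1e-9) - 1e-12], tol = 1e-7)
  ord <- do.call(order, as.data.frame(do.call(rbind, keep)))
  out <- lapply(keep[ord], function(b) on_curve_strategy(m, b))
  attr(out, "W_star") <- best
  out
}

#' Sorted greedy optimum for heterogeneous linear trade-offs
#'
#' With linear trade-offs of distinct slopes `gamma_i` ("strong
#' differentiation of types"), the resource-free optimum is unique: cells
#' specialize in germ in order of increasing `gamma_i` (fecundity is cheapest
#' in viability terms there), cells with the highest slopes specialize in
#' soma, and at most one cell is partially specialized. Cells with equal
#' slopes are merged into a composite cell (their total fecundity is what
#' matters); the representative strategy splits a composite's fecundity in
#' proportion to the members' `b_max`.
#'
#' @param m a [colony_model()] whose cells all have linear trade-offs.
#' @return a [strategy()] with attributes `W_star` and `B_star`.
#' @export
linear_hetero_sorted <- function(m) {
  cv <- curvature_vec(m)
  if (!all(cv == "linear"))
    stop("linear_hetero_sorted requires all trade-offs to be linear")
  L <- b_max_vec(m); v <- v_max_vec(m)
  gam <- v / L
  ## merge equal-slope cells into composite segments, sorted by slope
  key <- round(gam / (max(gam) * 1e-9))
  groups <- split(seq_len(m$N), key)
  groups <- groups[order(vapply(groups, function(ix) gam[ix[1]], numeric(1)))]
  seg_gam <- vapply(groups, function(ix) gam[ix[1]], numeric(1))
  seg_len <- vapply(groups, function(ix) sum(L[ix]), numeric(1))
  Vtot <- sum(v)
  ## V(B) is piecewise linear with slope -seg_gam over consecutive segments;
  ## log W = alpha*log B + beta*log V(B) is concave, so evaluate the interior
  ## stationary candidate of every segment plus all breakpoints
  brk <- unname(cumsum(c(0, seg_len)))
  Vbrk <- unname(Vtot - cumsum(c(0, seg_gam * seg_len)))
  candB <- brk
  for (k in seq_along(groups)) {
    g <- unname(seg_gam[k])
    Bc <- m$alpha * (Vbrk[k] + g * brk[k]) / (g * (m$alpha + m$beta))
    if (Bc > brk[k] && Bc < brk[k + 1]) candB <- c(candB, Bc)
  }
  VofB <- function(B) {
    k <- findInterval(B, brk, rightmost.closed = TRUE)
    Vbrk[k] - seg_gam[k] * (B - brk[k])
  }
  Wc <- vapply(candB, function(B)
    fitness_bv(B, max(VofB(B), 0), m$alpha, m$beta), numeric(1))
  B_star <- candB[which.max(Wc)]
  ## greedy fill in slope order; proportional split inside a composite
  b <- numeric(m$N); rem <- B_star
  for (ix in groups) {
    take <- min(rem, sum(L[ix]))
    b[ix] <- take * L[ix] / sum(L[ix])
    rem <- rem - take
    if (rem <= 1e-12) break
  }
  s <- on_curve_strategy(m, b)
  attr(s, "W_star") <- max(Wc)
  attr(s, "B_star") <- B_star
  s
}
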