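#' Resource-free optimum of a colony
#'
#' Solves the fitness problem without the resource budget (trade-offs binding,
#' as they are at any resource-free optimum) and reports the minimal resource
#' usage `k1*B + k2*V` over the optimal set — the boundary resource level
#' below which the budget starts to bind. Dispatches on curvature: concave
#' colonies use the interior first-order condition, linear colonies the
#' slope-sorted greedy optimum, convex colonies the bang-bang enumeration, and
#' mixed colonies a numeric scan of `W(T) = T^alpha * vmax_at(T)^beta` over
#' total fecundity.
#'
#' @param m a [colony_model()].
#' @return a list: `strategies` (representative optimal strategies),
#'   `C_unconstrained` (minimal usage over the optimum set), `W_star`,
#'   `B_star`, `V_star`.
#' @export
unconstrained_optimum <- function(m) {
  cv <- curvature_vec(m)
  v <- v_max_vec(m); L <- b_max_vec(m)
  if (all(cv == "concave")) {
    s <- concave_foc_solve(m)
    strategies <- list(s)
    W <- attr(s, "W_star")
  } else if (all(cv == "linear")) {
    s <- linear_hetero_sorted(m)
    strategies <- list(s)
    W <- attr(s, "W_star")
  } else if (all(cv == "convex")) {
    strategies <- convex_case1_enumerate(m)
    W <- attr(strategies, "W_star")
  } else {
    ## mixed curvature: at the optimum V = vmax_at(B); numeric 1-D scan
    Lsum <- sum(L)
    obj <- function(T) fitness_bv(T, vmax_at(T, m)$value, m$alpha, m$beta)
    Ts <- seq(0, Lsum, length.out = 401L)
    vals <- vapply(Ts, obj, numeric(1))
    k <- which.max(vals)
    lo <- Ts[max(1L, k - 1L)]; hi <- Ts[min(length(Ts), k + 1L)]
    op <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)
    Tstar <- op$maximum
    env <- vmax_at(Tstar, m)
    strategies <- lapply(env$ties, function(b) on_curve_strategy(m, b))
    W <- op$objective
  }
  usage <- vapply(strategies, resource_usage, numeric(1), m = m)
  g <- group_levels(strategies[[which.min(usage)]])
  list(strategies = strategies, C_unconstrained = min(usage),
       W_star = W, B_star = g[["B"]], V_star = g[["V"]])
}

#' Minimal resource needed for a nonempty equality-mode domain
#'
#' With binding trade-offs the feasible domain is nonempty iff the minimum of
#' `sum_i [k1*b_i + k2*phi_i(b_i)]` over the box does not exceed `C`. The
#' minimum is separable and computed per cell over the candidates
#' `{0, b_max, interior stationary points}`.
#'
#' @param m a [colony_model()].
#' @return the minimal achievable resource usage (the empty-domain threshold).
#' @export
min_required_resource <- function(m) {
  per_cell <- vapply(seq_len(m$N), function(i) {
    tr <- m$cells[[i]]; L <- tr$b_max
    g <- function(b) m$k1 * b + m$k2 * phi_at(tr, b)
    cand <- c(0, L)
    st <- switch(tr$form,
                 quadratic_concave = NULL, # g is concave: endpoints only
                 linear = NULL,
                 quadratic_convex = {
                   bb <- L * (1 - m$k1 * L / (2 * m$k2 * tr$v_max))
                   if (bb > 0 && bb < L) bb else NULL
                 },
                 custom = stats::optimize(g, c(0, L), tol = 1e-10)$minimum)
    min(vapply(c(cand, st), g, numeric(1)))
  }, numeric(1))
  sum(per_cell)
}

#' Solution-regime classification
#'
#' Decides which regime of the fitness problem a model instance falls in.
#' In equality mode (every cell exactly on its trade-off curve):
#' \describe{
#'   \item{CASE_1}{the resource budget is slack — the resource-free optimum
#'     is still affordable (`C >= C_unconstrained`).}
#'   \item{CASE_2}{the budget binds and the level-set pair `(B*, V*)` from
#'     [setA_targets()] is attainable: `B* <= sum(b_max)` and
#'     `vmin_at(B*) <= V* <= vmax_at(B*)`.}
#'   \item{CASE_3}{the budget binds and the level set is unattainable, but
#'     the domain is nonempty.}
#'   \item{CASE_0}{the domain is empty — the environment is too poor for the
#'     colony to exist (only possible in equality mode).}
#' }
#' In inequality mode the primed analogues CASE_1P/2P/3P apply; attainability
#' of the level set only requires `V* <= vmax_at(B*)` (viability is free
#' downward), and the domain always contains `(0, 0)`.
#' A boundary-of-case input resolves to the lower-numbered case.
#'
#' @param m a [colony_model()].
#' @param tol absolute tolerance for attainability comparisons.
#' @return object of class `"case_label"`: `regime` (string), `mode`,
#'   `C_unconstrained`, `setA_nonempty`, `B_star`, `V_star`, `unconstrained`
#'   (the [unconstrained_optimum()] result).
#' @export
classify_regime <- function(m, tol = 1e-8) {
  un <- unconstrained_optimum(m)
  primed <- m$mode == "inequality"
  lab <- function(base) paste0("CASE_", base, if (primed) "P" else "")
  tg <- setA_targets(m)
  Bs <- tg[["B_star"]]; Vs <- tg[["V_star"]]
  out <- list(regime = NA_character_, mode = m$mode,
              C_unconstrained = un$C_unconstrained,
              setA_nonempty = FALSE, B_star = Bs, V_star = Vs,
              unconstrained = un)
  if (m$C >= un$C_unconstrained - tol) {
    out$regime <- lab("1")
  } else {
    nonempty <- FALSE
    if (Bs <= sum(b_max_vec(m)) + tol) {
      vhi <- vmax_at(min(Bs, sum(b_max_vec(m))), m)$value
      if (primed) {
        nonempty <- Vs <= vhi + tol
      } else {
        vlo <- vmin_at(min(Bs, sum(b_max_vec(m))), m)$value
        nonempty <- (Vs <= vhi + tol) && (Vs >= vlo - tol)
      }
    }
    out$setA_nonempty <- nonempty
    if (nonempty) {
      out$regime <- lab("2")
    } else if (primed) {
      out$regime <- lab("3")
    } else {
      out$regime <- if (min_required_resource(m) > m$C + tol) "CASE_0"
                    else "CASE_3"
    }
  }
  class(out) <- "case_label"
  out
}

#' @export
print.case_label <- function(x, ...) {
  cat(sprintf("regime %s (%s mode); resource-slack boundary C* = %.6g\n",
              x$regime, x$mode, x$C_unconstrained))
  cat(sprintf("  level-set targets: B* = %.6g, V* = %.6g (%sattainable)\n",
              x$B_star, x$V_star, if (x$setA_nonempty) "" else "not "))
  invisible(x)
}

#' Environment-quality ordering of inequality-mode regimes
#'
#' With trade-offs as inequalities, regimes are ordered along the resource
#' axis: the level-set regime (2') occurs at small `C`, the surface regime
#' (3'), if present, at intermediate `C`, and the slack regime (1') at large
#' `C`. This checks that classification along an increasing `C` grid follows
#' the (possibly degenerate) sequence 2' -> 3' -> 1', and additionally runs
#' the scaling subtest: a level-set solution `(b, v)` at some grid `C` is
#' scaled by `lambda < 1` and must remain a level-set solution at
#' `lambda * C`.
#'
#' @param m an inequality-mode [colony_model()].
#' @param C_grid increasing vector of resource levels.
#' @return logical; attributes `labels` (regime per grid point) and
#'   `scaling_ok`.
#' @export
quality_ordering_check <- function(m, C_grid) {
  if (m$mode != "inequality")
    stop("quality ordering is only guaranteed in inequality mode")
  C_grid <- sort(C_grid)
  labels <- vapply(C_grid, function(C) classify_regime(with_resource(m, C))$regime,
                   character(1))
  rank <- c(CASE_2P = 1L, CASE_3P = 2L, CASE_1P = 3L)[labels]
  ordered <- !is.unsorted(rank)
  ## lambda-scaling subtest on the first level-set grid point, if any
  scaling_ok <- NA
  i2 <- which(labels == "CASE_2P")
  if (length(i2)) {
    C2 <- C_grid[max(i2)]
    m2 <- with_resource(m, C2)
    ss <- sample_solution_set(m2, n = 1L, seed = 1L)
    if (length(ss)) {
      s <- ss[[1L]]; lam <- 0.5
      m3 <- with_resource(m, lam * C2)
      tg <- setA_targets(m3)
      sl <- strategy(lam * s$b, lam * s$v)
      g <- group_levels(sl)
      scaling_ok <- isTRUE(is_feasible(sl, m3, tol = 1e-6)) &&
        abs(g[["B"]] - tg[["B_star"]]) <= 1e-6 * max(1, tg[["B_star"]]) &&
        abs(g[["V"]] - tg[["V_star"]]) <= 1e-6 * max(1, tg[["V_star"]])
      ordered <- ordered && isTRUE(scaling_ok)
    }
  }
  structure(ordered, labels = labels, scaling_ok = scaling_ok)
}
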