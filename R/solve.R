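#' Solve a colony fitness problem
#'
#' Central solver: classifies the model's regime and produces the optimal
#' fitness together with representative optimal strategies.
#' \describe{
#'   \item{resource-slack (Case 1/1')}{the resource-free optimum via the
#'     curvature-appropriate analytic path.}
#'   \item{level-set (Case 2/2')}{the closed-form optimum [wstar_case2()] on
#'     the pair [setA_targets()]; the optimal set is explored with
#'     [sample_solution_set()].}
#'   \item{resource-surface (Case 3/3')}{[case3_surface_solve()].}
#'   \item{empty domain (Case 0)}{a report with no strategies and
#'     `dead = TRUE`.}
#' }
#'
#' @param m a [colony_model()].
#' @param n_sample number of optimal-set samples in the level-set regime.
#' @param seed seed for optimal-set sampling (deterministic default).
#' @param tol numeric tolerance for classification and reconstruction.
#' @return an object of class `"colony_solution"` with fields `case`,
#'   `W_star`, `B_star`, `V_star`, `strategies`, `set_kind`,
#'   `specialization`, `dead` and `diagnostics`. Methods: `print`, `summary`,
#'   `coef` (named `c(B, V, W)`), `plot`.
#' @examples
#' m <- worked_example_model("inequality", C = 25)
#' fit <- solve_colony(m)
#' fit
#' coef(fit)
#' @export
solve_colony <- function(m, n_sample = 60L, seed = 20180808L, tol = 1e-8) {
  cl <- classify_regime(m, tol = tol)
  base <- sub("P$", "", sub("CASE_", "", cl$regime))
  if (base == "0") {
    sol <- new_solution(m, cl, W_star = NA_real_, B_star = NA_real_,
                        V_star = NA_real_, strategies = list(),
                        set_kind = "single_point", dead = TRUE)
    return(sol)
  }
  if (base == "1") {
    un <- cl$unconstrained
    kind <- case1_set_kind(m, un$strategies)
    return(new_solution(m, cl, W_star = un$W_star, B_star = un$B_star,
                        V_star = un$V_star, strategies = un$strategies,
                        set_kind = kind))
  }
  if (base == "2") {
    W <- wstar_case2(m)
    samples <- sample_solution_set(m, n = n_sample, seed = seed, cl = cl)
    uniq <- unique_vectors(lapply(samples, `[[`, "b"),
                           tol = 1e-5 * max(1, max(b_max_vec(m))))
    if (length(uniq) == 1L) {
      kind <- "single_point"
      strategies <- samples[1L]
    } else if (length(uniq) < 0.5 * length(samples)) {
      kind <- "isolated_points"
      strategies <- lapply(uniq, function(b) {
        i <- which.min(vapply(samples, function(s) max(abs(s$b - b)),
                              numeric(1)))
        samples[[i]]
      })
    } else {
      kind <- "connected_set"
      strategies <- samples
    }
    return(new_solution(m, cl, W_star = W, B_star = cl$B_star,
                        V_star = cl$V_star, strategies = strategies,
                        set_kind = kind))
  }
  case3_surface_solve(m, cl = cl, tol = tol)
}

case1_set_kind <- function(m, strategies) {
  cv <- curvature_vec(m)
  if (all(cv == "linear")) {
    gam <- v_max_vec(m) / b_max_vec(m)
    if (length(unique(round(gam / (max(gam) * 1e-9)))) < m$N)
      return("connected_set")  # composite-cell simplex
    return("single_point")
  }
  if (length(strategies) > 1L) "isolated_points" else "single_point"
}

new_solution <- function(m, cl, W_star, B_star, V_star, strategies, set_kind,
                         dead = FALSE, diagnostics = list()) {
  spec <- lapply(strategies, classify_cells, m = m)
  if (length(strategies)) {
    r <- 0.05 * max(b_max_vec(m))
    diagnostics$n_components <- count_components(strategies, r)
    diagnostics$component_radius <- r
  }
  structure(list(model = m, case = cl, W_star = W_star, B_star = B_star,
                 V_star = V_star, strategies = strategies,
                 set_kind = set_kind, specialization = spec, dead = dead,
                 diagnostics = diagnostics),
            class = "colony_solution")
}

## single-linkage component count of strategy fecundity vectors
count_components <- function(strategies, radius) {
  bs <- do.call(rbind, lapply(strategies, `[[`, "b"))
  if (nrow(bs) < 2L) return(as.integer(nrow(bs)))
  hc <- stats::hclust(stats::dist(bs), method = "single")
  max(stats::cutree(hc, h = radius))
}

#' Resource-surface optimum (Case 3 / 3')
#'
#' When the budget binds and the level set is unattainable, every optimum
#' lies on the surface `k1*B + k2*V = C` at the attainable total fecundity
#' closest to `B*`. The solver finds the total fecundity `T` at which the
#' surface viability `(C - k1*T)/k2` meets the attainable envelope
#' ([vmax_at()], or the lower envelope [vmin_at()] in equality mode when the
#' surface passes below it), scanning a coarse grid and sharpening the
#' feasibility boundary by bisection, then reconstructs the per-cell
#' allocation from the envelope solution (interpolating between the two
#' envelope allocations when the surface viability is strictly between them).
#'
#' @param m a [colony_model()] classified in the surface regime.
#' @param cl optional precomputed [classify_regime()] result.
#' @param tol numeric tolerance.
#' @return a `"colony_solution"` (see [solve_colony()]).
#' @export
case3_surface_solve <- function(m, cl = classify_regime(m), tol = 1e-8) {
  if (!cl$regime %in% c("CASE_3", "CASE_3P"))
    stop("case3_surface_solve requires a surface-regime model (got ",
         cl$regime, ")")
  L <- b_max_vec(m)
  surfV <- function(T) (m$C - m$k1 * T) / m$k2
  Tdom <- min(sum(L), m$C / m$k1)
  eqmode <- m$mode == "equality"
  ## effective group viability at total fecundity T: the budget cap and the
  ## upper envelope, whichever binds (with convex cells the budget can stay
  ## slack at the optimum); in equality mode T is infeasible when even the
  ## lower envelope exceeds the cap
  veff <- function(T) {
    v <- min(surfV(T), vmax_at(T, m)$value)
    if (v < -1e-9) return(NA_real_)
    if (eqmode && v < vmin_at(T, m)$value - 1e-9) return(NA_real_)
    max(v, 0)
  }
  Wof <- function(T) {
    v <- veff(T)
    if (is.na(v)) -Inf else fitness_bv(T, v, m$alpha, m$beta)
  }
  Ts <- seq(0, Tdom, length.out = 161L)
  Ws <- vapply(Ts, Wof, numeric(1))
  fs <- is.finite(Ws)
  cand <- numeric()
  ## candidates where the surface crosses an envelope: kinks of W(T) and, in
  ## equality mode, boundaries of thin feasible sets (with linear identical
  ## cells the feasible set can be a single such crossing)
  crossings <- function(f) {
    gap <- vapply(Ts, f, numeric(1))
    sg <- sign(gap)
    out <- numeric()
    for (i in which(sg[-1] * sg[-length(sg)] < 0)) {
      out <- c(out, stats::uniroot(f, c(Ts[i], Ts[i + 1L]), tol = 1e-12)$root)
    }
    out
  }
  cand <- c(cand, crossings(function(T) surfV(T) - vmax_at(T, m)$value))
  if (eqmode)
    cand <- c(cand, crossings(function(T) surfV(T) - vmin_at(T, m)$value))
  if (any(fs)) {
    k <- which.max(Ws)
    cand <- c(cand, Ts[k])
    ## sharpen a feasibility boundary next to the best grid point
    refine <- function(T_ok, T_bad) {
      for (it in 1:80) {
        mid <- (T_ok + T_bad) / 2
        if (is.finite(Wof(mid))) T_ok <- mid else T_bad <- mid
        if (abs(T_ok - T_bad) < 1e-12 * max(1, Tdom)) break
      }
      T_ok
    }
    if (k > 1L && !fs[k - 1L]) cand <- c(cand, refine(Ts[k], Ts[k - 1L]))
    if (k < length(Ts) && !fs[k + 1L]) cand <- c(cand, refine(Ts[k], Ts[k + 1L]))
    lo_br <- Ts[max(1L, k - 1L)]; hi_br <- Ts[min(length(Ts), k + 1L)]
    if (hi_br > lo_br) {
      op <- stats::optimize(function(T) {
        w <- Wof(T); if (is.finite(w)) w else -1e308
      }, c(lo_br, hi_br), maximum = TRUE, tol = 1e-10)
      cand <- c(cand, op$maximum)
    }
  }
  cand <- cand[is.finite(vapply(cand, Wof, numeric(1)))]
  if (!length(cand))
    stop("no point of the resource surface is attainable; ",
         "classification flagged the surface regime inconsistently")
  Tstar <- cand[which.max(vapply(cand, Wof, numeric(1)))]
  vs <- surfV(Tstar)
  hi <- vmax_at(Tstar, m)
  Vstar <- min(vs, hi$value)
  rtol <- max(1e-6 * max(1, abs(Vstar)), 2e-5 * max(1, hi$value))
  if (hi$value <= vs + rtol) {
    ## envelope binds (budget may be slack): cells sit on their curves
    strategies <- lapply(hi$ties, function(b) on_curve_strategy(m, b))
  } else if (!eqmode) {
    ## budget binds below the envelope: scale viability down proportionally
    strategies <- lapply(hi$ties, function(b) {
      v <- phi_vec(m, b)
      if (sum(v) > 0) v <- v * Vstar / sum(v)
      strategy(b, v)
    })
  } else {
    lo <- vmin_at(Tstar, m)
    if (abs(vs - lo$value) <= max(rtol, 2e-5 * max(1, lo$value))) {
      strategies <- lapply(lo$ties, function(b) strategy(b, phi_vec(m, b)))
    } else {
      b <- blend_to_level(m, lo$b, hi$b, vs)
      strategies <- list(on_curve_strategy(m, b))
    }
  }
  strategies <- unique_strategies(strategies)
  kind <- if (length(strategies) > 1L) "isolated_points" else "single_point"
  new_solution(m, cl, W_star = fitness_bv(Tstar, Vstar, m$alpha, m$beta),
               B_star = Tstar, V_star = Vstar, strategies = strategies,
               set_kind = kind)
}

unique_strategies <- function(strategies, tol = 1e-7) {
  bs <- unique_vectors(lapply(strategies, `[[`, "b"), tol = tol)
  lapply(bs, function(b) {
    i <- which.min(vapply(strategies, function(s) max(abs(s$b - b)),
                          numeric(1)))
    strategies[[i]]
  })
}

## find b on the segment between two equal-total-fecundity allocations with
## sum(phi(b)) equal to `target` (intermediate-value bisection)
blend_to_level <- function(m, b_lo, b_hi, target) {
  f <- function(s) sum_phi_all(m, (1 - s) * b_lo + s * b_hi) - target
  lo <- 0; hi <- 1
  if (f(lo) * f(hi) > 0) stop("target viability outside the envelope segment")
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) * f(lo) <= 0) hi <- mid else lo <- mid
  }
  (1 - (lo + hi) / 2) * b_lo + (lo + hi) / 2 * b_hi
}

#' Brute-force grid oracle
#'
#' Exhaustively grids per-cell fecundity over the box and returns the best
#' feasible fitness. In equality mode viability is `phi_i(b_i)`; in
#' inequality mode, since fitness increases in viability, the optimal
#' viability given `b` is the trade-off viability capped by the remaining
#' budget, applied proportionally. Intended as an independent check of the
#' analytic and surface solvers at small problem sizes.
#'
#' @param m a [colony_model()].
#' @param grid_n grid points per cell (default 101).
#' @param refine number of nested local refinement passes per start: the
#'   grid is rebuilt (21 points per cell) inside a shrinking box around the
#'   incumbent. Refinement is multistart — it runs from every
#'   well-separated top candidate of the coarse pass, since the constrained
#'   landscape can hold several local basins.
#' @return a list: `W` (best feasible fitness, `-Inf` if the grid holds no
#'   feasible point), `strategy` (the attaining [strategy()] or `NULL`),
#'   `feasible` (logical).
#' @export
brute_force_oracle <- function(m, grid_n = 101L, refine = 0L) {
  L <- b_max_vec(m)
  if (grid_n^m$N > 2.2e7)
    stop("grid too large: reduce grid_n or the number of cells")
  grids <- lapply(L, function(l) seq(0, l, length.out = grid_n))
  res <- oracle_pass(m, grids, n_top = if (refine > 0L) 8L else 1L)
  if (!res$feasible || refine == 0L) {
    res$starts <- NULL
    return(res)
  }
  h0 <- rep(if (grid_n > 1) 1 / (grid_n - 1) else 1, m$N) * L
  best <- res
  for (b_start in res$starts) {
    cur <- list(W = -Inf, strategy = strategy(b_start, phi_vec(m, b_start)),
                feasible = TRUE)
    h <- h0
    for (pass in seq_len(refine)) {
      b0 <- cur$strategy$b
      lo <- pmax(0, b0 - h); hi <- pmin(L, b0 + h)
      grids <- lapply(seq_len(m$N), function(i)
        seq(lo[i], hi[i], length.out = 21L))
      r2 <- oracle_pass(m, grids)
      improved <- r2$feasible && r2$W > cur$W * (1 + 1e-10) + 1e-14
      if (r2$feasible && r2$W > cur$W) cur <- r2
      ## keep the box width while the incumbent still improves (it may be
      ## crawling along a constraint ridge); shrink on stagnation
      if (!improved) h <- h / 5
      if (max(h / pmax(L, 1e-12)) < 1e-8) break
    }
    if (cur$feasible && cur$W > best$W) best <- cur
  }
  best$starts <- NULL
  best
}

## one exhaustive pass; optionally reports the n_top best feasible grid
## points separated by at least three grid steps (multistart seeds)
oracle_pass <- function(m, grids, n_top = 1L) {
  G <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  B <- rowSums(G)
  Vphi <- 0
  for (i in seq_len(m$N)) Vphi <- Vphi + phi_at(m$cells[[i]], G[, i])
  if (m$mode == "equality") {
    V <- Vphi
    ok <- m$k1 * B + m$k2 * V <= m$C + 1e-9
  } else {
    Vcap <- (m$C - m$k1 * B) / m$k2
    ok <- Vcap >= -1e-12
    V <- pmin(Vphi, pmax(Vcap, 0))
  }
  W <- pmax(B, 0)^m$alpha * pmax(V, 0)^m$beta
  W[!ok] <- -Inf
  k <- which.max(W)
  if (!is.finite(W[k]) && !any(ok))
    return(list(W = -Inf, strategy = NULL, feasible = FALSE))
  b <- as.numeric(G[k, ])
  v <- phi_vec(m, b)
  if (m$mode == "inequality" && sum(v) > 0 && V[k] < sum(v))
    v <- v * V[k] / sum(v)
  out <- list(W = W[k], strategy = strategy(b, v), feasible = TRUE)
  if (n_top > 1L) {
    step <- vapply(grids, function(g) if (length(g) > 1) diff(g[1:2]) else 1,
                   numeric(1))
    ord <- order(W, decreasing = TRUE)
    ord <- ord[is.finite(W[ord])][seq_len(min(2000L, sum(is.finite(W))))]
    starts <- list()
    for (idx in ord) {
      bi <- as.numeric(G[idx, ])
      far <- all(vapply(starts, function(s)
        any(abs(s - bi) > 3 * step), logical(1)))
      if (far || !length(starts)) starts[[length(starts) + 1L]] <- bi
      if (length(starts) >= n_top) break
    }
    out$starts <- starts
  }
  out
}

#' Sample the level-set optimal set
#'
#' In the level-set regime every optimum has group levels exactly
#' `(B*, V*)`. This draws `n` strategies from that set: a random fecundity
#' vector on the slice `sum(b) = B*` (box-respecting), then moved along the
#' segment towards a (randomly chosen, when tied) envelope allocation until
#' the group viability hits `V*`. In inequality mode surplus trade-off
#' viability is scaled down proportionally instead, which spreads samples
#' over the wider primed optimal set.
#'
#' @param m a level-set-regime [colony_model()].
#' @param n number of samples.
#' @param seed RNG seed (the global RNG state is preserved).
#' @param cl optional precomputed [classify_regime()].
#' @return list of [strategy()] objects; attribute `n_distinct` counts
#'   distinct fecundity vectors, and `short` flags a sample shortfall.
#' @export
sample_solution_set <- function(m, n = 50L, seed = 20180808L,
                                cl = classify_regime(m)) {
  if (!cl$regime %in% c("CASE_2", "CASE_2P"))
    stop("sampling is defined for the level-set regime only (got ",
         cl$regime, ")")
  Bs <- cl$B_star; Vs <- cl$V_star
  L <- b_max_vec(m)
  hi <- vmax_at(Bs, m)
  lo <- if (m$mode == "equality") vmin_at(Bs, m) else NULL
  ## pick a blend endpoint on the required side of the viability level:
  ## usually a random envelope allocation, sometimes a qualifying pairwise
  ## mixture of two of them, which spreads samples along connected arcs of
  ## the optimal set instead of piling them up near the envelope vertices
  pick_bend <- function(tlist, above) {
    if (length(tlist) > 1L && stats::runif(1) < 0.7) {
      ij <- sample.int(length(tlist), 2L)
      w <- stats::runif(1)
      cand <- w * tlist[[ij[1L]]] + (1 - w) * tlist[[ij[2L]]]
      val <- sum_phi_all(m, cand)
      if ((above && val >= Vs) || (!above && val <= Vs)) return(cand)
    }
    tlist[[sample.int(length(tlist), 1L)]]
  }
  out <- with_seed(seed, {
    lapply(seq_len(n), function(dummy) {
      b0 <- random_slice_point(L, Bs)
      cur <- sum_phi_all(m, b0)
      if (m$mode == "inequality") {
        if (cur >= Vs - 1e-12) {
          v <- phi_vec(m, b0)
          if (sum(v) > 0) v <- v * Vs / sum(v)
          return(strategy(b0, v))
        }
        b <- blend_to_level(m, b0, pick_bend(hi$ties, TRUE), Vs)
        return(on_curve_strategy(m, b))
      }
      ## equality mode: hit sum(phi(b)) = V* exactly
      if (abs(cur - Vs) <= 1e-10 * max(1, Vs)) return(on_curve_strategy(m, b0))
      bend <- if (cur < Vs) pick_bend(hi$ties, TRUE) else pick_bend(lo$ties, FALSE)
      b <- blend_to_level(m, b0, bend, Vs)
      on_curve_strategy(m, b)
    })
  })
  nd <- length(unique_vectors(lapply(out, `[[`, "b"),
                              tol = 1e-7 * max(1, max(L))))
  structure(out, n_distinct = nd, short = nd < n)
}

## uniform-ish random point of the slice {sum(b)=T, 0<=b<=L}
random_slice_point <- function(L, T) {
  w <- stats::runif(length(L))
  b <- w / sum(w) * T
  for (it in 1:100) {
    over <- pmax(b - L, 0)
    if (sum(over) <= 1e-12) break
    b <- pmin(b, L)
    head <- L - b
    b <- b + sum(over) * head / sum(head)
  }
  pmin(b, L)
}

## ---- methods on colony_solution ------------------------------------------

#' @export
print.colony_solution <- function(x, ...) {
  cat(sprintf("colony solution [%s, %s mode]\n", x$case$regime, x$model$mode))
  if (x$dead) {
    cat("  empty feasible domain: the environment cannot sustain the colony\n")
    return(invisible(x))
  }
  cat(sprintf("  W* = %.6g at B* = %.6g, V* = %.6g\n",
              x$W_star, x$B_star, x$V_star))
  cat(sprintf("  optimal set: %s (%d representative strateg%s",
              x$set_kind, length(x$strategies),
              if (length(x$strategies) == 1) "y)" else "ies)"))
  if (!is.null(x$diagnostics$n_components))
    cat(sprintf(", %d component(s)", x$diagnostics$n_components))
  cat("\n")
  if (length(x$specialization)) {
    sp <- x$specialization[[1L]]
    cat(sprintf("  specialization (first strategy): %d germ, %d soma, %d unspecialized\n",
                sp$n_germ, sp$n_soma, sp$n_unspecialized))
  }
  invisible(x)
}

#' @export
summary.colony_solution <- function(object, ...) {
  print(object)
  if (length(object$strategies)) {
    cat("\nstrategies:\n")
    print(utils::head(strategy_table(object), 12L), row.names = FALSE)
    if (nrow(strategy_table(object)) > 12L) cat("  ...\n")
  }
  invisible(object)
}

#' @export
coef.colony_solution <- function(object, ...) {
  c(B = object$B_star, V = object$V_star, W = object$W_star)
}

#' Tabulate solution strategies
#'
#' One row per (strategy, cell) with fecundity, viability and the germ/soma
#' label.
#'
#' @param x a `"colony_solution"`.
#' @return a data.frame with columns `strategy`, `cell`, `b`, `v`, `label`.
#' @export
strategy_table <- function(x) {
  stopifnot(inherits(x, "colony_solution"))
  if (!length(x$strategies))
    return(data.frame(strategy = integer(), cell = integer(),
                      b = numeric(), v = numeric(), label = character()))
  do.call(rbind, lapply(seq_along(x$strategies), function(k) {
    s <- x$strategies[[k]]
    data.frame(strategy = k, cell = seq_along(s$b), b = s$b, v = s$v,
               label = x$specialization[[k]]$labels)
  }))
}

#' @export
plot.colony_solution <- function(x, ...) {
  m <- x$model
  L <- b_max_vec(m); vmx <- v_max_vec(m)
  plot(NA, xlim = c(0, max(L) * 1.05), ylim = c(0, max(vmx) * 1.05),
       xlab = "cell fecundity b", ylab = "cell viability v",
       main = sprintf("trade-off curves and optima [%s]", x$case$regime), ...)
  for (i in seq_len(m$N)) {
    bs <- seq(0, L[i], length.out = 200L)
    graphics::lines(bs, phi_at(m$cells[[i]], bs), col = i, lwd = 1.5)
  }
  for (s in x$strategies)
    graphics::points(s$b, s$v, col = seq_len(m$N), pch = 19)
  graphics::legend("topright", legend = paste("cell", seq_len(m$N)),
                   col = seq_len(m$N), lty = 1, bty = "n")
  invisible(x)
}
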