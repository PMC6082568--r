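#' Attainable-viability envelopes at fixed total fecundity
#'
#' At a given total fecundity `T = sum(b_i)` the colony can realise any group
#' viability between `vmin_at(T)` and `vmax_at(T)` by redistributing fecundity
#' across cells (with every cell on its trade-off curve). These envelopes are
#' the machinery behind the attainability test of the level-set regime (is the
#' optimal pair `(B*, V*)` reachable?) and behind the resource-surface solver.
#'
#' `vmax_at()` maximizes `sum(phi_i(b_i))` subject to `sum(b_i) = T` and box
#' bounds. For concave/linear cells this is solved by equalizing the marginal
#' slopes `|phi_i'|` via monotone bisection on the shared multiplier, with
#' per-cell clipping (water-filling with box constraints). When convex cells
#' are present, their specialization patterns (each convex cell at 0 or at
#' `b_max`, at most one interior) are enumerated and combined with the
#' concave subproblem.
#'
#' `vmin_at()` minimizes the same sum. For concave/linear cells the minimum of
#' a concave sum over the slice polytope sits at a vertex (every cell at a box
#' face except at most one), found by vertex enumeration — exact for the
#' quadratic forms. Convex cells contribute a smooth convex subproblem solved
#' by the same marginal-equalization bisection.
#'
#' @param T total fecundity, in `[0, sum(b_max)]`.
#' @param m a [colony_model()].
#' @return a list with `value` (the envelope viability), `b` (an attaining
#'   fecundity vector) and `ties` (all attaining vectors found, for
#'   enumeration-based paths).
#' @examples
#' m <- worked_example_model("inequality")
#' vmax_at(11 / 6, m)$value # 79/6
#' @export
vmax_at <- function(T, m) {
  env_check_T(T, m)
  envelope_solve(T, m, sense = "max")
}

#' @rdname vmax_at
#' @export
vmin_at <- function(T, m) {
  env_check_T(T, m)
  envelope_solve(T, m, sense = "min")
}

env_check_T <- function(T, m) {
  Lsum <- sum(b_max_vec(m))
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) ||
      T < -1e-9 || T > Lsum + 1e-9 * max(1, Lsum))
    stop(sprintf("T must lie in [0, %.6g]", Lsum))
}

envelope_solve <- function(T, m, sense) {
  L <- b_max_vec(m)
  T <- min(max(T, 0), sum(L))
  cv <- curvature_vec(m)
  if (any(cv == "mixed"))
    stop("custom trade-off with mixed curvature is not supported by envelopes")
  if (sense == "max") {
    smooth <- which(cv %in% c("concave", "linear"))
    enum <- which(cv == "convex")
  } else {
    smooth <- which(cv == "convex")
    enum <- which(cv %in% c("concave", "linear"))
  }
  ## linear cells are handled on the water-filling side for the max (their
  ## contribution is concave) and on the vertex side for the min (an LP
  ## attains its minimum at a vertex); reassign for the min:
  if (sense == "min") {
    lin <- which(cv == "linear")
    smooth <- setdiff(smooth, lin)
    enum <- sort(unique(c(enum, lin)))
  }
  if (!length(enum)) {
    r <- smooth_allocate(T, m, smooth, sense)
    return(list(value = r$value, b = r$b, ties = list(r$b)))
  }
  enumerate_with_smooth(T, m, enum, smooth, sense)
}

## ---- smooth subproblem: equalize marginal slopes with clipping ----------
## For sense "max" over concave/linear cells, b_i(lam) = argmax phi_i(b)+lam*b
## is nondecreasing in lam; for sense "min" over convex cells the analogous
## b_i(mu) is nondecreasing in mu. sum(b_i) is piecewise linear in the
## multiplier, so the breakpoint tables (computed once per colony in this
## factory) give an exact O(K) solve per budget; only custom curves need a
## bisection. Linear cells contribute jumps, resolved by one-sided limits and
## a residual fill over the jumping (tied) cells.
make_smooth_alloc <- function(m, idx, sense) {
  if (!length(idx)) {
    zero <- numeric(0)
    return(function(T) {
      if (T > 1e-9) return(NULL)
      list(b_idx = zero, value = 0)
    })
  }
  L <- b_max_vec(m)[idx]
  cells <- m$cells[idx]
  vv <- vapply(cells, function(tr) tr$v_max, numeric(1))
  islin <- vapply(cells, function(tr) tr$form == "linear", logical(1))
  isccv <- vapply(cells, function(tr) tr$form == "quadratic_concave", logical(1))
  iscvx <- vapply(cells, function(tr) tr$form == "quadratic_convex", logical(1))
  iscus <- vapply(cells, function(tr) tr$form == "custom", logical(1))
  gam <- ifelse(islin, vv / L, NA_real_)
  ccoef <- L^2 / (2 * vv)  # quadratic forms: multiplier-to-b slope
  b_of <- function(lam) {
    b <- numeric(length(cells))
    if (any(isccv)) b[isccv] <- pmin(lam * ccoef[isccv], L[isccv])
    if (any(iscvx)) b[iscvx] <- pmin(pmax(L[iscvx] - lam * ccoef[iscvx], 0),
                                     L[iscvx])
    if (any(islin)) b[islin] <- if (sense == "max")
      ifelse(lam > gam[islin], L[islin], 0) else
      ifelse(lam < gam[islin], L[islin], 0)
    if (any(iscus)) b[iscus] <- vapply(which(iscus), function(j)
      invert_dphi(cells[[j]], -lam), numeric(1))
    b
  }
  b_incl <- function(lam) {  # right limit at a breakpoint: jumps included
    b <- b_of(lam)
    if (any(islin)) b[islin] <- if (sense == "max")
      ifelse(lam >= gam[islin], L[islin], 0) else
      ifelse(lam <= gam[islin], L[islin], 0)
    b
  }
  value_of <- function(b) {  # sum of phi over the idx cells only
    val <- 0
    if (any(isccv)) val <- val + sum(vv[isccv] * (1 - (b[isccv] / L[isccv])^2))
    if (any(iscvx)) val <- val + sum(vv[iscvx] * (1 - b[iscvx] / L[iscvx])^2)
    if (any(islin)) val <- val + sum(vv[islin] * (1 - b[islin] / L[islin]))
    if (any(iscus)) val <- val + sum(vapply(which(iscus), function(j)
      phi_at(cells[[j]], b[j]), numeric(1)))
    val
  }
  slope_mag <- vapply(seq_along(cells), function(j) {
    if (islin[j]) gam[j]
    else max(abs(dphi_at(cells[[j]], c(0, L[j]))))
  }, numeric(1))
  hi0 <- max(slope_mag) * (1 + 1e-9) + 1e-9
  increasing <- sum(b_of(hi0)) >= sum(b_of(0))
  exact <- !any(iscus)
  if (exact) {
    brk <- sort(unique(c(0, hi0, pmin(pmax(c(
      if (any(isccv)) L[isccv] / ccoef[isccv],
      if (any(iscvx)) L[iscvx] / ccoef[iscvx],
      gam[islin]), 0), hi0))))
    Sm <- vapply(brk, function(x) sum(b_of(x)), numeric(1))
    Sp <- vapply(brk, function(x) sum(b_incl(x)), numeric(1))
  }
  Lsum <- sum(L)
  tiewin <- 1e-7 * max(1, max(slope_mag))
  function(T) {
    if (T <= 0) {
      b <- b_of(if (increasing) 0 else hi0) * 0
      return(list(b_idx = b, value = value_of(b)))
    }
    if (T >= Lsum) {
      return(list(b_idx = L, value = value_of(L)))
    }
    if (exact) {
      lam <- NA_real_
      if (increasing) {
        for (k in seq_along(brk)) {
          if (Sm[k] <= T + 1e-12 && T <= Sp[k] + 1e-12) { lam <- brk[k]; break }
          if (k < length(brk) && Sp[k] <= T + 1e-12 && T <= Sm[k + 1L] + 1e-12) {
            slope <- (Sm[k + 1L] - Sp[k]) / (brk[k + 1L] - brk[k])
            lam <- if (slope > 1e-12) brk[k] + (T - Sp[k]) / slope else brk[k]
            break
          }
        }
      } else {
        for (k in seq_along(brk)) {
          if (Sp[k] <= T + 1e-12 && T <= Sm[k] + 1e-12) { lam <- brk[k]; break }
          if (k < length(brk) && Sm[k + 1L] <= T + 1e-12 && T <= Sp[k] + 1e-12) {
            slope <- (Sm[k + 1L] - Sp[k]) / (brk[k + 1L] - brk[k])
            lam <- if (abs(slope) > 1e-12) brk[k] + (T - Sp[k]) / slope
                   else brk[k]
            break
          }
        }
      }
      if (is.na(lam)) lam <- hi0
      lam <- min(max(lam, 0), hi0)
    } else {
      lo <- 0; hi <- hi0
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        if ((sum(b_of(mid)) - T > 0) == increasing) hi <- mid else lo <- mid
        if (hi - lo < 1e-14 * max(1, hi)) break
      }
      lam <- if (increasing) lo else hi
    }
    cand <- b_of(lam)
    r <- T - sum(cand)
    if (r > 0) {
      ## distribute the residual (large only at linear-slope ties) over the
      ## tied cells first, then over any remaining headroom
      pref <- order(!(islin & abs(gam - lam) <= tiewin))
      for (j in pref) {
        add <- min(r, L[j] - cand[j])
        cand[j] <- cand[j] + add
        r <- r - add
        if (r <= 0) break
      }
    } else if (r < 0) {
      for (j in seq_along(cand)) {
        cut <- min(-r, cand[j])
        cand[j] <- cand[j] - cut
        r <- r + cut
        if (r >= 0) break
      }
    }
    list(b_idx = cand, value = value_of(cand))
  }
}

## one-off interface over the allocator factory
smooth_allocate <- function(T, m, idx, sense) {
  alloc <- make_smooth_alloc(m, idx, sense)
  r <- alloc(min(max(T, 0), if (length(idx)) sum(b_max_vec(m)[idx]) else 0))
  b <- numeric(m$N)
  if (length(idx)) b[idx] <- r$b_idx
  list(value = sum_phi_all(m, b), b = b)
}

sum_phi_all <- function(m, b) sum(phi_vec(m, b))

## ---- vertex/pattern enumeration combined with the smooth subproblem ------
## Cells in `enum` are placed at 0 or b_max, with at most one interior;
## the remaining budget goes to the smooth subproblem. All candidates within
## relative tie tolerance 1e-9 are retained; ties are ordered
## lexicographically (smallest b first) so results are reproducible.
enumerate_with_smooth <- function(T, m, enum, smooth, sense) {
  L <- b_max_vec(m)
  vmx <- v_max_vec(m)
  nE <- length(enum)
  Lsm <- if (length(smooth)) sum(L[smooth]) else 0
  alloc <- make_smooth_alloc(m, smooth, sense)
  best_val <- if (sense == "max") -Inf else Inf
  cands <- list()
  push <- function(val, b) {
    cands[[length(cands) + 1L]] <<- list(value = val, b = b)
    if (sense == "max") best_val <<- max(best_val, val)
    else best_val <<- min(best_val, val)
  }
  ## value and allocation with `budget` on the smooth cells, enum cells at
  ## b_enum contributing `base_v` viability
  eval_sub <- function(budget, b_enum, base_v, keep = TRUE) {
    if (budget < -1e-9 || budget > Lsm + 1e-9) return(NA_real_)
    r <- alloc(min(max(budget, 0), Lsm))
    if (is.null(r)) return(NA_real_)
    val <- base_v + r$value
    if (keep) {
      b <- b_enum
      if (length(smooth)) b[smooth] <- r$b_idx
      push(val, b)
    }
    val
  }
  for (mask in 0:(2^nE - 1L)) {
    full <- enum[bitwAnd(mask, 2^(seq_len(nE) - 1L)) > 0]
    base <- sum(L[full])
    if (base > T + 1e-9) next
    b_enum <- numeric(m$N)
    b_enum[full] <- L[full]
    rest <- setdiff(enum, full)
    base_v0 <- sum(vmx[rest])  # enum cells at rest sit at b = 0
    ## (a) no interior enum cell: smooth cells absorb the remainder
    eval_sub(T - base, b_enum, base_v0)
    ## (b) one interior enum cell j
    for (j in rest) {
      R <- T - base
      t_lo <- max(0, R - Lsm); t_hi <- min(L[j], R)
      if (t_lo > t_hi + 1e-12) next
      base_vj <- base_v0 - vmx[j]
      objf <- function(t) {
        v <- eval_sub(R - t, b_enum, base_vj + phi_at(m$cells[[j]], t),
                      keep = FALSE)
        if (is.na(v)) (if (sense == "max") -Inf else Inf) else v
      }
      ts <- if (t_hi - t_lo < 1e-10) t_lo
            else seq(t_lo, t_hi, length.out = 17L)
      vals <- vapply(ts, objf, numeric(1))
      kbest <- which.min(if (sense == "max") -vals else vals)
      blo <- ts[max(1L, kbest - 1L)]; bhi <- ts[min(length(ts), kbest + 1L)]
      if (bhi > blo + 1e-12) {
        op <- stats::optimize(objf, c(blo, bhi),
                              maximum = (sense == "max"), tol = 1e-10)
        tstar <- if (sense == "max") op$maximum else op$minimum
      } else tstar <- ts[kbest]
      for (t in unique(c(tstar, t_lo, t_hi))) {
        be <- b_enum; be[j] <- t
        eval_sub(R - t, be, base_vj + phi_at(m$cells[[j]], t))
      }
    }
  }
  if (!length(cands)) stop("envelope enumeration found no feasible allocation")
  tol <- 1e-9 * max(1, abs(best_val))
  keep <- Filter(function(cc) abs(cc$value - best_val) <= tol, cands)
  bs <- unique_vectors(lapply(keep, `[[`, "b"))
  ## lexicographic order on the vectors themselves (reproducible tie-breaks)
  ord <- do.call(order, as.data.frame(do.call(rbind, bs)))
  bs <- bs[ord]
  list(value = best_val, b = bs[[1L]], ties = bs)
}

## deduplicate a list of numeric vectors (absolute tolerance 1e-9)
unique_vectors <- function(bs, tol = 1e-9) {
  out <- list()
  for (b in bs) {
    dup <- any(vapply(out, function(o) max(abs(o - b)) <= tol, logical(1)))
    if (!dup) out[[length(out) + 1L]] <- b
  }
  out
}
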