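#' Scan the resource axis for regime and pattern transitions
#'
#' Classifies the model on a coarse grid of resource levels and bisects every
#' detected regime change down to `tol`, yielding the ordered thresholds that
#' separate regimes. Within regimes whose solution is a single point it also
#' tracks the per-cell germ/soma label vector and bisects
#' specialization-pattern changes (a cell's optimal fecundity hitting or
#' leaving its bound) the same way.
#'
#' @param m a [colony_model()]; its own `C` is ignored in favour of the grid.
#' @param C_lo,C_hi scan range, `C_lo < C_hi`.
#' @param tol bisection tolerance on the threshold location.
#' @param grid_n coarse grid size (transitions inside a grid step narrower
#'   than the step can be missed).
#' @return object of class `"regime_scan"`: `grid`, `labels`, `patterns`,
#'   and a data.frame `thresholds` with columns `value`, `left`, `right`,
#'   `kind` (`"case_change"` or `"pattern_change"`).
#' @examples
#' \donttest{
#' m <- worked_example_model("inequality")
#' sc <- scan_resource(m, 5, 45, tol = 1e-3)
#' sc$thresholds
#' }
#' @export
scan_resource <- function(m, C_lo, C_hi, tol = 1e-3, grid_n = 81L) {
  if (!(C_lo < C_hi) || tol <= 0) stop("need C_lo < C_hi and tol > 0")
  grid <- seq(C_lo, C_hi, length.out = grid_n)
  state_at <- function(C) {
    mm <- with_resource(m, C)
    cl <- classify_regime(mm)
    pat <- NA_character_
    base <- sub("P$", "", sub("CASE_", "", cl$regime))
    if (base %in% c("1", "3")) {
      sol <- solve_colony(mm)
      if (sol$set_kind == "single_point" && length(sol$specialization))
        pat <- paste(sol$specialization[[1L]]$labels, collapse = ",")
    }
    list(regime = cl$regime, pattern = pat)
  }
  states <- lapply(grid, state_at)
  labels <- vapply(states, `[[`, character(1), "regime")
  patterns <- vapply(states, `[[`, character(1), "pattern")
  thresholds <- data.frame(value = numeric(), left = character(),
                           right = character(), kind = character(),
                           stringsAsFactors = FALSE)
  bisect <- function(loC, hiC, pick, kind) {
    lv <- pick(state_at(loC)); hv <- pick(state_at(hiC))
    while (hiC - loC > tol) {
      mid <- (loC + hiC) / 2
      if (identical(pick(state_at(mid)), lv)) loC <- mid else hiC <- mid
    }
    data.frame(value = (loC + hiC) / 2, left = as.character(lv),
               right = as.character(pick(state_at(hiC))), kind = kind,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(grid_n - 1L)) {
    if (!identical(labels[i], labels[i + 1L])) {
      thresholds <- rbind(thresholds,
                          bisect(grid[i], grid[i + 1L],
                                 function(st) st$regime, "case_change"))
    } else if (!is.na(patterns[i]) && !is.na(patterns[i + 1L]) &&
               !identical(patterns[i], patterns[i + 1L])) {
      thresholds <- rbind(thresholds,
                          bisect(grid[i], grid[i + 1L],
                                 function(st) st$pattern, "pattern_change"))
    }
  }
  thresholds <- thresholds[order(thresholds$value), , drop = FALSE]
  structure(list(param = "C", grid = grid, labels = labels,
                 patterns = patterns, thresholds = thresholds, tol = tol),
            class = "regime_scan")
}

#' @export
print.regime_scan <- function(x, ...) {
  cat(sprintf("resource scan over [%.4g, %.4g] (%d grid points, tol %.2g)\n",
              min(x$grid), max(x$grid), length(x$grid), x$tol))
  rl <- rle(x$labels)
  cat("  regimes:", paste(rl$values, collapse = " -> "), "\n")
  if (nrow(x$thresholds)) {
    cat("  thresholds:\n")
    print(x$thresholds, row.names = FALSE)
  } else cat("  no transitions detected\n")
  invisible(x)
}

#' @export
plot.regime_scan <- function(x, ...) {
  reg <- factor(x$labels)
  plot(x$grid, as.integer(reg), type = "s", yaxt = "n",
       xlab = "available resource C", ylab = "regime",
       main = "regime along the resource axis", ...)
  graphics::axis(2, at = seq_along(levels(reg)), labels = levels(reg), las = 1)
  graphics::abline(v = x$thresholds$value,
                   lty = ifelse(x$thresholds$kind == "case_change", 2, 3),
                   col = "grey40")
  invisible(x)
}

#' Three-cell heterogeneous concave example
#'
#' The small-colony example with trade-off curves `v1 = 6 - 3*b1^2`,
#' `v2 = 4 - b2^2`, `v3 = 5 - 2*b3^2` (so `b_max = (sqrt(2), 2, sqrt(2.5))`),
#' exponents `alpha = beta = 1` and costs `k1 = 2`, `k2 = 3`. Scanning its
#' resource level exhibits every solution regime in both trade-off modes.
#'
#' @param mode trade-off constraint mode.
#' @param C resource level (vary it to move between regimes).
#' @return a [colony_model()].
#' @export
worked_example_model <- function(mode = c("inequality", "equality"), C = 25) {
  mode <- match.arg(mode)
  cells <- list(tradeoff("quadratic_concave", v_max = 6, b_max = sqrt(2)),
                tradeoff("quadratic_concave", v_max = 4, b_max = 2),
                tradeoff("quadratic_concave", v_max = 5, b_max = sqrt(2.5)))
  colony_model(cells, alpha = 1, beta = 1, k1 = 2, k2 = 3, C = C, mode = mode)
}

#' Catalog of three-cell illustration models
#'
#' Ready-made three-aggregate-cell models covering the curvature classes and
#' regimes of the accompanying illustrations: convex identical cells
#' (`fig1a`-`fig3b`, `phi = (b-1)^2`), linear identical cells (`fig4a/b`,
#' `phi = 1-b`), concave identical cells (`fig5a`-`fig7b`, `phi = 1-b^2`),
#' and heterogeneous colonies with positional effects (`fig8a`-`fig8f`).
#' The `fig8*` models illustrate the resource-slack regime; their costs and
#' resource level (`k1 = k2 = 1`, `C = 100`) are set so the budget is slack.
#'
#' @param name fixture name, e.g. `"fig1a"`.
#' @return a [colony_model()] (equality mode, as in the original problem).
#' @export
figure_fixture <- function(name) {
  cvx1 <- tradeoff("quadratic_convex", v_max = 1, b_max = 1)    # (b-1)^2
  lin1 <- tradeoff("linear", v_max = 1, b_max = 1)              # 1-b
  ccv1 <- tradeoff("quadratic_concave", v_max = 1, b_max = 1)   # 1-b^2
  mk <- function(tr, alpha, beta, k1, k2, C)
    colony_model(tr, n = 3L, alpha = alpha, beta = beta, k1 = k1, k2 = k2,
                 C = C, mode = "equality")
  mk8 <- function(cells, beta)
    colony_model(cells, alpha = 1, beta = beta, k1 = 1, k2 = 1, C = 100,
                 mode = "equality")
  cells8ab <- list(tradeoff("quadratic_convex", v_max = 4, b_max = 2),  # (b-2)^2
                   tradeoff("quadratic_convex", v_max = 4, b_max = 2),
                   tradeoff("quadratic_convex", v_max = 3, b_max = 3))  # (b/sqrt(3)-sqrt(3))^2
  cells8cd <- list(tradeoff("linear", v_max = 4, b_max = 4),            # 4-b
                   tradeoff("linear", v_max = 4, b_max = 4),
                   tradeoff("linear", v_max = 2, b_max = 6))            # 2-b/3
  cells8ef <- list(tradeoff("quadratic_concave", v_max = 4, b_max = 2), # 4-b^2
                   tradeoff("quadratic_concave", v_max = 2, b_max = 4), # 2-b^2/8
                   tradeoff("quadratic_concave", v_max = 3, b_max = 3)) # 3-b^2/3
  switch(name,
         fig1a = mk(cvx1, 1, 0.5, 1, 1, 4),
         fig1b = mk(cvx1, 1, 2,   1, 1, 4),
         fig2a = mk(cvx1, 1, 0.5, 1, 1, 2.85),
         fig2b = mk(cvx1, 1, 2,   1, 1, 2.85),
         fig3a = mk(cvx1, 1, 4,   1, 1, 2.85),
         fig3b = mk(cvx1, 1, 4,   1, 1, 2.5),
         fig4a = mk(lin1, 1, 2,   1, 1, 4),
         fig4b = mk(lin1, 1, 2,   1, 2, 4),
         fig5a = mk(ccv1, 1, 0.5, 2, 1, 8),
         fig5b = mk(ccv1, 1, 2,   2, 1, 8),
         fig6a = mk(ccv1, 1, 0.5, 2, 1, 5.5),
         fig6b = mk(ccv1, 1, 0.25, 2, 1, 5),
         fig7a = mk(ccv1, 1, 2,   2, 1, 5),
         fig7b = mk(ccv1, 1, 1,   1, 1, 3.12),
         fig8a = mk8(cells8ab, 2),
         fig8b = mk8(cells8ab, 0.5),
         fig8c = mk8(cells8cd, 2),
         fig8d = mk8(cells8cd, 0.5),
         fig8e = mk8(cells8ef, 2),
         fig8f = mk8(cells8ef, 0.5),
         stop("unknown fixture name: ", name))
}

#' Names of the available illustration models
#' @return character vector accepted by [figure_fixture()].
#' @export
figure_fixture_names <- function() {
  c(paste0("fig", rep(1:7, each = 2), c("a", "b")),
    paste0("fig8", letters[1:6]))
}
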