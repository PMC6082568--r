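#' Colony optimization problem instance
#'
#' Bundles the full problem data: the per-cell trade-off curves, the fitness
#' exponents, the resource costs and budget, and the trade-off constraint mode.
#' Colony fitness is `W = B^alpha * V^beta` with group fecundity `B = sum(b_i)`
#' and group viability `V = sum(v_i)`; the resource budget is
#' `k1*B + k2*V <= C`. In `"equality"` mode every cell sits exactly on its
#' trade-off curve (`v_i = phi_i(b_i)`); in `"inequality"` mode viability may
#' fall below the curve (`0 <= v_i <= phi_i(b_i)`).
#'
#' @param cells a [tradeoff()] object (replicated `n` times) or a list of them.
#' @param alpha,beta positive fitness exponents — the 'importances' (or rates)
#'   of fecundity and viability. The generation-time fitness `W = B * V^T` is
#'   the special case `alpha = 1, beta = T`.
#' @param k1,k2 positive resource cost per unit of fecundity / viability.
#' @param C positive amount of available resource.
#' @param mode trade-off constraint form, `"equality"` or `"inequality"`.
#' @param n number of cells when `cells` is a single trade-off.
#' @return an object of class `"colony_model"`.
#' @examples
#' m <- colony_model(tradeoff("linear", v_max = 1, b_max = 1), n = 3,
#'                   alpha = 1, beta = 2, k1 = 1, k2 = 1, C = 4)
#' m
#' @export
colony_model <- function(cells, alpha, beta, k1, k2, C,
                         mode = c("equality", "inequality"), n = NULL) {
  mode <- match.arg(mode)
  if (inherits(cells, "tradeoff")) {
    if (is.null(n)) n <- 1L
    cells <- rep(list(cells), n)
  }
  if (!is.list(cells) || !length(cells) ||
      !all(vapply(cells, inherits, logical(1), "tradeoff")))
    stop("'cells' must be a tradeoff or a non-empty list of tradeoffs")
  for (p in c("alpha", "beta", "k1", "k2", "C")) {
    val <- get(p)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("'%s' must be a single finite positive number", p))
  }
  if (length(cells) > 20L)
    stop("at most 20 cells are supported (specialization-pattern enumeration)")
  structure(list(cells = cells, N = length(cells),
                 alpha = alpha, beta = beta, k1 = k1, k2 = k2, C = C,
                 mode = mode),
            class = "colony_model")
}

#' @export
print.colony_model <- function(x, ...) {
  forms <- vapply(x$cells, function(tr) tr$form, character(1))
  cat(sprintf("colony model: %d cell(s), %s trade-offs\n", x$N,
              paste(unique(forms), collapse = "/")))
  cat(sprintf("  W = B^%.4g * V^%.4g; budget %.4g*B + %.4g*V <= %.4g\n",
              x$alpha, x$beta, x$k1, x$k2, x$C))
  cat(sprintf("  mode: %s; v_max = (%s); b_max = (%s)\n", x$mode,
              paste(signif(v_max_vec(x), 5), collapse = ", "),
              paste(signif(b_max_vec(x), 5), collapse = ", ")))
  invisible(x)
}

## per-cell bound vectors
b_max_vec <- function(m) vapply(m$cells, function(tr) tr$b_max, numeric(1))
v_max_vec <- function(m) vapply(m$cells, function(tr) tr$v_max, numeric(1))

## phi_i(b_i) for a fecundity vector
phi_vec <- function(m, b) {
  vapply(seq_len(m$N), function(i) phi_at(m$cells[[i]], b[i]), numeric(1))
}

## curvature classes of all cells
curvature_vec <- function(m) vapply(m$cells, tradeoff_curvature, character(1))

## shallow copy with a different resource level (used by scans/bisection)
with_resource <- function(m, C) { m$C <- C; m }

#' Candidate allocation strategy
#'
#' A per-cell allocation `(b, v)` of fecundity and viability. Validity against
#' a model (box bounds, trade-off mode, resource budget) is checked by
#' [is_feasible()].
#'
#' @param b,v numeric vectors of equal length: per-cell fecundity, viability.
#' @return an object of class `"strategy"`.
#' @export
strategy <- function(b, v) {
  if (!is.numeric(b) || !is.numeric(v) || length(b) != length(v))
    stop("'b' and 'v' must be numeric vectors of equal length")
  structure(list(b = as.numeric(b), v = as.numeric(v)), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat("strategy:\n")
  print(data.frame(cell = seq_along(x$b), b = x$b, v = x$v), row.names = FALSE)
  invisible(x)
}

## strategy with viability on the trade-off curve
on_curve_strategy <- function(m, b) strategy(b, phi_vec(m, b))

#' Group fecundity and viability of a strategy
#'
#' @param s a [strategy()].
#' @return named numeric `c(B, V)` with `B = sum(b_i)`, `V = sum(v_i)`.
#' @export
group_levels <- function(s) {
  stopifnot(inherits(s, "strategy"))
  c(B = sum(s$b), V = sum(s$v))
}

#' Colony fitness of a strategy
#'
#' `W = B^alpha * V^beta`; zero exactly when `B = 0` or `V = 0`.
#'
#' @param s a [strategy()].
#' @param m a [colony_model()] (supplies the exponents).
#' @return fitness value (nonnegative scalar).
#' @export
fitness <- function(s, m) {
  g <- group_levels(s)
  if (length(s$b) != m$N) stop("strategy length does not match model")
  fitness_bv(g[["B"]], g[["V"]], m$alpha, m$beta)
}

## fitness from group levels; 0^0 never arises since alpha, beta > 0
fitness_bv <- function(B, V, alpha, beta) {
  if (any(B < -1e-12) || any(V < -1e-12))
    stop("negative group fecundity or viability")
  pmax(B, 0)^alpha * pmax(V, 0)^beta
}

#' Resource usage of a strategy
#'
#' @inheritParams fitness
#' @return `k1*B + k2*V`.
#' @export
resource_usage <- function(s, m) {
  g <- group_levels(s)
  m$k1 * g[["B"]] + m$k2 * g[["V"]]
}

#' Feasibility of a strategy
#'
#' Checks box bounds, the trade-off constraints in the model's mode, and the
#' resource budget, all within tolerance `tol`. Returns `FALSE` with a
#' `"reason"` attribute rather than erroring.
#'
#' @inheritParams fitness
#' @param tol absolute tolerance.
#' @return logical scalar with attribute `reason` (`"ok"` when `TRUE`).
#' @export
is_feasible <- function(s, m, tol = 1e-8) {
  if (length(s$b) != m$N)
    return(structure(FALSE, reason = "length mismatch"))
  L <- b_max_vec(m)
  fail <- function(why) structure(FALSE, reason = why)
  if (any(s$b < -tol) || any(s$v < -tol)) return(fail("negative allocation"))
  if (any(s$b > L + tol)) return(fail("fecundity above b_max"))
  ph <- phi_vec(m, pmin(pmax(s$b, 0), L))
  if (m$mode == "equality") {
    if (any(abs(s$v - ph) > tol)) return(fail("off the trade-off curve"))
  } else {
    if (any(s$v > ph + tol)) return(fail("viability above trade-off curve"))
  }
  if (resource_usage(s, m) > m$C + tol) return(fail("resource budget exceeded"))
  structure(TRUE, reason = "ok")
}

#' Germ/soma specialization labels of a strategy
#'
#' A cell is germ-specialized when its fecundity reaches `b_max`, and
#' soma-specialized when its viability reaches `v_max`; otherwise it is an
#' unspecialized generalist. Comparison uses relative tolerance `tol` of the
#' corresponding bound.
#'
#' @inheritParams fitness
#' @param tol relative tolerance.
#' @return a list of class `"specialization_summary"`: `labels` (character
#'   vector), `n_germ`, `n_soma`, `n_unspecialized`.
#' @export
classify_cells <- function(s, m, tol = 1e-6) {
  L <- b_max_vec(m); vmx <- v_max_vec(m)
  germ <- s$b >= L * (1 - tol)
  soma <- !germ & (s$v >= vmx * (1 - tol))
  labels <- ifelse(germ, "germ", ifelse(soma, "soma", "unspecialized"))
  structure(list(labels = labels,
                 n_germ = sum(germ), n_soma = sum(soma),
                 n_unspecialized = sum(!germ & !soma)),
            class = "specialization_summary")
}

#' @export
print.specialization_summary <- function(x, ...) {
  cat(sprintf("specialization: %d germ, %d soma, %d unspecialized\n",
              x$n_germ, x$n_soma, x$n_unspecialized))
  cat("  cells:", paste(sprintf("%d=%s", seq_along(x$labels), x$labels),
                        collapse = " "), "\n")
  invisible(x)
}
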