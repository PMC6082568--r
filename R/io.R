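#' Read and write colony model configurations
#'
#' The JSON configuration holds exactly the keys `alpha`, `beta`, `k1`, `k2`,
#' `C`, `mode` and `cells`; each cell holds `form`, `b_max` and either a flat
#' `v_max` or a `params` object containing it. Unknown keys are rejected with
#' the offending name; `v_max`, when also derivable from the form, is
#' cross-checked against `phi(0)`. Validation samples each curve at 101
#' points and rejects non-decreasing trade-offs.
#'
#' @param path file path.
#' @return `read_colony_config()` returns a [colony_model()];
#'   `write_colony_config()` invisibly returns `path`.
#' @export
read_colony_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  allowed <- c("alpha", "beta", "k1", "k2", "C", "mode", "cells")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(allowed, names(cfg))
  if (length(missing)) stop("missing config key(s): ", paste(missing, collapse = ", "))
  cells <- lapply(seq_along(cfg$cells), function(i) {
    cc <- cfg$cells[[i]]
    ok_keys <- c("form", "b_max", "v_max", "params")
    extra <- setdiff(names(cc), ok_keys)
    if (length(extra))
      stop(sprintf("cell %d: unknown key(s): %s", i, paste(extra, collapse = ", ")))
    v_max <- cc$v_max
    if (is.null(v_max) && !is.null(cc$params)) v_max <- cc$params$v_max
    if (is.null(v_max)) stop(sprintf("cell %d: v_max missing", i))
    if (is.null(cc$form) || is.null(cc$b_max))
      stop(sprintf("cell %d: form and b_max are required", i))
    tr <- tradeoff(cc$form, v_max = v_max, b_max = cc$b_max)
    ## monotonicity check (catches malformed custom parameter sets)
    bs <- seq(0, tr$b_max, length.out = 101L)
    if (any(diff(phi_at(tr, bs)) > 1e-9 * max(1, tr$v_max)))
      stop(sprintf("cell %d: trade-off is not strictly decreasing", i))
    if (abs(phi_at(tr, 0) - v_max) > 1e-6 * max(1, v_max))
      stop(sprintf("cell %d: v_max inconsistent with phi(0)", i))
    tr
  })
  colony_model(cells, alpha = cfg$alpha, beta = cfg$beta, k1 = cfg$k1,
               k2 = cfg$k2, C = cfg$C, mode = cfg$mode)
}

#' @rdname read_colony_config
#' @param m a [colony_model()].
#' @export
write_colony_config <- function(m, path) {
  stopifnot(inherits(m, "colony_model"))
  cfg <- list(alpha = m$alpha, beta = m$beta, k1 = m$k1, k2 = m$k2, C = m$C,
              mode = m$mode,
              cells = lapply(m$cells, function(tr)
                list(form = tr$form, v_max = tr$v_max, b_max = tr$b_max)))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a solution report
#'
#' JSON reports round-trip losslessly through [jsonlite]; TSV reports hold
#' one row per (strategy, cell) as in [strategy_table()].
#'
#' @param sol a `"colony_solution"`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
write_report <- function(sol, path, format = c("json", "tsv")) {
  stopifnot(inherits(sol, "colony_solution"))
  if (!is.character(format) || !all(format %in% c("json", "tsv")))
    stop("unsupported report format: ", paste(setdiff(format, c("json", "tsv")),
                                              collapse = ", "))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(strategy_table(sol), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  rep <- list(case = sol$case$regime, mode = sol$model$mode, dead = sol$dead,
              W_star = sol$W_star, B_star = sol$B_star, V_star = sol$V_star,
              set_kind = sol$set_kind,
              C_unconstrained = sol$case$C_unconstrained,
              strategies = lapply(seq_along(sol$strategies), function(k)
                list(b = sol$strategies[[k]]$b, v = sol$strategies[[k]]$v,
                     labels = sol$specialization[[k]]$labels)),
              diagnostics = sol$diagnostics)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Seeded random colony generator
#'
#' Draws a colony of `n_cells` random cells of a given curvature class, for
#' property-style testing: per-cell `v_max ~ U[1, 10]`, `b_max ~ U[0.5, 3]`
#' (linear colonies redraw until all slopes are distinct — strong
#' differentiation), exponents log-uniform in `[0.4, 2.5]`, costs uniform in
#' `[0.5, 3]`, and a resource level drawn as a uniform fraction (0.15 to
#' 1.25) of the colony's maximal conceivable usage
#' `k1*sum(b_max) + k2*sum(v_max)`, so that every regime occurs across draws.
#' The same seed yields the identical model; the global RNG is untouched.
#'
#' @param n_cells number of cells (at least 1).
#' @param curvature_class `"concave"`, `"linear"`, `"convex"` or `"mixed"`.
#' @param seed integer seed.
#' @param mode trade-off constraint mode.
#' @return a [colony_model()].
#' @export
random_colony <- function(n_cells,
                          curvature_class = c("concave", "linear", "convex",
                                              "mixed"),
                          seed, mode = c("inequality", "equality")) {
  curvature_class <- match.arg(curvature_class)
  mode <- match.arg(mode)
  if (n_cells < 1L) stop("n_cells must be at least 1")
  with_seed(seed, {
    forms <- switch(curvature_class,
                    concave = rep("quadratic_concave", n_cells),
                    linear = rep("linear", n_cells),
                    convex = rep("quadratic_convex", n_cells),
                    mixed = sample(c("quadratic_concave", "linear",
                                     "quadratic_convex"), n_cells,
                                   replace = TRUE))
    repeat {
      v <- stats::runif(n_cells, 1, 10)
      L <- stats::runif(n_cells, 0.5, 3)
      if (curvature_class != "linear") break
      gam <- v / L
      if (n_cells == 1L ||
          min(diff(sort(gam))) > 1e-3 * max(gam)) break
    }
    cells <- lapply(seq_len(n_cells), function(i)
      tradeoff(forms[i], v_max = v[i], b_max = L[i]))
    alpha <- exp(stats::runif(1, log(0.4), log(2.5)))
    beta <- exp(stats::runif(1, log(0.4), log(2.5)))
    k1 <- stats::runif(1, 0.5, 3)
    k2 <- stats::runif(1, 0.5, 3)
    C <- stats::runif(1, 0.15, 1.25) * (k1 * sum(L) + k2 * sum(v))
    colony_model(cells, alpha = alpha, beta = beta, k1 = k1, k2 = k2, C = C,
                 mode = mode)
  })
}
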