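## independent mini-oracles used to freeze expected values; deliberately
## plain grid searches, sharing no code with the package internals

## best sum(phi_i(b_i)) (max or min) on the slice sum(b) = T, by grid
slice_grid_envelope <- function(m, T, n = 400L, sense = "max") {
  L <- vapply(m$cells, function(tr) tr$b_max, numeric(1))
  N <- length(L)
  stopifnot(N %in% 2:3)
  best <- if (sense == "max") -Inf else Inf
  g1 <- seq(0, L[1], length.out = n)
  if (N == 2L) {
    b2 <- T - g1
    ok <- b2 >= 0 & b2 <= L[2]
    if (!any(ok)) return(NA_real_)
    v <- phi_at(m$cells[[1]], g1[ok]) + phi_at(m$cells[[2]], b2[ok])
    return(if (sense == "max") max(v) else min(v))
  }
  g2 <- seq(0, L[2], length.out = n)
  for (b1 in g1) {
    b3 <- T - b1 - g2
    ok <- b3 >= 0 & b3 <= L[3]
    if (!any(ok)) next
    v <- phi_at(m$cells[[1]], b1) + phi_at(m$cells[[2]], g2[ok]) +
      phi_at(m$cells[[3]], b3[ok])
    best <- if (sense == "max") max(best, max(v)) else min(best, min(v))
  }
  best
}

## maximize B^alpha * V^beta on the budget line k1*B + k2*V = C, by grid
line_grid_max <- function(alpha, beta, k1, k2, C, n = 20001L) {
  B <- seq(0, C / k1, length.out = n)
  V <- (C - k1 * B) / k2
  W <- B^alpha * V^beta
  k <- which.max(W)
  list(B = B[k], V = V[k], W = W[k])
}

we_ineq <- function(C = 25) worked_example_model("inequality", C = C)
we_eq <- function(C = 25) worked_example_model("equality", C = C)
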