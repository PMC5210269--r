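# Shared construction of LPs over a network's flux space.

# Build a backend problem over the flux variables of `net`.
#   obj       numeric vector of length n (or NULL for feasibility)
#   rows      canonical rows: list of list(coefs = named vec, rhs), meaning
#             coefs . v <= rhs
#   fix_zero  indices of reactions clamped to zero
#   use_cone  TRUE: ignore l, u and use the sign cone C0 intersected with
#             the box [-1, 1]^n (flux-coupling / blockedness tests are
#             scale-invariant, so the box only bounds the LP)
flux_lp <- function(net, obj = NULL, sense = "min", rows = list(),
                    fix_zero = integer(), use_cone = FALSE,
                    delta_floor = NULL) {
  n <- n_reactions(net)
  if (use_cone) {
    lb <- ifelse(net$irreversible, 0, -1)
    ub <- rep(1, n)
  } else {
    lb <- net$lower
    ub <- net$upper
  }
  if (length(fix_zero)) {
    lb[fix_zero] <- 0
    ub[fix_zero] <- 0
  }
  if (!is.null(delta_floor)) {
    # named vector: reaction index -> required signed minimum flux
    for (k in seq_along(delta_floor)) {
      i <- as.integer(names(delta_floor)[k])
      v <- delta_floor[k]
      if (v >= 0) lb[i] <- max(lb[i], v) else ub[i] <- min(ub[i], v)
    }
  }
  S <- net$S
  trip <- Matrix::mat2triplet(S)
  Ai <- trip$i; Aj <- trip$j; Ax <- trip$x
  rlb <- rep(0, nrow(S)); rub <- rep(0, nrow(S))
  r <- nrow(S)
  for (row in rows) {
    r <- r + 1L
    idx <- rxn_index(net, names(row$coefs))
    Ai <- c(Ai, rep(r, length(idx))); Aj <- c(Aj, idx)
    Ax <- c(Ax, as.numeric(row$coefs))
    rlb <- c(rlb, -Inf); rub <- c(rub, row$rhs)
  }
  list(nvar = n, obj = obj, sense = sense, lb = lb, ub = ub,
       integrality = NULL, A = list(i = Ai, j = Aj, x = Ax),
       rlb = rlb, rub = rub)
}

# objective vector with a single 1 at reaction id/index
unit_obj <- function(net, rxn) {
  o <- numeric(n_reactions(net))
  o[if (is.character(rxn)) rxn_index(net, rxn) else rxn] <- 1
  o
}
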