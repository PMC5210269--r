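# Construction of the reduction MILPs.
#
# Three formulations are provided, all minimizing the number of active
# reactions subject to the scenario's requirements:
#
#  * build_minnw0()   -- one flux copy; all functionalities imposed on it;
#                        objective counts per-reaction (and per-direction)
#                        activity binaries. Only usable when the
#                        functionalities are mutually compatible.
#  * build_minnw()    -- one flux copy per functionality plus a copy for
#                        the protected sets; per-copy activity binaries are
#                        aggregated into one binary per reaction, which the
#                        objective counts. Handles conflicting
#                        functionalities (e.g. growth with and without
#                        oxygen).
#  * build_minnw_rep() -- minNW over a flux-coupling partition: one binary
#                        per coupling class (weighted by class size)
#                        instead of one per reaction.
#
# A problem is held in a solver-agnostic form; encode() turns it into the
# final constraint system in either big-M or indicator mode, and
# solve_milp() runs it through the HiGHS backend.

# ---- internal constructor -------------------------------------------------

# groups: list of reaction-index vectors (binary groups; singletons for the
#         reaction-space formulations)
# group_rev: logical, group gets a reverse-direction binary abar
# n_copies: number of flux copies (J); copy 1 is the protected-set copy
# fun_on_copy0: MinNW-0 semantics (all functionality rows on the only copy)
new_milp_problem <- function(net, scenario, groups, group_rev, group_weight,
                             n_copies, aggregate, formulation) {
  for (f in scenario$functionalities) {
    if (!is_resolved(f)) {
      stop("functionality '", f$label, "' has an unresolved ",
           "fraction-of-optimum spec; run resolve_scenario() first",
           call. = FALSE)
    }
  }
  if (scenario$delta >= scenario$big_M) {
    stop("delta must be smaller than big_M", call. = FALSE)
  }
  structure(list(net = net, scenario = scenario, groups = groups,
                 group_rev = group_rev, group_weight = group_weight,
                 n_copies = n_copies, aggregate = aggregate,
                 formulation = formulation, cuts = list()),
            class = "milp_problem")
}

#' @export
print.milp_problem <- function(x, ...) {
  lay <- milp_layout(x)
  cat("MILP problem (", x$formulation, "): ", x$n_copies, " flux cop",
      if (x$n_copies == 1) "y" else "ies", ", ",
      length(x$groups), " binary group(s), ", lay$nvar, " variables, ",
      length(x$cuts), " exclusion cut(s)\n", sep = "")
  invisible(x)
}

#' Build the single-copy reduction MILP
#'
#' One flux vector must simultaneously satisfy every functionality, carry
#' flux through every protected reaction, and touch every protected
#' metabolite (unless some protected reaction already does). Activity is
#' linked to the fluxes through per-reaction binaries \eqn{a_i} (and
#' \eqn{\bar a_i} for the reverse direction of reversible reactions); the
#' objective minimizes their sum, which equals the number of active
#' reactions since \eqn{a_i + \bar a_i \le 1}.
#'
#' @param net a preprocessed `metabolic_network` (no blocked reactions).
#' @param scenario a resolved `reduction_scenario`.
#' @return A `milp_problem`.
#' @seealso [build_minnw()] for conflicting functionalities,
#'   [solve_milp()].
#' @export
build_minnw0 <- function(net, scenario) {
  n <- n_reactions(net)
  new_milp_problem(net, scenario,
                   groups = as.list(seq_len(n)),
                   group_rev = !net$irreversible,
                   group_weight = rep(1, n),
                   n_copies = 1L, aggregate = FALSE,
                   formulation = "minnw0")
}

#' Build the multi-copy reduction MILP
#'
#' The workhorse formulation. Each functionality gets its own flux copy
#' \eqn{v^j} with its own activity binaries \eqn{a_i^j}; copy 0 carries the
#' protected-reaction and protected-metabolite requirements. Aggregated
#' binaries \eqn{a_i} flag a reaction as active in *any* copy, and the
#' objective minimizes their sum, so conflicting functionalities (which no
#' single flux vector can satisfy) are preserved jointly at minimum total
#' cost.
#'
#' With an empty functionality list the problem degenerates to a single
#' protected-set copy (still with aggregated binaries, so enumeration cuts
#' stay well-defined).
#'
#' @inheritParams build_minnw0
#' @return A `milp_problem`.
#' @export
build_minnw <- function(net, scenario) {
  n <- n_reactions(net)
  new_milp_problem(net, scenario,
                   groups = as.list(seq_len(n)),
                   group_rev = !net$irreversible,
                   group_weight = rep(1, n),
                   n_copies = length(scenario$functionalities) + 1L,
                   aggregate = TRUE,
                   formulation = "minnw")
}

#' Build the reduction MILP over coupling classes
#'
#' Same semantics as [build_minnw()], but binaries are indexed by the
#' classes of a flux-coupling partition instead of by individual reactions:
#' partially coupled reactions are active or inactive together, so one
#' binary per class suffices. The objective weights each class binary by
#' its class size, so the optimum still counts active *reactions*. On
#' genome-scale models this roughly halves the number of binary variables.
#'
#' A class is treated as reversible (and gets a reverse binary) exactly
#' when its representative is reversible; representatives are chosen
#' irreversible whenever the class contains an irreversible member.
#'
#' @inheritParams build_minnw0
#' @param partition a [partial_coupling_classes()] result for `net`.
#' @return A `milp_problem`.
#' @export
build_minnw_rep <- function(net, scenario, partition) {
  stopifnot(inherits(partition, "coupling_partition"))
  all_members <- unlist(partition$classes)
  if (!setequal(all_members, net$reaction_ids) ||
      length(all_members) != n_reactions(net)) {
    stop("coupling partition does not match the network's reaction set",
         call. = FALSE)
  }
  groups <- lapply(partition$classes, function(cl) rxn_index(net, cl))
  rep_idx <- rxn_index(net, partition$representative)
  new_milp_problem(net, scenario,
                   groups = groups,
                   group_rev = !net$irreversible[rep_idx],
                   group_weight = as.numeric(partition$class_size),
                   n_copies = length(scenario$functionalities) + 1L,
                   aggregate = TRUE,
                   formulation = "minnw_rep")
}

# ---- variable layout ------------------------------------------------------

milp_layout <- function(p) {
  n <- n_reactions(p$net)
  J <- p$n_copies
  G <- length(p$groups)
  rev_groups <- which(p$group_rev)
  Rv <- length(rev_groups)
  rev_pos <- integer(G)
  rev_pos[rev_groups] <- seq_len(Rv)
  v_idx <- function(j, i) (j - 1L) * n + i
  a_idx <- function(j, g) J * n + (j - 1L) * G + g
  abar_idx <- function(j, g) J * n + J * G + (j - 1L) * Rv + rev_pos[g]
  agg_idx <- if (p$aggregate) function(g) J * n + J * G + J * Rv + g
             else function(g) stop("no aggregated binaries in this problem")
  nvar <- J * n + J * G + J * Rv + if (p$aggregate) G else 0L
  list(n = n, J = J, G = G, Rv = Rv, rev_groups = rev_groups,
       v_idx = v_idx, a_idx = a_idx, abar_idx = abar_idx,
       agg_idx = agg_idx, nvar = nvar)
}

# ---- encoding -------------------------------------------------------------

#' Encode a reduction MILP into a backend-ready constraint system
#'
#' Produces the full linear constraint matrix, variable bounds,
#' integrality pattern and objective for a `milp_problem`, in one of two
#' activity encodings:
#'
#' * `"bigM"`: the classical rows
#'   \eqn{\delta a_i \le v_i \le M a_i} (irreversible) and
#'   \eqn{\delta a_i - M \bar a_i \le v_i \le M a_i - \delta \bar a_i}
#'   (reversible), with `M = scenario$big_M`; infinite model bounds are
#'   capped at \eqn{\pm M} inside the encoding only.
#' * `"indicator"`: the implications `a=0 => v=0`, `a=1 => v >= delta`
#'   (and mirrored for the reverse direction) compiled into exact
#'   linearizations that use each reaction's own finite bounds instead of
#'   a global M. A reaction with an infinite bound cannot be linked this
#'   way; encoding then fails with a capability error suggesting the
#'   big-M fallback.
#'
#' @param problem a `milp_problem`.
#' @param mode `"bigM"` or `"indicator"`; defaults to the scenario's
#'   encoding.
#' @return A list with the backend arrays (`nvar`, `obj`, `lb`, `ub`,
#'   `integrality`, triplets `A`, `rlb`, `rub`), row `names` tagging each
#'   constraint family, and the layout.
#' @export
encode <- function(problem, mode = NULL) {
  stopifnot(inherits(problem, "milp_problem"))
  sc <- problem$scenario
  mode <- match.arg(mode %||% sc$encoding, c("bigM", "indicator"))
  net <- problem$net
  lay <- milp_layout(problem)
  n <- lay$n; J <- lay$J; G <- lay$G
  delta <- sc$delta; M <- sc$big_M

  Ai <- integer(0); Aj <- integer(0); Ax <- numeric(0)
  rlb <- numeric(0); rub <- numeric(0); rname <- character(0)
  nrow_cur <- 0L
  add_row <- function(idx, val, lo, hi, name) {
    nrow_cur <<- nrow_cur + 1L
    Ai <<- c(Ai, rep(nrow_cur, length(idx)))
    Aj <<- c(Aj, idx); Ax <<- c(Ax, val)
    rlb <<- c(rlb, lo); rub <<- c(rub, hi); rname <<- c(rname, name)
  }

  # variable bounds
  lb <- numeric(lay$nvar); ub <- numeric(lay$nvar)
  l <- net$lower; u <- net$upper
  if (mode == "bigM") {
    l <- ifelse(is.finite(l), l, -M)
    u <- ifelse(is.finite(u), u, M)
  }
  for (j in seq_len(J)) {
    lb[lay$v_idx(j, seq_len(n))] <- l
    ub[lay$v_idx(j, seq_len(n))] <- u
  }
  bin_from <- J * n + 1L
  lb[bin_from:lay$nvar] <- 0; ub[bin_from:lay$nvar] <- 1
  integrality <- c(rep(0L, J * n), rep(1L, lay$nvar - J * n))

  # steady state, per copy
  trip <- Matrix::mat2triplet(net$S)
  for (j in seq_len(J)) {
    base <- nrow_cur
    m <- nrow(net$S)
    Ai <- c(Ai, base + trip$i)
    Aj <- c(Aj, lay$v_idx(j, trip$j))
    Ax <- c(Ax, trip$x)
    rlb <- c(rlb, rep(0, m)); rub <- c(rub, rep(0, m))
    rname <- c(rname, rep(sprintf("steady_state_c%d", j - 1L), m))
    nrow_cur <- nrow_cur + m
  }

  # functionality rows
  funs <- sc$functionalities
  fun_copy <- function(k) if (problem$formulation == "minnw0") 1L else k + 1L
  for (k in seq_along(funs)) {
    j <- fun_copy(k)
    for (row in canonical_rows(funs[[k]]$rows)) {
      idx <- rxn_index(net, names(row$coefs))
      add_row(lay$v_idx(j, idx), as.numeric(row$coefs), -Inf, row$rhs,
              sprintf("functionality_%s", funs[[k]]$label))
    }
  }

  # activity linking rows (eq1/eq2 single copy, eq4/eq5/eq6 multi copy)
  irrev <- net$irreversible
  for (j in seq_len(J)) {
    for (g in seq_len(G)) {
      members <- problem$groups[[g]]
      a <- lay$a_idx(j, g)
      grev <- problem$group_rev[g]
      ab <- if (grev) lay$abar_idx(j, g) else NA_integer_
      for (i in members) {
        v <- lay$v_idx(j, i)
        if (!grev) {
          if (irrev[i]) {
            # delta*a <= v_i <= cap*a
            cap <- if (mode == "bigM") M else u[i]
            if (!is.finite(cap)) {
              stop("indicator encoding needs a finite upper bound for ",
                   "reaction '", net$reaction_ids[i], "'; use the bigM ",
                   "encoding instead", call. = FALSE)
            }
            add_row(c(v, a), c(1, -cap), -Inf, 0, "eq_act_ub")
            add_row(c(v, a), c(-1, delta), -Inf, 0, "eq_act_lb")
          } else {
            # reversible member of an irreversible class: sign-free gate
            cap_u <- if (mode == "bigM") M else u[i]
            cap_l <- if (mode == "bigM") -M else l[i]
            if (!is.finite(cap_u) || !is.finite(cap_l)) {
              stop("indicator encoding needs finite bounds for reaction '",
                   net$reaction_ids[i], "'; use the bigM encoding instead",
                   call. = FALSE)
            }
            add_row(c(v, a), c(1, -cap_u), -Inf, 0, "eq_gate_ub")
            add_row(c(v, a), c(-1, cap_l), -Inf, 0, "eq_gate_lb")
          }
        } else {
          if (irrev[i]) {
            # irreversible member of a reversible class: active in either
            # class direction must push it forward
            cap <- if (mode == "bigM") M else u[i]
            if (!is.finite(cap)) {
              stop("indicator encoding needs a finite upper bound for ",
                   "reaction '", net$reaction_ids[i], "'; use the bigM ",
                   "encoding instead", call. = FALSE)
            }
            add_row(c(v, a, ab), c(1, -cap, -cap), -Inf, 0, "eq_act_ub")
            add_row(c(v, a, ab), c(-1, delta, delta), -Inf, 0, "eq_act_lb")
          } else {
            cap_u <- if (mode == "bigM") M else u[i]
            cap_l <- if (mode == "bigM") -M else l[i]
            if (!is.finite(cap_u) || !is.finite(cap_l)) {
              stop("indicator encoding needs finite bounds for reaction '",
                   net$reaction_ids[i], "'; use the bigM encoding instead",
                   call. = FALSE)
            }
            # v <= cap_u*a - delta*abar ; v >= delta*a + cap_l*abar
            add_row(c(v, a, ab), c(1, -cap_u, delta), -Inf, 0, "eq_act_ub")
            add_row(c(v, a, ab), c(-1, delta, cap_l), -Inf, 0, "eq_act_lb")
          }
        }
      }
      if (grev) {
        add_row(c(a, ab), c(1, 1), -Inf, 1, "eq_dir_excl")
      }
    }
  }

  # protected reactions (copy 0 binaries)
  g_of_rxn <- integer(n)
  for (g in seq_len(G)) g_of_rxn[problem$groups[[g]]] <- g
  for (rid in sc$protected_reactions) {
    i <- rxn_index(net, rid)
    g <- g_of_rxn[i]
    a <- lay$a_idx(1L, g)
    if (problem$group_rev[g]) {
      add_row(c(a, lay$abar_idx(1L, g)), c(1, 1), 1, 1, "protected_rxn")
    } else {
      add_row(a, 1, 1, 1, "protected_rxn")
    }
  }

  # protected metabolites without a protected reaction (eq3/eq7)
  prot_rxn_idx <- rxn_index(net, sc$protected_reactions)
  for (mid in sc$protected_metabolites) {
    m <- met_index(net, mid)
    rxns_m <- which(net$S[m, ] != 0)
    if (length(intersect(rxns_m, prot_rxn_idx)) > 0) next
    gs <- unique(g_of_rxn[rxns_m])
    idx <- lay$a_idx(1L, gs)
    val <- rep(1, length(gs))
    grev <- gs[problem$group_rev[gs]]
    if (length(grev)) {
      idx <- c(idx, lay$abar_idx(1L, grev))
      val <- c(val, rep(1, length(grev)))
    }
    add_row(idx, val, 1, Inf, "protected_met")
  }

  # aggregation rows (eq8/eq9) and objective
  obj <- numeric(lay$nvar)
  if (problem$aggregate) {
    for (g in seq_len(G)) {
      agg <- lay$agg_idx(g)
      copies_a <- lay$a_idx(seq_len(J), g)
      if (problem$group_rev[g]) {
        copies_all <- c(copies_a, lay$abar_idx(seq_len(J), g))
        cap <- 2 * J
      } else {
        copies_all <- copies_a
        cap <- J
      }
      # agg <= sum(copies) : agg - sum <= 0
      add_row(c(agg, copies_all), c(1, rep(-1, length(copies_all))),
              -Inf, 0, "eq_agg_lb")
      # sum(copies) <= cap * agg
      add_row(c(copies_all, agg), c(rep(1, length(copies_all)), -cap),
              -Inf, 0, "eq_agg_ub")
      obj[agg] <- problem$group_weight[g]
    }
  } else {
    for (g in seq_len(G)) {
      obj[lay$a_idx(1L, g)] <- 1
      if (problem$group_rev[g]) obj[lay$abar_idx(1L, g)] <- 1
    }
  }

  # exclusion cuts over the pattern binaries
  for (pat in problem$cuts) {
    in_idx <- which(pat); out_idx <- which(!pat)
    idx <- c(if (problem$aggregate) lay$agg_idx(out_idx)
             else lay$a_idx(1L, out_idx),
             if (problem$aggregate) lay$agg_idx(in_idx)
             else lay$a_idx(1L, in_idx))
    val <- c(rep(1, length(out_idx)), rep(-1, length(in_idx)))
    add_row(idx, val, 1 - length(in_idx), Inf, "integer_cut")
  }

  list(nvar = lay$nvar, obj = obj, sense = "min", lb = lb, ub = ub,
       integrality = integrality,
       A = list(i = Ai, j = Aj, x = Ax), rlb = rlb, rub = rub,
       names = rname, layout = lay, mode = mode)
}

#' Export an encoded problem in LP format
#'
#' Writes a CPLEX-style LP file of the encoded constraint system for
#' debugging, with row names carrying the constraint-family tags.
#'
#' @param encoded result of [encode()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_lp <- function(encoded, path) {
  vn <- function(j) paste0("x", j)
  con <- file(path, "w"); on.exit(close(con))
  nz <- which(encoded$obj != 0)
  writeLines("Minimize", con)
  writeLines(paste(" obj:", paste(sprintf("%+g %s", encoded$obj[nz], vn(nz)),
                                  collapse = " ")), con)
  writeLines("Subject To", con)
  A <- encoded$A
  rows <- split(seq_along(A$i), A$i)
  for (r in seq_along(encoded$rlb)) {
    k <- rows[[as.character(r)]]
    expr <- paste(sprintf("%+g %s", A$x[k], vn(A$j[k])), collapse = " ")
    lo <- encoded$rlb[r]; hi <- encoded$rub[r]
    tag <- sprintf("%s_%d", encoded$names[r], r)
    if (is.finite(lo) && is.finite(hi) && lo == hi) {
      writeLines(sprintf(" %s: %s = %g", tag, expr, lo), con)
    } else {
      if (is.finite(hi)) writeLines(sprintf(" %s_u: %s <= %g", tag, expr, hi), con)
      if (is.finite(lo)) writeLines(sprintf(" %s_l: %s >= %g", tag, expr, lo), con)
    }
  }
  writeLines("Bounds", con)
  for (j in seq_len(encoded$nvar)) {
    writeLines(sprintf(" %g <= %s <= %g", encoded$lb[j], vn(j),
                       encoded$ub[j]), con)
  }
  writeLines("Binaries", con)
  writeLines(paste("", paste(vn(which(encoded$integrality == 1)),
                             collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}

# ---- solving --------------------------------------------------------------

#' Solve a reduction MILP
#'
#' Encodes and solves the problem with the HiGHS backend, then extracts a
#' subnetwork solution: the set of active reactions, one witness flux
#' vector per copy, and the objective value. Activity flags are re-derived
#' from the witness fluxes (a group is active when some member carries more
#' than `delta / 2` in some copy) and cross-checked against the solver's
#' binaries; a mismatch raises a consistency error rather than silently
#' returning a corrupt active set. The witnesses themselves are verified
#' against steady state and the functionality rows within `1e-06`.
#'
#' @param problem a `milp_problem`.
#' @param mode encoding override (default: the scenario's).
#' @param time_limit seconds, or `NULL`.
#' @param mip_gap relative MIP gap (default `1e-9`, i.e. prove optimality).
#' @return A `subnetwork_solution` with fields `active`, `witness_fluxes`
#'   (list, names `"0"`, `"1"`, ... per copy), `n_active`, `objective`,
#'   `binaries`, `dof` (`NA` until filled by the enumeration layer),
#'   `solver_status`, `encoding`, `delta`.
#'   On infeasibility an error of class `minsubnet_infeasible` is raised.
#' @export
solve_milp <- function(problem, mode = NULL, time_limit = NULL,
                       mip_gap = 1e-9) {
  enc <- encode(problem, mode)
  prob <- enc[c("nvar", "obj", "sense", "lb", "ub", "integrality",
                "A", "rlb", "rub")]
  prob$time_limit <- time_limit
  prob$mip_gap <- mip_gap
  sol <- solve_lp(prob)
  if (identical(sol$status, "infeasible")) {
    cond <- structure(class = c("minsubnet_infeasible", "error", "condition"),
                      list(message = paste0(
                        "the reduction requirements cannot be satisfied (",
                        problem$formulation, " is infeasible)"),
                        call = sys.call()))
    stop(cond)
  }
  if (identical(sol$status, "error") || is.null(sol$x)) {
    stop("solver failure: ", sol$message %||% sol$status, call. = FALSE)
  }
  extract_solution(problem, enc, sol)
}

extract_solution <- function(problem, enc, sol) {
  net <- problem$net
  lay <- enc$layout
  sc <- problem$scenario
  x <- sol$x
  witnesses <- lapply(seq_len(lay$J), function(j) {
    stats::setNames(x[lay$v_idx(j, seq_len(lay$n))], net$reaction_ids)
  })
  names(witnesses) <- as.character(seq_len(lay$J) - 1L)

  # witness-derived group activity
  act_group <- vapply(seq_len(lay$G), function(g) {
    members <- problem$groups[[g]]
    any(vapply(witnesses, function(w) any(abs(w[members]) > sc$delta / 2),
               logical(1)))
  }, logical(1))

  # solver binaries for the same pattern
  bin_group <- if (problem$aggregate) {
    x[lay$agg_idx(seq_len(lay$G))] > 0.5
  } else {
    on <- x[lay$a_idx(1L, seq_len(lay$G))]
    rv <- which(problem$group_rev)
    if (length(rv)) on[rv] <- on[rv] + x[lay$abar_idx(1L, rv)]
    on > 0.5
  }
  if (!identical(act_group, bin_group)) {
    bad <- which(act_group != bin_group)
    stop("solver activity flags disagree with witness fluxes for group(s) ",
         paste(bad, collapse = ", "),
         " (numerically suspect solution)", call. = FALSE)
  }

  # verify witnesses: steady state and functionality rows within tolerance
  for (j in seq_len(lay$J)) {
    resid <- max(abs(as.numeric(net$S %*% witnesses[[j]])), 0)
    if (resid > 1e-6) {
      stop("witness flux for copy ", j - 1L, " violates steady state (|Sv| = ",
           format(resid), ")", call. = FALSE)
    }
  }
  funs <- sc$functionalities
  for (k in seq_along(funs)) {
    j <- if (problem$formulation == "minnw0") 1L else k + 1L
    w <- witnesses[[j]]
    for (row in canonical_rows(funs[[k]]$rows)) {
      lhs <- sum(row$coefs * w[names(row$coefs)])
      if (lhs > row$rhs + 1e-6) {
        stop("witness for functionality '", funs[[k]]$label,
             "' violates a row by ", format(lhs - row$rhs), call. = FALSE)
      }
    }
  }

  active <- sort(net$reaction_ids[unlist(problem$groups[act_group])])
  structure(list(
    active = active,
    witness_fluxes = witnesses,
    n_active = length(active),
    objective = sol$objective,
    group_active = act_group,
    dof = NA_integer_,
    encoding = enc$mode,
    delta = sc$delta,
    solver_status = sol$status
  ), class = "subnetwork_solution")
}

#' @export
print.subnetwork_solution <- function(x, ...) {
  cat("Subnetwork solution: ", x$n_active, " active reaction(s), ",
      length(x$witness_fluxes), " witness flux vector(s), status ",
      x$solver_status,
      if (!is.na(x$dof)) paste0(", dof = ", x$dof), "\n", sep = "")
  cat("  active:", paste(x$active, collapse = ", "), "\n")
  invisible(x)
}
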