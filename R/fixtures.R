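# Deterministic toy networks with known ground truth, seeded random
# networks/scenarios, and the brute-force enumeration oracle used by the
# test suites.

# sample() without the scalar-expansion surprise
sample_safe <- function(x, k = length(x)) x[sample.int(length(x), k)]

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Branch toy network (greedy-vs-optimal trap)
#'
#' A substrate can reach the exported product either through one direct
#' reaction (`r1`) or through a two-step detour (`r2`, `r3`). Protecting
#' the export, the unique minimum subnetwork uses the direct reaction
#' (3 active reactions including uptake and export), while a greedy
#' pruning order that first removes `r1` gets stuck with 4.
#'
#' @return A list with `network` and `scenario`.
#' @export
make_branch_toy <- function() {
  mets <- c("A", "B", "X")
  rxns <- c("up", "r1", "r2", "r3", "ex")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "up"] <- 1
  S["A", "r1"] <- -1; S["B", "r1"] <- 1
  S["A", "r2"] <- -1; S["X", "r2"] <- 1
  S["X", "r3"] <- -1; S["B", "r3"] <- 1
  S["B", "ex"] <- -1
  net <- metabolic_network(S, lower = rep(0, 5), upper = rep(10, 5))
  scenario <- reduction_scenario(net, protected_reactions = "ex")
  list(network = net, scenario = scenario)
}

#' Dual-condition toy network (conflicting functionalities)
#'
#' An 8-reaction network with an oxygen uptake, a high-yield respiratory
#' conversion and a fermentative one, two parallel transport steps to the
#' biomass precursor, a biomass export and a never-needed byproduct
#' export. The scenario demands two functionalities no single flux vector
#' can satisfy: biomass production *with* oxygen uptake (which requires
#' the high-yield route) and biomass production *without* oxygen.
#'
#' Minimizing per functionality and taking the union can cost 7 reactions
#' (the two solves may pick different parallel transports), while the
#' joint minimum has 6; there are exactly two joint minima (one per
#' transport choice).
#'
#' @return A list with `network` and `scenario`.
#' @export
make_dual_condition_toy <- function() {
  mets <- c("A", "B", "C", "O")
  rxns <- c("up", "o2", "resp", "ferm", "t1", "t2", "bio", "byp")
  S <- matrix(0, 4, 8, dimnames = list(mets, rxns))
  S["A", "up"] <- 1
  S["O", "o2"] <- 1
  S["A", "resp"] <- -1; S["O", "resp"] <- -1; S["B", "resp"] <- 2
  S["A", "ferm"] <- -1; S["B", "ferm"] <- 1
  S["B", "t1"] <- -1; S["C", "t1"] <- 1
  S["B", "t2"] <- -1; S["C", "t2"] <- 1
  S["C", "bio"] <- -1
  S["C", "byp"] <- -1
  net <- metabolic_network(S, lower = rep(0, 8),
                           upper = c(1, rep(10, 7)))
  aerobic <- linear_functionality("aerobic", rows = list(
    list(coefs = c(bio = 1), rel = ">=", rhs = 1.5),
    list(coefs = c(o2 = 1), rel = ">=", rhs = 0.1)))
  anaerobic <- linear_functionality("anaerobic", rows = list(
    list(coefs = c(bio = 1), rel = ">=", rhs = 0.5),
    list(coefs = c(o2 = 1), rel = "==", rhs = 0)))
  scenario <- reduction_scenario(net,
                                 protected_reactions = "bio",
                                 functionalities = list(aerobic, anaerobic))
  list(network = net, scenario = scenario)
}

#' Parallel-pathways toy network
#'
#' One uptake, `k` interchangeable conversions of the substrate into the
#' product, and a protected export: exactly `k` symmetric minimum
#' subnetworks of 3 reactions each.
#'
#' @param k number of parallel conversion reactions.
#' @return A list with `network` and `scenario`.
#' @export
make_parallel_paths_toy <- function(k = 3) {
  rxns <- c("up", paste0("p", seq_len(k)), "ex")
  S <- matrix(0, 2, k + 2, dimnames = list(c("A", "B"), rxns))
  S["A", "up"] <- 1
  for (i in seq_len(k)) {
    S["A", paste0("p", i)] <- -1
    S["B", paste0("p", i)] <- 1
  }
  S["B", "ex"] <- -1
  net <- metabolic_network(S, lower = rep(0, k + 2), upper = rep(10, k + 2))
  scenario <- reduction_scenario(net, protected_reactions = "ex")
  list(network = net, scenario = scenario)
}

#' Generate a random feasible metabolic network
#'
#' Deterministic per seed. The network always contains a functional
#' backbone -- an import, a chain of conversions covering the metabolites,
#' and an export -- so at least one reaction is unblocked; the remaining
#' reactions are random sparse internal conversions or exchanges with
#' small integer stoichiometry. Bounds are `[0, 10]`, or `[-10, 10]` for
#' the fraction of reactions drawn reversible.
#'
#' @param n_met,n_rxn network dimensions (`n_rxn >= n_met + 1`).
#' @param rev_fraction probability that a non-backbone-import reaction is
#'   reversible.
#' @param seed integer seed.
#' @return A `metabolic_network`.
#' @export
random_feasible_network <- function(n_met = 8, n_rxn = 12,
                                    rev_fraction = 0.3, seed = 1) {
  stopifnot(n_rxn >= n_met + 1, n_met >= 1)
  with_local_seed(seed, {
    m <- n_met; n <- n_rxn
    S <- matrix(0, m, n,
                dimnames = list(paste0("M", seq_len(m)),
                                paste0("R", seq_len(n))))
    # backbone: import M1, chain M1 -> ... -> Mm, export Mm
    S[1, 1] <- 1
    for (k in seq_len(m - 1)) {
      coef <- sample(c(1, 1, 2), 1)
      S[k, k + 1] <- -1
      S[k + 1, k + 1] <- coef
    }
    S[m, m + 1] <- -1
    # extra reactions: random exchanges or conversions
    for (r in seq_len(max(0, n - m - 1)) + m + 1) {
      if (stats::runif(1) < 0.25) {
        S[sample(m, 1), r] <- sample(c(-1, 1), 1)
      } else {
        subs <- sample(m, sample(1:2, 1))
        prods <- sample(setdiff(seq_len(m), subs), sample(1:2, 1))
        S[subs, r] <- -sample(c(1, 1, 2), length(subs), replace = TRUE)
        S[prods, r] <- sample(c(1, 1, 2), length(prods), replace = TRUE)
      }
    }
    rev <- stats::runif(n) < rev_fraction
    rev[1] <- FALSE  # keep the backbone import a true import
    metabolic_network(S, lower = ifelse(rev, -10, 0), upper = rep(10, n))
  })
}

#' Generate a random reduction scenario for a network
#'
#' Picks functionality targets among reactions with a usable flux range
#' (each functionality demands half the target's maximum flux, the second
#' one optionally with another reaction held at zero, creating a
#' conflict), and protects one randomly chosen unblocked reaction.
#' Deterministic per seed. Designed for networks that have already had
#' their blocked reactions removed.
#'
#' @param net a preprocessed `metabolic_network`.
#' @param n_functionalities number of functionalities (1 or 2).
#' @param seed integer seed.
#' @return A `reduction_scenario`, or `NULL` when the network offers no
#'   usable targets (rare; callers should then skip the seed).
#' @export
random_scenario <- function(net, n_functionalities = 2, seed = 1) {
  ranges <- fva(net)
  span <- pmax(ranges$max, -ranges$min)
  usable <- which(span >= 1)
  if (length(usable) < n_functionalities) return(NULL)
  with_local_seed(seed + 57L, {
    targets <- sample_safe(usable, n_functionalities)
    funs <- list()
    for (k in seq_along(targets)) {
      t <- targets[k]
      sgn <- if (ranges$max[t] >= -ranges$min[t]) 1 else -1
      level <- 0.5 * span[t]
      rows <- list(list(coefs = stats::setNames(sgn, net$reaction_ids[t]),
                        rel = ">=", rhs = level))
      if (k == 2) {
        # try to add a conflicting zero-fix on some other reaction
        cand <- sample_safe(setdiff(seq_len(n_reactions(net)), targets))
        probs <- lapply(cand, function(z) {
          flux_lp(net, unit_obj(net, t) * sgn, "max", fix_zero = z)
        })
        sols <- solve_lp_batch(probs)
        ok <- vapply(sols, function(s) {
          identical(s$status, "optimal") && s$objective >= level
        }, logical(1))
        if (any(ok)) {
          z <- cand[which(ok)[1]]
          rows <- c(rows, list(list(
            coefs = stats::setNames(1, net$reaction_ids[z]),
            rel = "==", rhs = 0)))
        }
      }
      funs[[k]] <- linear_functionality(paste0("f", k), rows)
    }
    prot <- sample_safe(usable, 1)
    reduction_scenario(net,
                       protected_reactions = net$reaction_ids[prot],
                       functionalities = funs)
  })
}

# ---- brute-force oracle ---------------------------------------------------

# Requirement view of a scenario: the functionality rows plus the
# "copy 0" requirement (protected reactions at |v| >= delta; protected
# metabolites touched by an active reaction). Disjunctive choices (sign of
# a reversible protected reaction; which reaction activates a protected
# metabolite) are expanded into variants.
copy0_variants <- function(net, scenario, delta) {
  choices <- list()
  for (rid in scenario$protected_reactions) {
    i <- rxn_index(net, rid)
    choices[[length(choices) + 1]] <-
      if (net$irreversible[i]) list(stats::setNames(delta, i))
      else list(stats::setNames(delta, i), stats::setNames(-delta, i))
  }
  prot_idx <- rxn_index(net, scenario$protected_reactions)
  for (mid in scenario$protected_metabolites) {
    m <- met_index(net, mid)
    rxns_m <- which(net$S[m, ] != 0)
    if (length(intersect(rxns_m, prot_idx)) > 0) next
    opts <- list()
    for (i in rxns_m) {
      opts <- c(opts, list(stats::setNames(delta, i)))
      if (!net$irreversible[i]) {
        opts <- c(opts, list(stats::setNames(-delta, i)))
      }
    }
    choices[[length(choices) + 1]] <- opts
  }
  if (length(choices) == 0) return(list(numeric(0)))
  grids <- do.call(expand.grid, c(lapply(choices, seq_along),
                                  list(KEEP.OUT.ATTRS = FALSE)))
  if (nrow(grids) > 256) {
    stop("too many disjunctive copy-0 variants for the brute-force oracle",
         call. = FALSE)
  }
  lapply(seq_len(nrow(grids)), function(r) {
    floors <- numeric(0)
    for (c in seq_along(choices)) {
      floors <- c(floors, choices[[c]][[grids[r, c]]])
    }
    floors
  })
}

#' Brute-force enumeration of all minimum subnetworks
#'
#' Independent oracle for the reduction MILPs on small networks: decides
#' by plain LPs which reaction subsets can realize every functionality
#' (with all excluded reactions clamped to zero) and the protected-set
#' requirement (protected reactions at flux at least `delta`), and
#' returns all feasible subsets of minimum cardinality.
#'
#' The search space is cut down soundly before enumeration: reactions
#' essential for some requirement (the requirement is infeasible with the
#' reaction clamped to zero) belong to every feasible subset, and
#' reactions unusable in every requirement (cannot reach `delta/2` flux
#' under it) belong to no *minimal* one. The remaining subsets are
#' checked level-wise by cardinality, in batched LPs.
#'
#' @param net a small `metabolic_network` (at most 16 reactions).
#' @param scenario a `reduction_scenario` (resolved automatically).
#' @param dof_min override for the degrees-of-freedom side condition
#'   (default: the scenario's).
#' @return A list with `minimum_size`, `active_sets` (list of sorted
#'   reaction-id vectors), `dof` (per set), and `feasible` (`FALSE` when
#'   even the full network cannot satisfy the requirements, in which case
#'   `active_sets` is empty).
#' @export
brute_force_minimum_subnetworks <- function(net, scenario,
                                            dof_min = scenario$dof_min) {
  n <- n_reactions(net)
  if (n > 16) {
    stop("brute-force oracle is limited to networks with <= 16 reactions",
         call. = FALSE)
  }
  scenario <- resolve_scenario(net, scenario)
  delta <- scenario$delta
  act_tol <- delta / 2
  fun_rows <- lapply(scenario$functionalities,
                     function(f) canonical_rows(f$rows))
  variants <- copy0_variants(net, scenario, delta)

  feas_lp <- function(rows, fix_zero, floors) {
    flux_lp(net, obj = NULL, rows = rows, fix_zero = fix_zero,
            delta_floor = floors)
  }
  status_of <- function(s) {
    if (identical(s$status, "error")) {
      stop("oracle LP failed: ", s$message, call. = FALSE)
    }
    s$status
  }
  req_feasible <- function(sols) {
    vapply(sols, function(s) status_of(s) %in% c("optimal", "unbounded"),
           logical(1))
  }

  # subset feasibility: one LP per functionality + copy-0 variants
  subset_lps <- function(A_excl) {
    c(lapply(fun_rows, function(rows) feas_lp(rows, A_excl, numeric(0))),
      lapply(variants, function(fl) {
        keep <- setdiff(A_excl, as.integer(names(fl)))
        # a variant demanding flux through an excluded reaction is void
        if (length(keep) < length(A_excl)) NULL
        else feas_lp(list(), A_excl, fl)
      }))
  }
  n_fun <- length(fun_rows)
  subset_ok <- function(sols) {
    fun_ok <- req_feasible(sols[seq_len(n_fun)])
    v_sols <- sols[-seq_len(n_fun)]
    v_ok <- vapply(v_sols, function(s) {
      !is.null(s) && status_of(s) %in% c("optimal", "unbounded")
    }, logical(1))
    all(fun_ok) && (length(v_sols) == 0 || any(v_ok))
  }

  # full-network feasibility gate
  full <- subset_lps(integer(0))
  nonnull <- !vapply(full, is.null, logical(1))
  sols <- vector("list", length(full))
  sols[nonnull] <- solve_lp_batch(full[nonnull])
  if (!subset_ok(sols)) {
    return(list(minimum_size = NA_integer_, active_sets = list(),
                dof = integer(0), feasible = FALSE))
  }

  # per-requirement essential and usable reactions
  requirement_specs <- c(
    lapply(fun_rows, function(rows) list(rows = rows, floors = numeric(0))),
    lapply(variants, function(fl) list(rows = list(), floors = fl)))
  essential <- rep(FALSE, n)   # essential for some functionality / all variants
  usable <- rep(FALSE, n)
  ess_by_req <- matrix(FALSE, n, length(requirement_specs))
  for (k in seq_along(requirement_specs)) {
    spec <- requirement_specs[[k]]
    probs <- list(); tags <- list()
    for (i in seq_len(n)) {
      if (i %in% as.integer(names(spec$floors))) {
        ess_by_req[i, k] <- TRUE
        usable[i] <- TRUE
        next
      }
      probs[[length(probs) + 1]] <- feas_lp(spec$rows, i, spec$floors)
      tags[[length(tags) + 1]] <- c(i, 0)
      probs[[length(probs) + 1]] <- flux_lp(net, unit_obj(net, i), "max",
                                            spec$rows,
                                            delta_floor = spec$floors)
      tags[[length(tags) + 1]] <- c(i, 1)
      if (!net$irreversible[i]) {
        probs[[length(probs) + 1]] <- flux_lp(net, unit_obj(net, i), "min",
                                              spec$rows,
                                              delta_floor = spec$floors)
        tags[[length(tags) + 1]] <- c(i, -1)
      }
    }
    res <- solve_lp_batch(probs)
    for (q in seq_along(res)) {
      i <- tags[[q]][1]; kind <- tags[[q]][2]
      s <- res[[q]]
      if (kind == 0) {
        if (!(status_of(s) %in% c("optimal", "unbounded"))) {
          ess_by_req[i, k] <- TRUE
        }
      } else if (status_of(s) %in% c("optimal", "unbounded")) {
        val <- if (identical(s$status, "unbounded")) Inf else abs(s$objective)
        if (val >= act_tol) usable[i] <- TRUE
      }
    }
  }
  if (n_fun > 0) {
    essential <- essential | apply(ess_by_req[, seq_len(n_fun), drop = FALSE],
                                   1, any)
  }
  if (length(variants) > 0) {
    v_cols <- ess_by_req[, n_fun + seq_along(variants), drop = FALSE]
    essential <- essential | apply(v_cols, 1, all)
  }
  core <- which(essential)
  extras <- setdiff(which(usable), core)
  if (length(extras) > 14) {
    stop("brute-force oracle: candidate space too large (",
         length(extras), " optional reactions)", call. = FALSE)
  }

  # level-wise enumeration over subsets of the optional reactions
  best <- NULL
  for (level in 0:length(extras)) {
    combos <- if (level == 0) list(integer(0))
              else if (length(extras) == 1) list(extras)
              else utils::combn(extras, level, simplify = FALSE)
    probs <- list(); meta <- list()
    for (ci in seq_along(combos)) {
      A <- sort(c(core, combos[[ci]]))
      excl <- setdiff(seq_len(n), A)
      lps <- subset_lps(excl)
      keepmask <- !vapply(lps, is.null, logical(1))
      meta[[ci]] <- list(A = A, n_lp = sum(keepmask), mask = keepmask,
                         n_tot = length(lps))
      probs <- c(probs, lps[keepmask])
    }
    res <- solve_lp_batch(probs)
    pos <- 0
    found <- list()
    for (ci in seq_along(combos)) {
      mm <- meta[[ci]]
      sols <- vector("list", mm$n_tot)
      sols[mm$mask] <- res[pos + seq_len(mm$n_lp)]
      pos <- pos + mm$n_lp
      if (subset_ok(sols)) {
        A_ids <- net$reaction_ids[mm$A]
        if (degrees_of_freedom(net, A_ids) >= dof_min) {
          found[[length(found) + 1]] <- sort(A_ids)
        }
      }
    }
    if (length(found)) {
      best <- found
      break
    }
  }
  if (is.null(best)) {
    return(list(minimum_size = NA_integer_, active_sets = list(),
                dof = integer(0), feasible = FALSE))
  }
  best <- unique(best)
  list(minimum_size = length(best[[1]]),
       active_sets = best,
       dof = vapply(best, function(a) degrees_of_freedom(net, a), integer(1)),
       feasible = TRUE)
}
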