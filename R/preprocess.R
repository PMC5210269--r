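# Preprocessing: dead-end metabolites, blocked reactions, flux coupling.

#' Find dead-end metabolites
#'
#' A metabolite is a dead end when, taking reaction directionality into
#' account, it can only be produced or only be consumed (a reversible
#' reaction counts as both a producer and a consumer). Dead-end metabolites
#' force the reactions touching them to zero flux, so detection is iterated
#' to a fixed point: the reactions touching a dead end are dropped and the
#' test repeated on the remainder.
#'
#' Every reaction touching a dead-end metabolite is necessarily blocked,
#' so this purely combinatorial pass is a fast prefilter for
#' [find_blocked_reactions()]; the final unblocked set is identical with
#' or without it.
#'
#' @param net a `metabolic_network`.
#' @return Character vector of dead-end metabolite ids (the full cascade).
#'   The reactions forced to zero by them are attached as attribute
#'   `"reactions"`.
#' @export
find_dead_end_metabolites <- function(net) {
  S <- as.matrix(net$S)
  rev <- !net$irreversible
  alive_m <- rep(TRUE, nrow(S))
  alive_r <- rep(TRUE, ncol(S))
  repeat {
    changed <- FALSE
    for (m in which(alive_m)) {
      row <- S[m, ]
      row[!alive_r] <- 0
      produced <- any(row > 0) || any(row < 0 & rev)
      consumed <- any(row < 0) || any(row > 0 & rev)
      if (!produced || !consumed) {
        alive_m[m] <- FALSE
        dead_rxns <- which(row != 0 & alive_r)
        alive_r[dead_rxns] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- net$metabolite_ids[!alive_m]
  attr(out, "reactions") <- net$reaction_ids[!alive_r]
  out
}

#' Find blocked reactions
#'
#' A reaction is blocked when it carries zero flux in every vector of the
#' sign-constrained cone
#' \eqn{C_0 = \{ v \mid S v = 0,\; v_i \ge 0 \;\forall i \in Irrev \}}.
#' Note that \eqn{C_0} uses only the irreversibility signs, not the finite
#' bounds `l`, `u` -- blockedness is a structural property. The test runs
#' two LPs per reaction (maximum and, for reversible reactions, minimum of
#' \eqn{v_r}) over \eqn{C_0} intersected with the unit box, which is
#' equivalent by scale invariance of the cone.
#'
#' @param net a `metabolic_network`.
#' @param tol LP-level zero tolerance (default `1e-09`).
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(net, tol = 1e-9) {
  n <- n_reactions(net)
  # combinatorial prefilter: reactions killed by dead-end metabolites
  dead <- attr(find_dead_end_metabolites(net), "reactions")
  candidates <- setdiff(seq_len(n), rxn_index(net, dead))
  probs <- list(); key <- list()
  for (i in candidates) {
    probs[[length(probs) + 1]] <- flux_lp(net, obj = unit_obj(net, i),
                                          sense = "max", use_cone = TRUE)
    key[[length(key) + 1]] <- c(i, 1)
    if (!net$irreversible[i]) {
      probs[[length(probs) + 1]] <- flux_lp(net, obj = unit_obj(net, i),
                                            sense = "min", use_cone = TRUE)
      key[[length(key) + 1]] <- c(i, -1)
    }
  }
  sols <- solve_lp_batch(probs)
  can_flux <- rep(FALSE, n)
  for (k in seq_along(sols)) {
    s <- sols[[k]]
    if (identical(s$status, "error")) {
      stop("LP failure while testing reaction '",
           net$reaction_ids[key[[k]][1]], "' for blockedness: ", s$message,
           call. = FALSE)
    }
    if (identical(s$status, "optimal") && abs(s$objective) > tol) {
      can_flux[key[[k]][1]] <- TRUE
    }
  }
  net$reaction_ids[!can_flux]
}

#' Coupling partition of the reaction set
#'
#' Two unblocked reactions r, s are *partially coupled* (written
#' \eqn{r \Leftrightarrow s}) when \eqn{v_r = 0 \iff v_s = 0} for every
#' flux vector of the sign cone \eqn{C_0}. This is an equivalence relation;
#' its classes act as all-or-nothing reaction groups (akin to enzyme
#' subsets), so one binary variable per class suffices in the reduction
#' MILP.
#'
#' The partition is computed by nullspace seeding plus LP refinement:
#' reactions whose rows in an orthonormal nullspace basis of `S` are
#' proportional are fully coupled and merged immediately; the remaining
#' candidate pairs are decided by LPs over \eqn{C_0} (maximize
#' \eqn{|v_s|} subject to \eqn{v_r = 0}, and vice versa).
#'
#' @param net a `metabolic_network` containing only unblocked reactions
#'   (preprocess first; a blocked reaction raises an error naming it).
#' @param tol zero tolerance for the LP tests and the nullspace seeding.
#' @return An object of class `coupling_partition` with fields `classes`
#'   (list of reaction-id vectors), `representative` (one member per
#'   class, an irreversible member when the class has one), `class_size`,
#'   and `class_of` (named integer vector reaction -> class index).
#' @export
partial_coupling_classes <- function(net, tol = 1e-9) {
  blocked <- find_blocked_reactions(net, tol = tol)
  if (length(blocked)) {
    stop("network contains blocked reaction(s): ",
         paste(blocked, collapse = ", "),
         "; remove them before computing coupling classes", call. = FALSE)
  }
  n <- n_reactions(net)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }

  # seed: proportional rows of a nullspace basis => fully coupled
  K <- nullspace_basis(as.matrix(net$S))
  if (ncol(K) > 0) {
    nrm <- sqrt(rowSums(K^2))
    for (i in seq_len(n - 1)) {
      if (nrm[i] < tol) next
      for (j in seq(i + 1, n)) {
        if (nrm[j] < tol) next
        cross <- abs(sum(K[i, ] * K[j, ]))
        if (abs(cross - nrm[i] * nrm[j]) < 1e-9 * nrm[i] * nrm[j]) {
          union2(i, j)
        }
      }
    }
  }

  # refine: pairwise LP tests between current class representatives
  reps <- sort(unique(vapply(seq_len(n), find, integer(1))))
  pairs <- list(); probs <- list()
  uncoupled <- function(r, s) {
    # LPs asking: can s carry flux while r is fixed to zero?
    out <- list(flux_lp(net, obj = unit_obj(net, s), sense = "max",
                        fix_zero = r, use_cone = TRUE))
    if (!net$irreversible[s]) {
      out <- c(out, list(flux_lp(net, obj = unit_obj(net, s), sense = "min",
                                 fix_zero = r, use_cone = TRUE)))
    }
    out
  }
  if (length(reps) > 1) {
    for (a in seq_along(reps)[-length(reps)]) {
      for (b in seq(a + 1, length(reps))) {
        r <- reps[a]; s <- reps[b]
        pr <- c(uncoupled(r, s), uncoupled(s, r))
        pairs[[length(pairs) + 1]] <- c(r, s, length(pr))
        probs <- c(probs, pr)
      }
    }
    sols <- solve_lp_batch(probs)
    pos <- 1L
    for (p in pairs) {
      k <- p[3]
      vals <- vapply(sols[pos:(pos + k - 1)], function(s) {
        if (!identical(s$status, "optimal")) {
          stop("LP failure during coupling test", call. = FALSE)
        }
        abs(s$objective)
      }, numeric(1))
      pos <- pos + k
      if (max(vals) <= tol) union2(p[1], p[2])
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  uroots <- sort(unique(roots))
  classes <- lapply(uroots, function(r) net$reaction_ids[roots == r])
  representative <- vapply(uroots, function(r) {
    members <- which(roots == r)
    irr <- members[net$irreversible[members]]
    net$reaction_ids[if (length(irr)) irr[1] else members[1]]
  }, character(1))
  class_of <- match(roots, uroots)
  names(class_of) <- net$reaction_ids
  structure(list(classes = classes,
                 representative = representative,
                 class_size = lengths(classes),
                 class_of = class_of),
            class = "coupling_partition")
}

#' @export
print.coupling_partition <- function(x, ...) {
  cat("Coupling partition: ", length(x$classes), " class(es) over ",
      sum(x$class_size), " reactions (largest: ", max(x$class_size), ")\n",
      sep = "")
  invisible(x)
}

# orthonormal basis of the nullspace of A (columns), via SVD
nullspace_basis <- function(A, tol = 1e-10) {
  sv <- svd(A, nu = 0, nv = ncol(A))
  d <- sv$d
  rank <- sum(d > max(max(dim(A)) * .Machine$double.eps * max(d, 0), tol))
  if (rank >= ncol(A)) {
    matrix(0, nrow = ncol(A), ncol = 0)
  } else {
    sv$v[, seq(rank + 1, ncol(A)), drop = FALSE]
  }
}

#' Preprocess a network for reduction
#'
#' Removes blocked reactions (detected over the sign cone, see
#' [find_blocked_reactions()]) and, optionally, computes the coupling
#' partition of the remaining reactions.
#'
#' @param net a `metabolic_network`.
#' @param coupling also compute [partial_coupling_classes()]?
#' @param tol LP zero tolerance.
#' @return A list with `network` (pruned), `blocked` (removed reaction
#'   ids), `dead_end_metabolites`, and `partition` (or `NULL`).
#' @export
preprocess_network <- function(net, coupling = FALSE, tol = 1e-9) {
  dead <- find_dead_end_metabolites(net)
  blocked <- find_blocked_reactions(net, tol = tol)
  pruned <- if (length(blocked)) remove_reactions(net, blocked) else net
  partition <- if (coupling) partial_coupling_classes(pruned, tol = tol)
               else NULL
  list(network = pruned, blocked = blocked,
       dead_end_metabolites = as.character(dead), partition = partition)
}

#' Write a preprocessing status report
#'
#' One TSV row per reaction of the original network with its status and,
#' when a coupling partition is available, its class index and whether it
#' is the class representative.
#'
#' @param net the original `metabolic_network`.
#' @param prep result of [preprocess_network()].
#' @param path output TSV path.
#' @return The report `data.frame`, invisibly.
#' @export
write_preprocess_report <- function(net, prep, path) {
  dead_rxns <- attr(find_dead_end_metabolites(net), "reactions")
  status <- ifelse(net$reaction_ids %in% dead_rxns, "dead_end_removed",
                   ifelse(net$reaction_ids %in% prep$blocked, "blocked",
                          "unblocked"))
  cls <- rep(NA_integer_, n_reactions(net))
  is_rep <- rep(FALSE, n_reactions(net))
  if (!is.null(prep$partition)) {
    idx <- match(net$reaction_ids, names(prep$partition$class_of))
    cls <- as.integer(prep$partition$class_of[idx])
    is_rep <- net$reaction_ids %in% prep$partition$representative
  }
  df <- data.frame(reaction_id = net$reaction_ids, status = status,
                   class_index = cls, is_representative = is_rep)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
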