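# Supporting LP analyses and cross-subnetwork comparison statistics.

#' Flux variability analysis
#'
#' Minimum and maximum steady-state flux per reaction over the bounded
#' flux space, optionally under extra linear rows (e.g. a
#' fraction-of-optimum constraint). Solves two LPs per reaction in one
#' backend batch.
#'
#' @param net a `metabolic_network`.
#' @param extra_rows list of rows (`coefs` named vector, `rel`, `rhs`) as
#'   in [linear_functionality()].
#' @param reactions subset of reaction ids (default: all).
#' @return A `data.frame` with columns `reaction`, `min`, `max`.
#' @export
fva <- function(net, extra_rows = list(), reactions = net$reaction_ids) {
  idx <- rxn_index(net, reactions)
  rows <- canonical_rows(lapply(extra_rows, validate_row))
  probs <- list()
  for (i in idx) {
    probs[[length(probs) + 1]] <- flux_lp(net, unit_obj(net, i), "min", rows)
    probs[[length(probs) + 1]] <- flux_lp(net, unit_obj(net, i), "max", rows)
  }
  sols <- solve_lp_batch(probs)
  get <- function(k) {
    s <- sols[[k]]
    if (identical(s$status, "infeasible")) {
      stop("flux space is infeasible under the given rows", call. = FALSE)
    }
    if (identical(s$status, "unbounded")) {
      return(if (k %% 2 == 1) -Inf else Inf)
    }
    s$objective
  }
  data.frame(reaction = net$reaction_ids[idx],
             min = vapply(seq(1, 2 * length(idx), by = 2), get, numeric(1)),
             max = vapply(seq(2, 2 * length(idx), by = 2), get, numeric(1)))
}

#' Maximum achievable objective flux
#'
#' Solves \eqn{\max\{ v_{obj} \mid Sv = 0, l \le v \le u,
#' \text{fixing rows}\}}.
#'
#' @param net a `metabolic_network`.
#' @param objective_reaction reaction id to maximize.
#' @param fixing_rows optional rows applied while optimizing (e.g. an
#'   exchange held at zero).
#' @param .label context used in error messages.
#' @return The LP optimum (a scalar).
#' @export
max_objective <- function(net, objective_reaction, fixing_rows = list(),
                          .label = objective_reaction) {
  rows <- canonical_rows(lapply(fixing_rows, validate_row))
  sol <- solve_lp(flux_lp(net, unit_obj(net, objective_reaction), "max",
                          rows))
  if (identical(sol$status, "infeasible")) {
    stop("LP for '", .label, "' is infeasible under the fixing constraints",
         call. = FALSE)
  }
  if (identical(sol$status, "unbounded")) {
    stop("LP for '", .label, "' is unbounded; add finite bounds",
         call. = FALSE)
  }
  if (!identical(sol$status, "optimal")) {
    stop("LP for '", .label, "' failed: ", sol$status, call. = FALSE)
  }
  sol$objective
}

#' Essential reactions for an objective
#'
#' A reaction is essential when forcing it to zero drops the maximal
#' objective flux below `p` percent of its unconstrained optimum
#' (strictly, with an absolute tolerance of `1e-06`). Forcing `v_i = 0`
#' is equivalent to deleting the reaction and cheaper. One LP per
#' reaction, solved in a single backend batch.
#'
#' @param net a `metabolic_network`.
#' @param objective_reaction reaction id whose maximum defines the
#'   reference optimum (must be positive).
#' @param p percent threshold (default 20).
#' @return Character vector of essential reaction ids. The reference
#'   optimum is attached as attribute `"optimum"`.
#' @export
essential_reactions <- function(net, objective_reaction, p = 20) {
  opt <- max_objective(net, objective_reaction)
  if (opt <= 0) {
    stop("maximal objective flux is not positive (", format(opt),
         "); essentiality is undefined", call. = FALSE)
  }
  thr <- (p / 100) * opt
  n <- n_reactions(net)
  probs <- lapply(seq_len(n), function(i) {
    flux_lp(net, unit_obj(net, objective_reaction), "max", fix_zero = i)
  })
  sols <- solve_lp_batch(probs)
  ess <- vapply(seq_len(n), function(i) {
    s <- sols[[i]]
    if (identical(s$status, "infeasible")) return(TRUE)
    thr - s$objective > 1e-6
  }, logical(1))
  out <- net$reaction_ids[ess]
  attr(out, "optimum") <- opt
  out
}

#' Compare the subnetworks of an enumeration result
#'
#' Summarizes how reactions are distributed across the enumerated minimum
#' subnetworks: the core (present in all) and union sets, per-reaction
#' occurrence counts, the 0/1 membership matrix, and co-occurrence
#' patterns among the non-core reactions -- pairs that are *mutually
#' exclusive* (their occurrence sets are disjoint and both nonempty, e.g.
#' two isoenzymes of which any minimum subnetwork needs exactly one) and
#' pairs that are *always together* (identical occurrence sets, e.g. two
#' transport reactions forming a cycle).
#'
#' @param result an `enumeration_result`.
#' @return A `subnetwork_comparison` list with `core`, `union`,
#'   `occurrence` (data.frame `reaction`, `count`, `is_core`),
#'   `membership` (reactions x solutions 0/1 matrix), and data.frames
#'   `mutually_exclusive` and `always_together`.
#' @export
compare_subnetworks <- function(result) {
  stopifnot(inherits(result, "enumeration_result"))
  sets <- lapply(result$solutions, `[[`, "active")
  all_rxns <- result$union_reactions
  membership <- vapply(sets, function(s) as.integer(all_rxns %in% s),
                       integer(length(all_rxns)))
  membership <- matrix(membership, nrow = length(all_rxns),
                       dimnames = list(all_rxns,
                                       paste0("S", seq_along(sets))))
  counts <- rowSums(membership)
  is_core <- all_rxns %in% result$core_reactions
  occurrence <- data.frame(reaction = all_rxns, count = as.integer(counts),
                           is_core = is_core)
  noncore <- all_rxns[!is_core]
  excl <- list(); together <- list()
  if (length(noncore) > 1) {
    for (a in seq_len(length(noncore) - 1)) {
      for (b in seq(a + 1, length(noncore))) {
        occ_a <- membership[noncore[a], ] > 0
        occ_b <- membership[noncore[b], ] > 0
        if (!any(occ_a & occ_b) && any(occ_a) && any(occ_b)) {
          excl[[length(excl) + 1]] <- c(noncore[a], noncore[b])
        } else if (identical(occ_a, occ_b)) {
          together[[length(together) + 1]] <- c(noncore[a], noncore[b])
        }
      }
    }
  }
  to_df <- function(x) {
    if (length(x) == 0) {
      data.frame(reaction_a = character(), reaction_b = character())
    } else {
      data.frame(reaction_a = vapply(x, `[`, character(1), 1),
                 reaction_b = vapply(x, `[`, character(1), 2))
    }
  }
  structure(list(core = result$core_reactions,
                 union = result$union_reactions,
                 occurrence = occurrence,
                 membership = membership,
                 mutually_exclusive = to_df(excl),
                 always_together = to_df(together)),
            class = "subnetwork_comparison")
}

#' @export
print.subnetwork_comparison <- function(x, ...) {
  cat("Subnetwork comparison across ", ncol(x$membership), " solution(s):\n",
      "  core ", length(x$core), " / union ", length(x$union),
      " reactions; ", nrow(x$mutually_exclusive),
      " mutually exclusive pair(s), ", nrow(x$always_together),
      " always-together pair(s)\n", sep = "")
  invisible(x)
}

#' Write a comparison report
#'
#' TSV with one row per union reaction (occurrence count, core flag,
#' per-solution membership) plus a JSON sidecar with the pair lists.
#'
#' @param comparison a `subnetwork_comparison`.
#' @param path output TSV path; the JSON is written next to it with
#'   extension `.pairs.json`.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(comparison, path) {
  df <- cbind(comparison$occurrence,
              as.data.frame(comparison$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mutually_exclusive = comparison$mutually_exclusive,
         always_together = comparison$always_together),
    sub("\\.tsv$", "", path) |> paste0(".pairs.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
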