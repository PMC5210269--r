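# MetabolicNetwork: the steady-state flux space C = {v | Sv = 0, l <= v <= u}.

#' Construct a metabolic network
#'
#' Represents the steady-state flux space
#' \eqn{C = \{ v \mid S v = 0,\; l \le v \le u \}} of a metabolic model:
#' a stoichiometric matrix over the *internal* metabolites, per-reaction
#' flux bounds, and the irreversibility pattern. A reaction is treated as
#' reversible exactly when its lower bound is negative; irreversible
#' reactions must have a non-negative lower bound.
#'
#' Exchange (boundary) reactions are represented as unbalanced columns:
#' there are no rows for external metabolites.
#'
#' @param S stoichiometric matrix, metabolites x reactions (dense or
#'   `Matrix` sparse). Negative entries consume, positive entries produce.
#' @param reaction_ids,metabolite_ids unique identifier vectors matching
#'   the columns resp. rows of `S`. Defaults to the dimnames of `S`.
#' @param lower,upper per-reaction flux bounds; `-Inf`/`Inf` allowed.
#' @return An object of class `metabolic_network` with fields `S`
#'   (a `dgCMatrix`), `metabolite_ids`, `reaction_ids`, `lower`, `upper`,
#'   and the derived logical vector `irreversible`.
#' @examples
#' net <- metabolic_network(
#'   S = matrix(c(1, -1), nrow = 1,
#'              dimnames = list("A", c("EX_A", "sink"))),
#'   lower = c(0, 0), upper = c(10, 10))
#' net
#' @export
metabolic_network <- function(S, reaction_ids = colnames(S),
                              metabolite_ids = rownames(S),
                              lower, upper) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  auto_ids <- function(prefix, k) {
    if (k > 0) paste0(prefix, seq_len(k)) else character(0)
  }
  if (is.null(reaction_ids)) reaction_ids <- auto_ids("R", ncol(S))
  if (is.null(metabolite_ids)) metabolite_ids <- auto_ids("M", nrow(S))
  net <- structure(list(
    S = S,
    metabolite_ids = as.character(metabolite_ids),
    reaction_ids = as.character(reaction_ids),
    lower = as.numeric(lower),
    upper = as.numeric(upper)
  ), class = "metabolic_network")
  net$irreversible <- net$lower >= 0
  dimnames(net$S) <- list(
    if (nrow(net$S) > 0) net$metabolite_ids else NULL,
    if (ncol(net$S) > 0) net$reaction_ids else NULL)
  validate_network(net)
  net
}

#' Validate a metabolic network object
#'
#' Checks dimension agreement, identifier uniqueness, bound ordering
#' (`l <= u`) and that irreversible reactions have non-negative lower
#' bounds. Called by the constructor; exported because readers and
#' editing helpers reuse it.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly. Errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  n <- length(net$reaction_ids)
  m <- length(net$metabolite_ids)
  if (!all(dim(net$S) == c(m, n))) {
    stop("stoichiometric matrix is ", nrow(net$S), "x", ncol(net$S),
         " but there are ", m, " metabolites and ", n, " reactions",
         call. = FALSE)
  }
  if (anyDuplicated(net$reaction_ids)) {
    stop("duplicated reaction ids: ",
         paste(unique(net$reaction_ids[duplicated(net$reaction_ids)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(net$metabolite_ids)) {
    stop("duplicated metabolite ids: ",
         paste(unique(net$metabolite_ids[duplicated(net$metabolite_ids)]),
               collapse = ", "), call. = FALSE)
  }
  if (length(net$lower) != n || length(net$upper) != n) {
    stop("bound vectors must have one entry per reaction", call. = FALSE)
  }
  bad <- which(net$lower > net$upper)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(net$reaction_ids[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(net$irreversible & net$lower < 0)
  if (length(bad)) {
    stop("reaction(s) flagged irreversible with negative lower bound: ",
         paste(net$reaction_ids[bad], collapse = ", "), call. = FALSE)
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network: ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions (",
      sum(!x$irreversible), " reversible)\n", sep = "")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param net a `metabolic_network`.
#' @return integer count.
#' @export
n_reactions <- function(net) length(net$reaction_ids)

#' @rdname n_reactions
#' @export
n_metabolites <- function(net) length(net$metabolite_ids)

rxn_index <- function(net, ids, what = "reaction") {
  idx <- match(ids, net$reaction_ids)
  if (anyNA(idx)) {
    stop("unknown ", what, " id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

met_index <- function(net, ids) {
  idx <- match(ids, net$metabolite_ids)
  if (anyNA(idx)) {
    stop("unknown metabolite id(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Remove reactions from a network
#'
#' Drops the given reaction columns; metabolite rows that become all-zero
#' (untouched by any surviving reaction) are dropped as well. Identifier
#' order is otherwise preserved.
#'
#' @param net a `metabolic_network`.
#' @param rxns character vector of reaction ids to remove.
#' @return The reduced `metabolic_network`.
#' @export
remove_reactions <- function(net, rxns) {
  rxns <- unique(as.character(rxns))
  if (length(rxns) == 0) return(net)
  idx <- rxn_index(net, rxns)
  keep <- setdiff(seq_len(n_reactions(net)), idx)
  if (length(keep) == 0) {
    stop("removing all reactions would leave an empty network", call. = FALSE)
  }
  S <- net$S[, keep, drop = FALSE]
  touched <- Matrix::rowSums(S != 0) > 0
  metabolic_network(S[touched, , drop = FALSE],
                    reaction_ids = net$reaction_ids[keep],
                    metabolite_ids = net$metabolite_ids[touched],
                    lower = net$lower[keep], upper = net$upper[keep])
}

#' Restrict a network to a set of reactions
#'
#' Convenience inverse of [remove_reactions()]: keeps exactly `active`
#' (plus the metabolites they touch).
#'
#' @param net a `metabolic_network`.
#' @param active character vector of reaction ids to keep.
#' @return The induced sub-`metabolic_network`.
#' @export
subnetwork <- function(net, active) {
  active <- unique(as.character(active))
  rxn_index(net, active)  # validate
  drop <- setdiff(net$reaction_ids, active)
  if (length(drop) == 0) return(net)
  remove_reactions(net, drop)
}
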