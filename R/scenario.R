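# Reduction scenarios: protected sets, linear functionalities, thresholds.

#' Define a linear flux functionality
#'
#' A functionality is a set of linear conditions \eqn{D_f v \le d_f} that
#' the reduced subnetwork must be able to realize with *some* steady-state
#' flux vector of its own (each functionality gets its own flux copy in the
#' reduction MILP, so mutually exclusive conditions such as growth with and
#' without oxygen can both be preserved).
#'
#' Rows may use relations `"<="`, `">="` or `"=="`; they are canonicalized
#' to the `<=` form internally. Alternatively (or additionally) a
#' fraction-of-optimum requirement can be given: "reaction `obj` must reach
#' at least `fraction` of its maximum", optionally under fixing rows (e.g.
#' an oxygen exchange held at zero). Fraction-of-optimum specs are turned
#' into explicit rows by [resolve_functionality()], which solves the
#' corresponding LP.
#'
#' @param label short name used in messages and reports.
#' @param rows list of rows, each a list with `coefs` (named numeric vector
#'   over reaction ids), `rel` (one of `"<="`, `">="`, `"=="`) and `rhs`.
#' @param fraction_of_optimum optional list with `reaction`, `fraction`
#'   (in (0, 1]) and optionally `fixed` (list of rows as above) applied both
#'   while computing the optimum and in the resolved functionality.
#' @return An object of class `linear_functionality`.
#' @examples
#' f <- linear_functionality("aerobic",
#'   rows = list(list(coefs = c(biomass = 1), rel = ">=", rhs = 1.5)))
#' @export
linear_functionality <- function(label, rows = list(),
                                 fraction_of_optimum = NULL) {
  stopifnot(is.character(label), length(label) == 1)
  rows <- lapply(rows, validate_row)
  if (!is.null(fraction_of_optimum)) {
    fo <- fraction_of_optimum
    if (is.null(fo$reaction) || is.null(fo$fraction)) {
      stop("fraction_of_optimum needs elements 'reaction' and 'fraction'",
           call. = FALSE)
    }
    if (fo$fraction <= 0 || fo$fraction > 1) {
      stop("fraction-of-optimum fraction must lie in (0, 1], got ",
           fo$fraction, call. = FALSE)
    }
    fo$fixed <- lapply(fo$fixed %||% list(), validate_row)
    fraction_of_optimum <- fo
  }
  structure(list(label = label, rows = rows,
                 fraction_of_optimum = fraction_of_optimum),
            class = "linear_functionality")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_row <- function(row) {
  if (is.null(row$coefs) || is.null(names(row$coefs)) ||
      any(!nzchar(names(row$coefs)))) {
    stop("functionality row needs a named 'coefs' vector over reaction ids",
         call. = FALSE)
  }
  row$coefs <- vapply(row$coefs, as.numeric, numeric(1))
  row$rel <- match.arg(row$rel %||% "<=", c("<=", ">=", "=="))
  if (is.null(row$rhs) || !is.finite(as.numeric(row$rhs))) {
    stop("functionality row needs a finite 'rhs'", call. = FALSE)
  }
  row$rhs <- as.numeric(row$rhs)
  row
}

# canonical D v <= d form: list of list(coefs, rhs)
canonical_rows <- function(rows) {
  out <- list()
  for (row in rows) {
    if (row$rel %in% c("<=", "==")) {
      out[[length(out) + 1]] <- list(coefs = row$coefs, rhs = row$rhs)
    }
    if (row$rel %in% c(">=", "==")) {
      out[[length(out) + 1]] <- list(coefs = -row$coefs, rhs = -row$rhs)
    }
  }
  out
}

#' @export
print.linear_functionality <- function(x, ...) {
  cat("Functionality '", x$label, "': ", length(x$rows), " row(s)", sep = "")
  if (!is.null(x$fraction_of_optimum)) {
    cat(", unresolved fraction-of-optimum on '",
        x$fraction_of_optimum$reaction, "' (gamma = ",
        x$fraction_of_optimum$fraction, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

is_resolved <- function(f) is.null(f$fraction_of_optimum)

#' Resolve a fraction-of-optimum functionality into explicit rows
#'
#' Solves the LP \eqn{\max\{ v_{obj} \mid Sv = 0, l \le v \le u,
#' \text{fixing rows}\}} and replaces the fraction-of-optimum spec by the
#' rows `v_obj >= fraction * optimum` plus the fixing rows themselves.
#' A functionality without a fraction-of-optimum spec is returned
#' unchanged.
#'
#' @param net a `metabolic_network`.
#' @param f a `linear_functionality`.
#' @return A resolved `linear_functionality`; its `fraction_of_optimum`
#'   field is `NULL` and the derived optimum is kept in attribute
#'   `"optimum"`.
#' @export
resolve_functionality <- function(net, f) {
  stopifnot(inherits(f, "linear_functionality"))
  if (is_resolved(f)) return(f)
  fo <- f$fraction_of_optimum
  opt <- max_objective(net, fo$reaction, fixing_rows = fo$fixed,
                       .label = f$label)
  rows <- c(f$rows, fo$fixed,
            list(list(coefs = stats::setNames(1, fo$reaction),
                      rel = ">=", rhs = fo$fraction * opt)))
  out <- linear_functionality(f$label, rows)
  attr(out, "optimum") <- opt
  out
}

#' Define a reduction scenario
#'
#' Bundles everything the reduced subnetwork must preserve: protected
#' metabolites (must remain connected by at least one active reaction),
#' protected reactions (must be able to carry flux at least `delta`),
#' a list of linear functionalities, and a minimum number of degrees of
#' freedom. Also carries the numerical knobs of the MILP encoding: the
#' activity threshold `delta`, the big-M constant, and the encoding mode.
#'
#' @param net the `metabolic_network` the scenario refers to.
#' @param protected_metabolites,protected_reactions character id vectors.
#' @param functionalities list of [linear_functionality()] objects.
#' @param dof_min minimum degrees of freedom (default 1; values above 1
#'   trigger the exclude-and-resolve loop in [minimum_subnetwork()]).
#' @param delta activity threshold \eqn{\delta > 0}: a reaction counts as
#'   active when it can carry at least this much flux. Values outside
#'   `[1e-06, 1e-04]` are accepted with a warning.
#' @param big_M big-M constant; defaults to
#'   `max(1000, max(abs(finite bounds)))`. Used only in `"bigM"` encoding.
#' @param encoding `"indicator"` (default) or `"bigM"`.
#' @return An object of class `reduction_scenario`.
#' @export
reduction_scenario <- function(net,
                               protected_metabolites = character(),
                               protected_reactions = character(),
                               functionalities = list(),
                               dof_min = 1,
                               delta = 1e-4,
                               big_M = NULL,
                               encoding = c("indicator", "bigM")) {
  stopifnot(inherits(net, "metabolic_network"))
  encoding <- match.arg(encoding)
  protected_metabolites <- unique(as.character(protected_metabolites))
  protected_reactions <- unique(as.character(protected_reactions))
  met_index(net, protected_metabolites)
  rxn_index(net, protected_reactions, "protected reaction")
  if (inherits(functionalities, "linear_functionality")) {
    functionalities <- list(functionalities)
  }
  for (f in functionalities) {
    stopifnot(inherits(f, "linear_functionality"))
    for (row in c(f$rows, f$fraction_of_optimum$fixed %||% list())) {
      rxn_index(net, names(row$coefs), "functionality reaction")
    }
    if (!is.null(f$fraction_of_optimum)) {
      rxn_index(net, f$fraction_of_optimum$reaction, "functionality reaction")
    }
  }
  delta <- as.numeric(delta)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (delta < 1e-6 || delta > 1e-4) {
    warning("delta = ", delta, " is outside the recommended range ",
            "[1e-06, 1e-04]", call. = FALSE)
  }
  finite <- c(abs(net$lower[is.finite(net$lower)]),
              abs(net$upper[is.finite(net$upper)]))
  if (is.null(big_M)) big_M <- max(1000, finite)
  big_M <- as.numeric(big_M)
  if (big_M <= delta) stop("big_M must exceed delta", call. = FALSE)
  if (length(finite) && big_M < max(finite)) {
    stop("big_M (", big_M, ") must be at least the largest finite bound (",
         max(finite), ")", call. = FALSE)
  }
  dof_min <- as.integer(dof_min)
  if (dof_min < 0) stop("dof_min must be non-negative", call. = FALSE)
  structure(list(protected_metabolites = protected_metabolites,
                 protected_reactions = protected_reactions,
                 functionalities = functionalities,
                 dof_min = dof_min, delta = delta, big_M = big_M,
                 encoding = encoding),
            class = "reduction_scenario")
}

#' @export
print.reduction_scenario <- function(x, ...) {
  cat("Reduction scenario: ",
      length(x$protected_reactions), " protected reaction(s), ",
      length(x$protected_metabolites), " protected metabolite(s), ",
      length(x$functionalities), " functionalit",
      if (length(x$functionalities) == 1) "y" else "ies",
      "\n  dof_min = ", x$dof_min, ", delta = ", format(x$delta),
      ", big_M = ", format(x$big_M), ", encoding = ", x$encoding, "\n",
      sep = "")
  invisible(x)
}

#' Resolve all functionalities of a scenario
#'
#' Applies [resolve_functionality()] to every functionality that still has
#' a fraction-of-optimum spec.
#'
#' @param net a `metabolic_network`.
#' @param scenario a `reduction_scenario`.
#' @return The scenario with all functionalities resolved.
#' @export
resolve_scenario <- function(net, scenario) {
  stopifnot(inherits(scenario, "reduction_scenario"))
  scenario$functionalities <- lapply(scenario$functionalities,
                                     function(f) resolve_functionality(net, f))
  scenario
}
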