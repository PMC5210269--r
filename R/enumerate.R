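# Degrees of freedom, integer-cut exclusion, and enumeration of all
# minimum subnetworks.

#' Degrees of freedom of a subnetwork
#'
#' The dimension of the nullspace of the stoichiometric matrix restricted
#' to the active reactions (and the metabolites they touch):
#' `|active| - rank(S_active)`. A subnetwork with `dof = k` supports a
#' k-dimensional space of steady-state flux distributions.
#'
#' @param net a `metabolic_network`.
#' @param active non-empty character vector of active reaction ids.
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(net, active) {
  active <- unique(as.character(active))
  if (length(active) == 0) stop("active set must be non-empty", call. = FALSE)
  idx <- rxn_index(net, active)
  S <- as.matrix(net$S[, idx, drop = FALSE])
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  rank <- if (nrow(S) == 0) 0L else qr(S)$rank
  length(active) - rank
}

#' Add an integer cut excluding one activity pattern
#'
#' Appends the exclusion constraint
#' \deqn{\sum_{i \notin Z} a_i + \sum_{i \in Z} (1 - a_i) \ge 1}
#' to the problem, where `Z` is the binary activity pattern of the given
#' solution. The row is violated exactly by that 0/1 assignment and by no
#' other, so re-solving yields a different subnetwork (or a larger
#' optimum, proving exhaustion). Cuts act in the problem's own binary
#' index space: per reaction for the reaction-level formulations, per
#' coupling class for the representative formulation.
#'
#' @param problem a `milp_problem`.
#' @param solution a `subnetwork_solution` obtained from this problem (or
#'   one with the same binary space).
#' @return The problem with the cut appended.
#' @export
add_exclusion_constraint <- function(problem, solution) {
  stopifnot(inherits(problem, "milp_problem"),
            inherits(solution, "subnetwork_solution"))
  pat <- solution$group_active
  if (is.null(pat) || length(pat) != length(problem$groups)) {
    stop("solution's activity pattern does not live in this problem's ",
         "binary index space", call. = FALSE)
  }
  # the pattern must describe the same active reaction set
  expanded <- sort(problem$net$reaction_ids[unlist(problem$groups[pat])])
  if (!identical(expanded, solution$active)) {
    stop("solution's active set is not expressible over this problem's ",
         "binary groups", call. = FALSE)
  }
  problem$cuts[[length(problem$cuts) + 1L]] <- pat
  problem
}

#' Compute one minimum subnetwork
#'
#' Solves the reduction MILP; if the optimum violates the
#' degrees-of-freedom requirement (`dof_min`), that activity pattern is
#' excluded with an integer cut and the MILP re-solved, until a subnetwork
#' with `dof >= dof_min` is found. With the default `dof_min = 1` the loop
#' exits on the first solve, because protected reactions and
#' functionalities force nonzero flux and hence at least one degree of
#' freedom.
#'
#' @param net a preprocessed `metabolic_network` (no blocked reactions).
#' @param scenario a `reduction_scenario`; fraction-of-optimum
#'   functionalities are resolved automatically.
#' @param use_representatives solve over coupling classes
#'   ([build_minnw_rep()]) instead of individual reactions.
#' @param partition optional precomputed [partial_coupling_classes()]
#'   result (computed on demand when `use_representatives = TRUE`).
#' @param max_iter safety bound on the exclude-and-resolve loop.
#' @param time_limit per-solve time limit in seconds, or `NULL`.
#' @return A `subnetwork_solution` with its `dof` field filled in. The
#'   dof-rejected solutions, if any, are attached as attribute
#'   `"rejected"`. Errors with class `minsubnet_infeasible` when the
#'   requirements are unsatisfiable, or with class
#'   `minsubnet_dof_exhausted` (carrying the rejected solutions) when no
#'   subnetwork reaches `dof_min`.
#' @export
minimum_subnetwork <- function(net, scenario, use_representatives = FALSE,
                               partition = NULL, max_iter = 1000L,
                               time_limit = NULL) {
  problem <- prepare_problem(net, scenario, use_representatives, partition)
  scenario <- problem$scenario
  rejected <- list()
  for (iter in seq_len(max_iter)) {
    sol <- tryCatch(solve_milp(problem, time_limit = time_limit),
                    minsubnet_infeasible = function(e) e)
    if (inherits(sol, "minsubnet_infeasible")) {
      if (length(rejected) == 0) stop(sol)
      cond <- structure(
        class = c("minsubnet_dof_exhausted", "error", "condition"),
        list(message = paste0("no subnetwork satisfies dof >= ",
                              scenario$dof_min, " (", length(rejected),
                              " smaller subnetwork(s) rejected)"),
             call = sys.call(), rejected = rejected))
      stop(cond)
    }
    sol$dof <- degrees_of_freedom(net, sol$active)
    if (sol$dof >= scenario$dof_min) {
      attr(sol, "rejected") <- rejected
      return(sol)
    }
    rejected[[length(rejected) + 1L]] <- sol
    problem <- add_exclusion_constraint(problem, sol)
  }
  stop("dof filtering did not terminate within ", max_iter, " iterations",
       call. = FALSE)
}

prepare_problem <- function(net, scenario, use_representatives, partition) {
  scenario <- resolve_scenario(net, scenario)
  if (use_representatives) {
    if (is.null(partition)) partition <- partial_coupling_classes(net)
    build_minnw_rep(net, scenario, partition)
  } else {
    build_minnw(net, scenario)
  }
}

#' Enumerate all minimum subnetworks
#'
#' Iteratively solves the reduction MILP, excluding each found activity
#' pattern with an integer cut, and collects every solution whose number
#' of active reactions equals the minimum. Enumeration stops with
#' `exhausted = TRUE` as soon as the optimum strictly exceeds the minimum
#' size or the cut problem becomes infeasible -- cuts only remove already
#' found patterns, so the first strictly larger optimum proves there are
#' no further minimum subnetworks. Solutions failing the
#' degrees-of-freedom requirement are excluded but not collected; the
#' minimum size is then the smallest dof-passing size.
#'
#' @inheritParams minimum_subnetwork
#' @param max_solutions stop (with `exhausted = FALSE`) after this many
#'   solutions.
#' @param time_limit overall wall-clock budget in seconds, or `NULL`.
#' @return An `enumeration_result`: `solutions` (sorted by lexicographic
#'   active-set order), `minimum_size`, `core_reactions` (in every
#'   solution), `union_reactions`, and `exhausted`.
#' @export
enumerate_minimum_subnetworks <- function(net, scenario,
                                          use_representatives = FALSE,
                                          partition = NULL,
                                          max_solutions = Inf,
                                          time_limit = NULL) {
  problem <- prepare_problem(net, scenario, use_representatives, partition)
  scenario <- problem$scenario
  t0 <- Sys.time()
  budget_left <- function() {
    if (is.null(time_limit)) return(NULL)
    max(1, time_limit - as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  solutions <- list()
  minimum_size <- NA_integer_
  exhausted <- FALSE
  repeat {
    sol <- tryCatch(solve_milp(problem, time_limit = budget_left()),
                    minsubnet_infeasible = function(e) e)
    if (inherits(sol, "minsubnet_infeasible")) {
      if (length(solutions) == 0) stop(sol)
      exhausted <- TRUE
      break
    }
    if (!identical(sol$solver_status, "optimal")) break  # time limit
    sol$dof <- degrees_of_freedom(net, sol$active)
    if (!is.na(minimum_size) && sol$n_active > minimum_size) {
      exhausted <- TRUE
      break
    }
    if (sol$dof >= scenario$dof_min) {
      if (is.na(minimum_size)) minimum_size <- sol$n_active
      solutions[[length(solutions) + 1L]] <- sol
    }
    problem <- add_exclusion_constraint(problem, sol)
    if (length(solutions) >= max_solutions) break
    if (!is.null(time_limit) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit) {
      break
    }
  }
  if (length(solutions) == 0) {
    cond <- structure(
      class = c("minsubnet_dof_exhausted", "error", "condition"),
      list(message = paste0("no subnetwork satisfies dof >= ",
                            scenario$dof_min), call = sys.call()))
    stop(cond)
  }
  ord <- order(vapply(solutions, function(s) paste(s$active, collapse = "\r"),
                      character(1)))
  solutions <- solutions[ord]
  active_sets <- lapply(solutions, `[[`, "active")
  structure(list(
    solutions = solutions,
    minimum_size = minimum_size,
    core_reactions = sort(Reduce(intersect, active_sets)),
    union_reactions = sort(Reduce(union, active_sets)),
    exhausted = exhausted
  ), class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("Enumeration result: ", length(x$solutions), " minimum subnetwork(s) ",
      "of size ", x$minimum_size,
      if (x$exhausted) " (exhaustive)" else " (stopped early)", "\n",
      "  core: ", length(x$core_reactions), " reaction(s), union: ",
      length(x$union_reactions), " reaction(s)\n", sep = "")
  invisible(x)
}

#' Write an enumeration result to JSON
#'
#' @param result an `enumeration_result`.
#' @param path output path.
#' @param provenance optional named list recorded verbatim (solver seeds,
#'   model checksum, ...).
#' @return `path`, invisibly.
#' @export
write_enumeration_json <- function(result, path, provenance = list()) {
  body <- list(
    minimum_size = result$minimum_size,
    exhausted = result$exhausted,
    core_reactions = result$core_reactions,
    union_reactions = result$union_reactions,
    solutions = lapply(result$solutions, function(s) list(
      active = s$active,
      n_active = s$n_active,
      dof = s$dof,
      witness_fluxes = lapply(s$witness_fluxes, function(w) as.list(w))
    )),
    provenance = provenance
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
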