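# Model and scenario I/O: SBML (Level 3 + FBC, with legacy fallbacks),
# BiGG-style JSON, scenario config files, and TSV reports.

#' Read a metabolic model
#'
#' Reads SBML or BiGG-style JSON into a [metabolic_network()]. Boundary
#' metabolites (SBML `boundaryCondition="true"`, or ids ending in `_b` in
#' BiGG-style JSON) are excluded, so exchange reactions appear as
#' unbalanced columns. Reversibility is inferred from the bounds
#' (`lower < 0`).
#'
#' SBML bounds are taken from the FBC package (`fbc:lowerFluxBound` /
#' `fbc:upperFluxBound` parameters) when present, falling back to legacy
#' `kineticLaw` parameters `LOWER_BOUND` / `UPPER_BOUND`, and finally to
#' the `reversible` attribute (`[-Inf, Inf]` vs `[0, Inf]`). The tokens
#' `INF` / `-INF` are understood as infinities.
#'
#' @param path model file.
#' @param format `"sbml"`, `"bigg_json"`, or `"auto"` (dispatch on
#'   extension, then content sniffing).
#' @return A `metabolic_network`. The file's MD5 checksum is attached as
#'   attribute `"checksum"`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "bigg_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
              else if (ext == "json") "bigg_json"
              else {
                head <- readChar(path, 256)
                if (grepl("^\\s*<", head)) "sbml" else "bigg_json"
              }
  }
  net <- switch(format,
                sbml = read_sbml(path),
                bigg_json = read_bigg_json(path))
  attr(net, "checksum") <- tools::md5sum(path)[[1]]
  net
}

parse_bound_token <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_real_)
  if (x %in% c("INF", "inf", "Inf")) return(Inf)
  if (x %in% c("-INF", "-inf", "-Inf")) return(-Inf)
  suppressWarnings(as.numeric(x))
}

xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("SBML parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    stop("SBML parse failure: no <model> element in '", path, "'",
         call. = FALSE)
  }

  species <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_id <- vapply(species, function(s) xattr(s, "id"), character(1))
  boundary <- vapply(species, function(s) {
    identical(xattr(s, "boundaryCondition"), "true")
  }, logical(1))
  mets <- sp_id[!boundary]

  params <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  pvals <- stats::setNames(
    vapply(params, function(p) parse_bound_token(xattr(p, "value")),
           numeric(1)),
    vapply(params, function(p) xattr(p, "id"), character(1)))

  rxn_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rxn_nodes) == 0) {
    stop("SBML parse failure: model has no reactions", call. = FALSE)
  }
  n <- length(rxn_nodes)
  rxn_id <- character(n); lower <- numeric(n); upper <- numeric(n)
  S <- matrix(0, length(mets), n, dimnames = list(mets, NULL))
  for (k in seq_len(n)) {
    rn <- rxn_nodes[[k]]
    rxn_id[k] <- xattr(rn, "id")
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sp <- xattr(ref, "species")
        st <- parse_bound_token(xattr(ref, "stoichiometry"))
        if (is.na(st)) st <- 1
        if (sp %in% mets) S[sp, k] <- S[sp, k] + sgn * st
      }
    }
    # bounds: FBC parameters, then legacy kineticLaw, then reversibility
    lb_ref <- xattr(rn, "lowerFluxBound"); ub_ref <- xattr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
          else NA_real_
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]]
          else NA_real_
    if (is.na(lb) || is.na(ub)) {
      kl <- xml2::xml_find_all(rn, ".//kineticLaw//parameter | .//kineticLaw//localParameter")
      for (p in kl) {
        pid <- xattr(p, "id")
        val <- parse_bound_token(xattr(p, "value"))
        if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- val
        if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- val
      }
    }
    if (is.na(lb) || is.na(ub)) {
      rev_attr <- xattr(rn, "reversible")
      reversible <- is.na(rev_attr) || identical(rev_attr, "true")
      if (is.na(lb)) lb <- if (reversible) -Inf else 0
      if (is.na(ub)) ub <- Inf
    }
    lower[k] <- lb; upper[k] <- ub
  }
  metabolic_network(S, reaction_ids = rxn_id, metabolite_ids = mets,
                    lower = lower, upper = upper)
}

read_bigg_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("JSON parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$reactions)) {
    stop("BiGG JSON parse failure: no 'reactions' array in '", path, "'",
         call. = FALSE)
  }
  met_ids <- vapply(doc$metabolites %||% list(), function(m) {
    m$id %||% stop("BiGG JSON parse failure: metabolite without id",
                   call. = FALSE)
  }, character(1))
  met_ids <- met_ids[!endsWith(met_ids, "_b")]  # boundary convention
  n <- length(doc$reactions)
  rxn_id <- character(n); lower <- numeric(n); upper <- numeric(n)
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, NULL))
  for (k in seq_len(n)) {
    r <- doc$reactions[[k]]
    rxn_id[k] <- r$id %||% stop("BiGG JSON parse failure: reaction without id",
                                call. = FALSE)
    lower[k] <- as.numeric(r$lower_bound %||% -Inf)
    upper[k] <- as.numeric(r$upper_bound %||% Inf)
    for (met in names(r$metabolites %||% list())) {
      if (met %in% met_ids) S[met, k] <- as.numeric(r$metabolites[[met]])
    }
  }
  metabolic_network(S, reaction_ids = rxn_id, metabolite_ids = met_ids,
                    lower = lower, upper = upper)
}

fmt_bound <- function(x) {
  if (x == Inf) "INF" else if (x == -Inf) "-INF" else format(x, digits = 17)
}

#' Write a metabolic model
#'
#' Writes SBML Level 3 (with FBC flux-bound parameters) or BiGG-style
#' JSON. Round-tripping through [read_model()] preserves the
#' stoichiometry, bounds and reversibility exactly.
#'
#' @param net a `metabolic_network`.
#' @param path output file.
#' @param format `"sbml"` or `"bigg_json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(net, path, format = c("sbml", "bigg_json")) {
  format <- match.arg(format)
  switch(format,
         sbml = write_sbml(net, path),
         bigg_json = write_bigg_json(net, path))
  invisible(path)
}

write_sbml <- function(net, path) {
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = fbc,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")

  sp_list <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in net$metabolite_ids) {
    xml2::xml_add_child(sp_list, "species", id = m, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  # one shared parameter per distinct bound value
  bound_vals <- sort(unique(c(net$lower, net$upper)))
  par_id <- stats::setNames(paste0("bnd_", seq_along(bound_vals)),
                            vapply(bound_vals, fmt_bound, character(1)))
  par_list <- xml2::xml_add_child(model, "listOfParameters")
  for (v in bound_vals) {
    xml2::xml_add_child(par_list, "parameter", id = par_id[[fmt_bound(v)]],
                        value = fmt_bound(v), constant = "true")
  }

  rxn_list <- xml2::xml_add_child(model, "listOfReactions")
  for (k in seq_len(n_reactions(net))) {
    rn <- xml2::xml_add_child(
      rxn_list, "reaction", id = net$reaction_ids[k],
      reversible = if (net$lower[k] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = par_id[[fmt_bound(net$lower[k])]],
      "fbc:upperFluxBound" = par_id[[fmt_bound(net$upper[k])]])
    col <- net$S[, k]
    nz <- which(col != 0)
    reac <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in reac) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = net$metabolite_ids[m],
                            stoichiometry = format(-col[m], digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in prod) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = net$metabolite_ids[m],
                            stoichiometry = format(col[m], digits = 17),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
}

write_bigg_json <- function(net, path) {
  reactions <- lapply(seq_len(n_reactions(net)), function(k) {
    col <- net$S[, k]
    nz <- which(col != 0)
    mets <- as.list(stats::setNames(as.numeric(col[nz]),
                                    net$metabolite_ids[nz]))
    list(id = net$reaction_ids[k],
         lower_bound = if (is.finite(net$lower[k])) net$lower[k] else NULL,
         upper_bound = if (is.finite(net$upper[k])) net$upper[k] else NULL,
         metabolites = mets)
  })
  body <- list(
    metabolites = lapply(net$metabolite_ids, function(m) list(id = m)),
    reactions = reactions,
    genes = list(),
    id = "model",
    version = "1"
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Write a reduced subnetwork
#'
#' SBML / BiGG JSON output contains exactly the active reactions plus the
#' metabolites they touch (bounds copied from the parent network); the
#' TSV variant lists every reaction of the full network with an
#' `in_subnetwork` flag and, when a solution is given, the per-copy
#' witness fluxes.
#'
#' @param net the parent `metabolic_network`.
#' @param active character vector of active reaction ids (non-empty), or
#'   a `subnetwork_solution`.
#' @param path output file.
#' @param format `"sbml"`, `"bigg_json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(net, active, path,
                             format = c("sbml", "bigg_json", "tsv")) {
  format <- match.arg(format)
  solution <- NULL
  if (inherits(active, "subnetwork_solution")) {
    solution <- active
    active <- solution$active
  }
  active <- unique(as.character(active))
  if (length(active) == 0) {
    stop("active set is empty; refusing to write an empty model",
         call. = FALSE)
  }
  rxn_index(net, active)
  if (format == "tsv") {
    df <- data.frame(reaction_id = net$reaction_ids,
                     in_subnetwork = as.integer(net$reaction_ids %in% active))
    if (!is.null(solution)) {
      for (j in names(solution$witness_fluxes)) {
        df[[paste0("witness_", j)]] <-
          as.numeric(solution$witness_fluxes[[j]][net$reaction_ids])
      }
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  write_model(subnetwork(net, active), path, format)
}

# ---- scenario config ------------------------------------------------------

suggest_ids <- function(bad, pool) {
  hints <- vapply(bad, function(b) {
    near <- agrep(b, pool, max.distance = 0.25, value = TRUE)
    if (length(near)) paste0(" (did you mean ",
                             paste(utils::head(near, 3), collapse = ", "),
                             "?)") else ""
  }, character(1))
  paste0(bad, hints, collapse = "; ")
}

check_ids <- function(ids, pool, what) {
  bad <- setdiff(ids, pool)
  if (length(bad)) {
    stop("unknown ", what, ": ", suggest_ids(bad, pool), call. = FALSE)
  }
}

parse_config_row <- function(row) {
  if (is.null(row$coefs) || length(row$coefs) == 0) {
    stop("malformed functionality row: missing 'coefs' mapping",
         call. = FALSE)
  }
  list(coefs = unlist(row$coefs), rel = row$rel %||% "<=",
       rhs = as.numeric(row$rhs %||% stop("malformed functionality row: ",
                                          "missing 'rhs'", call. = FALSE)))
}

#' Read a reduction scenario from a config file
#'
#' The config is JSON or YAML (by extension) with keys
#' `protected_metabolites`, `protected_reactions`, `functionalities`
#' (each with `label` and `rows` and/or `fraction_of_optimum`),
#' `dof_min`, `delta`, `big_M` and `encoding`. Row coefficients are given
#' as a reaction-id to coefficient mapping with `rel` in `<=`, `>=`,
#' `==`. Unknown ids are rejected with nearest-match suggestions.
#'
#' @param path config file.
#' @param net the `metabolic_network` the scenario refers to.
#' @return A `reduction_scenario` (fraction-of-optimum functionalities
#'   still unresolved; see [resolve_scenario()]).
#' @export
read_scenario <- function(path, net) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  pm <- as.character(unlist(cfg$protected_metabolites %||% list()))
  pr <- as.character(unlist(cfg$protected_reactions %||% list()))
  check_ids(pm, net$metabolite_ids, "protected metabolite id(s)")
  check_ids(pr, net$reaction_ids, "protected reaction id(s)")
  funs <- lapply(cfg$functionalities %||% list(), function(fc) {
    rows <- lapply(fc$rows %||% list(), parse_config_row)
    fo <- fc$fraction_of_optimum
    if (!is.null(fo)) {
      fo <- list(reaction = fo$reaction,
                 fraction = as.numeric(fo$fraction),
                 fixed = lapply(fo$fixed %||% list(), parse_config_row))
      check_ids(fo$reaction, net$reaction_ids, "objective reaction id")
    }
    for (row in rows) {
      check_ids(names(row$coefs), net$reaction_ids,
                "functionality reaction id(s)")
    }
    linear_functionality(fc$label %||% "functionality", rows,
                         fraction_of_optimum = fo)
  })
  args <- list(net = net, protected_metabolites = pm,
               protected_reactions = pr, functionalities = funs)
  for (key in c("dof_min", "delta", "big_M")) {
    if (!is.null(cfg[[key]])) args[[key]] <- as.numeric(cfg[[key]])
  }
  if (!is.null(cfg$encoding)) args$encoding <- cfg$encoding
  do.call(reduction_scenario, args)
}
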