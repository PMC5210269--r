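# Shared helpers for the test suite. All fixtures are built in code.

# canonical string form of a family of active sets, for set comparison
family_strings <- function(sets) {
  sort(vapply(sets, function(a) paste(sort(a), collapse = ","),
              character(1)))
}

solution_family <- function(result) {
  family_strings(lapply(result$solutions, `[[`, "active"))
}

# a tiny linear chain:  -> A -> B ->  (all irreversible, bounds [0, 10])
make_chain_net <- function() {
  S <- matrix(c(1, 0,
                -1, 1,
                0, -1), nrow = 2,
              dimnames = list(c("A", "B"), c("in", "conv", "out")))
  metabolic_network(S, lower = rep(0, 3), upper = rep(10, 3))
}

# definitional partial-coupling partition: for each reaction pair, four
# LPs over the sign cone asking whether one can run while the other is
# clamped to zero (independent of the nullspace-seeded implementation)
definitional_coupling <- function(net, tol = 1e-9) {
  n <- n_reactions(net)
  stopifnot(n <= 12)
  can_flux_without <- function(s, r) {
    probs <- list(minsubnet:::flux_lp(net, minsubnet:::unit_obj(net, s),
                                      "max", fix_zero = r, use_cone = TRUE),
                  minsubnet:::flux_lp(net, minsubnet:::unit_obj(net, s),
                                      "min", fix_zero = r, use_cone = TRUE))
    sols <- minsubnet:::solve_lp_batch(probs)
    any(vapply(sols, function(x) abs(x$objective) > tol, logical(1)))
  }
  coupled <- diag(TRUE, n)
  for (r in seq_len(n - 1)) {
    for (s in seq(r + 1, n)) {
      coupled[r, s] <- coupled[s, r] <-
        !can_flux_without(s, r) && !can_flux_without(r, s)
    }
  }
  # connected components of the coupling graph (it is transitive)
  seen <- rep(FALSE, n)
  classes <- list()
  for (r in seq_len(n)) {
    if (seen[r]) next
    members <- which(coupled[r, ])
    seen[members] <- TRUE
    classes[[length(classes) + 1]] <- sort(net$reaction_ids[members])
  }
  classes
}

# hand-written 3-metabolite, 4-reaction SBML document (legacy kineticLaw
# bounds on purpose, to exercise the fallback path)
write_tiny_sbml <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="tiny">
  <listOfSpecies>
   <species id="A" compartment="c" boundaryCondition="false"/>
   <species id="B" compartment="c" boundaryCondition="false"/>
   <species id="C" compartment="c" boundaryCondition="false"/>
   <species id="X_ext" compartment="e" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="vin" reversible="false">
    <listOfReactants>
     <speciesReference species="X_ext" stoichiometry="1"/>
    </listOfReactants>
    <listOfProducts>
     <speciesReference species="A" stoichiometry="1"/>
    </listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="10"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="v1" reversible="true">
    <listOfReactants>
     <speciesReference species="A" stoichiometry="1"/>
    </listOfReactants>
    <listOfProducts>
     <speciesReference species="B" stoichiometry="2"/>
    </listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="-5"/>
      <parameter id="UPPER_BOUND" value="5"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="v2" reversible="false">
    <listOfReactants>
     <speciesReference species="B" stoichiometry="1"/>
    </listOfReactants>
    <listOfProducts>
     <speciesReference species="C" stoichiometry="1"/>
    </listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="10"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="vout" reversible="false">
    <listOfReactants>
     <speciesReference species="C" stoichiometry="1"/>
    </listOfReactants>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="10"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', path)
  path
}
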