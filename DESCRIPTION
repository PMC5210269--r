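Package: minsubnet
Title: Minimum Metabolic Subnetworks by Mixed-Integer Linear Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces genome-scale metabolic network models to minimum
    subnetworks, i.e. subnetworks with the fewest active reactions that
    still retain user-specified protected metabolites, protected reactions,
    linear flux functionalities (such as fraction-of-optimum growth under
    different conditions) and a minimum number of degrees of freedom. The
    reduction is formulated as a mixed-integer linear program with binary
    reaction-activity variables; all alternative minimum subnetworks can be
    enumerated with integer-cut constraints, and the number of binary
    variables can be reduced by grouping partially coupled reactions into
    flux-coupling classes. Includes SBML and BiGG-style JSON import/export,
    removal of dead-end metabolites and blocked reactions, flux variability
    analysis, reaction essentiality screens, and cross-subnetwork
    co-occurrence reports. Linear and mixed-integer programs are solved
    with the HiGHS solver through a bundled Python bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.9) with numpy and scipy on the PATH
Config/testthat/edition: 3
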