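test_that("a protected reaction forces itself active in MinNW-0", {
  # a single exchange reaction (no internal metabolite rows)
  S <- matrix(numeric(0), nrow = 0, ncol = 1,
              dimnames = list(NULL, "only"))
  net <- metabolic_network(S, lower = 0, upper = 10)
  sc <- reduction_scenario(net, protected_reactions = "only")
  sol <- solve_milp(build_minnw0(net, sc))
  expect_identical(sol$active, "only")
  expect_identical(sol$n_active, 1L)
  expect_gte(sol$witness_fluxes[["0"]][["only"]], sc$delta)
})

test_that("protected metabolites need a row only when unprotected by a reaction", {
  toy <- make_branch_toy()
  net <- toy$network
  # B is touched by the protected export: no protected_met row emitted
  sc1 <- reduction_scenario(net, protected_reactions = "ex",
                            protected_metabolites = "B")
  enc1 <- encode(build_minnw(net, sc1))
  expect_false("protected_met" %in% enc1$names)
  # with no protected reaction the row must appear, and suffices to keep B
  sc2 <- reduction_scenario(net, protected_metabolites = "B")
  enc2 <- encode(build_minnw(net, sc2))
  expect_true("protected_met" %in% enc2$names)
  sol <- solve_milp(build_minnw(net, sc2))
  touching_B <- c("r1", "r3", "ex")
  expect_true(any(touching_B %in% sol$active))
})

test_that("the branch fixture has a unique optimum avoiding the detour", {
  toy <- make_branch_toy()
  sol <- solve_milp(build_minnw(toy$network,
                                resolve_scenario(toy$network, toy$scenario)))
  expect_identical(sol$active, c("ex", "r1", "up"))
  expect_identical(sol$n_active, 3L)
})

test_that("removing the direct branch forces the longer pathway", {
  toy <- make_branch_toy()
  net <- remove_reactions(toy$network, "r1")
  sc <- reduction_scenario(net, protected_reactions = "ex")
  sol <- solve_milp(build_minnw(net, sc))
  expect_identical(sol$n_active, 4L)
})

test_that("bigM and indicator encodings yield the same optima", {
  fixtures <- list(make_branch_toy(), make_dual_condition_toy(),
                   make_parallel_paths_toy(3))
  for (fx in fixtures) {
    prob <- build_minnw(fx$network, resolve_scenario(fx$network, fx$scenario))
    sM <- solve_milp(prob, mode = "bigM")
    sI <- solve_milp(prob, mode = "indicator")
    expect_identical(sM$n_active, sI$n_active)
    expect_equal(sM$objective, sI$objective, tolerance = 1e-6)
  }
})

test_that("indicator encoding demands finite bounds, suggesting bigM", {
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", c("in", "out")))
  net <- metabolic_network(S, lower = c(0, 0), upper = c(Inf, 10))
  sc <- reduction_scenario(net, protected_reactions = "out")
  expect_error(encode(build_minnw(net, sc), mode = "indicator"),
               "finite.*bigM")
  # the bigM encoding of the same problem solves fine
  sol <- solve_milp(build_minnw(net, sc), mode = "bigM")
  expect_identical(sol$n_active, 2L)
})

test_that("solutions carry delta-consistent witnesses", {
  toy <- make_dual_condition_toy()
  sc <- resolve_scenario(toy$network, toy$scenario)
  sol <- solve_milp(build_minnw(toy$network, sc))
  eps <- 1e-6
  for (w in sol$witness_fluxes) {
    # steady state
    expect_lt(max(abs(as.numeric(toy$network$S %*% w))), eps)
    # inactive reactions carry no flux; active ones are active in some copy
    inactive <- setdiff(toy$network$reaction_ids, sol$active)
    expect_true(all(abs(w[inactive]) <= eps))
  }
  act_flux <- sapply(sol$active, function(r) {
    max(sapply(sol$witness_fluxes, function(w) abs(w[[r]])))
  })
  expect_true(all(act_flux >= sc$delta - eps))
})

test_that("optima are monotone in the requirements", {
  toy <- make_dual_condition_toy()
  net <- toy$network
  sc <- resolve_scenario(net, toy$scenario)
  base <- solve_milp(build_minnw(net, sc))$n_active
  # adding a protected reaction never decreases the optimum
  sc_plus <- reduction_scenario(net,
                                protected_reactions = c("bio", "byp"),
                                functionalities = sc$functionalities)
  expect_gte(solve_milp(build_minnw(net, sc_plus))$n_active, base)
  # removing a functionality never increases it
  sc_minus <- reduction_scenario(net, protected_reactions = "bio",
                                 functionalities = sc$functionalities[1])
  expect_lte(solve_milp(build_minnw(net, sc_minus))$n_active, base)
})

test_that("minNW and minNW_rep agree, with active sets unions of classes", {
  fixtures <- list(make_branch_toy(), make_dual_condition_toy(),
                   make_parallel_paths_toy(3))
  for (fx in fixtures) {
    net <- fx$network
    sc <- resolve_scenario(net, fx$scenario)
    part <- partial_coupling_classes(net)
    s1 <- solve_milp(build_minnw(net, sc))
    s2 <- solve_milp(build_minnw_rep(net, sc, part))
    expect_identical(s1$n_active, s2$n_active)
    expect_equal(s2$objective, s2$n_active)
    # both active sets are unions of coupling classes
    for (sol in list(s1, s2)) {
      touched <- unique(part$class_of[sol$active])
      expanded <- sort(names(part$class_of)[part$class_of %in% touched])
      expect_identical(sort(sol$active), expanded)
    }
  }
})

test_that("a singleton partition reduces minNW_rep to minNW", {
  toy <- make_branch_toy()
  net <- toy$network
  sc <- resolve_scenario(net, toy$scenario)
  singleton <- structure(list(
    classes = as.list(net$reaction_ids),
    representative = net$reaction_ids,
    class_size = rep(1L, n_reactions(net)),
    class_of = stats::setNames(seq_len(n_reactions(net)),
                               net$reaction_ids)),
    class = "coupling_partition")
  s1 <- solve_milp(build_minnw(net, sc))
  s2 <- solve_milp(build_minnw_rep(net, sc, singleton))
  expect_identical(s1$n_active, s2$n_active)
  expect_identical(s1$active, s2$active)
})

test_that("partition/network mismatch is rejected", {
  toy <- make_branch_toy()
  other <- make_chain_net()
  part <- partial_coupling_classes(other)
  expect_error(build_minnw_rep(toy$network,
                               resolve_scenario(toy$network, toy$scenario),
                               part),
               "does not match")
})

test_that("infeasible requirements raise a structured condition", {
  # protecting a reaction while a functionality pins it to zero
  net <- make_chain_net()
  f <- linear_functionality("off", rows = list(
    list(coefs = c(conv = 1), rel = "==", rhs = 0)))
  sc <- reduction_scenario(net, protected_reactions = "conv",
                           functionalities = list(f))
  # in MinNW-0 the single copy must satisfy both: impossible
  expect_error(solve_milp(build_minnw0(net, sc)),
               class = "minsubnet_infeasible")
  # minNW keeps them on separate copies: feasible
  sol <- solve_milp(build_minnw(net, sc))
  expect_identical(sol$n_active, 3L)
})

test_that("LP-format export lists objective, rows and binaries", {
  toy <- make_branch_toy()
  enc <- encode(build_minnw(toy$network,
                            resolve_scenario(toy$network, toy$scenario)))
  path <- withr::local_tempfile(fileext = ".lp")
  export_lp(enc, path)
  txt <- readLines(path)
  expect_true(any(grepl("^Minimize", txt)))
  expect_true(any(grepl("steady_state", txt)))
  expect_true(any(grepl("protected_rxn", txt)))
  expect_true(any(grepl("^Binaries", txt)))
})
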