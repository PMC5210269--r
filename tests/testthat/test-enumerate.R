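test_that("degrees of freedom equal nullspace dimension", {
  # one exchange chain -> A -> : 2 reactions, 1 metabolite, dof 1
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", c("in", "out")))
  net <- metabolic_network(S, lower = c(0, 0), upper = c(10, 10))
  expect_identical(degrees_of_freedom(net, c("in", "out")), 1L)

  # two independent chains: block diagonal, dof 2
  S2 <- matrix(0, 2, 4, dimnames = list(c("A", "B"),
                                        c("inA", "outA", "inB", "outB")))
  S2["A", c("inA", "outA")] <- c(1, -1)
  S2["B", c("inB", "outB")] <- c(1, -1)
  net2 <- metabolic_network(S2, lower = rep(0, 4), upper = rep(10, 4))
  expect_identical(degrees_of_freedom(net2, colnames(S2)), 2L)

  # random fixtures: QR rank agrees with an SVD-based nullity
  for (seed in c(3, 8, 21)) {
    net3 <- random_feasible_network(8, 12, rev_fraction = 0.3, seed = seed)
    active <- net3$reaction_ids
    Ssub <- as.matrix(net3$S)
    svd_rank <- sum(svd(Ssub)$d > 1e-9)
    expect_identical(degrees_of_freedom(net3, active),
                     as.integer(length(active) - svd_rank))
  }
  expect_error(degrees_of_freedom(net, character()), "non-empty")
})

test_that("an exclusion cut removes exactly the excluded pattern", {
  pp <- make_parallel_paths_toy(2)
  net <- pp$network
  sc <- resolve_scenario(net, pp$scenario)
  prob <- build_minnw(net, sc)
  s1 <- solve_milp(prob)
  expect_identical(s1$n_active, 3L)
  prob2 <- add_exclusion_constraint(prob, s1)
  expect_length(prob2$cuts, 1)
  s2 <- solve_milp(prob2)
  # the other parallel path, same size, different set
  expect_identical(s2$n_active, 3L)
  expect_false(identical(s2$active, s1$active))
  prob3 <- add_exclusion_constraint(prob2, s2)
  expect_length(prob3$cuts, 2)
  s3 <- solve_milp(prob3)
  # both paths exhausted: optimum must grow
  expect_gt(s3$n_active, 3L)
})

test_that("cuts are rejected outside their binary index space", {
  toy <- make_branch_toy()
  net <- toy$network
  sc <- resolve_scenario(net, toy$scenario)
  sol <- solve_milp(build_minnw(net, sc))
  other <- make_chain_net()
  prob_other <- build_minnw(other,
                            reduction_scenario(other,
                                               protected_reactions = "out"))
  expect_error(add_exclusion_constraint(prob_other, sol),
               "binary index space")
})

test_that("the default dof requirement is satisfied on the first solve", {
  toy <- make_branch_toy()
  sol <- minimum_subnetwork(toy$network, toy$scenario)
  expect_identical(sol$n_active, 3L)
  expect_gte(sol$dof, 1L)
  expect_length(attr(sol, "rejected"), 0)
})

test_that("dof filtering rejects small subnetworks until dof is reached", {
  toy <- make_branch_toy()
  sc <- toy$scenario
  sc$dof_min <- 2L
  sol <- minimum_subnetwork(toy$network, sc)
  expect_identical(sol$dof, 2L)
  expect_identical(sol$n_active, 5L)
  # the unique size-3 and size-4 subnetworks both have dof 1
  rejected <- attr(sol, "rejected")
  expect_length(rejected, 2)
  expect_true(all(vapply(rejected, function(s) s$dof, integer(1)) == 1L))
  # matches the brute-force search with the dof side condition
  orc <- brute_force_minimum_subnetworks(toy$network, sc, dof_min = 2)
  expect_identical(orc$minimum_size, 5L)
  expect_identical(sort(sol$active), orc$active_sets[[1]])
})

test_that("an unreachable dof requirement raises a structured error", {
  net <- make_chain_net()
  sc <- reduction_scenario(net, protected_reactions = "out", dof_min = 5)
  expect_error(minimum_subnetwork(net, sc),
               class = "minsubnet_dof_exhausted")
})

test_that("enumeration finds all symmetric optima and proves exhaustion", {
  for (k in c(2, 3, 4)) {
    pp <- make_parallel_paths_toy(k)
    res <- enumerate_minimum_subnetworks(pp$network, pp$scenario)
    expect_length(res$solutions, k)
    expect_true(res$exhausted)
    expect_identical(res$minimum_size, 3L)
    expect_setequal(res$core_reactions, c("up", "ex"))
    expect_identical(length(res$union_reactions), as.integer(k + 2))
    # all found patterns distinct
    expect_identical(anyDuplicated(solution_family(res)), 0L)
  }
})

test_that("a unique optimum yields one solution and exhaustion", {
  toy <- make_branch_toy()
  res <- enumerate_minimum_subnetworks(toy$network, toy$scenario)
  expect_length(res$solutions, 1)
  expect_true(res$exhausted)
})

test_that("max_solutions stops early without claiming exhaustion", {
  pp <- make_parallel_paths_toy(3)
  res <- enumerate_minimum_subnetworks(pp$network, pp$scenario,
                                       max_solutions = 2)
  expect_length(res$solutions, 2)
  expect_false(res$exhausted)
})

test_that("class-space and reaction-space enumeration agree", {
  fixtures <- list(make_branch_toy(), make_dual_condition_toy(),
                   make_parallel_paths_toy(3))
  for (fx in fixtures) {
    part <- partial_coupling_classes(fx$network)
    r1 <- enumerate_minimum_subnetworks(fx$network, fx$scenario)
    r2 <- enumerate_minimum_subnetworks(fx$network, fx$scenario,
                                        use_representatives = TRUE,
                                        partition = part)
    expect_identical(solution_family(r1), solution_family(r2))
    expect_identical(r1$minimum_size, r2$minimum_size)
    expect_true(r2$exhausted)
  }
})

test_that("enumeration results serialize to JSON with provenance", {
  toy <- make_branch_toy()
  res <- enumerate_minimum_subnetworks(toy$network, toy$scenario)
  path <- withr::local_tempfile(fileext = ".json")
  write_enumeration_json(res, path, provenance = list(solver = "highs"))
  doc <- jsonlite::fromJSON(path)
  expect_identical(doc$minimum_size, 3L)
  expect_true(doc$exhausted)
  expect_identical(doc$provenance$solver, "highs")
})
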