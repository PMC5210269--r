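test_that("fva recovers closed-form ranges on a chain", {
  net <- make_chain_net()  # -> A -> B ->, all bounds [0, 10]
  ranges <- fva(net)
  expect_equal(ranges$min, rep(0, 3))
  expect_equal(ranges$max, rep(10, 3))
  # extra row shrinks every range consistently
  ranges2 <- fva(net, extra_rows = list(
    list(coefs = c(out = 1), rel = "<=", rhs = 4)))
  expect_true(all(ranges2$max <= ranges$max + 1e-9))
  expect_equal(ranges2$max, rep(4, 3))
  expect_true(all(ranges2$min <= ranges2$max))
})

test_that("fva matches per-reaction single-objective LPs on a random fixture", {
  net <- preprocess_network(
    random_feasible_network(7, 11, rev_fraction = 0.4, seed = 12))$network
  ranges <- fva(net)
  # independent oracle: maximize/minimize each reaction directly
  for (k in seq_len(n_reactions(net))) {
    p_max <- minsubnet:::flux_lp(net, minsubnet:::unit_obj(net, k), "max")
    p_min <- minsubnet:::flux_lp(net, minsubnet:::unit_obj(net, k), "min")
    sols <- minsubnet:::solve_lp_batch(list(p_max, p_min))
    expect_equal(ranges$max[k], sols[[1]]$objective, tolerance = 1e-7)
    expect_equal(ranges$min[k], sols[[2]]$objective, tolerance = 1e-7)
  }
})

test_that("max_objective respects bounds, stoichiometry and fixing rows", {
  toy <- make_dual_condition_toy()
  net <- toy$network
  # uptake bound 1, respiratory yield 2
  expect_equal(max_objective(net, "bio"), 2, tolerance = 1e-8)
  # without oxygen only fermentation (yield 1) remains
  expect_equal(max_objective(net, "bio", fixing_rows = list(
    list(coefs = c(o2 = 1), rel = "==", rhs = 0))), 1, tolerance = 1e-8)
  # bound-limited case
  net2 <- make_chain_net()
  net2$upper[3] <- 5
  expect_equal(max_objective(net2, "out"), 5, tolerance = 1e-8)
})

test_that("essential reactions are the sole-path ones", {
  toy <- make_dual_condition_toy()
  ess <- essential_reactions(toy$network, "bio", p = 20)
  # uptake and export are unavoidable; everything else has alternatives
  expect_setequal(as.character(ess), c("up", "bio"))
  expect_equal(attr(ess, "optimum"), 2, tolerance = 1e-8)
  # at p = 80, fermentation alone (max 1 < 1.6) no longer suffices:
  # oxygen and respiration become essential too
  ess80 <- essential_reactions(toy$network, "bio", p = 80)
  expect_true(all(c("o2", "resp") %in% ess80))
})

test_that("essentiality is undefined for a dead objective", {
  S <- matrix(c(1, -1, 1), nrow = 1,
              dimnames = list("A", c("in", "out", "dead_in")))
  net <- metabolic_network(S, lower = c(0, 0, 0), upper = c(10, 10, 0))
  expect_error(essential_reactions(net, "dead_in"), "not positive")
})

test_that("comparison reports core, counts and co-occurrence pairs", {
  toy <- make_dual_condition_toy()
  res <- enumerate_minimum_subnetworks(toy$network, toy$scenario)
  cmp <- compare_subnetworks(res)
  # two solutions differing by the swap t1 <-> t2
  expect_identical(ncol(cmp$membership), 2L)
  expect_setequal(setdiff(cmp$union, cmp$core), c("t1", "t2"))
  expect_identical(
    sort(unname(unlist(cmp$mutually_exclusive[1, ]))), c("t1", "t2"))
  expect_identical(nrow(cmp$always_together), 0L)
  occ <- cmp$occurrence
  expect_identical(occ$count[match(c("t1", "t2"), occ$reaction)], c(1L, 1L))
  expect_true(all(occ$count[occ$is_core] == 2L))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_report(cmp, path)
  df <- read.delim(path)
  expect_identical(nrow(df), length(cmp$union))
})

test_that("a single solution degenerates to core = union and no pairs", {
  toy <- make_branch_toy()
  res <- enumerate_minimum_subnetworks(toy$network, toy$scenario)
  cmp <- compare_subnetworks(res)
  expect_identical(cmp$core, cmp$union)
  expect_identical(nrow(cmp$mutually_exclusive), 0L)
  expect_identical(nrow(cmp$always_together), 0L)
})

test_that("always-together pairs are detected in constructed families", {
  # hand-built enumeration result: {a,x,y}, {a,w,z} twice over -> x,y always
  # together, both non-core; (x,w), (x,z), (y,w), (y,z) mutually exclusive
  mk <- function(active) {
    structure(list(active = sort(active), n_active = length(active),
                   witness_fluxes = list(), dof = 1L),
              class = "subnetwork_solution")
  }
  res <- structure(list(
    solutions = list(mk(c("a", "x", "y")), mk(c("a", "w", "z"))),
    minimum_size = 3L,
    core_reactions = "a",
    union_reactions = sort(c("a", "x", "y", "w", "z")),
    exhausted = TRUE), class = "enumeration_result")
  cmp <- compare_subnetworks(res)
  at <- cmp$always_together
  expect_identical(nrow(at), 2L)
  expect_setequal(paste(at$reaction_a, at$reaction_b),
                  c("x y", "w z"))
  expect_identical(nrow(cmp$mutually_exclusive), 4L)
})
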