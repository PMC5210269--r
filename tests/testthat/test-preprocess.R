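test_that("dead-end detection cascades along unconsumed chains", {
  # A -> B -> C with no export for C: C is a dead end, and removing its
  # producer makes B one too, all the way back up the chain
  S <- matrix(c(1, 0, 0,
                -1, 1, 0,
                0, -1, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("in", "r1", "r2")))
  net <- metabolic_network(S, lower = rep(0, 3), upper = rep(10, 3))
  dead <- find_dead_end_metabolites(net)
  expect_setequal(as.character(dead), c("A", "B", "C"))
  expect_setequal(attr(dead, "reactions"), c("in", "r1", "r2"))

  # balanced network: no dead ends
  chain <- make_chain_net()
  dead2 <- find_dead_end_metabolites(chain)
  expect_length(dead2, 0)
})

test_that("reactions killed by dead ends are a subset of blocked ones", {
  for (seed in c(2, 11, 23)) {
    net <- random_feasible_network(8, 12, rev_fraction = 0.3, seed = seed)
    dead_rxns <- attr(find_dead_end_metabolites(net), "reactions")
    blocked <- find_blocked_reactions(net)
    expect_true(all(dead_rxns %in% blocked))
  }
})

test_that("blocked reactions are exactly those without a cone witness", {
  # a reaction producing a metabolite nothing consumes is blocked
  S <- matrix(c(1, 0, 0,
                -1, 1, 0,
                0, -1, 0,
                0, 1, 0,
                0, 0, 1), nrow = 3, byrow = FALSE,
              dimnames = list(c("A", "B", "D"),
                              c("in", "conv", "out", "toB", "orphan")))
  net <- metabolic_network(S, lower = rep(0, 5), upper = rep(10, 5))
  blocked <- find_blocked_reactions(net)
  expect_true("orphan" %in% blocked)   # D is never consumed
  expect_false("in" %in% blocked)
  # a closed chain with exchanges at both ends has no blocked reactions
  expect_length(find_blocked_reactions(make_chain_net()), 0)
})

test_that("blocked detection is idempotent after removal", {
  for (seed in c(5, 17)) {
    net <- random_feasible_network(8, 12, rev_fraction = 0.4, seed = seed)
    # graft a guaranteed-blocked tail: a reaction feeding an orphan
    # metabolite that only a second, downstream-orphan reaction consumes
    S <- rbind(cbind(as.matrix(net$S), mk = 0, use = 0), Q1 = 0, Q2 = 0)
    S["Q1", "mk"] <- 1
    S["Q1", "use"] <- -1; S["Q2", "use"] <- 1
    aug <- metabolic_network(S, lower = c(net$lower, 0, 0),
                             upper = c(net$upper, 10, 10))
    blocked <- find_blocked_reactions(aug)
    expect_true(all(c("mk", "use") %in% blocked))
    pruned <- remove_reactions(aug, blocked)
    expect_length(find_blocked_reactions(pruned), 0)
  }
})

test_that("blockedness ignores finite bounds (cone semantics)", {
  # clamping a reaction's bounds to [0, 0] does not make it 'blocked'
  # in the structural sense
  net <- make_chain_net()
  net$upper[2] <- 0
  expect_length(find_blocked_reactions(net), 0)
})

test_that("coupling partition matches forced-flux intuition on toys", {
  # unbranched chain: all three reactions in one class
  part <- partial_coupling_classes(make_chain_net())
  expect_length(part$classes, 1)
  expect_setequal(part$classes[[1]], c("in", "conv", "out"))
  expect_true(part$representative[1] %in% part$classes[[1]])

  # two independent parallel chains: two classes
  S <- matrix(0, 2, 4, dimnames = list(c("A", "B"),
                                       c("inA", "outA", "inB", "outB")))
  S["A", "inA"] <- 1; S["A", "outA"] <- -1
  S["B", "inB"] <- 1; S["B", "outB"] <- -1
  net2 <- metabolic_network(S, lower = rep(0, 4), upper = rep(10, 4))
  part2 <- partial_coupling_classes(net2)
  expect_length(part2$classes, 2)
})

test_that("coupling partition equals the definitional pairwise-LP partition", {
  for (seed in c(1, 4, 9, 15)) {
    net <- random_feasible_network(7, 11, rev_fraction = 0.3, seed = seed)
    pruned <- preprocess_network(net)$network
    part <- partial_coupling_classes(pruned)
    expect_identical(
      family_strings(part$classes),
      family_strings(definitional_coupling(pruned)),
      label = paste("seed", seed))
    # partition invariants
    expect_identical(sum(part$class_size), n_reactions(pruned))
    expect_true(all(mapply(function(cl, rep) rep %in% cl,
                           part$classes, part$representative)))
  }
})

test_that("coupling partition is invariant to reaction order", {
  net <- random_feasible_network(7, 11, rev_fraction = 0.3, seed = 4)
  pruned <- preprocess_network(net)$network
  perm <- rev(seq_len(n_reactions(pruned)))
  shuffled <- metabolic_network(pruned$S[, perm],
                                reaction_ids = pruned$reaction_ids[perm],
                                metabolite_ids = pruned$metabolite_ids,
                                lower = pruned$lower[perm],
                                upper = pruned$upper[perm])
  expect_identical(
    family_strings(partial_coupling_classes(pruned)$classes),
    family_strings(partial_coupling_classes(shuffled)$classes))
})

test_that("coupling refuses networks with blocked reactions", {
  S2 <- matrix(c(1, -1, 0, 0, 0, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "D"), c("in", "out", "mk_D")))
  net2 <- metabolic_network(S2, lower = rep(0, 3), upper = rep(10, 3))
  expect_error(partial_coupling_classes(net2), "blocked.*mk_D")
})

test_that("preprocess report lists status per reaction", {
  net <- random_feasible_network(8, 12, rev_fraction = 0.3, seed = 5)
  prep <- preprocess_network(net, coupling = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_preprocess_report(net, prep, path)
  expect_identical(nrow(df), 12L)
  expect_true(all(df$status %in% c("unblocked", "blocked",
                                   "dead_end_removed")))
  expect_identical(sum(df$status == "unblocked"),
                   n_reactions(prep$network))
})
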