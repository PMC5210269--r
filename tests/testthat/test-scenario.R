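test_that("functionality rows are validated and canonicalized", {
  f <- linear_functionality("f", rows = list(
    list(coefs = c(r1 = 1, r2 = -2), rel = "==", rhs = 3)))
  canon <- minsubnet:::canonical_rows(f$rows)
  # an equality becomes two <= rows with mirrored coefficients
  expect_length(canon, 2)
  expect_equal(canon[[1]]$rhs, 3)
  expect_equal(canon[[2]]$rhs, -3)
  expect_equal(canon[[2]]$coefs, -canon[[1]]$coefs)

  expect_error(linear_functionality("f", rows = list(list(rhs = 1))),
               "named 'coefs'")
  expect_error(linear_functionality("f", fraction_of_optimum =
                                      list(reaction = "r", fraction = 1.2)),
               "\\(0, 1\\]")
})

test_that("scenario validation rejects unknown ids and bad constants", {
  net <- make_chain_net()
  expect_error(reduction_scenario(net, protected_reactions = "nope"),
               "unknown protected reaction")
  expect_error(reduction_scenario(net, protected_metabolites = "nope"),
               "unknown metabolite")
  expect_error(reduction_scenario(net, delta = -1), "positive")
  expect_error(reduction_scenario(net, big_M = 2,
                                  functionalities = list()),
               "largest finite bound")
  expect_error(reduction_scenario(net, dof_min = -1), "non-negative")
})

test_that("fraction-of-optimum resolution appends the right rows", {
  toy <- make_dual_condition_toy()
  net <- toy$network
  # max biomass is 2 (uptake 1, respiration yield 2)
  f <- linear_functionality("growth", fraction_of_optimum =
                              list(reaction = "bio", fraction = 0.999))
  fr <- resolve_functionality(net, f)
  expect_true(minsubnet:::is_resolved(fr))
  expect_equal(attr(fr, "optimum"), 2, tolerance = 1e-8)
  last <- fr$rows[[length(fr$rows)]]
  expect_identical(names(last$coefs), "bio")
  expect_identical(last$rel, ">=")
  expect_equal(last$rhs, 0.999 * 2, tolerance = 1e-8)

  # fixing rows are applied while optimizing and retained in the result
  f0 <- linear_functionality("anaerobic growth", fraction_of_optimum =
    list(reaction = "bio", fraction = 0.999,
         fixed = list(list(coefs = c(o2 = 1), rel = "==", rhs = 0))))
  fr0 <- resolve_functionality(net, f0)
  expect_equal(attr(fr0, "optimum"), 1, tolerance = 1e-8)  # fermentation only
  expect_equal(fr0$rows[[length(fr0$rows)]]$rhs, 0.999, tolerance = 1e-8)

  # no fraction-of-optimum: identity
  plain <- linear_functionality("p", rows = list(
    list(coefs = c(bio = 1), rel = ">=", rhs = 1)))
  expect_identical(resolve_functionality(net, plain), plain)
})

test_that("unbounded or infeasible resolution LPs are reported by label", {
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", c("mk", "use")))
  net <- metabolic_network(S, lower = c(0, 0), upper = c(Inf, Inf))
  f <- linear_functionality("runaway", fraction_of_optimum =
                              list(reaction = "use", fraction = 0.5))
  expect_error(resolve_functionality(net, f), "runaway.*unbounded")
})
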