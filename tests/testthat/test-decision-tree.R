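test_that("validation accepts valid trees and names each violated rule", {
  expect_identical(validate_tree(dt_terminal("t", 42)), character(0))

  bad_sum <- dt_chance("x", list(
    dt_branch("a", dt_terminal("t", 1), p = 0.6),
    dt_branch("b", dt_terminal("t", 2), p = 0.6)
  ))
  expect_match(validate_tree(bad_sum), "probabilities sum != 1", all = FALSE)

  neg_p <- dt_chance("x", list(
    dt_branch("a", dt_terminal("t", 1), p = -0.1),
    dt_branch("b", dt_terminal("t", 2), p = 1.1)
  ))
  expect_match(validate_tree(neg_p), "probability out of range", all = FALSE)

  dec_p <- dt_decision("d", list(
    dt_branch("a", dt_terminal("t", 1), p = 0.5),
    dt_branch("b", dt_terminal("t", 2), p = 0.5)
  ))
  expect_match(validate_tree(dec_p), "must not carry probabilities",
               all = FALSE)

  # diagnostics name the offending node
  expect_match(validate_tree(bad_sum), "node 0 \\(x\\)", all = FALSE)
  expect_error(rollback(bad_sum), "invalid decision tree")
})

test_that("rollback handles terminal, chance and decision nodes", {
  expect_equal(rollback(dt_terminal("t", 42))$root_emv, 42)

  coin <- dt_chance("coin", list(
    dt_branch("heads", dt_terminal("h", 10), p = 0.5),
    dt_branch("tails", dt_terminal("t", 30), p = 0.5)
  ))
  expect_equal(rollback(coin)$root_emv, 20)

  dec <- dt_decision("choose", list(
    dt_branch("A", dt_terminal("a", 20)),
    dt_branch("B", dt_terminal("b", 15))
  ))
  r <- rollback(dec)
  expect_equal(r$root_emv, 20)
  expect_equal(unname(r$optimal_choice["0"]), "A")

  # deterministic tie-break: first branch in declaration order wins
  tie <- dt_decision("tie", list(
    dt_branch("first", dt_terminal("a", 7)),
    dt_branch("second", dt_terminal("b", 7))
  ))
  expect_equal(unname(rollback(tie)$optimal_choice["0"]), "first")
})

test_that("tiny probability-sum deviations renormalize; larger ones fail", {
  exact <- dt_chance("sex", list(
    dt_branch("male", dt_terminal("m", 50), p = 0.485 / 1.001),
    dt_branch("female", dt_terminal("f", 100), p = 0.516 / 1.001)
  ))
  expect_silent(r0 <- rollback(exact))

  # deviation of 5e-7 (<= 1e-6): renormalized with a warning
  tiny <- dt_chance("sex", list(
    dt_branch("male", dt_terminal("m", 50), p = 0.485 / 1.001),
    dt_branch("female", dt_terminal("f", 100), p = 0.516 / 1.001 + 5e-7)
  ))
  expect_warning(r1 <- rollback(tiny), "renormalized")
  expect_equal(r1$root_emv, r0$root_emv, tolerance = 1e-6)

  # deviation of 1e-3 (the raw published sex split): a validation error —
  # renormalization of published tables belongs to economic_parameters()
  raw <- dt_chance("sex", list(
    dt_branch("male", dt_terminal("m", 50), p = 0.485),
    dt_branch("female", dt_terminal("f", 100), p = 0.516)
  ))
  expect_match(validate_tree(raw), "probabilities sum != 1", all = FALSE)
  expect_error(rollback(raw), "invalid decision tree")
})

test_that("path enumeration matches expectations and conserves probability", {
  pt <- enumerate_paths(dt_terminal("t", 42))
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$probability, 1)
  expect_equal(pt$payoff, 42)

  two <- dt_chance("toss", list(
    dt_branch("lose", dt_terminal("t0", 0), p = 0.3),
    dt_branch("win", dt_terminal("t1", 100), p = 0.7)
  ))
  pt2 <- enumerate_paths(two)
  expect_equal(nrow(pt2), 2L)
  expect_equal(sum(pt2$probability * pt2$payoff), 70)

  dec <- dt_decision("d", list(dt_branch("A", two),
                               dt_branch("B", dt_terminal("b", 5))))
  expect_error(enumerate_paths(dec), "policy missing decision node")
  expect_error(enumerate_paths(dec, c(`0` = "C")), "unknown branch")
  ptA <- enumerate_paths(dec, c(`0` = "A"))
  expect_equal(sum(ptA$probability), 1, tolerance = 1e-9)
})

test_that("rollback equals path enumeration on random trees (oracle)", {
  set.seed(42)
  for (i in 1:60) {
    tree <- random_tree(max_depth = 5L)
    n_dec <- nrow(decision_nodes(tree))
    r <- rollback(tree)
    if (n_dec <= 6L) {
      # exhaustive policy search: rollback must attain the maximum
      policies <- enumerate_policies(tree)
      vals <- vapply(policies, function(pol) policy_value(tree, pol),
                     numeric(1))
      expect_equal(r$root_emv, max(vals), tolerance = 1e-9)
    }
    # per-policy rollback agrees with enumeration (first-branch policy)
    dn <- decision_nodes(tree)
    pol <- stats::setNames(
      vapply(strsplit(dn$branches, ",", fixed = TRUE), `[[`, character(1), 1),
      dn$id)
    expect_equal(rollback(tree, pol)$root_emv, policy_value(tree, pol),
                 tolerance = 1e-9)
    # probability conservation under that policy
    pt <- enumerate_paths(tree, pol)
    expect_equal(sum(pt$probability), 1, tolerance = 1e-9)
  }
})

test_that("affine payoff shifts move every EMV by the constant", {
  shift_tree <- function(node, c) {
    if (node$kind == "terminal") return(dt_terminal(node$label,
                                                    node$payoff + c))
    node$branches <- lapply(node$branches, function(b) {
      b$child <- shift_tree(b$child, c)
      b
    })
    node
  }
  set.seed(7)
  for (i in 1:10) {
    tree <- random_tree(max_depth = 4L)
    r0 <- rollback(tree)
    r1 <- rollback(shift_tree(tree, 13.5))
    expect_equal(r1$emv_by_node, r0$emv_by_node + 13.5, tolerance = 1e-9)
    expect_identical(r1$optimal_choice, r0$optimal_choice)
  }
})

test_that("one-way sensitivity sweeps span the grid and flag clamping", {
  # constant builder: flat series
  flat <- one_way_sensitivity(function(p) dt_terminal("t", 9),
                              list(x = 2), "x", 0.5, 5)
  expect_true(all(flat$emv_series == 9))

  # payoff = parameter: exact linearity
  lin <- one_way_sensitivity(function(p) dt_terminal("t", p$value),
                             list(value = 100), "value", 0.5, 3)
  expect_equal(lin$grid, c(50, 100, 150))
  expect_equal(lin$emv_series, c(50, 100, 150))

  # zero range: single-point sweep at baseline
  pt <- one_way_sensitivity(function(p) dt_terminal("t", p$value),
                            list(value = 100), "value", 0)
  expect_equal(length(pt$grid), 1L)
  expect_equal(pt$emv_series, pt$baseline_emv)

  # probability clamping keeps grid strictly increasing, flags points
  cl <- one_way_sensitivity(
    function(p) dt_chance("c", list(
      dt_branch("yes", dt_terminal("y", 100), p = min(1, max(0, p$prob))),
      dt_branch("no", dt_terminal("n", 0),
                p = 1 - min(1, max(0, p$prob)))
    )),
    list(prob = 0.863), "prob", 0.5, 11, clamp = c(0, 1))
  expect_true(all(diff(cl$grid) > 0))
  expect_true(any(cl$clamped))
  expect_true(all(cl$effective_grid <= 1))

  expect_error(
    one_way_sensitivity(function(p) dt_terminal("t", 1), list(a = 1),
                        "nope", 0.5),
    "valid names: a")
})

test_that("DOT export produces one graph node per tree node", {
  dot1 <- to_dot(dt_terminal("only", 42))
  expect_match(dot1, "digraph")
  expect_equal(length(gregexpr("shape=", dot1)[[1]]), 1L)

  two <- dt_chance("c", list(
    dt_branch("a", dt_terminal("t1", 1), p = 0.4),
    dt_branch("b", dt_terminal("t2", 2), p = 0.6)
  ))
  dot2 <- to_dot(two)
  expect_equal(length(gregexpr("shape=", dot2)[[1]]), 3L)
  expect_equal(length(gregexpr("->", dot2)[[1]]), 2L)
  # minimal DOT well-formedness: balanced braces, all edges reference
  # declared nodes
  expect_equal(length(gregexpr("\\{", dot2)[[1]]),
               length(gregexpr("\\}", dot2)[[1]]))
  dot3 <- to_dot(calving_decision_tree("primiparous"))
  declared <- regmatches(dot3, gregexpr("n[0-9]+(?= \\[shape)", dot3,
                                        perl = TRUE))[[1]]
  used <- unlist(regmatches(dot3, gregexpr("n[0-9]+(?= ->)|(?<=-> )n[0-9]+",
                                           dot3, perl = TRUE)))
  expect_true(all(used %in% declared))
})

test_that("JSON serialization round-trips trees exactly", {
  set.seed(99)
  for (i in 1:5) {
    tree <- random_tree(max_depth = 4L)
    back <- tree_from_json(tree_to_json(tree))
    expect_equal(back, tree)
    expect_equal(rollback(back)$root_emv, rollback(tree)$root_emv,
                 tolerance = 1e-12)
  }
})
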