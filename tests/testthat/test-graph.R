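# admixture-graph algebra, I/O and the frequency simulator

test_that("leaf edge weights follow the mixing definitions", {
  # pure tree: weight 1 on root-path edges, 0 elsewhere
  g <- null_quartet_graph()
  W <- leaf_edge_weights(g)
  on_path <- g$edges$child %in% c("n1", "n2", "P1")
  expect_equal(unname(W[, "P1"]), as.numeric(on_path))

  # leaf under an admixture node with alpha = 0.25
  ga <- admixture_graph(
    data.frame(parent = c("R", "R", "n1", "n1", "m"),
               child = c("A", "n1", "B", "C", "L"),
               drift = 0.01),
    data.frame(child = "m", parent1 = "n1", parent2 = "R", alpha = 0.25))
  Wa <- leaf_edge_weights(ga)
  ed <- ga$edges
  expect_equal(unname(Wa[ed$type == "admix1", "L"]), 0.25)
  expect_equal(unname(Wa[ed$type == "admix2", "L"]), 0.75)

  # two stacked admixture events (0.5 atop 0.4): path probabilities
  # {0.5*0.4, 0.5*0.6, 0.5} = {0.2, 0.3, 0.5} checked by enumeration
  gs <- admixture_graph(
    data.frame(parent = c("R", "R", "R", "m1", "m2"),
               child = c("A", "B", "C", "mid", "L"),
               drift = 0.01),
    data.frame(child = c("m1", "m2"), parent1 = c("A", "mid"),
               parent2 = c("B", "C"), alpha = c(0.4, 0.5)))
  paths <- enumerate_paths(gs, "L")
  probs <- sort(vapply(paths, `[[`, numeric(1), "prob"))
  expect_equal(probs, c(0.2, 0.3, 0.5))
  Ws <- leaf_edge_weights(gs)
  eds <- gs$edges
  for (i in seq_len(nrow(eds))) {
    brute <- sum(vapply(paths, function(p)
      p$prob * (i %in% p$edges), numeric(1)))
    expect_equal(unname(Ws[i, "L"]), brute)
  }
})

test_that("expected f4 equals the brute-force path-combination oracle", {
  # balanced tree ((A,B),(C,D)): disjoint quartets are 0, the internal
  # edge is recovered exactly
  gt <- admixture_graph(data.frame(
    parent = c("R", "R", "u", "u", "v", "v"),
    child = c("u", "v", "A", "B", "C", "D"),
    drift = c(0.01, 0.02, 0.01, 0.01, 0.01, 0.01)))
  expect_equal(expected_f4(gt, c("A", "B", "C", "D")), 0)
  expect_equal(expected_f4(gt, c("A", "C", "B", "D")), 0.01 + 0.02)

  g <- ratio_graph(0.3)
  for (q in list(c("A", "B", "C", "X"), c("A", "O", "X", "C"),
                 c("X", "B", "C", "O"), c("A", "X", "A", "X"))) {
    expect_equal(expected_f4(g, q), brute_force_f4(g, q), tolerance = 1e-12)
  }
})

test_that("graph expectations obey the f2 decomposition and 0-drift edges", {
  g <- ratio_graph(0.4)
  f2g <- function(x, y) expected_f2(g, x, y)
  expect_equal(expected_f4(g, c("A", "B", "C", "X")),
               (f2g("A", "X") + f2g("B", "C") - f2g("A", "C") -
                  f2g("B", "X")) / 2, tolerance = 1e-12)

  # splitting an edge with a zero-drift pass-through node changes nothing
  ed2 <- g$edges[g$edges$type == "normal", c("parent", "child", "drift")]
  i <- which(ed2$parent == "n2" & ed2$child == "A")
  ed2$child[i] <- "mid0"
  ed2 <- rbind(ed2, data.frame(parent = "mid0", child = "A", drift = 0))
  g2 <- admixture_graph(ed2, g$admix[, c("child", "parent1", "parent2",
                                         "alpha")])
  for (q in list(c("A", "B", "C", "O"), c("A", "O", "X", "C")))
    expect_equal(expected_f4(g2, q), expected_f4(g, q), tolerance = 1e-12)
})

test_that("graph validation rejects cycles, multi-roots and bad alpha", {
  expect_error(admixture_graph(data.frame(
    parent = c("A", "B", "C"), child = c("B", "C", "A"), drift = 0.1)))
  expect_error(admixture_graph(data.frame(
    parent = c("R1", "R2"), child = c("A", "B"), drift = 0.1)),
    "exactly one root")
  expect_error(admixture_graph(
    data.frame(parent = c("R", "R"), child = c("A", "B"), drift = 0.1),
    data.frame(child = "A", parent1 = "R", parent2 = "B", alpha = 1.4)),
    "proportions")
  expect_error(expected_f4(ratio_graph(0.2), c("A", "B", "C", "nope")),
               "unknown leaf")
})

test_that("the DAG text format round-trips", {
  g <- ratio_graph(0.35)
  f <- tempfile(fileext = ".dag")
  write_graph(g, f)
  g2 <- read_graph(f)
  expect_setequal(g2$leaves, g$leaves)
  expect_equal(g2$admix$alpha, 0.35)
  for (q in list(c("A", "B", "C", "O"), c("A", "O", "X", "C")))
    expect_equal(expected_f4(g2, q), expected_f4(g, q))
})

test_that("simulator is deterministic and respects no-drift limits", {
  g <- ratio_graph(0.3)
  s1 <- simulate_frequencies(g, 500, seed = 77, outgroup = "O")
  s2 <- simulate_frequencies(g, 500, seed = 77, outgroup = "O")
  expect_identical(s1$panel$freq, s2$panel$freq)
  expect_true(all(s1$panel$freq >= 0 & s1$panel$freq <= 1))
  expect_false(anyNA(s1$panel$freq))

  # all drift 0: every leaf equals the root frequency at every site
  g0 <- admixture_graph(data.frame(
    parent = c("R", "R", "n", "n"), child = c("A", "n", "B", "C"),
    drift = 0))
  s0 <- simulate_frequencies(g0, 200, seed = 1, ascertain = FALSE)
  expect_equal(s0$panel$freq[, "A"], s0$panel$freq[, "B"])
  expect_equal(s0$panel$freq[, "A"], s0$panel$freq[, "C"])

  # excessive drift names the failing edge
  gbig <- admixture_graph(data.frame(
    parent = c("R", "R"), child = c("A", "B"), drift = c(0.5, 0.01)))
  expect_error(simulate_frequencies(gbig, 10, seed = 1), "R->A")
})

test_that("empirical f2/f4 match graph expectations within Monte Carlo error", {
  g <- ratio_graph(0.3)
  sim <- simulate_frequencies(g, 60000, seed = 19, outgroup = "O",
                              ascertain = FALSE)
  p <- assign_blocks(sim$panel, 50)
  for (q in list(c("A", "B", "A", "B"),     # f2(A,B)
                 c("A", "O", "B", "C"),
                 c("A", "O", "X", "C"))) {
    emp <- f4_stat(p, q)
    expect_lt(abs(emp$estimate - expected_f4(g, q)), 3 * emp$se)
  }
  # f2 along a simple path equals the summed edge drift
  emp_f2 <- f2_stat(p, "A", "B")
  expect_lt(abs(emp_f2$estimate - (0.01 + 0.008 + 0.012)), 3 * emp_f2$se)
})
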