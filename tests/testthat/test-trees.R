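# Robinson-Foulds distances, topology counting, concordance filtering
# and the branch-length mixture test

test_that("rf_distance matches brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(rf_distance(t1, t1), 0)

  # 5-leaf trees sharing no internal bipartition: normalized distance 1
  ta <- ape::read.tree(text = "((A,B),(C,D),E);")
  tb <- ape::read.tree(text = "((A,C),(B,E),D);")
  expect_equal(rf_distance(ta, tb, normalized = TRUE), 1)

  # 6-leaf trees one rearrangement apart: hand-enumerated bipartitions
  u1 <- ape::read.tree(text = "(((A,B),C),(D,E),F);")
  u2 <- ape::read.tree(text = "(((A,C),B),(D,E),F);")
  expect_equal(rf_distance(u1, u2), brute_force_rf(u1, u2))
  expect_equal(rf_distance(u1, u2), 2)

  expect_error(rf_distance(ta, ape::read.tree(text = "((A,B),(C,Z),E);")),
               "leaf set")

  # metric properties on random 8-leaf trees against the oracle
  set.seed(7)
  trees <- lapply(1:6, function(i) ape::rtree(8, tip.label = LETTERS[1:8]))
  for (i in 1:5) for (j in (i + 1):6) {
    dij <- rf_distance(trees[[i]], trees[[j]])
    expect_equal(dij, brute_force_rf(trees[[i]], trees[[j]]))
    expect_equal(dij, rf_distance(trees[[j]], trees[[i]]))  # symmetry
    for (k in seq_len(6)[-c(i, j)])                        # triangle
      expect_lte(dij, rf_distance(trees[[i]], trees[[k]]) +
                        rf_distance(trees[[k]], trees[[j]]))
  }
})

test_that("topology counting classifies, prunes and flags correctly", {
  nwk <- c("((mur,(sic,raf)),bal,out);",   # class 1 (x3)
           "((mur,(sic,raf)),bal,out);",
           "(((mur,sic),raf),bal,out);",   # class 2 (x2)
           "((mur,(sic,raf)),bal,out);",
           "(((mur,sic),raf),bal,out);",
           "(((mur,raf),sic),bal,out);")   # class 3 (x1)
  trees <- lapply(nwk, function(x) ape::read.tree(text = x))
  tc <- topology_counts(trees, c("mur", "sic", "raf"), outgroup = "out")
  expect_equal(sort(unname(tc$proportions), decreasing = TRUE),
               c(0.5, 2 / 6, 1 / 6))
  expect_equal(sum(tc$proportions), 1)

  # all windows one topology
  tc1 <- topology_counts(trees[c(1, 2, 4)], c("mur", "sic", "raf"), "out")
  expect_equal(unname(tc1$proportions), 1)

  # taxa outside the focal set never change the class
  nwk_extra <- "(((mur,(sic,raf)),(bal,x1)),(x2,x3),out);"
  te <- ape::read.tree(text = nwk_extra)
  tc2 <- topology_counts(list(trees[[1]], te), c("mur", "sic", "raf"),
                         "out")
  expect_length(tc2$counts, 1)  # same class for both

  # polytomies count as unresolved; missing focal taxa are excluded
  poly <- ape::read.tree(text = "(mur,sic,raf,out);")
  lost <- ape::read.tree(text = "((mur,sic),bal,out);")
  tc3 <- topology_counts(list(trees[[1]], poly, lost),
                         c("mur", "sic", "raf"), "out")
  expect_equal(tc3$n_unresolved, 1L)
  expect_equal(tc3$n_excluded, 1L)
  expect_equal(sum(tc3$counts), 1)
})

test_that("concordant-window selection keeps exactly the RF-0 trees", {
  cons <- ape::read.tree(text = "(((A,B),C),(D,E));")
  same <- ape::read.tree(text = "((C,(B,A)),(E,D));")  # same topology
  diff1 <- ape::read.tree(text = "(((A,C),B),(D,E));")
  trees <- c(lapply(1:3, function(i) same), lapply(1:7, function(i) diff1))
  sel <- select_concordant_windows(trees, cons)
  expect_equal(sel$ids, 1:3)
  expect_equal(sel$fraction, 0.3)
})

test_that("newick tree sets round-trip through files", {
  trees <- lapply(1:4, function(i) ape::rtree(6))
  f <- tempfile(fileext = ".nwk")
  write_tree_set(trees, f)
  back <- read_tree_set(f)
  expect_length(back, 4)
  expect_equal(rf_distance(back[[2]], trees[[2]]), 0)
})

test_that("the branch-length mixture test separates ILS from admixture", {
  # pure exponential: single model preferred, rate recovered
  s0 <- simulate_triplet_lengths(0, 0, 1, 2000, seed = 41)
  q0 <- quibl_fit(s0$lengths)
  expect_equal(q0$preferred, 1L)
  expect_lt(abs(q0$lambda1 - 1), 0.1)
  expect_gte(q0$loglik_2, q0$loglik_1)  # nesting

  # strong mixture: second model preferred, weight and shift recovered
  s1 <- simulate_triplet_lengths(0.5, 2, 1, 2000, seed = 42)
  q1 <- quibl_fit(s1$lengths)
  expect_equal(q1$preferred, 2L)
  expect_lt(abs(q1$mix[["pi2"]] - 0.5), 0.1)
  expect_lt(abs(q1$shift - 2), 0.3)
  expect_gte(q1$loglik_2, q1$loglik_1)
  expect_true(all(diff(q1$ll_trace) >= -1e-6 * abs(q1$ll_trace[-1])))

  # degenerate constant input: flagged, single model with lambda = 1/c
  qd <- quibl_fit(rep(2.5, 50))
  expect_true(qd$degenerate)
  expect_equal(qd$preferred, 1L)
  expect_equal(qd$lambda1, 1 / 2.5)

  expect_error(quibl_fit(c(rep(1, 20), -0.1)), "positive")
  expect_error(quibl_fit(rep(1, 5)), "at least 10")
})

test_that("simulated triplet lengths match their generative moments", {
  s <- simulate_triplet_lengths(0, 0, 2, 4000, seed = 9)
  expect_lt(abs(mean(s$lengths) - 0.5), 3 * 0.5 / sqrt(4000))
  s1 <- simulate_triplet_lengths(1, 5, 1, 500, seed = 10)
  expect_gte(min(s1$lengths), 5)
  s2a <- simulate_triplet_lengths(0.3, 1, 1, 100, seed = 2)
  s2b <- simulate_triplet_lengths(0.3, 1, 1, 100, seed = 2)
  expect_identical(s2a$lengths, s2b$lengths)
})
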