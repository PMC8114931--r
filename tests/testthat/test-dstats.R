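# Patterson's D, f-statistics and the block jackknife

test_that("site patterns reproduce the fixed ABBA/BABA forms", {
  expect_equal(site_patterns(0, 1, 1, 0), list(abba = 1, baba = 0))
  expect_equal(site_patterns(1, 0, 1, 0), list(abba = 0, baba = 1))
  sp <- site_patterns(0.5, 0.5, 1, 0)
  expect_equal(sp$abba, 0.25)
  expect_equal(sp$abba, sp$baba)  # p1 = p2 forces equality
})

test_that("D matches hand enumeration and count ratios on fixed alleles", {
  # three sites: ABBA, BABA, ABBA -> D = (2 - 1) / 3
  f <- rbind(c(0, 1, 1, 0), c(1, 0, 1, 0), c(0, 1, 1, 0))
  colnames(f) <- c("P1", "P2", "P3", "O")
  d <- d_statistic(toy_panel(f), c("P1", "P2", "P3", "O"))
  expect_equal(d$D, 1 / 3)

  # random fixed-allele panel: frequency form equals integer-count ratio
  set.seed(42)
  ff <- matrix(sample(0:1, 400, replace = TRUE), 100, 4,
               dimnames = list(NULL, c("P1", "P2", "P3", "O")))
  dd <- d_statistic(toy_panel(ff), c("P1", "P2", "P3", "O"))
  is_abba <- ff[, 1] == 0 & ff[, 2] == 1 & ff[, 3] == 1 & ff[, 4] == 0
  is_baba <- ff[, 1] == 1 & ff[, 2] == 0 & ff[, 3] == 1 & ff[, 4] == 0
  expect_identical(dd$D, (sum(is_abba) - sum(is_baba)) /
                           (sum(is_abba) + sum(is_baba)))

  # identical P1 and P2 frequencies: numerator vanishes termwise
  set.seed(1)
  p <- runif(50)
  f0 <- cbind(P1 = p, P2 = p, P3 = runif(50), O = 0)
  expect_equal(d_statistic(toy_panel(f0), c("P1", "P2", "P3", "O"))$D, 0)
})

test_that("block jackknife matches the hand delete-one formula", {
  # zero dispersion: identical blocks
  jk0 <- block_jackknife(c(1, 1, 1), c(4, 4, 4), c(10, 10, 10))
  expect_equal(jk0$se, 0)
  expect_true(is.na(jk0$Z))

  # 3 equal-weight blocks, num/den = (1,4),(2,4),(3,4)
  jk <- block_jackknife(1:3, c(4, 4, 4), c(1, 1, 1))
  expect_equal(jk$estimate, 0.5)
  loo <- c(5 / 8, 4 / 8, 3 / 8)
  se_hand <- sqrt((3 - 1) / 3 * sum((loo - mean(loo))^2))
  expect_equal(jk$se, se_hand)
  expect_equal(jk$Z, 0.5 / se_hand)
})

test_that("the D point estimate is invariant to the blocking", {
  g <- null_quartet_graph()
  sim <- simulate_frequencies(g, 2000, seed = 5, outgroup = "O")
  q <- c("P1", "P2", "P3", "O")
  d10 <- d_statistic(assign_blocks(sim$panel, 10), q)
  d100 <- d_statistic(assign_blocks(sim$panel, 100), q)
  expect_equal(d10$D, d100$D)
  expect_gt(d10$se, 0)
})

test_that("swapping P1/P2 or P3/P4 negates D and f4; both swaps restore", {
  g <- ratio_graph(0.4)
  sim <- simulate_frequencies(g, 3000, seed = 9, outgroup = "O")
  p <- assign_blocks(sim$panel, 20)
  for (q in list(c("A", "B", "C", "O"), c("A", "X", "B", "C"))) {
    d <- d_statistic(p, q)
    d12 <- d_statistic(p, q[c(2, 1, 3, 4)])
    expect_equal(d12$D, -d$D)
    # P3/P4 antisymmetry is an f4 property: D's site weighting
    # p3 (1 - p4) is not symmetric under that swap
    f0 <- f4_stat(p, q)$estimate
    expect_equal(f4_stat(p, q[c(2, 1, 3, 4)])$estimate, -f0)
    expect_equal(f4_stat(p, q[c(1, 2, 4, 3)])$estimate, -f0)
    expect_equal(f4_stat(p, q[c(2, 1, 4, 3)])$estimate, f0)
  }
})

test_that("f4 decomposes into f2 terms and degenerate quartets behave", {
  g <- ratio_graph(0.25)
  sim <- simulate_frequencies(g, 2000, seed = 13, outgroup = "O")
  p <- sim$panel
  q <- c("A", "B", "C", "X")
  f4v <- f4_stat(p, q)$estimate
  f2 <- function(x, y) f2_stat(p, x, y)$estimate
  expect_equal(f4v, (f2("A", "X") + f2("B", "C") -
                       f2("A", "C") - f2("B", "X")) / 2, tolerance = 1e-12)

  # p1 = p2 everywhere -> f4 = 0; ratio of a quartet to itself -> 1
  f <- cbind(P1 = c(0.2, 0.7), P2 = c(0.2, 0.7), P3 = c(1, 0), O = 0)
  expect_equal(f4_stat(toy_panel(f), c("P1", "P2", "P3", "O"))$estimate, 0)
  pb <- assign_blocks(p, 10)
  r <- f4_ratio(pb, c("A", "O", "B", "C"), c("A", "O", "B", "C"))
  expect_equal(r$ratio, 1)
})

test_that("jackknife SE shrinks roughly as 1/sqrt(sites)", {
  g <- null_quartet_graph()
  s1 <- simulate_frequencies(g, 5000, seed = 2, outgroup = "O")
  s2 <- simulate_frequencies(g, 45000, seed = 3, outgroup = "O")
  q <- c("P1", "P2", "P3", "O")
  se1 <- d_statistic(assign_blocks(s1$panel, 25), q)$se
  se2 <- d_statistic(assign_blocks(s2$panel, 25), q)$se
  expect_gt(se1 / se2, 1.8)   # expected 3, generous band
  expect_lt(se1 / se2, 5)
})

test_that("triplet sweep enumerates, orients and flags correctly", {
  g <- ratio_graph(0.3)
  sim <- simulate_frequencies(g, 2000, seed = 4, outgroup = "O")
  p <- assign_blocks(sim$panel, 10)
  tab <- triplet_sweep(p)
  expect_equal(nrow(tab), choose(4, 3))
  # canonical orientation: P3 alphabetically smallest, then P1 < P2
  expect_true(all(tab$P3 < tab$P1 & tab$P1 < tab$P2))
  expect_true(all(tab$O == "O"))
  expect_true(all(tab$z_sig == (abs(tab$Z) > 3.3)))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
})

test_that("missing lineages are skipped per quartet only", {
  f <- rbind(c(0, 1, 1, 0), c(NA, 1, 1, 0), c(1, 0, 1, 0))
  colnames(f) <- c("P1", "P2", "P3", "O")
  d <- d_statistic(toy_panel(f), c("P1", "P2", "P3", "O"))
  expect_equal(d$n_sites, 2L)          # NA site dropped
  expect_equal(d$D, 0)                 # one ABBA, one BABA
  # no informative sites: undefined, flagged, no exception
  f2 <- cbind(P1 = c(0, 0), P2 = c(0, 0), P3 = c(0, 0), O = c(0, 0))
  d2 <- d_statistic(toy_panel(f2), c("P1", "P2", "P3", "O"))
  expect_true(is.na(d2$D))
})
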