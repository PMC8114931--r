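# shared fixtures: toy panels, reference graphs, brute-force oracles

toy_panel <- function(freq, chrom = NULL, pos = NULL, outgroup = NULL,
                      called = NULL) {
  freq <- as.matrix(freq)
  n <- nrow(freq)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n)
  afreq_panel(chrom, pos, freq, called, outgroup = outgroup,
              polarized = TRUE)
}

# 5-leaf graph with X admixed between the B and C branch points; the
# f4-ratio f4(A,O;X,C)/f4(A,O;B,C) equals alpha exactly
ratio_graph <- function(alpha = 0.3) {
  ed <- data.frame(
    parent = c("R", "R", "n1", "n1", "n2", "n2", "b1", "c1", "x0"),
    child  = c("O", "n1", "c1", "n2", "A", "b1", "B", "C", "X"),
    drift  = c(0.02, 0.01, 0.015, 0.02, 0.01, 0.008, 0.012, 0.01, 0.005))
  adm <- data.frame(child = "x0", parent1 = "b1", parent2 = "c1",
                    alpha = alpha)
  admixture_graph(ed, adm)
}

# symmetric quartet tree ((P1,P2),P3),O: E[D(P1,P2,P3,O)] = 0
null_quartet_graph <- function() {
  admixture_graph(data.frame(
    parent = c("R", "R", "n1", "n1", "n2", "n2"),
    child  = c("O", "n1", "P3", "n2", "P1", "P2"),
    drift  = c(0.02, 0.02, 0.02, 0.015, 0.02, 0.02)))
}

# D / f4 quartet set used when fitting 5-leaf graphs: all outgroup
# triplets plus the three ingroup quartets (keeps fits overdetermined)
fit_quartets <- function(ingroup, outgroup) {
  trips <- t(utils::combn(ingroup, 3))
  rows <- cbind(trips[, 2], trips[, 3], trips[, 1], outgroup)
  if (length(ingroup) >= 4) {
    quads <- t(utils::combn(ingroup, 4))
    rows <- rbind(rows,
                  quads[, c(1, 2, 3, 4), drop = FALSE],
                  quads[, c(1, 3, 2, 4), drop = FALSE])
  }
  unname(rows)
}

# nested scenario family on leaves (O, MU, BA, SI, RA): M1 plain tree,
# M2 adds BA-ancestor -> SI, M3 adds MU -> RA, M4 adds SI -> RA (truth)
scenario_family <- function(a1 = 0.25, a2 = 0.2, a3 = 0.2) {
  base <- data.frame(
    parent = c("R", "R", "m0", "mu1", "m0", "t1", "ba1", "t1", "s0",
               "si1", "s0", "ra1"),
    child  = c("O", "m0", "mu1", "MU", "t1", "ba1", "BA", "s0", "si1",
               "sA", "ra1", "rA1"),
    drift  = c(0.02, 0.01, 0.01, 0.015, 0.012, 0.01, 0.015, 0.01, 0.008,
               0.0, 0.012, 0.0))
  # sA and rA1/rA2 are attachment points; the tree-only scenarios collapse
  # them into plain pass-through nodes ending at the leaves
  m1_ed <- rbind(base,
                 data.frame(parent = c("sA", "rA1"), child = c("SI", "RA"),
                            drift = c(0.01, 0.01)))
  M1 <- admixture_graph(m1_ed)
  adm1 <- data.frame(child = "sB", parent1 = "ba1", parent2 = "sA",
                     alpha = a1)
  m2_ed <- rbind(base,
                 data.frame(parent = c("sB", "rA1"), child = c("SI", "RA"),
                            drift = c(0.01, 0.01)))
  M2 <- admixture_graph(m2_ed, adm1)
  adm2 <- rbind(adm1, data.frame(child = "rA2", parent1 = "mu1",
                                 parent2 = "rA1", alpha = a2))
  m3_ed <- rbind(base,
                 data.frame(parent = c("sB", "rA2"), child = c("SI", "RA"),
                            drift = c(0.01, 0.01)))
  M3 <- admixture_graph(m3_ed, adm2)
  adm3 <- rbind(adm2, data.frame(child = "rA3", parent1 = "sA",
                                 parent2 = "rA2", alpha = a3))
  m4_ed <- rbind(base,
                 data.frame(parent = c("sB", "rA3"), child = c("SI", "RA"),
                            drift = c(0.01, 0.01)))
  M4 <- admixture_graph(m4_ed, adm3)
  list(M1 = M1, M2 = M2, M3 = M3, M4 = M4)
}

# ---- brute-force oracles -------------------------------------------------

# enumerate all leaf-to-root paths with their probabilities
enumerate_paths <- function(graph, leaf) {
  ed <- graph$edges
  alpha_of <- function(i) {
    if (ed$type[i] == "normal") return(1)
    a <- graph$admix$alpha[graph$admix$child == ed$child[i]]
    if (ed$type[i] == "admix1") a else 1 - a
  }
  rec <- function(node, prob, edges_used) {
    if (node == graph$root)
      return(list(list(prob = prob, edges = edges_used)))
    up <- which(ed$child == node)
    out <- list()
    for (i in up)
      out <- c(out, rec(ed$parent[i], prob * alpha_of(i),
                        c(edges_used, i)))
    out
  }
  rec(leaf, 1, integer(0))
}

# f4 by exhaustive enumeration over independent path choices
brute_force_f4 <- function(graph, quartet) {
  paths <- lapply(quartet, enumerate_paths, graph = graph)
  d <- graph$edges$drift
  total <- 0
  for (pa in paths[[1]]) for (pb in paths[[2]])
    for (pc in paths[[3]]) for (pd in paths[[4]]) {
      ind <- function(p) as.numeric(seq_along(d) %in% p$edges)
      total <- total + pa$prob * pb$prob * pc$prob * pd$prob *
        sum(d * (ind(pa) - ind(pb)) * (ind(pc) - ind(pd)))
    }
  total
}

# nontrivial bipartitions of an unrooted binary tree as canonical strings
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_below))
  }
  internal <- tree$edge[, 2][tree$edge[, 2] > ntip]
  parts <- character(0)
  for (node in internal) {
    side <- sort(tips_below(node))
    if (length(side) >= 2 && length(side) <= ntip - 2) {
      other <- sort(setdiff(tree$tip.label, side))
      key <- if (paste(side, collapse = ",") <
                 paste(other, collapse = ","))
        paste(side, collapse = ",") else paste(other, collapse = ",")
      parts <- c(parts, key)
    }
  }
  unique(parts)
}

brute_force_rf <- function(t1, t2) {
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# write a small VCF + popmap pair for I/O tests
write_toy_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
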