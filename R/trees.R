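#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the nontrivial bipartition sets of the two
#' (unrooted) topologies; branch lengths are ignored. Normalisation
#' divides by `2 (n - 3)` for `n` shared leaves. Leaf sets must match
#' exactly: no silent pruning.
#'
#' @param tree1,tree2 `phylo` objects with identical leaf sets.
#' @param normalized divide by the maximum possible distance.
#' @return numeric distance.
#' @export
rf_distance <- function(tree1, tree2, normalized = FALSE) {
  if (!setequal(tree1$tip.label, tree2$tip.label))
    stop("trees must share an identical leaf set")
  as.numeric(phangorn::RF.dist(tree1, tree2, normalize = normalized,
                               check.labels = TRUE))
}

# canonical label-sorted newick of an unrooted topology (no branch
# lengths); identical strings <=> identical unrooted topologies
canonical_topology <- function(tree) {
  tree <- ape::unroot(tree)
  anchor <- sort(tree$tip.label)[1]
  tree <- ape::root(tree, outgroup = anchor, resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    parts <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}

#' Count gene-tree topologies across windows
#'
#' Prunes every local tree to the focal taxa (plus outgroup, if given),
#' classifies the resulting unrooted topology, and tallies proportions
#' over classified windows. Trees in which the pruned subtree is not
#' binary count as unresolved; trees missing a focal taxon are excluded
#' from the denominator.
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`).
#' @param focal character vector of focal taxa (>= 3).
#' @param outgroup optional outgroup taxon kept during pruning.
#' @return list with `counts` (named, per canonical topology),
#'   `proportions` (sum to 1 over classified windows), `n_unresolved`,
#'   `n_excluded`, and `class` (per-window topology string, `NA` for
#'   unresolved/excluded).
#' @export
topology_counts <- function(trees, focal, outgroup = NULL) {
  if (length(focal) < 3) stop("need at least 3 focal taxa")
  keep <- unique(c(focal, outgroup))
  cls <- rep(NA_character_, length(trees))
  unresolved <- excluded <- 0L
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!all(keep %in% tr$tip.label)) { excluded <- excluded + 1L; next }
    sub <- ape::keep.tip(tr, keep)
    usub <- ape::unroot(sub)
    if (!ape::is.binary(usub)) { unresolved <- unresolved + 1L; next }
    cls[i] <- canonical_topology(usub)
  }
  counts <- table(cls)
  props <- if (length(counts)) counts / sum(counts) else counts
  list(counts = c(counts), proportions = c(props),
       n_unresolved = unresolved, n_excluded = excluded, class = cls)
}

#' Select windows whose local tree matches the consensus topology
#'
#' @param trees list of `phylo` local trees (window order preserved).
#' @param consensus `phylo` consensus tree on the same leaf set.
#' @return list with `ids` (indices of concordant windows) and `fraction`
#'   retained.
#' @export
select_concordant_windows <- function(trees, consensus) {
  conc <- vapply(seq_along(trees), function(i)
    rf_distance(trees[[i]], consensus) == 0, logical(1))
  list(ids = which(conc), fraction = mean(conc))
}

#' Read / write window-local trees
#'
#' One Newick tree per line; window ids can be carried in a side TSV.
#'
#' @param path file of Newick strings, one per line.
#' @return a `multiPhylo` (list of `phylo`).
#' @export
read_tree_set <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- c(tr)  # single tree -> multiPhylo
  tr
}

#' @rdname read_tree_set
#' @param trees list of `phylo` objects.
#' @export
write_tree_set <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}
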