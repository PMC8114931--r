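#' Admixture graphs
#'
#' An admixture graph is a rooted directed acyclic graph whose edges carry
#' drift lengths (in f2 units) and whose admixture nodes have exactly two
#' parents with a mixing proportion `alpha` attached to the first parent's
#' edge. Leaves map to lineage labels. The graph predicts every f2/f4
#' statistic through edge-overlap path algebra, which is what scenario
#' fitting optimises against.
#'
#' @param edges data.frame with columns `parent`, `child`, `drift`
#'   (drift >= 0) describing single-parent edges.
#' @param admix optional data.frame with columns `child`, `parent1`,
#'   `parent2`, `alpha` and optionally `drift1`, `drift2` (default 0):
#'   each row makes `child` an admixture node receiving a fraction `alpha`
#'   of its ancestry from `parent1` and `1 - alpha` from `parent2`.
#' @return object of class `admixture_graph` with elements `nodes`,
#'   `edges` (all edges, including admixture edges, with columns `parent`,
#'   `child`, `drift`, `type` in normal/admix1/admix2), `admix`, `leaves`,
#'   `root`.
#' @export
admixture_graph <- function(edges, admix = NULL) {
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      drift = as.numeric(edges$drift),
                      type = "normal", stringsAsFactors = FALSE)
  if (!is.null(admix) && nrow(admix)) {
    admix <- data.frame(child = as.character(admix$child),
                        parent1 = as.character(admix$parent1),
                        parent2 = as.character(admix$parent2),
                        alpha = as.numeric(admix$alpha),
                        drift1 = if (is.null(admix$drift1)) 0 else as.numeric(admix$drift1),
                        drift2 = if (is.null(admix$drift2)) 0 else as.numeric(admix$drift2),
                        stringsAsFactors = FALSE)
    if (any(admix$alpha < 0 | admix$alpha > 1))
      stop("admixture proportions must be in [0, 1]")
    edges <- rbind(edges,
                   data.frame(parent = admix$parent1, child = admix$child,
                              drift = admix$drift1, type = "admix1"),
                   data.frame(parent = admix$parent2, child = admix$child,
                              drift = admix$drift2, type = "admix2"))
  } else {
    admix <- data.frame(child = character(), parent1 = character(),
                        parent2 = character(), alpha = numeric(),
                        drift1 = numeric(), drift2 = numeric())
  }
  if (any(edges$drift < 0)) stop("drift lengths must be >= 0")
  nodes <- unique(c(edges$parent, edges$child))
  n_in <- table(factor(edges$child, levels = nodes))
  roots <- nodes[n_in == 0]
  if (length(roots) != 1)
    stop("graph must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  bad <- nodes[n_in > 2 | (n_in == 2 & !nodes %in% admix$child)]
  if (length(bad))
    stop("node(s) with invalid parent count: ", paste(bad, collapse = ", "))
  leaves <- setdiff(nodes, edges$parent)
  g <- structure(list(nodes = nodes, edges = edges, admix = admix,
                      leaves = leaves, root = roots),
                 class = "admixture_graph")
  g$topo <- topo_sort(g)   # errors on cycles
  g
}

topo_sort <- function(g) {
  nodes <- g$nodes
  indeg <- table(factor(g$edges$child, levels = nodes))
  queue <- nodes[indeg == 0]
  out <- character(0)
  indeg <- as.integer(indeg); names(indeg) <- nodes
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    ch <- g$edges$child[g$edges$parent == v]
    for (c_ in ch) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) queue <- c(queue, c_)
    }
  }
  if (length(out) != length(nodes)) stop("graph contains a cycle")
  out
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture_graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges,", nrow(x$admix), "admixture event(s),",
      length(x$leaves), "leaves\n")
  cat("  leaves:", paste(x$leaves, collapse = ", "), "\n")
  invisible(x)
}

#' Per-leaf edge traversal probabilities
#'
#' For every leaf i and edge e, the probability `w_i(e)` that a lineage
#' sampled at leaf i traverses e on its way to the root, multiplying
#' `alpha` / `1 - alpha` at each admixture node passed through.
#'
#' @param graph an [admixture_graph()].
#' @param leaves which leaves to compute (default all).
#' @return numeric matrix, edges x leaves (edge order as in
#'   `graph$edges`).
#' @export
leaf_edge_weights <- function(graph, leaves = graph$leaves) {
  bad <- setdiff(leaves, graph$leaves)
  if (length(bad)) stop("not leaves of the graph: ", paste(bad, collapse = ", "))
  ed <- graph$edges
  # mixing multiplier of each edge at its child end
  mult <- rep(1, nrow(ed))
  if (nrow(graph$admix)) {
    a <- graph$admix$alpha[match(ed$child, graph$admix$child)]
    mult[ed$type == "admix1"] <- a[ed$type == "admix1"]
    mult[ed$type == "admix2"] <- 1 - a[ed$type == "admix2"]
  }
  rev_topo <- rev(graph$topo)
  W <- matrix(0, nrow(ed), length(leaves),
              dimnames = list(NULL, leaves))
  for (j in seq_along(leaves)) {
    nw <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
    nw[leaves[j]] <- 1
    for (v in rev_topo) {
      ei <- which(ed$parent == v)
      if (length(ei)) nw[v] <- nw[v] + sum(W[ei, j])
      up <- which(ed$child == v)
      if (length(up)) W[up, j] <- nw[v] * mult[up]
    }
  }
  W
}

#' Expected f4 statistic under an admixture graph
#'
#' `F4(A, B; C, D) = sum_e d_e (w_A(e) - w_B(e)) (w_C(e) - w_D(e))`.
#'
#' @param graph an [admixture_graph()].
#' @param quartet character vector `(A, B, C, D)` of leaf labels.
#' @param W optional precomputed [leaf_edge_weights()] matrix.
#' @return numeric scalar.
#' @export
expected_f4 <- function(graph, quartet, W = NULL) {
  miss <- setdiff(quartet, graph$leaves)
  if (length(miss)) stop("unknown leaf/leaves: ", paste(miss, collapse = ", "))
  if (is.null(W)) W <- leaf_edge_weights(graph, unique(quartet))
  d <- graph$edges$drift
  sum(d * (W[, quartet[1]] - W[, quartet[2]]) *
        (W[, quartet[3]] - W[, quartet[4]]))
}

#' @rdname expected_f4
#' @param x,y leaf labels.
#' @export
expected_f2 <- function(graph, x, y, W = NULL) {
  expected_f4(graph, c(x, y, x, y), W)
}

#' Expected statistic vector for a set of quartets
#'
#' For `statistic = "D"` the quartets are read as `(P1, P2, P3, O)` and
#' the model value is the expected ABBA-BABA numerator direction,
#' `F4(P2, P1; P3, O)`; the observed D's quartet-specific denominator is
#' absorbed by a free scale parameter during fitting. For `"f4"` the
#' quartets are used as given.
#'
#' @param graph an [admixture_graph()].
#' @param quartets matrix with 4 columns (or list of 4-vectors).
#' @param statistic `"D"` or `"f4"`.
#' @return numeric vector of model-expected statistics.
#' @export
expected_stat_vector <- function(graph, quartets, statistic = c("D", "f4")) {
  statistic <- match.arg(statistic)
  if (is.list(quartets)) quartets <- do.call(rbind, quartets)
  W <- leaf_edge_weights(graph)
  vapply(seq_len(nrow(quartets)), function(i) {
    q <- quartets[i, ]
    if (statistic == "D") q <- q[c(2, 1, 3, 4)]
    expected_f4(graph, q, W)
  }, numeric(1))
}

#' Read / write the plain-text DAG exchange format
#'
#' One line per edge: `parent child drift`, and one line per admixture
#' node: `admix child parent1 parent2 alpha`. Blank lines and `#` comments
#' are ignored.
#'
#' @param path file path.
#' @return an [admixture_graph()].
#' @export
read_graph <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  tk <- strsplit(ln, "[ \t]+")
  is_adm <- vapply(tk, function(x) x[1] == "admix", logical(1))
  ed <- do.call(rbind, lapply(tk[!is_adm], function(x) {
    if (length(x) != 3) stop("bad edge line: ", paste(x, collapse = " "))
    data.frame(parent = x[1], child = x[2], drift = as.numeric(x[3]))
  }))
  adm <- NULL
  if (any(is_adm))
    adm <- do.call(rbind, lapply(tk[is_adm], function(x) {
      if (length(x) < 5) stop("bad admix line: ", paste(x, collapse = " "))
      data.frame(child = x[2], parent1 = x[3], parent2 = x[4],
                 alpha = as.numeric(x[5]),
                 drift1 = if (length(x) >= 6) as.numeric(x[6]) else 0,
                 drift2 = if (length(x) >= 7) as.numeric(x[7]) else 0)
    }))
  admixture_graph(ed, adm)
}

#' @rdname read_graph
#' @param graph an [admixture_graph()].
#' @export
write_graph <- function(graph, path) {
  ed <- graph$edges[graph$edges$type == "normal", ]
  lines <- sprintf("%s %s %.10g", ed$parent, ed$child, ed$drift)
  if (nrow(graph$admix)) {
    a <- graph$admix
    lines <- c(lines, sprintf("admix %s %s %s %.10g %.10g %.10g",
                              a$child, a$parent1, a$parent2, a$alpha,
                              a$drift1, a$drift2))
  }
  writeLines(lines, path)
  invisible(path)
}

# replace drift / alpha values (used by the optimizer); drift is a vector
# over all edges in graph$edges order, alpha over graph$admix rows.
set_graph_params <- function(graph, drift = NULL, alpha = NULL) {
  if (!is.null(drift)) graph$edges$drift <- drift
  if (!is.null(alpha) && nrow(graph$admix)) {
    graph$admix$alpha <- alpha
  }
  graph
}
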