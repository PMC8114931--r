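#' Fit an admixture-graph scenario to observed D / f4 statistics
#'
#' Minimises the Mahalanobis cost
#' `(F - f)' S^{-1} (F - f)` over the graph's drift lengths and admixture
#' proportions, where `f` is the observed statistic vector with jackknife
#' covariance `S` and `F` the graph-expected vector. Optimisation uses
#' Nelder-Mead with multiple jittered restarts; drift lengths are kept
#' nonnegative through a softplus transform and admixture proportions in
#' `[0, 1]` through a logistic transform. When the observed statistics are
#' D values, the expected f4 numerator is divided by each quartet's
#' observed per-site ABBA+BABA rate (a data-derived constant carried in
#' the [f4_vector()]), and one free positive scale parameter absorbs
#' remaining panel-level factors such as SNV ascertainment.
#'
#' Edges whose overlap coefficient is zero for every fitted quartet (in
#' particular the two edges above the root) are not identifiable from
#' f4-type statistics and are frozen at their input values.
#'
#' @param graph an [admixture_graph()] giving the scenario topology
#'   (its drift/alpha values seed one restart).
#' @param observed an [f4_vector()].
#' @param restarts number of jittered Nelder-Mead restarts (default 50).
#' @param seed integer seed for restart jitter.
#' @param use_scale fit a free positive scale on the expected vector;
#'   default `TRUE` for D statistics, `FALSE` for f4.
#' @param maxit Nelder-Mead evaluation cap per restart (default 20000).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param ridge ridge term added to `S` before inversion (default 1e-8).
#' @param init optional named list with `drift` (named
#'   `"parent->child"`), `alpha` (named by admixture child) and `scale`
#'   used to seed the first restart (warm start).
#' @param scenario_id label carried into the result.
#' @return object of class `scenario_fit`: list with `scenario_id`,
#'   `graph` (fitted parameters substituted), `fitted_drift`,
#'   `fitted_alpha`, `scale`, `minimal_error`, `n_restarts`, `converged`,
#'   `frozen_edges`, `n_admix`.
#' @export
fit_scenario <- function(graph, observed, restarts = 50, seed = 1,
                         use_scale = NULL, maxit = 20000, reltol = 1e-12,
                         ridge = 1e-8, init = NULL, scenario_id = "scenario") {
  stopifnot(inherits(observed, "f4_vector"))
  if (is.null(use_scale)) use_scale <- observed$statistic_kind == "D"
  f_obs <- observed$f
  k <- length(f_obs)
  if (k < 1) stop("need at least one observed quartet")
  S <- observed$S + diag(ridge, k)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("covariance not invertible; using pseudo-inverse")
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })

  quartets <- observed$quartets
  if (observed$statistic_kind == "D")
    quartets <- quartets[, c(2, 1, 3, 4), drop = FALSE]
  # expected D = expected f4 numerator / observed per-site ABBA+BABA rate;
  # the free scale then only absorbs panel-level factors (ascertainment)
  den_rate <- if (!is.null(observed$den_rate)) observed$den_rate
              else rep(1, k)

  ed <- graph$edges
  n_edge <- nrow(ed)
  n_adm <- nrow(graph$admix)

  # identifiability: an edge is fitted only if its overlap coefficient is
  # nonzero for at least one quartet under at least one alpha setting
  coef_max <- rep(0, n_edge)
  probe <- list(graph$admix$alpha, rep(0.5, n_adm), rep(0.23, n_adm),
                rep(0.81, n_adm))
  for (al in probe[seq_len(if (n_adm) 4 else 1)]) {
    gtry <- set_graph_params(graph, alpha = al)
    W <- leaf_edge_weights(gtry)
    for (i in seq_len(nrow(quartets))) {
      q <- quartets[i, ]
      co <- (W[, q[1]] - W[, q[2]]) * (W[, q[3]] - W[, q[4]])
      coef_max <- pmax(coef_max, abs(co))
    }
  }
  free_edge <- which(coef_max > 1e-12)
  frozen_edge <- setdiff(seq_len(n_edge), free_edge)
  edge_names <- paste0(ed$parent, "->", ed$child)

  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

  n_par <- length(free_edge) + n_adm + as.integer(use_scale)
  unpack <- function(par) {
    drift <- ed$drift
    if (length(free_edge))
      drift[free_edge] <- softplus(par[seq_along(free_edge)])
    alpha <- if (n_adm) stats::plogis(par[length(free_edge) + seq_len(n_adm)])
             else numeric(0)
    scale <- if (use_scale) softplus(par[n_par]) else 1
    list(drift = drift, alpha = alpha, scale = scale)
  }
  cost_fn <- function(par) {
    p <- unpack(par)
    g2 <- set_graph_params(graph, drift = p$drift, alpha = p$alpha)
    W <- leaf_edge_weights(g2)
    Fv <- vapply(seq_len(nrow(quartets)), function(i) {
      q <- quartets[i, ]
      sum(p$drift * (W[, q[1]] - W[, q[2]]) * (W[, q[3]] - W[, q[4]]))
    }, numeric(1)) / den_rate * p$scale
    r <- Fv - f_obs
    drop(t(r) %*% Sinv %*% r)
  }

  # starting points: graph's own values first (or warm start), then jitter
  base_par <- c(softplus_inv(pmax(ed$drift[free_edge], 1e-6)),
                if (n_adm) stats::qlogis(pmin(pmax(graph$admix$alpha, 0.02),
                                              0.98)),
                if (use_scale) softplus_inv(1))
  if (!is.null(init)) {
    if (!is.null(init$drift)) {
      m <- match(edge_names[free_edge], names(init$drift))
      hit <- !is.na(m)
      base_par[seq_along(free_edge)][hit] <-
        softplus_inv(pmax(init$drift[m[hit]], 1e-6))
    }
    if (!is.null(init$alpha) && n_adm) {
      m <- match(graph$admix$child, names(init$alpha))
      hit <- !is.na(m)
      base_par[length(free_edge) + which(hit)] <-
        stats::qlogis(pmin(pmax(init$alpha[m[hit]], 0.02), 0.98))
    }
    if (!is.null(init$scale) && use_scale)
      base_par[n_par] <- softplus_inv(max(init$scale, 1e-6))
  }

  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  best <- NULL
  any_finite <- FALSE
  for (r in seq_len(max(restarts, 1))) {
    par0 <- if (r == 1) base_par else base_par + stats::rnorm(n_par, 0, 1.5)
    if (!is.finite(cost_fn(par0))) next
    any_finite <- TRUE
    o <- stats::optim(par0, cost_fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!any_finite) stop("cost non-finite at every starting point")
  # polish: restart the simplex from the incumbent
  o <- stats::optim(best$par, cost_fn, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
  if (o$value < best$value) best <- o

  p <- unpack(best$par)
  g_fit <- set_graph_params(graph, drift = p$drift, alpha = p$alpha)
  structure(list(
    scenario_id = scenario_id,
    graph = g_fit,
    fitted_drift = stats::setNames(p$drift, edge_names),
    fitted_alpha = if (n_adm) stats::setNames(p$alpha, graph$admix$child)
                   else stats::setNames(numeric(0), character(0)),
    scale = p$scale,
    minimal_error = best$value,
    n_restarts = restarts,
    converged = best$convergence == 0,
    frozen_edges = edge_names[frozen_edge],
    n_admix = n_adm), class = "scenario_fit")
}

#' @export
print.scenario_fit <- function(x, ...) {
  cat(sprintf("scenario_fit '%s': minimal error %.6g (%d admixture events%s)\n",
              x$scenario_id, x$minimal_error, x$n_admix,
              if (x$converged) "" else "; NOT converged"))
  if (length(x$fitted_alpha))
    cat("  alpha:", paste(sprintf("%s=%.3f", names(x$fitted_alpha),
                                  x$fitted_alpha), collapse = ", "), "\n")
  invisible(x)
}

#' Fit and rank competing reticulation scenarios
#'
#' Fits every scenario to the same observed vector with an identical
#' restart budget and returns fits sorted by ascending minimal error;
#' ties (errors within `tie_tol`, absolute plus relative) are broken in
#' favour of fewer admixture events. When `warm_start` is `TRUE`, each
#' scenario's first restart is seeded with the parameter values fitted
#' for the preceding scenario (matched by edge and node names), which
#' keeps nested scenario sequences monotone.
#'
#' @param graphs named list of [admixture_graph()] scenarios on the same
#'   leaf set.
#' @param observed an [f4_vector()].
#' @param restarts,seed,... passed to [fit_scenario()].
#' @param warm_start seed each fit from the previous scenario's solution.
#' @param tie_tol tolerance for treating two minimal errors as tied.
#' @return list of `scenario_fit`, sorted best first.
#' @export
compare_scenarios <- function(graphs, observed, restarts = 50, seed = 1,
                              warm_start = TRUE, tie_tol = 1e-6, ...) {
  if (is.null(names(graphs)))
    names(graphs) <- paste0("M", seq_along(graphs))
  leaf_sets <- lapply(graphs, function(g) sort(g$leaves))
  if (length(unique(leaf_sets)) != 1)
    stop("all scenarios must share one leaf set")
  fits <- vector("list", length(graphs))
  prev <- NULL
  for (i in seq_along(graphs)) {
    init <- if (warm_start && !is.null(prev))
      list(drift = prev$fitted_drift, alpha = prev$fitted_alpha,
           scale = prev$scale)
    fits[[i]] <- fit_scenario(graphs[[i]], observed, restarts = restarts,
                              seed = seed + i, init = init,
                              scenario_id = names(graphs)[i], ...)
    prev <- fits[[i]]
  }
  err <- vapply(fits, `[[`, numeric(1), "minimal_error")
  nad <- vapply(fits, `[[`, numeric(1), "n_admix")
  ord <- order(err)
  # parsimony tie-break among near-equal errors
  i <- 1
  while (i < length(ord)) {
    j <- i
    while (j < length(ord) &&
           abs(err[ord[j + 1]] - err[ord[i]]) <=
             tie_tol * (1 + min(err[ord[i]], err[ord[j + 1]]))) j <- j + 1
    if (j > i) ord[i:j] <- ord[i:j][order(nad[ord[i:j]], err[ord[i:j]])]
    i <- j + 1
  }
  fits[ord]
}
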