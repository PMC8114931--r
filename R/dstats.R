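#' Per-site ABBA / BABA terms from allele frequencies
#'
#' For derived-allele frequencies (p1, p2, p3, p4) of a quartet
#' (P1, P2, P3, O), the frequency-weighted site-pattern terms are
#' `abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`.
#' Sites where any frequency is missing yield `NA` terms and are skipped
#' downstream (pairwise deletion per quartet).
#'
#' @param p1,p2,p3,p4 numeric vectors of frequencies in `[0, 1]` (or `NA`).
#' @return list with numeric vectors `abba` and `baba`.
#' @export
site_patterns <- function(p1, p2, p3, p4) {
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Weighted block jackknife for a ratio estimator
#'
#' Delete-one-block jackknife for estimators of the form
#' `sum(num) / sum(den)`, with block weights (typically informative-site
#' counts) entering through the weighted-jackknife variance of Busing et
#' al.; with equal weights this reduces to the classic delete-one formula.
#'
#' @param num,den per-block numerator and denominator sums.
#' @param weight per-block weights; default `den`-independent equal weights
#'   are used when `NULL`.
#' @return list with `estimate`, `se`, `Z` (`estimate/se`, `NA` when
#'   `se == 0`), and `n_blocks` actually used.
#' @export
block_jackknife <- function(num, den, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(num))
  use <- weight > 0
  num <- num[use]; den <- den[use]; weight <- weight[use]
  g <- length(num)
  tot_num <- sum(num); tot_den <- sum(den)
  if (g < 2 || tot_den <= 0)
    return(list(estimate = NA_real_, se = NA_real_, Z = NA_real_,
                n_blocks = g))
  est <- tot_num / tot_den
  loo <- (tot_num - num) / (tot_den - den)
  n <- sum(weight)
  h <- n / weight
  tau <- h * est - (h - 1) * loo
  theta_j <- g * est - sum((1 - weight / n) * loo)
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(max(v, 0))
  list(estimate = est, se = se,
       Z = if (se > 0) est / se else NA_real_, n_blocks = g)
}

#' Patterson's D for one quartet
#'
#' `D = sum(abba - baba) / sum(abba + baba)` over informative sites, with
#' a weighted block-jackknife standard error and Z-score. Sites at which
#' any of the four lineages has a missing frequency are skipped for this
#' quartet only.
#'
#' @param panel an [afreq_panel()] with blocks assigned (see
#'   [assign_blocks()]); without blocks only the point estimate is
#'   returned.
#' @param quartet character vector `(P1, P2, P3, O)` of lineage labels.
#' @return object of class `dstat`: list with `quartet`, `D`, `abba_sum`,
#'   `baba_sum`, `se`, `Z`, `p`, `n_sites`, and `per_block` (data.frame of
#'   per-block `num`, `den`, `weight`).
#' @export
d_statistic <- function(panel, quartet) {
  stopifnot(length(quartet) == 4)
  if (anyDuplicated(quartet)) stop("quartet lineages must be distinct")
  miss <- setdiff(quartet, panel$lineages)
  if (length(miss)) stop("unknown lineage(s): ", paste(miss, collapse = ", "))
  f <- panel$freq[, quartet, drop = FALSE]
  sp <- site_patterns(f[, 1], f[, 2], f[, 3], f[, 4])
  ok <- !is.na(sp$abba) & !is.na(sp$baba)
  num <- sp$abba - sp$baba
  den <- sp$abba + sp$baba
  inf <- ok & den > 0
  abba_sum <- sum(sp$abba[ok]); baba_sum <- sum(sp$baba[ok])
  res <- list(quartet = quartet, abba_sum = abba_sum, baba_sum = baba_sum,
              n_sites = sum(inf), per_block = NULL,
              D = NA_real_, se = NA_real_, Z = NA_real_, p = NA_real_)
  if (abba_sum + baba_sum <= 0) {
    class(res) <- "dstat"
    return(res)  # no informative sites: undefined D, flagged via NA
  }
  res$D <- (abba_sum - baba_sum) / (abba_sum + baba_sum)
  if (!is.null(panel$block)) {
    bl <- panel$block[ok]
    pb <- data.frame(
      num = as.vector(rowsum(num[ok], bl)),
      den = as.vector(rowsum(den[ok], bl)),
      weight = as.vector(rowsum(as.numeric(inf[ok]), bl)))
    res$per_block <- pb
    jk <- block_jackknife(pb$num, pb$den, pb$weight)
    res$se <- jk$se; res$Z <- jk$Z
    if (!is.na(jk$Z)) res$p <- 2 * stats::pnorm(-abs(jk$Z))
  }
  class(res) <- "dstat"
  res
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("D(%s, %s; %s | %s) = %s", x$quartet[1], x$quartet[2],
              x$quartet[3], x$quartet[4],
              ifelse(is.na(x$D), "undefined", sprintf("%.4f", x$D))))
  if (!is.na(x$se)) cat(sprintf("  SE = %.4f  Z = %.2f", x$se, x$Z))
  cat(sprintf("  (%d informative sites)\n", x$n_sites))
  invisible(x)
}

#' f2 and f4 statistics
#'
#' `f2(X, Y) = mean((x - y)^2)` and
#' `f4(A, B; C, D) = mean((a - b) * (c - d))` over sites where all named
#' lineages are called, with block-jackknife standard errors when blocks
#' are assigned.
#'
#' @param panel an [afreq_panel()].
#' @param x,y lineage labels.
#' @return list with `estimate`, `se`, `Z`, `n_sites`.
#' @export
f2_stat <- function(panel, x, y) {
  f4_stat(panel, c(x, y, x, y))
}

#' @rdname f2_stat
#' @param quartet character vector `(A, B, C, D)`.
#' @export
f4_stat <- function(panel, quartet) {
  stopifnot(length(quartet) == 4)
  miss <- setdiff(quartet, panel$lineages)
  if (length(miss)) stop("unknown lineage(s): ", paste(miss, collapse = ", "))
  f <- panel$freq[, quartet, drop = FALSE]
  term <- (f[, 1] - f[, 2]) * (f[, 3] - f[, 4])
  ok <- !is.na(term)
  n <- sum(ok)
  if (n == 0) return(list(estimate = NA_real_, se = NA_real_,
                          Z = NA_real_, n_sites = 0L))
  if (is.null(panel$block)) {
    return(list(estimate = mean(term[ok]), se = NA_real_, Z = NA_real_,
                n_sites = n))
  }
  bl <- panel$block[ok]
  num <- as.vector(rowsum(term[ok], bl))
  den <- as.vector(rowsum(rep(1, n), bl))
  jk <- block_jackknife(num, den, den)
  list(estimate = jk$estimate, se = jk$se, Z = jk$Z, n_sites = n)
}

#' f4-ratio estimate of an admixture proportion
#'
#' For a suitably chosen pair of quartets the ratio
#' `f4(numerator) / f4(denominator)` estimates the minority-ancestry
#' fraction alpha of an admixed lineage. The ratio is jackknifed as a
#' whole (delete-one-block ratios of delete-one f4s).
#'
#' @param panel an [afreq_panel()] with blocks assigned.
#' @param num_quartet,den_quartet character vectors `(A, B, C, D)`.
#' @param tol denominators with `|f4| < tol` flag the ratio unstable.
#' @return list with `ratio`, `se`, `f4_num`, `f4_den`, `unstable`.
#' @export
f4_ratio <- function(panel, num_quartet, den_quartet, tol = 1e-9) {
  tn <- f4_terms(panel, num_quartet)
  td <- f4_terms(panel, den_quartet)
  ok <- tn$ok & td$ok
  if (!any(ok)) stop("no sites informative for both quartets")
  f4n <- mean(tn$term[ok]); f4d <- mean(td$term[ok])
  out <- list(ratio = f4n / f4d, se = NA_real_, f4_num = f4n, f4_den = f4d,
              unstable = abs(f4d) < tol)
  if (!is.null(panel$block)) {
    bl <- panel$block[ok]
    sn <- as.vector(rowsum(tn$term[ok], bl))
    sd_ <- as.vector(rowsum(td$term[ok], bl))
    cnt <- as.vector(rowsum(rep(1, sum(ok)), bl))
    loo <- (sum(sn) - sn) / (sum(sd_) - sd_)
    g <- length(loo)
    jk <- block_jackknife_vals(out$ratio, loo, cnt)
    out$se <- jk$se
  }
  out
}

# jackknife SE from an estimate and its delete-one values (weighted)
block_jackknife_vals <- function(est, loo, weight) {
  g <- length(loo)
  n <- sum(weight)
  h <- n / weight
  tau <- h * est - (h - 1) * loo
  theta_j <- g * est - sum((1 - weight / n) * loo)
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(se = sqrt(max(v, 0)))
}

f4_terms <- function(panel, quartet) {
  f <- panel$freq[, quartet, drop = FALSE]
  term <- (f[, 1] - f[, 2]) * (f[, 3] - f[, 4])
  list(term = term, ok = !is.na(term))
}

#' Genome-wide D-statistic sweep over all ingroup triplets
#'
#' Computes D for every unordered triplet of ingroup lineages with a fixed
#' outgroup. Each triplet `{X, Y, Z}` is oriented canonically: P3 is the
#' alphabetically smallest member, and P1 < P2 alphabetically. Two
#' significance flags are reported: a Bonferroni-adjusted flag at family
#' level 0.05 over all triplets, and the fixed-threshold rule `|Z| > 3.3`.
#'
#' @param panel an [afreq_panel()] with blocks assigned.
#' @param outgroup outgroup label; defaults to the panel's.
#' @param z_threshold fixed Z threshold (default 3.3).
#' @param alpha family-wise level for the Bonferroni flag (default 0.05).
#' @return data.frame with columns `P1 P2 P3 O nsites ABBA BABA D SE Z p
#'   bonferroni_sig z_sig`.
#' @export
triplet_sweep <- function(panel, outgroup = panel$outgroup,
                          z_threshold = 3.3, alpha = 0.05) {
  if (is.null(outgroup)) stop("no outgroup given and none set on the panel")
  ingroup <- sort(setdiff(panel$lineages, outgroup))
  if (length(ingroup) < 3) stop("need at least 3 ingroup lineages")
  trips <- utils::combn(ingroup, 3)
  rows <- vector("list", ncol(trips))
  for (i in seq_len(ncol(trips))) {
    tri <- sort(trips[, i])         # tri[1] smallest -> P3
    q <- c(tri[2], tri[3], tri[1], outgroup)
    d <- d_statistic(panel, q)
    rows[[i]] <- data.frame(P1 = q[1], P2 = q[2], P3 = q[3], O = q[4],
                            nsites = d$n_sites, ABBA = d$abba_sum,
                            BABA = d$baba_sum, D = d$D, SE = d$se,
                            Z = d$Z, p = d$p)
  }
  out <- do.call(rbind, rows)
  out$bonferroni_sig <- !is.na(out$p) &
    stats::p.adjust(out$p, method = "bonferroni") < alpha
  out$z_sig <- !is.na(out$Z) & abs(out$Z) > z_threshold
  out
}

#' Observed D / f4 vector with jackknife covariance
#'
#' Bundles the observed statistic for a set of quartets together with the
#' block-jackknife covariance matrix `S` of the vector, as needed by the
#' admixture-graph cost function.
#'
#' @param panel an [afreq_panel()] with blocks assigned.
#' @param quartets list of character 4-vectors, or a 4-column matrix
#'   (one quartet per row).
#' @param statistic `"D"` or `"f4"`.
#' @return object of class `f4_vector`: list with `quartets` (matrix),
#'   `f` (observed values), `S` (covariance), `statistic_kind`.
#' @export
f4_vector <- function(panel, quartets, statistic = c("D", "f4")) {
  statistic <- match.arg(statistic)
  if (is.list(quartets)) quartets <- do.call(rbind, quartets)
  if (is.null(panel$block)) stop("assign jackknife blocks first")
  k <- nrow(quartets)
  g <- max(panel$block)
  est <- numeric(k)
  den_rate <- rep(1, k)   # observed (ABBA+BABA) per informative site
  loo <- matrix(NA_real_, g, k)
  for (i in seq_len(k)) {
    q <- quartets[i, ]
    if (statistic == "D") {
      f <- panel$freq[, q, drop = FALSE]
      sp <- site_patterns(f[, 1], f[, 2], f[, 3], f[, 4])
      num <- sp$abba - sp$baba; den <- sp$abba + sp$baba
    } else {
      t_ <- f4_terms(panel, q)
      num <- t_$term; den <- rep(1, length(num)); den[!t_$ok] <- NA
    }
    ok <- !is.na(num) & !is.na(den)
    bn <- as.vector(rowsum(num[ok], factor(panel$block[ok], levels = 1:g)))
    bd <- as.vector(rowsum(den[ok], factor(panel$block[ok], levels = 1:g)))
    bn[is.na(bn)] <- 0; bd[is.na(bd)] <- 0
    est[i] <- sum(bn) / sum(bd)
    if (statistic == "D") den_rate[i] <- sum(bd) / sum(ok)
    loo[, i] <- (sum(bn) - bn) / (sum(bd) - bd)
  }
  # delete-one covariance (unweighted blocks share a common site grid)
  ctr <- sweep(loo, 2, colMeans(loo))
  S <- (g - 1) / g * crossprod(ctr)
  structure(list(quartets = quartets, f = est, S = S, den_rate = den_rate,
                 statistic_kind = statistic), class = "f4_vector")
}

#' @export
print.f4_vector <- function(x, ...) {
  cat("f4_vector:", length(x$f), x$statistic_kind,
      "statistics with jackknife covariance\n")
  invisible(x)
}
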