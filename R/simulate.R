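#' Simulate allele frequencies drifting down an admixture graph
#'
#' Per-site ancestral frequencies are drawn at the root (default
#' Uniform(0.05, 0.95)) and evolved down the graph. Drift along an edge
#' with length `d_e` (f2 units) uses a Balding-Nichols Beta step whose
#' inbreeding parameter is calibrated as `F_e = d_e / h_parent`, where
#' `h_parent = E[p (1 - p)]` at the parent node is tracked analytically
#' through the graph. This makes the realised f2 contribution of every
#' edge exactly `d_e`, so empirical f2/f4 statistics match
#' [expected_f4()] without any unit conversion. At an admixture node the
#' frequency is `alpha * parent1 + (1 - alpha) * parent2` (after any
#' drift on the admixture edges). Because drift increments are martingale
#' differences, expected f4 values equal the edge-overlap path algebra
#' exactly.
#'
#' Sites monomorphic across all leaves are dropped afterwards when
#' `ascertain = TRUE`, mimicking an SNV panel; the retention fraction is
#' reported in the truth record. Note the ascertained f4 values are
#' inflated by 1 / retention relative to the graph expectation (ratios
#' and fitted proportions are unaffected).
#'
#' @param graph an [admixture_graph()] with true drift lengths and
#'   admixture proportions.
#' @param n_sites number of sites to simulate (before ascertainment).
#' @param seed integer seed; outputs are a pure function of
#'   `(arguments, seed)`.
#' @param root_min,root_max bounds of the uniform root-frequency law.
#' @param drift_model `"beta"` (exact-calibration Balding-Nichols,
#'   default) or `"gaussian"` (truncated normal with the same variance;
#'   approximate near the boundaries).
#' @param ascertain drop sites monomorphic at all leaves (default
#'   `TRUE`).
#' @param outgroup optional leaf to record as the panel outgroup.
#' @param spacing base pairs between successive sites (default 1000).
#' @param chrom chromosome name for the emitted panel.
#' @param called_n nominal called allele copies per lineage and site.
#' @return list with `panel` (an [afreq_panel()]), `truth` (list:
#'   `graph`, `seed`, `retention`, `drift_model`, `het` - the analytic
#'   per-node heterozygosities).
#' @export
simulate_frequencies <- function(graph, n_sites, seed = 1,
                                 root_min = 0.05, root_max = 0.95,
                                 drift_model = c("beta", "gaussian"),
                                 ascertain = TRUE, outgroup = NULL,
                                 spacing = 1000L, chrom = "chr1",
                                 called_n = 20L) {
  drift_model <- match.arg(drift_model)
  stopifnot(n_sites >= 1)
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  mu <- (root_min + root_max) / 2
  m2_root <- (root_max^3 - root_min^3) / (3 * (root_max - root_min))

  ed <- graph$edges
  nodes <- graph$topo
  # second-moment matrix E[p_i p_j], filled in topological order
  M2 <- matrix(NA_real_, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  vals <- matrix(NA_real_, n_sites, length(nodes),
                 dimnames = list(NULL, nodes))
  vals[, graph$root] <- stats::runif(n_sites, root_min, root_max)
  M2[graph$root, graph$root] <- m2_root
  het <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  het[graph$root] <- mu - m2_root

  drift_step <- function(p, F_e) {
    if (F_e == 0) return(p)
    out <- p
    inner <- p > 0 & p < 1
    if (any(inner)) {
      a <- p[inner] * (1 - F_e) / F_e
      b <- (1 - p[inner]) * (1 - F_e) / F_e
      if (drift_model == "beta") {
        out[inner] <- stats::rbeta(sum(inner), a, b)
      } else {
        z <- stats::rnorm(sum(inner), p[inner],
                          sqrt(F_e * p[inner] * (1 - p[inner])))
        out[inner] <- pmin(pmax(z, 0), 1)
      }
    }
    out
  }

  edge_F <- numeric(nrow(ed))
  for (v in nodes[-1]) {
    up <- which(ed$child == v)
    if (length(up) == 1) {
      par <- ed$parent[up]
      h <- het[par]
      F_e <- if (ed$drift[up] == 0) 0 else ed$drift[up] / h
      if (!is.finite(F_e) || F_e >= 1)
        stop("drift on edge ", par, "->", v,
             " implies a Beta shape <= 0 (d_e too large for parent ",
             "heterozygosity ", signif(h, 4), ")")
      edge_F[up] <- F_e
      vals[, v] <- drift_step(vals[, par], F_e)
      M2[v, ] <- M2[par, ]; M2[, v] <- M2[, par]
      M2[v, v] <- (1 - F_e) * M2[par, par] + F_e * mu
      het[v] <- mu - M2[v, v]
    } else {  # admixture node: drift each parent copy, then mix
      a_row <- graph$admix[graph$admix$child == v, ]
      ord <- match(c("admix1", "admix2"), ed$type[up])
      up <- up[ord]
      parents <- ed$parent[up]
      q <- vector("list", 2)
      qm2 <- numeric(2)
      for (k in 1:2) {
        h <- het[parents[k]]
        F_e <- if (ed$drift[up[k]] == 0) 0 else ed$drift[up[k]] / h
        if (!is.finite(F_e) || F_e >= 1)
          stop("drift on admixture edge ", parents[k], "->", v,
               " implies a Beta shape <= 0")
        edge_F[up[k]] <- F_e
        q[[k]] <- drift_step(vals[, parents[k]], F_e)
        qm2[k] <- (1 - F_e) * M2[parents[k], parents[k]] + F_e * mu
      }
      al <- a_row$alpha
      vals[, v] <- al * q[[1]] + (1 - al) * q[[2]]
      cross <- M2[parents[1], parents[2]]
      M2[v, ] <- al * M2[parents[1], ] + (1 - al) * M2[parents[2], ]
      M2[, v] <- M2[v, ]
      M2[v, v] <- al^2 * qm2[1] + (1 - al)^2 * qm2[2] +
        2 * al * (1 - al) * cross
      het[v] <- mu - M2[v, v]
    }
  }

  freq <- vals[, graph$leaves, drop = FALSE]
  keep <- rep(TRUE, n_sites)
  if (ascertain) {
    keep <- !(rowSums(freq > 0) == 0 | rowSums(freq < 1) == 0)
    freq <- freq[keep, , drop = FALSE]
  }
  nkeep <- nrow(freq)
  if (nkeep == 0) stop("no polymorphic sites survived ascertainment")
  pos <- as.integer(which(keep)) * as.integer(spacing)
  called <- matrix(as.integer(called_n), nkeep, ncol(freq),
                   dimnames = dimnames(freq))
  panel <- afreq_panel(rep(chrom, nkeep), pos, freq, called,
                       outgroup = outgroup, polarized = TRUE)
  list(panel = panel,
       truth = list(graph = graph, seed = seed, retention = nkeep / n_sites,
                    drift_model = drift_model, het = het))
}

#' Simulate a chromosome scan panel with a planted introgressed block
#'
#' Simulates frequencies under `graph`, then overwrites the recipient
#' lineage inside the planted interval with the donor's frequencies plus
#' a small amount of drift, producing locally low Dxy(donor, recipient)
#' and high fd. The planted interval is returned as a truth BED record. A
#' zero-length block leaves the panel identical to
#' [simulate_frequencies()] under the same seed.
#'
#' @param graph,n_sites,seed,... as in [simulate_frequencies()].
#' @param block numeric `(start, end)` of the planted interval in base
#'   pairs (0-based half-open).
#' @param donor,recipient leaf labels (must differ).
#' @param block_drift drift (f2 units) between donor and the introgressed
#'   recipient haplotypes (default 0.002).
#' @return list with `panel`, `truth` (adds `block`: data.frame `chrom
#'   start end`, plus `donor`, `recipient`).
#' @export
simulate_scan_panel <- function(graph, n_sites, block, donor, recipient,
                                seed = 1, block_drift = 0.002, ...) {
  if (donor == recipient) stop("donor and recipient must differ")
  stopifnot(all(c(donor, recipient) %in% graph$leaves))
  sim <- simulate_frequencies(graph, n_sites, seed = seed, ...)
  panel <- sim$panel
  inside <- panel$pos > block[1] & panel$pos <= block[2]
  if (any(inside)) {
    old_seed <- local_seed(seed + 1013904223)
    on.exit(restore_seed(old_seed), add = TRUE)
    pdon <- panel$freq[inside, donor]
    h <- mean(pdon * (1 - pdon))
    F_e <- min(if (h > 0) block_drift / h else 0, 0.5)
    pnew <- pdon
    inner <- pdon > 0 & pdon < 1
    if (F_e > 0 && any(inner)) {
      a <- pdon[inner] * (1 - F_e) / F_e
      b <- (1 - pdon[inner]) * (1 - F_e) / F_e
      pnew[inner] <- stats::rbeta(sum(inner), a, b)
    }
    panel$freq[inside, recipient] <- pnew
  }
  truth <- sim$truth
  truth$block <- data.frame(chrom = panel$chrom[1],
                            start = block[1], end = block[2])
  truth$donor <- donor; truth$recipient <- recipient
  list(panel = panel, truth = truth)
}

#' Simulate triplet internal branch lengths from an exponential /
#' shifted-exponential mixture
#'
#' Each draw is `Exp(lam)` with probability `1 - pi2`, otherwise
#' `C + Exp(lam)`.
#'
#' @param pi2 mixture weight of the shifted component, in `[0, 1]`.
#' @param C nonnegative shift.
#' @param lam exponential rate (> 0).
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list with `lengths` and `component` (1 or 2, the truth).
#' @export
simulate_triplet_lengths <- function(pi2, C, lam, n, seed = 1) {
  stopifnot(pi2 >= 0, pi2 <= 1, C >= 0, lam > 0, n >= 1)
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  comp <- stats::rbinom(n, 1, pi2)
  list(lengths = stats::rexp(n, lam) + comp * C, component = comp + 1L)
}

#' Simulate a pair of coding sequences with controlled dN/dS
#'
#' The ancestor is drawn uniformly from sense codons; the descendant is
#' produced by a proposal-acceptance substitution process: single-base
#' proposals arrive as a Poisson process with expectation
#' `3 * n_codons * t`, synonymous changes are accepted with probability
#' 1, nonsynonymous with probability `omega`, and changes creating stop
#' codons are rejected.
#'
#' @param omega relative acceptance rate of nonsynonymous changes (> 0,
#'   or 0 for complete constraint).
#' @param t expected proposals per site (branch-length-like scale, > 0;
#'   `t = 0` returns identical sequences).
#' @param n_codons number of codons.
#' @param seed RNG seed.
#' @return list with `seqA`, `seqB` (character strings) and `truth`
#'   (accepted `n_syn`, `n_nonsyn` event counts).
#' @export
simulate_codon_pair <- function(omega, t, n_codons, seed = 1) {
  stopifnot(omega >= 0, t >= 0, n_codons >= 1)
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  code <- genetic_code()
  sense <- sense_codons()
  anc <- sample(sense, n_codons, replace = TRUE)
  cur <- anc
  n_syn <- n_nonsyn <- 0L
  n_events <- stats::rpois(1, 3 * n_codons * t)
  bases <- c("A", "C", "G", "T")
  if (n_events > 0) {
    site <- sample.int(3L * n_codons, n_events, replace = TRUE)
    for (ev in seq_len(n_events)) {
      ci <- (site[ev] - 1L) %/% 3L + 1L
      pos <- (site[ev] - 1L) %% 3L + 1L
      nt <- strsplit(cur[ci], "")[[1]]
      nt[pos] <- sample(setdiff(bases, nt[pos]), 1)
      cand <- paste(nt, collapse = "")
      if (code[[cand]] == "*") next
      syn <- code[[cand]] == code[[cur[ci]]]
      if (syn || stats::runif(1) < omega) {
        cur[ci] <- cand
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      }
    }
  }
  list(seqA = paste(anc, collapse = ""), seqB = paste(cur, collapse = ""),
       truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn, omega = omega,
                    t = t, seed = seed))
}

#' Write a simulated panel as VCF plus popmap
#'
#' Diploid genotypes are drawn per individual as Binomial(2, p) from the
#' lineage frequency (REF = ancestral `A`, ALT = derived `T`), giving a
#' text VCF that [read_vcf_panel()] can consume; a matching
#' `sample<TAB>lineage` popmap is written alongside.
#'
#' @param panel an [afreq_panel()].
#' @param vcf_path,popmap_path output paths.
#' @param n_ind diploid individuals per lineage (default 5).
#' @param seed RNG seed for genotype sampling.
#' @export
simulate_vcf <- function(panel, vcf_path, popmap_path, n_ind = 5,
                         seed = 1) {
  old_seed <- local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  lg <- panel$lineages
  samples <- unlist(lapply(lg, function(l) paste0(l, "_", seq_len(n_ind))))
  n <- n_sites(panel)
  gtmat <- matrix("./.", n, length(samples))
  gts <- c("0/0", "0/1", "1/1")
  for (j in seq_along(lg)) {
    p <- panel$freq[, lg[j]]
    for (k in seq_len(n_ind)) {
      cnt <- stats::rbinom(n, 2, ifelse(is.na(p), 0, p))
      col <- (j - 1) * n_ind + k
      gtmat[, col] <- ifelse(is.na(p), "./.", gts[cnt + 1])
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos, ".", "A", "T", ".", "PASS", ".",
                "GT", apply(gtmat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf_path)
  writeLines(paste(samples, rep(lg, each = n_ind), sep = "\t"),
             popmap_path)
  invisible(vcf_path)
}
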