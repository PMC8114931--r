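#' Allele-frequency panel
#'
#' An `afreq_panel` holds per-site derived-allele frequencies for a set of
#' lineages (populations), the number of called allele copies behind each
#' frequency, and optional jackknife-block assignments. It is the common
#' input container for D/f4-statistics, window scans and admixture-graph
#' fitting.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, one per site; must be
#'   strictly increasing within each chromosome.
#' @param freq numeric matrix, sites x lineages, derived-allele frequencies
#'   in `[0, 1]`; `NA` marks a lineage with no called copies at a site.
#' @param called integer matrix, sites x lineages, called allele copies per
#'   site and lineage (0 where `freq` is `NA`).
#' @param outgroup optional lineage label used (or usable) for polarization.
#' @param polarized logical; `TRUE` when frequencies are oriented so that
#'   the outgroup carries the ancestral allele.
#'
#' @return An object of class `afreq_panel`: a list with elements `chrom`,
#'   `pos`, `freq`, `called`, `lineages`, `block`, `outgroup`, `polarized`.
#' @export
afreq_panel <- function(chrom, pos, freq, called = NULL, outgroup = NULL,
                        polarized = FALSE) {
  freq <- as.matrix(freq)
  if (is.null(colnames(freq))) stop("freq must have lineage column names")
  n <- nrow(freq)
  if (length(chrom) != n || length(pos) != n)
    stop("chrom/pos length must match nrow(freq)")
  if (is.null(called)) {
    called <- matrix(2L, n, ncol(freq), dimnames = dimnames(freq))
    called[is.na(freq)] <- 0L
  }
  called <- as.matrix(called)
  ok <- is.na(freq) | (freq >= 0 & freq <= 1)
  if (!all(ok)) stop("frequencies must be NA or in [0, 1]")
  if (!is.null(outgroup) && !outgroup %in% colnames(freq))
    stop("outgroup '", outgroup, "' is not a lineage of the panel")
  ord <- order(chrom, pos)
  if (is.unsorted(ord)) {
    chrom <- chrom[ord]; pos <- pos[ord]
    freq <- freq[ord, , drop = FALSE]; called <- called[ord, , drop = FALSE]
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 freq = freq, called = called, lineages = colnames(freq),
                 block = NULL, outgroup = outgroup, polarized = polarized),
            class = "afreq_panel")
}

#' @export
print.afreq_panel <- function(x, ...) {
  cat("afreq_panel:", nrow(x$freq), "sites,", length(x$lineages),
      "lineages,", length(unique(x$chrom)), "chromosome(s)\n")
  cat("  lineages:", paste(utils::head(x$lineages, 8), collapse = ", "),
      if (length(x$lineages) > 8) "..." else "", "\n")
  if (!is.null(x$outgroup)) cat("  outgroup:", x$outgroup,
                                if (x$polarized) "(polarized)" else "", "\n")
  if (!is.null(x$block)) cat("  jackknife blocks:", max(x$block), "\n")
  invisible(x)
}

n_sites <- function(panel) nrow(panel$freq)

#' Read a sample-to-lineage population map
#'
#' @param path TSV with two columns, `sample<TAB>lineage`, no header.
#' @return data.frame with columns `sample`, `lineage`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "lineage"),
                          colClasses = "character")
  if (anyDuplicated(pm$sample))
    stop("popmap assigns a sample to more than one lineage")
  pm
}

#' Read a VCF into an allele-frequency panel
#'
#' Retains biallelic SNVs only, computes per-lineage derived-allele
#' frequencies as derived copies / called copies, and (optionally)
#' polarizes against the outgroup: the allele carried by the outgroup
#' majority is taken as ancestral, and sites where the outgroup is missing
#' or polymorphic are dropped. Sites missing in every lineage are dropped.
#'
#' @param vcf_path path to a VCF 4.x file (only GT is used).
#' @param popmap_path path to a `sample<TAB>lineage` TSV, or a data.frame
#'   as returned by [read_popmap()].
#' @param outgroup lineage label present in the popmap.
#' @param polarize logical; default `TRUE`. When `FALSE` the ALT allele is
#'   counted as derived and no outgroup-based site filtering is applied.
#' @return An [afreq_panel()].
#' @export
read_vcf_panel <- function(vcf_path, popmap_path, outgroup,
                           polarize = TRUE) {
  pm <- if (is.data.frame(popmap_path)) popmap_path else read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("VCF contains no records")
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(pm$sample, samples)
  if (length(unknown))
    stop("popmap sample(s) absent from VCF: ", paste(unknown, collapse = ", "))
  if (!outgroup %in% pm$lineage)
    stop("outgroup lineage '", outgroup, "' not present in popmap")

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bial <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, pm$sample, drop = FALSE]

  keep <- which(bial)
  if (!length(keep)) stop("no biallelic SNVs in VCF")
  gt <- gt[keep, , drop = FALSE]
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])

  # per-sample allele counts from GT strings like 0/1, 1|1, ./.
  alleles <- gsub("[|/]", "", gt)
  alleles[is.na(alleles)] <- ""
  bad <- grepl("[^01.]", alleles)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed GT at VCF record ", keep[i[1]], ", sample ",
         colnames(gt)[i[2]])
  }
  nchar_a <- nchar(alleles)
  n_alt <- nchar_a - nchar(gsub("1", "", alleles))
  n_mis <- nchar_a - nchar(gsub(".", "", alleles, fixed = TRUE))
  n_called <- nchar_a - n_mis
  dim(n_alt) <- dim(n_called) <- dim(gt)

  lineages <- unique(pm$lineage)
  n_site <- nrow(gt)
  freq <- matrix(NA_real_, n_site, length(lineages),
                 dimnames = list(NULL, lineages))
  called <- matrix(0L, n_site, length(lineages),
                   dimnames = list(NULL, lineages))
  for (lg in lineages) {
    cols <- which(pm$lineage == lg)
    cc <- rowSums(n_called[, cols, drop = FALSE])
    aa <- rowSums(n_alt[, cols, drop = FALSE])
    called[, lg] <- as.integer(cc)
    freq[, lg] <- ifelse(cc > 0, aa / cc, NA_real_)
  }

  if (polarize) {
    og <- freq[, outgroup]
    keep2 <- !is.na(og) & (og == 0 | og == 1)
    flip <- keep2 & og == 1
    freq[flip, ] <- 1 - freq[flip, , drop = FALSE]
    freq <- freq[keep2, , drop = FALSE]
    called <- called[keep2, , drop = FALSE]
    chrom <- chrom[keep2]; pos <- pos[keep2]
  }
  some <- rowSums(!is.na(freq)) > 0
  afreq_panel(chrom[some], pos[some], freq[some, , drop = FALSE],
              called[some, , drop = FALSE], outgroup = outgroup,
              polarized = polarize)
}

#' Assign contiguous jackknife blocks by equal site counts
#'
#' Splits the retained sites into `n_blocks` contiguous runs, never letting
#' a block span two chromosomes. Blocks are allotted to chromosomes
#' proportionally to their site counts (largest-remainder rule, at least
#' one block per non-empty chromosome); within a chromosome, block sizes
#' differ by at most one site.
#'
#' @param panel an [afreq_panel()].
#' @param n_blocks integer number of blocks, `>= 2` and `<=` site count.
#' @return The panel with a `block` integer vector (1..n_blocks) attached.
#' @export
assign_blocks <- function(panel, n_blocks = 100L) {
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("jackknife needs at least 2 blocks")
  n <- n_sites(panel)
  if (n_blocks > n) stop("more blocks than retained sites")
  chroms <- unique(panel$chrom)
  cnt <- as.integer(table(factor(panel$chrom, levels = chroms)))
  if (n_blocks < length(chroms))
    stop("need at least one block per chromosome (", length(chroms), ")")
  # largest-remainder allocation, each chromosome >= 1 block, <= its sites
  alloc <- rep(1L, length(chroms))
  left <- n_blocks - sum(alloc)
  if (left > 0) {
    quota <- left * cnt / sum(cnt)
    alloc <- alloc + as.integer(floor(quota))
    rem <- quota - floor(quota)
    extra <- left - sum(floor(quota))
    if (extra > 0) {
      ord <- order(rem, decreasing = TRUE)
      alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
    }
  }
  over <- alloc > cnt
  while (any(over)) {  # cannot give a chromosome more blocks than sites
    spare <- sum(alloc[over] - cnt[over])
    alloc[over] <- cnt[over]
    room <- which(alloc < cnt)
    for (i in room) {
      if (spare == 0) break
      take <- min(spare, cnt[i] - alloc[i])
      alloc[i] <- alloc[i] + take; spare <- spare - take
    }
    over <- alloc > cnt
    if (spare == 0) break
  }
  block <- integer(n)
  b0 <- 0L
  for (ci in seq_along(chroms)) {
    m <- cnt[ci]; k <- alloc[ci]
    sizes <- rep(m %/% k, k) + as.integer(seq_len(k) <= m %% k)
    block[panel$chrom == chroms[ci]] <- b0 + rep(seq_len(k), times = sizes)
    b0 <- b0 + k
  }
  panel$block <- block
  panel
}

#' Build fixed genomic windows over a panel
#'
#' Tiles each chromosome with fixed-width, non-overlapping windows in
#' 0-based half-open coordinates and assigns every site to exactly one
#' window. A window is retained when its SNV missing rate (fraction of
#' member sites at which any lineage frequency is missing) is below
#' `max_missing`.
#'
#' @param panel an [afreq_panel()].
#' @param window_size window width in base pairs.
#' @param max_missing exclusion threshold on the window missing rate;
#'   windows with `missing_rate >= max_missing` are flagged excluded.
#'   Default 0.01.
#' @return A `window_index`: list with `windows` (data.frame `chrom`,
#'   `start`, `end`, `n_sites`, `missing_rate`, `retained`) and
#'   `site_window` (per-site row index into `windows`).
#' @export
build_windows <- function(panel, window_size, max_missing = 0.01) {
  if (window_size <= 0) stop("window_size must be positive")
  w <- as.integer(window_size)
  miss_site <- rowSums(is.na(panel$freq)) > 0
  chroms <- unique(panel$chrom)
  win_list <- list(); site_window <- integer(n_sites(panel)); off <- 0L
  for (ch in chroms) {
    idx <- which(panel$chrom == ch)
    wi <- (panel$pos[idx] - 1L) %/% w      # 0-based window index
    nw <- max(wi) + 1L
    nsit <- tabulate(wi + 1L, nbins = nw)
    nmis <- tabulate((wi + 1L)[miss_site[idx]], nbins = nw)
    mrate <- ifelse(nsit > 0, nmis / nsit, NA_real_)
    win_list[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(nw) - 1L) * w, end = seq_len(nw) * w,
      n_sites = nsit, missing_rate = mrate,
      retained = nsit > 0 & !is.na(mrate) & mrate < max_missing)
    site_window[idx] <- off + wi + 1L
    off <- off + nw
  }
  windows <- do.call(rbind, win_list)
  rownames(windows) <- NULL
  structure(list(windows = windows, site_window = site_window),
            class = "window_index")
}

#' @export
print.window_index <- function(x, ...) {
  cat("window_index:", nrow(x$windows), "windows,",
      sum(x$windows$retained), "retained\n")
  invisible(x)
}

#' Write / read a panel as TSV
#'
#' The TSV has header `chrom pos <lineage1> ... <lineageK>`; frequencies
#' are printed with full precision so a written panel re-reads bit-exactly.
#'
#' @param panel an [afreq_panel()].
#' @param path output path.
#' @param called_path optional companion TSV for called allele copies.
#' @export
write_panel <- function(panel, path, called_path = NULL) {
  df <- data.frame(chrom = panel$chrom, pos = panel$pos)
  fm <- as.data.frame(apply(panel$freq, 2, function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x))))
  names(fm) <- panel$lineages
  utils::write.table(cbind(df, fm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(called_path))
    utils::write.table(cbind(df, as.data.frame(panel$called)), called_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param outgroup,polarized metadata to attach to the re-read panel.
#' @export
read_panel_tsv <- function(path, called_path = NULL, outgroup = NULL,
                           polarized = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  freq <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(freq) <- "double"
  called <- NULL
  if (!is.null(called_path)) {
    cd <- utils::read.table(called_path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    called <- as.matrix(cd[, -(1:2), drop = FALSE])
    storage.mode(called) <- "integer"
  }
  afreq_panel(df$chrom, df$pos, freq, called, outgroup = outgroup,
              polarized = polarized)
}

#' Write a window index (or any interval table) as BED
#'
#' @param x a `window_index` or data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @param retained_only drop excluded windows (default `TRUE`).
#' @export
write_bed <- function(x, path, retained_only = TRUE) {
  df <- if (inherits(x, "window_index")) x$windows else x
  if (retained_only && !is.null(df$retained)) df <- df[df$retained, ]
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Subset a panel to a set of site indices
#' @param panel an [afreq_panel()].
#' @param i integer site indices to keep.
#' @return the subset panel (blocks dropped).
#' @export
subset_sites <- function(panel, i) {
  afreq_panel(panel$chrom[i], panel$pos[i], panel$freq[i, , drop = FALSE],
              panel$called[i, , drop = FALSE], outgroup = panel$outgroup,
              polarized = panel$polarized)
}
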