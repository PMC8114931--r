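# codon machinery for the counting (NG86-style) dN/dS estimator ----------

codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    codon_env$code <- stats::setNames(as.character(gc), names(gc))
  }
  codon_env$code
}

sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

# per-codon expected synonymous site count: over the 9 single-base
# changes, each position contributes (#synonymous)/3; changes to stop
# codons count as nonsynonymous, so S + N = 3 exactly per codon
codon_syn_sites <- function() {
  if (is.null(codon_env$syn_sites)) {
    code <- genetic_code()
    bases <- c("A", "C", "G", "T")
    s <- stats::setNames(numeric(length(sense_codons())), sense_codons())
    for (cd in sense_codons()) {
      aa <- code[[cd]]
      nt <- strsplit(cd, "")[[1]]
      syn <- 0
      for (pos in 1:3) for (b in setdiff(bases, nt[pos])) {
        alt <- nt; alt[pos] <- b
        alt_cd <- paste(alt, collapse = "")
        if (code[[alt_cd]] == aa) syn <- syn + 1 / 3
      }
      s[cd] <- syn
    }
    codon_env$syn_sites <- s
  }
  codon_env$syn_sites
}

# average synonymous / nonsynonymous difference counts between two sense
# codons over all minimal mutational paths, excluding paths through stops
# (falling back to all paths when every path hits a stop)
codon_path_diffs <- function(cd1, cd2) {
  if (cd1 == cd2) return(c(sd = 0, nd = 0))
  code <- genetic_code()
  nt1 <- strsplit(cd1, "")[[1]]; nt2 <- strsplit(cd2, "")[[1]]
  pos <- which(nt1 != nt2)
  paths <- if (length(pos) == 1) list(pos) else
    apply(permutations(length(pos)), 1, function(o) pos[o], simplify = FALSE)
  count_path <- function(ord, allow_stop) {
    cur <- nt1; sd_ <- 0; nd_ <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- nt2[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa2) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd_, nd = nd_)
  }
  res <- Filter(Negate(is.null), lapply(paths, count_path, allow_stop = FALSE))
  if (!length(res))
    res <- lapply(paths, count_path, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Counting-based pairwise dN/dS (NG86)
#'
#' Expected synonymous/nonsynonymous site counts are obtained by
#' enumerating all single-base changes of each codon under the standard
#' genetic code (changes to stop codons count as nonsynonymous, so
#' `S + N = 3 x codons`), averaged over the two sequences. Observed
#' differences at multi-difference codons are averaged over all minimal
#' mutational paths, excluding paths through stop codons. Proportions are
#' corrected with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - 4 p / 3)`; `omega = dN / dS` is `NA` (flagged)
#' when `dS = 0` or a proportion is saturated (`p >= 3/4`).
#'
#' Codon columns containing gaps or ambiguity codes in either sequence
#' are dropped pairwise; an internal stop codon is an error.
#'
#' @param seqA,seqB aligned coding sequences (character strings or
#'   anything `as.character`-coercible), equal length divisible by 3.
#' @param gene_id label carried into the result.
#' @return object of class `omega_result`: list with `gene_id`,
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `n_codons` (used), `n_dropped`, `saturated`.
#' @export
ng86_pairwise <- function(seqA, seqB, gene_id = NA_character_) {
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  if (nchar(a) %% 3 != 0) stop("alignment length must be divisible by 3")
  n_cod <- nchar(a) %/% 3
  starts <- 3 * (seq_len(n_cod) - 1) + 1
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  code <- genetic_code()
  if (any(code[ca] == "*") || any(code[cb] == "*"))
    stop("internal stop codon in coding sequence")
  ss <- codon_syn_sites()
  S <- (sum(ss[ca]) + sum(ss[cb])) / 2
  N <- 3 * length(ca) - S
  sd_ <- nd_ <- 0
  diff <- which(ca != cb)
  for (i in diff) {
    d <- codon_path_diffs(ca[i], cb[i])
    sd_ <- sd_ + d["sd"]; nd_ <- nd_ + d["nd"]
  }
  pS <- if (S > 0) sd_ / S else 0
  pN <- if (N > 0) nd_ / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(gene_id = gene_id, S_sites = S, N_sites = N,
                 Sd = unname(sd_), Nd = unname(nd_), pS = unname(pS),
                 pN = unname(pN), dS = unname(dS), dN = unname(dN),
                 omega = unname(omega), n_codons = length(ca),
                 n_dropped = n_cod - length(ca),
                 saturated = is.na(dS) || is.na(dN)),
            class = "omega_result")
}

#' @export
print.omega_result <- function(x, ...) {
  cat(sprintf(
    "ng86 %s: S=%.2f N=%.2f Sd=%.2f Nd=%.2f dS=%s dN=%s omega=%s\n",
    ifelse(is.na(x$gene_id), "", x$gene_id), x$S_sites, x$N_sites, x$Sd,
    x$Nd, fmt_na(x$dS), fmt_na(x$dN), fmt_na(x$omega)))
  invisible(x)
}

fmt_na <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences.
#' @return named character vector of sequences.
#' @export
read_codon_alignment <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Foreground versus background dN/dS permutation test
#'
#' Compares mean omega between genes from introgressed regions
#' (foreground) and genes consistent with the consensus phylogeny
#' (background) with a label-permutation null. The statistic is
#' `mean(fg) - mean(bg)`; the default alternative is one-sided
#' (foreground greater), and p-values use the add-one convention.
#' Undefined omegas are excluded (their count is reported).
#'
#' @param omega_fg,omega_bg numeric vectors of gene-level omega values.
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"greater"` (fg > bg) or `"two-sided"`.
#' @param exhaustive enumerate all label assignments instead of sampling
#'   (p then includes the identity permutation, without add-one).
#' @param statistic `"mean"` (default) or `"median"`.
#' @return list with `mean_fg`, `mean_bg`, `diff`, `p`, `n_fg`, `n_bg`,
#'   `n_excluded`, `n_perm`.
#' @export
foreground_background_test <- function(omega_fg, omega_bg, n_perm = 1000,
                                       seed = 1,
                                       alternative = c("greater",
                                                       "two-sided"),
                                       exhaustive = FALSE,
                                       statistic = c("mean", "median")) {
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  stat <- if (statistic == "mean") mean else stats::median
  n_excl <- sum(is.na(omega_fg)) + sum(is.na(omega_bg))
  fg <- omega_fg[!is.na(omega_fg)]; bg <- omega_bg[!is.na(omega_bg)]
  if (!length(fg) || !length(bg))
    stop("foreground or background empty after excluding undefined omegas")
  pool <- c(fg, bg)
  nf <- length(fg)
  obs <- stat(fg) - stat(bg)
  score <- function(d) if (alternative == "greater") d else abs(d)
  if (exhaustive) {
    combs <- utils::combn(length(pool), nf)
    null <- apply(combs, 2, function(i) stat(pool[i]) - stat(pool[-i]))
    p <- mean(score(null) >= score(obs))  # identity permutation included
    n_used <- ncol(combs)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    old_seed <- local_seed(seed)
    on.exit(restore_seed(old_seed), add = TRUE)
    null <- replicate(n_perm, {
      i <- sample.int(length(pool), nf)
      stat(pool[i]) - stat(pool[-i])
    })
    p <- (1 + sum(score(null) >= score(obs))) / (1 + n_perm)
    n_used <- n_perm
  }
  list(mean_fg = stat(fg), mean_bg = stat(bg), diff = obs, p = p,
       n_fg = length(fg), n_bg = length(bg), n_excluded = n_excl,
       n_perm = n_used)
}
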