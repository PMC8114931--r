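#' Window statistics: Dxy, fd and nucleotide diversity
#'
#' `window_dxy` is the absolute divergence between two lineages over a set
#' of sites, `mean(pA (1-pB) + pB (1-pA))`. `window_fd` is the
#' admixture-fraction statistic for a quartet `(P1, P2, P3, O)`: the
#' ABBA-BABA numerator divided by the same sum with both P2 and P3
#' replaced per site by the donor proxy PD (whichever of P2/P3 has the
#' larger derived frequency); it is undefined (`NA`) when the numerator is
#' `<= 0`. `window_pi` is the mean per-site nucleotide diversity
#' `2 k (n - k) / (n (n - 1))` with `k` derived copies out of `n` called.
#' All three use variant-only denominators by default; pass `n_bp` to
#' divide the per-window sum by a callable-site count instead.
#'
#' @param pA,pB,p1,p2,p3,pO numeric vectors of per-site derived-allele
#'   frequencies (NA allowed; such sites are skipped).
#' @param n_bp optional per-bp denominator replacing the variant count.
#' @return numeric scalar (`NA` when undefined).
#' @export
window_dxy <- function(pA, pB, n_bp = NULL) {
  ok <- !is.na(pA) & !is.na(pB)
  if (!any(ok)) return(NA_real_)
  s <- sum(pA[ok] * (1 - pB[ok]) + pB[ok] * (1 - pA[ok]))
  s / if (is.null(n_bp)) sum(ok) else n_bp
}

#' @rdname window_dxy
#' @export
window_fd <- function(p1, p2, p3, pO) {
  ok <- !is.na(p1) & !is.na(p2) & !is.na(p3) & !is.na(pO)
  if (!any(ok)) return(NA_real_)
  p1 <- p1[ok]; p2 <- p2[ok]; p3 <- p3[ok]; pO <- pO[ok]
  num <- sum((1 - p1) * p2 * p3 * (1 - pO) - p1 * (1 - p2) * p3 * (1 - pO))
  pd <- pmax(p2, p3)
  den <- sum((1 - p1) * pd * pd * (1 - pO) - p1 * (1 - pd) * pd * (1 - pO))
  if (num <= 0 || den == 0) return(NA_real_)
  num / den
}

#' @rdname window_dxy
#' @param p per-site derived-allele frequencies of the lineage.
#' @param n per-site called allele-copy counts.
#' @export
window_pi <- function(p, n, n_bp = NULL) {
  ok <- !is.na(p) & n >= 2
  if (!any(ok)) return(NA_real_)
  k <- p[ok] * n[ok]
  s <- sum(2 * k * (n[ok] - k) / (n[ok] * (n[ok] - 1)))
  s / if (is.null(n_bp)) sum(ok) else n_bp
}

#' Permutation p-value with the add-one convention
#'
#' `p = (1 + #(null as-or-more extreme)) / (1 + n_null)`; the floor is
#' therefore `1 / (n_null + 1)` and an observation matched by every null
#' draw gives `p = 1`.
#'
#' @param obs observed statistic.
#' @param null numeric vector of null draws (NAs dropped).
#' @param direction `"greater"`, `"less"` or `"two-sided"` (two-sided
#'   compares absolute deviations from the null mean).
#' @return p-value in `(0, 1]`.
#' @export
perm_pvalue <- function(obs, null, direction = c("greater", "less",
                                                 "two-sided")) {
  direction <- match.arg(direction)
  null <- null[!is.na(null)]
  if (!length(null)) return(NA_real_)
  extreme <- switch(direction,
                    greater = sum(null >= obs),
                    less = sum(null <= obs),
                    `two-sided` = {
                      c0 <- mean(null)
                      sum(abs(null - c0) >= abs(obs - c0))
                    })
  (1 + extreme) / (1 + length(null))
}

#' Exhaustive window-label permutation p-value
#'
#' Treats the genome-wide set of window statistics as the exact null for
#' any one window: under label exchange the observed window receives each
#' window's value once, so the p-value is the fraction of windows whose
#' statistic is as or more extreme (the identity permutation is included,
#' giving the `1/n` floor).
#'
#' @param values all window statistics (NAs dropped from the denominator).
#' @param i index of the focal window within `values`.
#' @param direction as in [perm_pvalue()].
#' @return p-value in `(0, 1]`.
#' @export
window_label_pvalue <- function(values, i, direction = c("greater", "less",
                                                         "two-sided")) {
  direction <- match.arg(direction)
  obs <- values[i]
  if (is.na(obs)) return(NA_real_)
  v <- values[!is.na(values)]
  extreme <- switch(direction,
                    greater = sum(v >= obs),
                    less = sum(v <= obs),
                    `two-sided` = {
                      c0 <- mean(v)
                      sum(abs(v - c0) >= abs(obs - c0))
                    })
  extreme / length(v)
}

#' Windowed Dxy / fd / pi introgression scan
#'
#' Computes per-window Dxy between the recipient (P2) and donor (P3)
#' lineages of the quartet, the fd statistic, and nucleotide diversity for
#' P1..P3, with optional permutation p-values against the genome-wide
#' background. The default null resamples, for each window, `n_perm`
#' random same-size site sets from the whole panel (preserving window
#' size); `scheme = "windows"` instead uses the exhaustive window-label
#' null of [window_label_pvalue()]. Introgression support is a low Dxy
#' (`direction = "less"`) together with a high fd (`direction =
#' "greater"`).
#'
#' @param panel a polarized [afreq_panel()].
#' @param windows a `window_index` from [build_windows()].
#' @param quartet character vector `(P1, P2, P3, O)`.
#' @param n_perm permutation count (0 skips the test). Default 1000.
#' @param scheme `"sites"` or `"windows"`.
#' @param seed RNG seed for site resampling.
#' @return data.frame with one row per window: `chrom start end n_sites
#'   retained dxy fd pi_P1 pi_P2 pi_P3 p_dxy p_fd`.
#' @export
scan_windows <- function(panel, windows, quartet, n_perm = 1000,
                         scheme = c("sites", "windows"), seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(length(quartet) == 4)
  miss <- setdiff(quartet, panel$lineages)
  if (length(miss)) stop("unknown lineage(s): ", paste(miss, collapse = ", "))
  wdf <- windows$windows
  sw <- windows$site_window
  fq <- panel$freq[, quartet, drop = FALSE]
  cn <- panel$called[, quartet, drop = FALSE]
  nw <- nrow(wdf)
  dxy <- fd <- rep(NA_real_, nw)
  pim <- matrix(NA_real_, nw, 3,
                dimnames = list(NULL, paste0("pi_", quartet[1:3])))
  for (w in which(wdf$n_sites > 0)) {
    s <- which(sw == w)
    dxy[w] <- window_dxy(fq[s, 2], fq[s, 3])
    fd[w] <- window_fd(fq[s, 1], fq[s, 2], fq[s, 3], fq[s, 4])
    for (j in 1:3) pim[w, j] <- window_pi(fq[s, j], cn[s, j])
  }
  out <- cbind(wdf[, c("chrom", "start", "end", "n_sites", "retained")],
               dxy = dxy, fd = fd, as.data.frame(pim),
               p_dxy = NA_real_, p_fd = NA_real_)
  if (n_perm >= 1) {
    ret <- which(wdf$retained)
    if (scheme == "windows") {
      for (w in ret) {
        out$p_dxy[w] <- window_label_pvalue(dxy[ret], match(w, ret), "less")
        out$p_fd[w] <- window_label_pvalue(fd[ret], match(w, ret), "greater")
      }
    } else {
      old_seed <- local_seed(seed)
      on.exit(restore_seed(old_seed), add = TRUE)
      N <- nrow(fq)
      # per-site terms reused across draws
      t_dxy <- fq[, 2] * (1 - fq[, 3]) + fq[, 3] * (1 - fq[, 2])
      for (w in ret) {
        m <- wdf$n_sites[w]
        nd <- nf <- numeric(n_perm)
        for (b in seq_len(n_perm)) {
          s <- sample.int(N, m)
          nd[b] <- mean(t_dxy[s], na.rm = TRUE)
          num <- sum((fq[s, 2] - fq[s, 1]) * fq[s, 3] * (1 - fq[s, 4]),
                     na.rm = TRUE)
          pd <- pmax(fq[s, 2], fq[s, 3])
          den <- sum((pd - fq[s, 1]) * pd * (1 - fq[s, 4]), na.rm = TRUE)
          nf[b] <- if (den != 0) num / den else NA_real_
        }
        if (!is.na(dxy[w])) out$p_dxy[w] <- perm_pvalue(dxy[w], nd, "less")
        if (!is.na(fd[w])) out$p_fd[w] <- perm_pvalue(fd[w], nf, "greater")
      }
    }
  }
  out
}

#' Detect candidate introgressed blocks from a window scan
#'
#' Flags retained windows with Dxy below a genome-wide quantile and fd
#' above a threshold, then reports maximal runs of at least `min_run`
#' consecutive qualifying windows per chromosome, optionally bridging
#' single-window gaps. Runs are returned ranked by length (longest
#' first).
#'
#' @param scan data.frame from [scan_windows()].
#' @param dxy_quantile genome-wide quantile of Dxy below which a window
#'   qualifies (default 0.25).
#' @param fd_threshold minimum fd for a window to qualify (default: the
#'   genome-wide mean fd over retained windows).
#' @param min_run minimum run length in windows (default 3).
#' @param merge_gaps bridge single-window gaps inside a run (default
#'   `TRUE`).
#' @return data.frame with `chrom start end n_windows rank` (BED-style
#'   0-based half-open intervals); zero rows when nothing qualifies.
#' @export
detect_blocks <- function(scan, dxy_quantile = 0.25, fd_threshold = NULL,
                          min_run = 3, merge_gaps = TRUE) {
  ret <- scan$retained & !is.na(scan$dxy)
  if (!any(ret)) return(empty_blocks())
  thr_dxy <- stats::quantile(scan$dxy[ret], dxy_quantile, na.rm = TRUE,
                             names = FALSE)
  if (is.null(fd_threshold))
    fd_threshold <- mean(scan$fd[ret], na.rm = TRUE)
  pass <- scan$retained & !is.na(scan$dxy) & scan$dxy < thr_dxy &
    !is.na(scan$fd) & scan$fd > fd_threshold
  blocks <- list()
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch)
    p <- pass[idx]
    if (merge_gaps && length(p) > 2) {
      gap <- which(!p[-c(1, length(p))]) + 1L
      bridge <- gap[p[gap - 1L] & p[gap + 1L]]
      p[bridge] <- TRUE
    }
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      i0 <- idx[starts[k]]; i1 <- idx[ends[k]]
      blocks[[length(blocks) + 1L]] <-
        data.frame(chrom = ch, start = scan$start[i0], end = scan$end[i1],
                   n_windows = r$lengths[k])
    }
  }
  if (!length(blocks)) return(empty_blocks())
  out <- do.call(rbind, blocks)
  out <- out[order(-out$n_windows), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

empty_blocks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_windows = integer(), rank = integer())
}
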