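---
title: "Detecting and quantifying introgression with introgressr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying introgression with introgressr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgressr)
```

# Scope and model

`introgressr` implements the statistical machinery used to detect and
quantify gene flow between diverged lineages from genome-wide variant
panels: Patterson's D (ABBA-BABA) and f4-statistics with block-jackknife
inference, admixture-graph fitting by cost minimisation, windowed
Dxy/fd/π scans with permutation nulls, local-tree concordance summaries,
an exponential-mixture test separating introgression from incomplete
lineage sorting (ILS), and a counting dN/dS comparison of introgressed
(foreground) versus tree-concordant (background) genes. Everything can be
exercised end to end on synthetic data generated under known admixture
graphs, so that each estimator is tested against its own generative
truth.

## Allele-frequency panels

The common container is the `afreq_panel`: per-site derived-allele
frequencies per lineage, built from a VCF of biallelic SNVs and a
sample-to-lineage popmap. Polarization (on by default) takes the allele
carried by the outgroup majority as ancestral and drops sites where the
outgroup is missing or polymorphic; D is invariant to joint allele
relabelling, but the windowed fd statistic assumes derived polarity, so
panels feeding scans should stay polarized. Missing data follow pairwise
deletion: a site missing in some lineage is skipped only for quartets
that touch that lineage.

Jackknife blocks are contiguous runs of equal site counts (default 100
blocks), never spanning a chromosome boundary. Equal-count blocks
equalise the information deleted per block; physical-length blocks can be
emulated by subsetting. Fixed windows are 0-based half-open intervals; a
window is kept when its SNV missing rate is below 1% (`max_missing =
0.01`), following the same retention rule used for local-tree windows.

## D, f4 and the block jackknife

For quartet (P1, P2, P3, O) with derived frequencies `p1..p4`,

```
abba = (1 - p1) p2 p3 (1 - p4),  baba = p1 (1 - p2) p3 (1 - p4)
D = sum(abba - baba) / sum(abba + baba)
```

Standard errors come from a weighted delete-one-block jackknife (weights
= per-block informative-site counts, the Busing form, which reduces to
the classic delete-one formula for equal weights), and `Z = D / SE`.
Genome-wide sweeps enumerate all ingroup triplets against a fixed
outgroup in a canonical orientation (P3 the alphabetically smallest
member, then P1 < P2), and report both a Bonferroni-adjusted significance
flag over the whole family at level 0.05 and the fixed `|Z| > 3.3` rule;
the two thresholds are deliberately not reconciled, since 3.3 is not the
Bonferroni cutoff for thousands of triplets.

`f4(A,B;C,D) = mean((a - b)(c - d))`, `f2(x,y) = f4(x,y;x,y)`, and
admixture proportions are estimated by f4-ratios: with a donor-side
reference pair the ratio of two f4 statistics is the minority ancestry
fraction α, jackknifed as a whole.

## Admixture graphs and scenario fitting

An admixture graph is a rooted DAG with drift lengths `d_e` (f2 units) on
edges and a mixing proportion α at each two-parent node. With `w_i(e)`
the probability that a lineage sampled at leaf i traverses edge e on its
way to the root (multiplying α / 1−α at admixture nodes),

```
F4(A,B;C,D) = sum_e d_e (w_A(e) - w_B(e)) (w_C(e) - w_D(e))
```

which the package verifies against brute-force path enumeration.
Scenario fitting minimises the Mahalanobis cost `(F - f)' S^-1 (F - f)`
over all drift lengths and α values with Nelder-Mead (softplus transform
for drift, logistic for α; multi-restart with jittered starts; ridge
`1e-8 I` on `S` before inversion, falling back to a pseudo-inverse). `S`
is the delete-one-block jackknife covariance of the observed vector —
the natural companion of the jackknife Z-scores; no other estimate of
`S` is attempted.

Two fitting modes exist. In f4 mode the model predicts the observed f4
values directly. In D mode each observed D has a quartet-specific
denominator that the graph does not predict; the package divides the
expected f4 numerator by the *observed* per-site ABBA+BABA rate of that
quartet (a data-derived constant), keeping a single free positive scale
to absorb panel-level factors such as SNV ascertainment. A single global
scale alone was tried first and systematically distorted α estimates
(the quartet denominators differ by factors of ~2), which is why the
observed denominator rates are used; with them, α is recovered within
±0.05 at 50 kb-scale panels in the acceptance suite.

Two classes of parameters are not identifiable from f4-type statistics:
the two edges above the root (every quartet's overlap coefficient there
is zero) and, more generally, any edge whose coefficient vanishes for
every fitted quartet. Rather than special-casing the root pair, the
fitter probes the coefficients at several α settings and freezes every
structurally invisible edge at its input value, reporting them in
`frozen_edges`. Unbranched edge chains are likewise only identified
through their sum; fits are still well-defined because the cost is flat
along such directions. Competing scenarios are compared with identical
data and restart budgets, ranked by minimal error with ties broken by
fewer admixture events (parsimony); nested scenario sequences can
warm-start each fit from the previous solution (matched by edge names),
which keeps the minimal errors monotone as true reticulations are added.

## Window scans

Per retained window the scan reports Dxy between recipient and donor
(`mean(pA(1-pB) + pB(1-pA))`), the fd admixture fraction (ABBA-BABA
numerator over the same sum with P2 and P3 replaced per site by whichever
of the two has the larger derived frequency), undefined when the window
numerator is non-positive (a negative-D window carries no meaningful
admixture fraction), and nucleotide diversity `2k(n-k)/(n(n-1))`.
Denominators are variant-only by default — the panel carries only SNVs —
with a per-bp option when a callable-site count is supplied.

Permutation support for "low Dxy and high fd" uses, by default, `n_perm`
random same-size site sets drawn from the whole panel as the null for
each window (preserving window size), with the add-one convention `p =
(1 + #extreme) / (1 + n_perm)`; an exhaustive window-label null is also
available. Candidate introgressed blocks are maximal runs (default at
least 3) of consecutive windows with Dxy below a genome-wide quantile
(default 0.25) and fd above a threshold (default the genome-wide mean
fd), optionally bridging single-window gaps, ranked by run length.

## Local trees and the branch-length mixture test

Robinson-Foulds distances are computed on unrooted topologies with
branch lengths ignored (normalised by `2(n-3)` on request) and leaf-set
mismatches are an error — no silent pruning. Topology counting prunes
each window tree to the focal taxa plus outgroup and tallies canonical
unrooted topologies; polytomic prunings count as unresolved, windows
missing a focal taxon are excluded from the denominator. Concordant
windows are those at RF distance 0 from the consensus.

The mixture test models the internal branch lengths of one triplet
topology across windows either as `Exp(λ)` (pure ILS) or as `π1 Exp(λ) +
π2 (C + Exp(λ))`, whose shifted component captures introgression (or
speciation) adding a fixed length C. The mixture is fitted by EM over
(π2, λ) with C profiled on a 50-point grid spanning `(0, 3·mean]` and
refined locally; the observed-data log-likelihood is monotone across EM
iterations by construction and the single exponential is included as the
π2 = 0 boundary, so the mixture log-likelihood can never fall below the
null's. Models are compared by `BIC = -2 logL + k log(n)` with k = 1
versus 3, preferring the single exponential on ties below 1e-6.
Zero-variance inputs are flagged degenerate and returned as the null
model with λ = 1/c.

## Counting dN/dS

Pairwise dN/dS uses the Nei-Gojobori counting method: per-codon expected
synonymous sites from all nine single-base changes under the standard
code (changes creating stop codons count as nonsynonymous, which makes
`S + N = 3 × codons` exact), observed differences averaged over all
minimal mutational paths that avoid stop codons, Jukes-Cantor correction
`d = -(3/4) log(1 - 4p/3)` (flagged at `p ≥ 3/4`), ω undefined when dS =
0. Codons with gaps or ambiguity codes in either sequence are dropped
pairwise. A maximum-likelihood codon model would give slightly different
absolute ω values; the foreground/background comparison — mean ω of
introgressed-region genes versus tree-concordant genes, label
permutation, one-sided (foreground greater) with the add-one convention
— is estimator-agnostic, and externally computed ω tables can be fed to
`foreground_background_test()` directly.

# The synthetic-data generators

`simulate_frequencies()` draws per-site root frequencies from
Uniform(0.05, 0.95) and evolves them down the graph with Balding-Nichols
Beta steps. The inbreeding coefficient of each edge is calibrated as
`F_e = d_e / h_parent`, with the parent heterozygosity `h = E[p(1-p)]`
tracked exactly through the graph via the full second-moment matrix
(including across admixture nodes). Two properties follow exactly, not
asymptotically: every edge contributes exactly `d_e` to f2 along paths
crossing it, and — because drift increments are martingale differences —
expected f4 values equal the edge-overlap path algebra. This is what
makes parameter-recovery acceptance checks analytic; a request for `d_e ≥
h_parent` is a hard error naming the edge (the Beta shape would be
non-positive). A truncated-Gaussian drift mode with the same variance is
available but is approximate near frequency boundaries and is not the
default. Sites monomorphic across all leaves are dropped afterwards, as
in a real SNV panel; this inflates raw f4 values by 1/retention (ratios
and fitted proportions are unaffected; the truth record reports the
retention fraction).

`simulate_scan_panel()` plants an introgressed block by copying the
donor's frequencies into the recipient inside the interval with a small
amount of extra drift (0.002 f2 units by default), guaranteeing locally
low Dxy(donor, recipient) and high fd. `simulate_triplet_lengths()`
draws from the exponential / shifted-exponential mixture.
`simulate_codon_pair()` evolves a uniform sense-codon ancestor by
Poisson(3·n·t) single-base proposals accepted at relative rate 1
(synonymous) versus ω (nonsynonymous), stops rejected. Because the
estimator's site counts include mutational opportunity toward stops that
the process never realises, ω̂ at generative ω = 1 sits a few percent
below 1 — a known, documented property of this estimator/process pair,
well inside the consistency band checked by the tests.

Every generator is a pure function of its arguments and seed, and
emits the same VCF/TSV/Newick/FASTA/BED dialects the analysis functions
read.

What the generators do *not* emulate: linkage and recombination (sites
are exchangeable given the graph; the block jackknife is exercised, but
its robustness to autocorrelation is not stressed), sequencing error and
genotype uncertainty, gene conversion, and coalescent variance in local
genealogies. Passing tests therefore demonstrate estimator correctness
under the drift model, not robustness to every property of real
resequencing data.

# Problem sizes and numerical choices

The test and acceptance runs use deliberately modest sizes chosen to make
Monte-Carlo bands comfortable: 20-50 thousand sites and 100 jackknife
blocks for D/f4 calibration and recovery; for scans, a 5 Mb chromosome
of 100 windows (50 kb) at one SNV per 250 bp — roughly the SNV density
of vertebrate resequencing panels, and enough that the planted 1 Mb
block's Dxy deficit (~0.07 against a ~0.3 heterozygosity baseline) is
several window standard errors deep; n = 2000 branch lengths for the mixture
test, 300-500 codons for dN/dS. Nelder-Mead runs with a relative
tolerance of 1e-12, up to 20000 evaluations, 50 restarts by default
(fewer in tests where the optimum is well-determined), plus one polish
restart from the incumbent. Permutation p-values never return 0 by
construction. Ties in the fd donor proxy (p2 = p3) need no rule — both
choices give the same term. BIC ties prefer the simpler model.

# Worked example

```{r example, eval = FALSE}
g <- admixture_graph(
  data.frame(
    parent = c("R","R","n1","n1","n2","n2","b1","c1","x0"),
    child  = c("O","n1","c1","n2","A","b1","B","C","X"),
    drift  = c(0.02,0.01,0.015,0.02,0.01,0.008,0.012,0.01,0.005)),
  data.frame(child = "x0", parent1 = "b1", parent2 = "c1", alpha = 0.3))

sim <- simulate_frequencies(g, 50000, seed = 7, outgroup = "O")
panel <- assign_blocks(sim$panel, 100)

triplet_sweep(panel)                 # D, Z, Bonferroni and |Z|>3.3 flags
f4_ratio(panel, c("A","O","X","C"), c("A","O","B","C"))  # alpha-hat
```

# Known limitations

- The fd statistic can exceed 1 in pathological windows where the
  recipient's sister exceeds both donor and recipient frequencies at
  many sites; such windows are rare under the generative model and the
  statistic is intended, as published, for positive-numerator windows.
- D-mode graph fitting relies on observed denominator rates; for very
  sparse quartets (few informative sites) those rates are noisy and f4
  mode is preferable.
- The mixture test shares one rate λ across both components; a
  two-rate variant is not implemented.
- Physical-length jackknife blocks and per-bp scan denominators require
  the caller to supply callable-site information.
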