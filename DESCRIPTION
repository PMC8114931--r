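Package: introgressr
Title: Genome-Wide Introgression Inference from Allele Frequencies,
    Local Trees and Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying introgression between
    diverged lineages from multi-sample variant panels. Implements
    Patterson's D (ABBA-BABA) and f4-statistics with weighted
    block-jackknife standard errors, genome-wide triplet sweeps with
    Bonferroni control, f4-ratio admixture proportions, admixture-graph
    fitting by Mahalanobis cost minimisation (Nelder-Mead) with scenario
    ranking, sliding-window Dxy / fd / nucleotide-diversity scans with
    permutation nulls and candidate-block detection, local-tree
    concordance and topology summaries with Robinson-Foulds distances,
    an exponential-mixture test separating introgression from incomplete
    lineage sorting on triplet branch lengths, counting-based pairwise
    dN/dS with a foreground-versus-background permutation test, and
    synthetic-data generators with known ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
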