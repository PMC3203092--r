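Package: mitonuc
Title: Congruence Analysis of Mitochondrial and Nuclear Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and dissecting discordance between
    mitochondrial, nuclear, and combined-data phylogenies of the same taxa.
    Classifies every combined-tree clade by which data set it agrees with
    (concordant, mtDNA wins, nucDNA wins, or unique), computes shared-node
    and Rohlf consensus-information similarity indices, parsimony-based
    homoplasy indices (ensemble consistency and retention indices on a fixed
    tree), node-depth and branch-length correlates of conflict resolution,
    and the associated exact non-parametric tests (exact tied-rank Wilcoxon
    rank-sum, exact binomial, correlation and regression). Includes a
    synthetic-data generator (trees, nearest-neighbour-interchange
    perturbations with known ground truth, and character matrices evolved
    under a symmetric substitution model) so every stage of the pipeline can
    be exercised without external data, plus a packaged summary of 14
    published vertebrate mito-nuclear data sets for cross-clade analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
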