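---
title: "Quantifying mito-nuclear discordance in combined-data phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mito-nuclear discordance in combined-data phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonuc)
```

## The problem

Animal phylogenies are routinely estimated by concatenating mitochondrial
(mtDNA) and nuclear (nucDNA) sequence data, yet the two genomes can disagree:
mitochondrial introgression, incomplete lineage sorting and plain estimation
error all produce gene trees that conflict with each other. When that
happens, every clade of the combined-data tree is implicitly a *decision*
— did the concatenated analysis side with the mitochondrial signal, the
nuclear signal, or neither? `mitonuc` makes that decision auditable. Given
three rooted trees on the same taxa (combined, mtDNA-only, nucDNA-only),
each with branch lengths and Bayesian posterior probabilities (Pp) on its
internal nodes, it classifies every combined-tree clade, quantifies
tree-to-tree similarity and data-set homoplasy, relates conflict resolution
to branch length and node depth, and runs the exact non-parametric tests
appropriate for the small, tie-rich samples these comparisons produce.

## Clade classification

A clade is identified by its leaf set on the rooted tree (outgroups are
pruned first; `clade_study()` prunes all three trees to their common leaf
set and reports every removed taxon). Each non-trivial combined-tree clade
is assigned one of four categories by `classify_nodes()`:

* **concordant** — the same leaf set is a clade of both the mtDNA and
  nucDNA trees;
* **mtDNA wins** — present only in the mtDNA tree;
* **nucDNA wins** — present only in the nucDNA tree;
* **unique** — present in neither.

For a tree in which the clade is absent, its recorded support is the
*discordance support*: the highest Pp of any clade of that tree that is
incompatible with the monophyly of the leaf set (two clades are compatible
when their intersection is empty or one contains the other). If no clade
conflicts — possible when the other tree has polytomies — the discordance
support is 0. Under the default `strict_presence = TRUE`, such
absent-but-compatible clades still count as discordant (with support 0,
hence always weakly supported); setting `strict_presence = FALSE` treats
compatibility as presence instead. The strict reading is the default
because consensus trees encode exactly the clades the data support, and a
polytomy is an absence of evidence, not evidence of the clade.

Discordant clades are cross-classified by whether the support on each side
reaches the `threshold` (default Pp ≥ 0.95, the conventional strong-support
cutoff): strongly supported by both, by mtDNA only, by nucDNA only, or by
neither. `conflict_summary()` tallies these into the standard per-study
report row, including the percentage of strongly supported conflicts
resolved in favour of mtDNA and an exact binomial test of that percentage
against 0.5.

### Binomial conventions

Three conventions are offered for that binomial test. The default,
`"deviation"`, is one-sided toward the observed deviation from 0.5 — for
`k` of `n` strong conflicts favouring mtDNA it reports
`P(X ≤ k)` when `k/n < 0.5` and `P(X ≥ k)` otherwise. `"two_sided"` is the
minimum-likelihood two-sided test. `"point"` reports the binomial point
probability `dbinom(k, n, 0.5)`. The point convention is included because
published per-study summaries of this kind can be reproduced exactly by it
(for example 15 of 19 gives 0.0074, and 6 of 8 gives 0.1094, values that no
tail convention yields), while for the `k = 0` rows the point probability
and the one-sided tail coincide (0 of 5 → 0.0313; 0 of 7 → 0.0078). A point
probability is not a valid P-value, so it is never the default; it exists
to let users reconcile our output with published tables.

## Similarity indices

`tree_similarity()` reports two numbers. The *shared-node proportion* is
the count of clades common to both trees divided by `n − 2`, the number of
non-trivial clades of a fully resolved rooted tree on `n` leaves. The
*Rohlf consensus-information index* CI(1) is computed on the strict
consensus `S` of the pair:

$$\mathrm{CI}(1) = 1 - \frac{\ln R(S)}{\ln (2n-3)!!},$$

where `R(S)` is the number of fully resolved rooted trees compatible with
`S` — the product over polytomies with `d ≥ 3` children of `(2d − 3)!!` —
and `(2n − 3)!!` is the number of rooted binary trees on `n` leaves.
Identical binary trees give 1 on both indices; a pair whose strict
consensus is the star tree gives CI(1) = 0. The resolution-counting form is
used (rather than a simple shared-node rescaling) because it is the variant
that behaves correctly on consensus trees with polytomies; both indices are
reported side by side since per-study summaries in the literature mix them.
All factorials are accumulated on the log scale, so the index is computable
for trees far beyond the range where `(2n−3)!!` overflows.

## Branch lengths and node depths

`compute_metrics()` records, for each numbered clade of the combined tree,
the branch length of the edge subtending its ancestor node, its
*topological depth* (edges from the root to that node; children of the root
have depth 1), and its *path-length depth* (sum of branch lengths along the
same path). To pool across studies whose trees differ in size and rate,
both are standardized within each tree: relative depth divides by the
largest (shallowest) depth among the numbered clades, so the shallowest
clade scores 1 and *larger values mean shallower*; relative branch length
divides by the longest numbered branch. The normalizers deliberately use
only the supplied (numbered) clades — conspecific-collapsed clades and
terminal branches never enter them — so the standardization matches how
such clades are numbered in published figures. Both relative quantities are
invariant to rescaling all branch lengths. When the maximum is tied, every
tied clade scores 1. Raw and relative per-category means are both emitted
by `category_stats()` (standard errors use the `n − 1` sample standard
deviation and are absent for singleton categories).

The cross-study depth prediction — conflicts won by nucDNA sit deeper than
conflicts won by mtDNA — is tested two ways: per study by an exact
rank-sum test on relative depths (`compare_categories()`), and across
studies by `depth_pattern_test()`, which scores each study as agreeing when
the mean relative depth of its `nucDNA_wins` clades is smaller (deeper)
than that of its `mtDNA_wins` clades. Under the null, the three orderings
(deeper / equal / shallower) are taken as equiprobable and lumped into
agree (1/3) versus not, and the count of agreeing studies is tested with a
one-sided exact binomial against 1/3. Studies with an empty winning
category are excluded and logged; by default the mean uses relative
topological depth, with the path-length variant available via the `depth`
argument.

## Homoplasy on a fixed tree

The homoplasy of each data partition is summarized by the ensemble
consistency and retention indices evaluated on a fixed tree (conventionally
the combined-data tree, but the tree is an explicit argument). For each
character, `s` is the minimum number of state changes on the tree, `m` is
the number of observed states minus one (the minimum on *any* tree), and
`g` is the number of scored cells minus the largest state frequency (the
star-tree maximum). Then

$$\mathrm{CI} = \frac{\sum m}{\sum s}, \qquad
  \mathrm{RI} = \frac{\sum g - \sum s}{\sum g - \sum m},$$

with CI summed over parsimony-informative characters only (the
conventional "CI excluding uninformative characters"; uninformative
characters have `s = m` and would only inflate the index) and RI over
characters with `g > m`. Lower values mean more homoplasy; RI = 1 means
none, RI = 0 means star-tree performance.

`fitch_length()` computes `s` by unit-cost dynamic programming over the
four nucleotide states (the Sankoff recursion). On binary trees this equals
the classical Fitch count; on polytomies the common sequential
intersection/union generalization of Fitch is order-dependent and can
overcount, whereas the dynamic program attains the true minimum under hard
polytomy semantics — the test suite checks it against exhaustive
enumeration of all ancestral-state assignments. IUPAC ambiguity codes
constrain a leaf to the corresponding state subset; `?`, `-` and absent
taxa are unconstrained. One asymmetry is deliberate: partially ambiguous
cells *do* constrain the step count `s` but are excluded from the
state tallies behind `m` and `g` (where a fractional attribution would be
arbitrary). With such cells present the bound `s ≤ g` is therefore not
guaranteed; matrices of resolved states plus missing symbols — including
everything the generator produces — satisfy `m ≤ s ≤ g` per character.

For cross-study correlations, the *relative homoplasy* of a study is the
difference `nucDNA index − mtDNA index` (on CI or RI). Only the magnitude
of this quantity is meaningful for correlation tests; the default sign
(`index_difference`, positive when mtDNA is the more homoplastic set) can
be flipped with `sign = "homoplasy_difference"`.

## Exact tests

The comparisons above involve small samples with many ties, so the package
carries its own exact machinery (`wilcoxon_exact()`, `binom_exact()`,
`pearson_test()`, `spearman_test()`, `ols_regress()`), each returning a
uniform `test_result` record.

The rank-sum test assigns mid-ranks to ties and computes the exact
permutation distribution of the rank sum by dynamic programming over
mid-ranks scaled by 2 to integers (the shift algorithm). Subset counts are
held in doubles, which are exact below 2⁵³ — far above the counts reachable
at the default `exact_limit = 50` pooled observations; beyond the limit a
normal approximation with tie-corrected variance and continuity correction
is used and flagged `exact = FALSE`. Both the rank-sum `W` of the first
sample and the Mann-Whitney `U = W − n_x(n_x+1)/2` are reported, because
published "W" values do not always state their convention. Two-sided
P-values are `min(1, 2·min(lower tail, upper tail))`. The default
sidedness for category comparisons is two-sided: the scientific predictions
are directional, but the published analyses do not state sidedness, and
two-sided is the conservative choice.

Pearson correlation uses the `t = r√((n−2)/(1−r²))` transform; Spearman is
Pearson on mid-ranks with the same transform, plus an exact permutation
option for `n ≤ 9`. Multiple regression is delegated to `stats::lm()`
behind a design-rank check that names collinear columns; the interaction
term is the elementwise product of the first two predictors. No
multiple-testing correction is applied anywhere — the reported analyses in
this literature apply none, and the per-test records make any correction
easy to apply downstream.

## The synthetic-data generator

`build_scenario()` produces tree triplets with *known* ground truth: the
combined tree is a random base tree (`generate_tree()`, Yule by default, so
clock-like branch lengths); the mtDNA and nucDNA trees are independent
sequences of random nearest-neighbour interchanges (`perturb_nni()`).
NNI was chosen as the discordance mechanism because each move changes
exactly one clade, so the construction yields an unambiguous per-clade
record of which base-tree clades survive in each perturbed tree — that
record is maintained move by move (a later move can destroy or even restore
a clade) and is therefore exact, independent of the classification code it
is used to validate. Supports are then drawn uniformly: clades shared with
the base tree from `support_strong` (default [0.95, 1]), novel clades from
`support_weak` (default [0.5, 0.94], spanning the weak side of the strong
cutoff so that strength classes are exercised). Character matrices are
evolved site-independently under the symmetric 4-state (Jukes-Cantor)
model via `phangorn::simSeq()` with a per-partition rate multiplier —
default 1.0 for mtDNA versus 0.2 for nucDNA, reflecting the several-fold
faster mitochondrial substitution rate typical of vertebrates — and
optional uniform missing-data masking. Every generator is a pure function
of its arguments and seed: per-component seeds are derived from the global
scenario seed by labelled hashing, and the global RNG stream is saved and
restored around each call.

What the generator does *not* emulate matters for interpretation: there is
no coalescent process (discordance is injected topologically, not via
incomplete lineage sorting), no introgression model, no among-site rate
heterogeneity, and no non-random missingness. Passing recovery tests on
these scenarios therefore shows that the pipeline measures what it claims
to measure on trees whose conflicts are localized and known — not that any
biological mechanism has been identified in real data.

### Experiment sizes

The packaged experiments use deliberately modest problem sizes chosen to
give stable Monte Carlo estimates: 200 scenarios of 20 taxa with up to 3
NNIs per data set for category recovery; 100 paired simulations of 500
sites at rates 0.1 versus 1.0 for rate-order recovery from CI; 60
replicates per NNI count (0, 1, 2, 4, 8) for the similarity-decay check;
and 2000 null replicates of 6-versus-6 tie-rich samples for the rank-sum
type-I-error check (the exact test is conservative: its realized size is
well below the nominal 5%).

## The packaged 14-study summary

`vertebrate_summary()` returns a transcription of published per-study
summary statistics for 14 vertebrate mito-nuclear data sets (fish, frogs,
salamanders, lizards, birds, turtles, mammals): resolution-category
percentages, pairwise shared-node percentages, variable-character counts
and CI/RI per partition. It exists so the cross-study layer — means,
`cross_clade_correlations()`, `depth_pattern_test()` — can be exercised and
reproduced without re-deriving 42 Bayesian trees from archived sequence
data; per-study recomputation from user-supplied trees uses exactly the
same code path. Note that the transcription inherits the printing precision
of its source (integer percentages, four-decimal indices), which is why
cross-study correlations recomputed from it are checked to ±0.02.

## Numerical choices and degenerate inputs

* Supports read from internal node labels by default; values above 1 are
  treated as percentages and divided by 100, so Pp and bootstrap inputs
  both work. Missing supports are `NA`, never 0.
* Missing branch lengths are excluded from branch-length analyses, not
  imputed as 0; trees without lengths still get topological depths.
* Clades whose terminals all map to one species can be excluded
  (`collapse_conspecific`), matching the convention of not numbering such
  clades; the root clade and leaves are never counted as nodes.
* Percentages are kept at full precision internally and rounded only at
  serialization.
* Zero strongly supported conflicts → the binomial P is absent, not 1.
  A constant missing-data percentage → the missing-data Spearman check is
  returned as not applicable rather than erroring the pipeline.
* All-identical pooled samples → rank-sum P = 1 (the degenerate
  distribution has a single atom).

## Limitations

Clade comparison is defined only for rooted trees on identical leaf sets;
unrooted comparison and taxon-mismatch beyond intersection pruning are out
of scope, as are tree inference itself, alignment, and model selection.
Homoplasy is measured by parsimony indices — adequate for ranking
partitions, but not a substitution-model-based estimate. The exact
rank-sum dynamic program is quadratic in total sample size times total
scaled rank sum; above the configurable limit the tie-corrected normal
approximation takes over.
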