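---
title: "Methods: drug-target networks and B-index similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target networks and B-index similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindexnet)
```

# The model

`bindexnet` treats a pharmacogenomic screen as three coupled problems.

**1. Association screening.** Given a gene-expression matrix (genes x
cell lines) and a drug-activity matrix (drugs x cell lines), both
standardized per row to z-scores, every (drug, gene) pair is tested for
association across the shared cell lines with Pearson's r (and
Spearman's rho on mid-ranks, reported alongside). P-values come from the
t transform with n − 2 degrees of freedom, two-sided. Because tens of
thousands of pairs are tested, the raw p-values are Holm-adjusted; a
pair is retained when r ≥ 0.334 *and* the Holm-adjusted p ≤ 0.05 (both
comparisons inclusive), keeping positive correlations only by default.
The 0.334 cutoff is the conventional moderate-association threshold for
a 60-line panel; at n = 60 it corresponds to a raw two-sided p of about
0.009, so the Holm condition — not the coefficient cutoff — is the
binding constraint in large screens.

**2. Network and target sets.** Retained pairs become edges of a
bipartite graph whose two node classes are drugs and genes; the edge
weight is the signed Pearson r. Drugs or genes without a retained edge
do not enter the network. A drug's *target set* is its gene
neighbourhood.

**3. Drug similarity and clustering.** Drug-drug similarity is
set-overlap similarity of target sets, by default the B-index
B(x, y) = ½|x∩y|(1/|x| + 1/|y|): the arithmetic mean of the two
conditional overlap proportions |x∩y|/|x| and |x∩y|/|y|. The complement
1 − B converts the symmetric similarity matrix to a dissimilarity,
Ward.D2 agglomeration builds the dendrogram, and the number of clusters
is chosen by the highest relative loss of inertia (below). Optionally,
structural similarity computed from SMILES provides an independent
reference partition, compared by the adjusted Rand index.

## Properties of the B-index

For non-empty sets the B-index is symmetric, lies in [0, 1], is 0
exactly for disjoint sets and 1 exactly for equal sets. Writing
a = |x|, b = |y|, i = |x∩y|, the chain

Russell–Rao = i/|U| ≤ Jaccard = i/(a + b − i) ≤ Dice = 2i/(a + b) ≤ B

holds for all pairs within a universe U; the last step is the AM–HM
inequality applied to 1/a and 1/b, with equality iff a = b. The
complement 1 − B violates the triangle inequality (e.g. x = {1},
y = {1, 2}, z = {2}: d(x, z) = 1 > 0.25 + 0.25), so 1 − B is a
dissimilarity, not a metric — acceptable for Ward clustering, which does
not require metricity, but worth remembering when reading the
dendrogram. The test suite verifies the chain and the equality
conditions over 10,000 random set pairs and exhibits a violating triple
found by exhaustive search.

Comparisons involving an empty set return 0 by convention, and drugs
with empty target sets are excluded from similarity *matrices* (with a
warning) while remaining in the exhaustive pair *report*, so that the
pair accounting always covers all C(n, 2) pairs.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `r_threshold` | 0.334 | coefficient cutoff (dimensionless correlation) |
| `alpha` | 0.05 | family-wise error level after Holm adjustment |
| `coefficient_mode` | `pearson` | which coefficient the retention rule tests (`spearman`, `either`, `both` available) |
| `sign_mode` | `positive` | keep positive correlations only, or threshold on the magnitude |
| `min_n_obs` | 40 | QC: minimum non-missing observations per drug row |
| `min_sd` | 1e-8 | QC: minimum activity standard deviation (drops flat profiles) |
| `holm_scope` | `per_drug` | Holm family: all genes tested for one drug, or the whole screen (`global`) |
| `planted_r` | 0.6 | synthetic panels: sample correlation planted between a drug and its anchor gene |
| `missing_rate` | 0 | synthetic panels: fraction of cells masked after planting |

The Holm family scope deserves a note: per-compound reporting treats
each drug's gene tests as one family, which keeps power comparable
across drugs and matches how per-drug results are usually read; the
`global` scope treats the entire screen as a single family and is the
right choice when the quantity of interest is the screen-wide
false-positive behaviour (the package's own null-panel tests use it for
exactly that reason — with D drugs as separate families, the chance of
at least one retained edge anywhere is bounded by 1 − (1 − α)^D, not α).

# The synthetic-panel generator

The generator emulates the *statistical shape* of an NCI-60-style
screen so the whole pipeline can be exercised against known ground
truth: 60 cell lines in 9 tissue-of-origin groups (counts 5, 6, 7, 6,
10, 9, 7, 2, 8 — the real panel's composition; tissue labels are
metadata for profile tables and exports and do not affect generation),
row-standardized Gaussian profiles, and a *blueprint* of planted drug
families.

A blueprint partitions drugs into families; each drug's target set is a
family-core set (a `shared_fraction` of the smallest set size in the
family, shared by all members) plus drug-private genes, and families
draw from disjoint gene pools. Per-drug set sizes are uniform on
`targets_per_drug` (default 5–10, a realistic recovered-target-set size
under stringent filtering).

Planting is exact in-sample: the drug's activity profile is built from
its anchor gene (the first gene of its set) as r·ĝ + sqrt(1 − r²)·ê,
where ĝ is the standardized anchor profile and ê is standardized noise
orthogonalized against ĝ in the sample. The sample Pearson correlation
equals `planted_r` to machine precision, which removes Monte-Carlo
flakiness from recovery tests: a planted edge either passes the filter
or the filter is wrong. The remaining family genes are drawn around a
family latent factor at correlation 0.95 — high enough that
activity-gene correlations for non-anchor truth pairs land near
planted_r × 0.95² ≈ 0.54 — and a deterministic rejection loop redraws
any gene whose realized correlation with a targeting drug falls below
`planted_r − 0.15`, making that floor a guarantee rather than a
tendency. Missing values are masked uniformly at random *after*
planting (so planted correlations are only approximate when
`missing_rate > 0`), and all rows are re-standardized over their
non-missing entries.

What the generator does **not** model: tissue-specific expression
covariance, batch or platform effects, multi-platform averaging, the
heavy-tailed or bimodal activity distributions of real screens, or
correlated missingness. Passing recovery tests therefore demonstrates
that the pipeline's statistics behave as designed under the assumed
Gaussian, row-independent model — not that real-data networks at any
particular scale will be recovered. Full-scale properties of real
screens (network size, cluster count, specific drug-gene correlations)
are outside what synthetic panels can certify.

Gaussian marginals are an explicit assumption: z-scored panels fix only
the first two moments, and nothing in the screening statistics depends
on higher moments under the null at n = 60, so Gaussian noise is the
parsimonious choice.

# Numerical choices

- **Distance transform.** d = 1 − s: order-reversing, maps [0, 1] onto
  [0, 1], and keeps the block structure of similarity matrices intact.
- **Cluster-count selection.** Let h(k) be the merge height traversed
  when k clusters become k − 1. The chosen k maximizes
  (h(k) + eps)/(h(k + 1) + eps) over [k_min, k_max], with
  eps = 1% of the top merge height. The regularizer matters: without
  it, any negligible positive height directly above an exactly zero
  height (identical recovered target sets produce many zero-height
  merges) yields an infinite ratio and a spurious k. Ties break toward
  the smallest k; a tree with all heights equal returns k_min with a
  warning; the choice is always overridable (`k = <int>`).
- **Ties and determinism.** Agglomeration uses `stats::hclust`
  (Ward.D2), whose merge order is deterministic for a fixed input;
  permuting the input ids permutes labels but not the partition (tested
  by ARI = 1 across permutations). Spearman uses mid-ranks; ranks are
  computed on the pairwise-complete subset of each pair, not once per
  row, so missing data never distort the rank transform.
- **Degenerate inputs.** Pairs with fewer than 3 complete observations
  or zero variance are flagged untestable and excluded from Holm
  families rather than raising; QC removes all-missing, flat, and
  sparse drug rows before the screen and errors only if nothing
  survives.
- **Missing data.** Pairwise-complete deletion per (drug, gene) pair
  maximizes the per-test n; listwise deletion across the panel would
  discard most of a sparse screen.
- **Newick export.** Branch length = parent merge height − child merge
  height (leaves at height 0), so the tree is ultrametric with leaf
  depth equal to the root height and sibling leaves merging at height h
  read `(a:h,b:h);`.
- **MCS search.** The maximum common connected substructure is found by
  exact McGregor-style backtracking over atom mappings (elements must
  match, bond orders must match on mapped bonds, adjacency preserved in
  both directions — the induced-subgraph variant), with a best-so-far
  bound and a step budget (default 2×10^5 nodes; exhaustion flags the
  pair rather than returning a wrong value). The smaller molecule
  always drives the search so results are symmetric even under the
  budget. Mismatch budgets (`atom_mismatch`, `bond_mismatch`) relax the
  label matching without giving up exactness. From the MCS atom count m
  and heavy-atom counts n_a, n_b: MCS-Tanimoto = m/(n_a + n_b − m) and
  MCS-overlap = m/min(n_a, n_b) ≥ MCS-Tanimoto.
- **Fingerprints.** The default fingerprint is Open Babel's path-based
  FP2 (1024 bits, linear fragments up to length 7) via `ChemmineOB`;
  FP3/FP4/MACCS are available. Absolute Tanimoto values differ across
  fingerprint dialects, so cross-toolkit comparisons should be read
  with a generous band; the MCS coefficients, by contrast, are
  dialect-free and reproduce published per-pair values exactly on the
  bundled fixture molecules.
- **Structural reference matrix.** Among the three structural matrices,
  the one whose average-linkage dendrogram has the highest cophenetic
  correlation is used as the reference partition for concordance — the
  matrix a hierarchy distorts least.

# Design choices where the design was open

- **Retention rule.** Retention is Pearson-based by default with
  Spearman reported alongside (`either`/`both` available): a single
  primary coefficient keeps the retained set interpretable, and the
  rank-based coefficient serves as a robustness column.
- **Inclusive thresholds.** r = 0.334 and Holm p = 0.05 are retained
  (≥ / ≤), so the worked boundary case keeps its edge.
- **Unannotated genes** default to category `"other"` rather than
  erroring: annotation tables are typically partial, and the network
  should not depend on their coverage.
- **Signed weights.** Edge weights store signed r even though the
  default keeps positives; switching `sign_mode` to `both` is then
  lossless.
- **Inertia criterion applied directly** to the B-index distance matrix
  rather than to a principal-component embedding: the matrix is already
  the object of interest, and an embedding would add a second
  approximation layer.
- **Empty-set convention.** Coefficients involving an empty set are 0
  (the index is defined on non-empty sets); matrices drop empty-set
  drugs with a warning, pair reports keep them.

# Problem sizes used in the test suite

Recovery tests run on panels of 15 drugs x 200 genes x 60 cell lines
with 5 planted families (shared fraction 0.85, planted r 0.6) — small
enough to run in seconds, large enough that every stage (QC, screen,
Holm, network, similarity, clustering, k selection) is exercised
non-trivially. False-positive behaviour is measured on 200 null panels
of 5 drugs x 100 genes, and the null tail of the correlation
distribution on a 100 x 100 panel (10,000 pairs). Property tests
(coefficient chain, Holm oracle) use 10,000 random set pairs and 1,000
random p-vectors. The pair-accounting identity is checked at the
124-drug scale, where C(124, 2) = 7626.

# Known limitations

- The generator's independence assumptions make synthetic FWER slightly
  conservative relative to real panels, where inter-gene correlation
  creates dependent tests (Holm remains valid under dependence, but the
  realized error rate shifts).
- The exact MCS search is exponential in the worst case; for molecules
  beyond roughly 35 heavy atoms the step budget may be reached and the
  pair flagged. The budget trades completeness for boundedness
  explicitly rather than silently approximating.
- 1 − B is not a metric; methods that require metricity (e.g. some
  embedding techniques) should not consume it unmodified.
- Structural concordance compares partitions at a common k; it does not
  test whether either clustering is "correct", only whether the two
  views agree more than chance.
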