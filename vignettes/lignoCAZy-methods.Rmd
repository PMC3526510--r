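---
title: "Methods: CAZyme annotation and induction calling in lignoCAZy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAZyme annotation and induction calling in lignoCAZy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignoCAZy)
```

# Scope

lignoCAZy implements the computational spine of a CAZyme re-annotation
and induction study: turning homology evidence into membership and
family calls, dating gene duplications against a focal clade to
partition paralogues into functional subgroups, and calling substrate
induction from replicated log2 expression data. Everything upstream of
these steps — running the homology search, building alignments and
trees, normalising arrays — is taken as input, not recomputed.

# Membership and family assignment

A query protein's hits against a family-labelled CAZy reference are
first filtered at E-value strictly below 10⁻¹¹. The best hit is the one
with maximal bitscore; because bitscore ties occur in real BLAST output,
ties break by lower E-value and then lexicographic subject id, making
the selection deterministic. (Ranking by E-value instead of bitscore is
available via the order the caller imposes; bitscore is the default
because it is monotone in alignment quality and independent of database
size.) A protein is a *confident member* when its best hit has identity
≥ 97% covering **more than** 200 aligned amino acids — the identity
bound is inclusive and the length bound exclusive, and both boundaries
are asserted exactly in the tests.

Cluster-level acceptance summarises a homology cluster by the mean
identity and mean alignment length of its members' best hits and
accepts the cluster when both means clear a rectangular boundary,
default mean identity ≥ 40 over mean length ≥ 100. The original
acceptance region was drawn as a line on a scatterplot rather than
published as a formula; a rectangular boundary preserves its monotone
"above the line" semantics while being explicit and configurable, and
raising either bound can only reject more clusters (tested as a
monotonicity property).

Family assignment is a majority vote: each cluster member with a
family-labelled best hit casts one vote per family of its reference
protein (a reference protein in several CAZy families gives each a full
vote). By default the focal species' own genes do not vote, so the
assignment rests on the family membership of the other species in the
panel. Ties break by the larger summed bitscore of the supporting
members, then by the smallest family label, and the `tie_broken` flag
records that a tie occurred. A cluster with no voting members is
`UNASSIGNED`, mirroring curated rows whose family column carries only
the bare class.

# Duplication dating and functional subgroups

The diversification question — did two focal-species paralogues split
before the focal clade's common ancestor? — is answered from the gene
tree alone with the species-overlap criterion: an internal node is a
duplication when at least two of its children contain a common species,
and the duplication is *ancient* when the species under the node extend
outside the focal clade. This is the standard tree-only
operationalisation of "the duplication predates the ancestor of clade
X" and needs no dated species tree.

Two focal genes share a functional subgroup exactly when the species
set under their lowest common ancestor stays inside the focal clade.
On a tree this pairwise relation is automatically transitive (of the
three pairwise LCAs of three leaves, two coincide and dominate the
third), so it defines a partition; the property is nevertheless tested
on random trees. Subgroup labels are the cluster id plus a letter,
assigned in order of each part's first member in left-to-right leaf
order — a deterministic convention the package fixes, since any
assignment of letters to parts is otherwise arbitrary. Letters extend to `aa`,
`ab`, ... beyond 26 parts.

Trees are parsed with `ape`; numeric internal labels become support
values, an unrooted trifurcation is treated as rooted at the
trifurcation, and a degenerate one-leaf tree is accepted. The partition
can depend on the rooting of the input tree; the package takes the root
as given. Support values are recorded on duplication events but no
minimum support is imposed by default (every node is trusted), since no
threshold was stated for discounting weak duplications.

# Induction calling

Contrasts compare induced cultures to the uninduced control cultures of
the **same cultivation batch** at the **same time point** — the two
cultivation sets used different array designs, so no cross-batch
contrast is ever formed. The log2 fold change is the difference of
stratum means over the four biological replicates per condition.

The test is a re-implementation of the empirical-Bayes moderated
t-statistic as implementable mathematics rather than a call into an
expression-analysis package: per-gene pooled two-group variances
*s²_g* (df *d_g*) are modelled as draws from a scaled
inverse-χ²(d₀, s₀²) prior; the hyperparameters are estimated by moment
matching on log variances, using the digamma/trigamma identities
E[log s²] = log σ² + ψ(d/2) − log(d/2), Var[log s²] = ψ′(d/2), with a
Newton inversion of the trigamma function. A non-positive between-gene
moment yields d₀ = ∞ (complete shrinkage, normal reference); the exact
degenerate case of identical variances returns that common value as
s₀². The posterior variance (d₀s₀² + d_g s²_g)/(d₀ + d_g) feeds a t
statistic on d₀ + d_g df; d₀ = 0 recovers the classical pooled t-test
exactly, which the tests verify to 1e-10 along with agreement with
`limma` on a shared dataset (limma serves only as an independent
cross-check). The prior is estimated per contrast from that contrast's
pooled variances, so each (substrate, time) comparison is moderated
within its own variance population. Raw p-values are gated, not
FDR-adjusted — the dual gate with a fold-change floor is itself the
multiplicity control of this design; Benjamini–Hochberg reporting can
be layered on by the caller via `p.adjust`.

A call is +1 when p < 0.01 **and** log₂FC > 0.4, −1 in the mirror case,
0 otherwise; all inequalities strict. At the reference noise level
(replicate sd 0.5, four replicates) the standard error of the fold
change is ≈ 0.354, so genes significant at 1% already satisfy
|log₂FC| ≳ 0.9 and the fold-change gate is inactive: under the null the
nonzero-call rate equals the nominal 1% of the p-gate. The gate bites —
and the caller becomes conservative — when replicate noise is small
relative to the 0.4 threshold.

Summaries derived from the calls: the induced set (any +1 on any
non-control substrate), the core set (induced on ≥ 1 cellulose-class
and ≥ 1 xylan-class substrate and on ≥ ⌈0.7 × n⌉ distinct substrates;
both Avicel concentrations count as distinct substrates, so the default
ten substrates give a threshold of seven), the family × substrate
induction count matrix with per-substrate gene and family margins, the
per-gene maximal-induction profile (the fold change at the time point
where it is largest, even if negative), and co-expression branches.
The default substrate class map places the two Avicels, spruce and
sophorose in the cellulose class (pretreated spruce is nearly pure
cellulose; sophorose is the soluble cellulose-derived inducer), the two
xylans in the xylan class, and the complex bagasse/wheat materials in
"other"; the map is user-configurable since reasonable analysts can
class the complex substrates differently.

Branches come from agglomerative complete-linkage clustering on
Euclidean distances of fold-change profiles — the common default of the
heatmap tooling of the study's period — cut into 18 groups by default
and labelled A, B, ... by each group's first gene in input order, so
the labelling is deterministic and row permutation changes only labels,
never the partition. An optional saturation flag is deliberately left
to the caller: saturated-signal genes (the known failure mode of highly
expressed cellobiohydrolases on arrays) should be excluded upstream.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of their parameters and a seed, and
they emit exactly the dialects the readers consume.

* `gen_hit_table` plants membership ground truth: members draw identity
  from U(97, 100) and length from U(201, 600) with E-values far below
  the discovery threshold; non-members violate the identity bound, the
  length bound, both, or the E-value bound, and the truth records which.
  Decoy hits with strictly lower bitscores exercise best-hit selection.
* `gen_gene_tree` plants `n_ancient` duplications above the focal-clade
  root (each separated lineage keeps an outside-clade witness leaf, so
  the events are datable) and `n_recent` duplications inside the focal
  species. Since any node joining two focal genes is a duplication on
  one side of the clade ancestor or the other, feasibility forces
  `n_ancient + n_recent = n_focal − 1`; the generator rejects other
  combinations as infeasible.
* `gen_expression_dataset` reproduces the experimental design — ten
  substrates over two cultivation batches, controls per batch, five
  time points, four replicates per stratum — with N(8, 1) baselines,
  planted +effect log2 shifts (default 2.0) in all non-zero-time strata
  of induced genes, and i.i.d. Gaussian noise (default sd 0.5) on the
  log2 scale.

Real microarray data differ in ways the generators do not emulate:
heavier-tailed and intensity-dependent noise, probe saturation,
correlated replicates, and genes induced in substrate-specific rather
than uniform strata. Passing the recovery tests therefore shows the
pipeline implements its rules correctly and is calibrated under the
stated noise model, not that the thresholds are optimal for any given
array platform.

# Numerical choices and problem sizes

Tolerances: the trigamma inversion iterates Newton steps to a relative
1e-8; moderated-vs-classical agreement is asserted to 1e-10; zero
posterior variance yields p = 0 with a warning (p = 1 when the means
also coincide). Keyword matching over the curated table is
case-insensitive fixed-substring after NFC normalisation, so composed
and decomposed Greek letters match equally.

The test and acceptance workloads are sized for quick, repeatable runs
on one CPU: 500 random trees up to 50 leaves against the brute-force
duplication oracle, the 55 feasible duplication plants up to ten focal
genes, 20 seeds × 2,000 genes for null calibration and 20 seeds × 500
genes for power, and compact single-substrate designs where the full
ten-substrate layout adds nothing to the property under test.

# Known limitations

Subgroup partitions inherit any error in the rooting of the input gene
tree. The rectangular cluster-acceptance boundary is a stated
approximation of a hand-drawn acceptance region. The moderated test
treats the estimated prior as known, which is very mildly
anti-conservative (fractions of a percent at 2,000 genes). Family votes
weight every member equally regardless of alignment quality beyond the
membership gate. The curated-table fixture is a transcription of a
printed table; its four letterless subgroup labels are accepted with a
warning rather than guessed at.
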