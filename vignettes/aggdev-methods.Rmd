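---
title: "Methods: HGT screening and single-replicate developmental expression"
author: "aggdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HGT screening and single-replicate developmental expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggdev)
```

## Scope and model

`aggdev` addresses a recurring analysis pattern in comparative genomics of
aggregative multicellularity (AGM): given a predicted proteome of an amoeba
from a sparsely sampled lineage, (i) which genes look horizontally
acquired, from which donor lineages, and did transfers expand into
families; and (ii) which genes respond to the developmental transition
from solitary growth to social aggregation, and back out into spore
germination, when only a single RNA-seq library per life-cycle stage is
available. The package implements the decision rules for both questions
and a synthetic-data layer that plants known answers, so every rule is
exercised against ground truth.

## Taxonomy-partitioned screening

Homology searches are assumed to have been run per major taxon group
(roughly kingdoms: Metazoa, Fungi, Viridiplantae, Bacteria, Archaea,
Amoebozoa, Stramenopila, Rhizaria, Alveolata, Rhodophyta and the
recipient's own lineage, Excavata, by default). The screen itself is never
run by the package; it consumes tabular hits (12-column BLAST dialect plus
a taxon-group column or a subject-to-group map).

Two e-value tiers apply. Hits weaker than `e_screen` (default `1e-10`,
per-database screening cut-off) are dropped on load. A query becomes a
*phylogenetic candidate* when it is non-novel, its globally best
non-recipient hit exists, and hits stronger than `e_tree` (default
`1e-35`) cover at least `min_euk_groups` (default 3) major eukaryote
groups — taxonomically widespread presence justifying a gene tree. The
eukaryote-group count includes the recipient group when it has a
sufficiently strong hit: the criterion is breadth of eukaryotic presence,
not breadth of foreign presence, and foreignness is enforced separately by
the top-hit condition. Pattern labels (`noHit`, `recipientOnly`, `uniHit`,
`multiHit`) partition queries by how many non-recipient groups retain a
hit after screening.

Determinism choices: the top-hit group is the argmin over non-recipient
groups by `(evalue, −bitscore)` with lexicographic group name as the final
tie-break; an e-value of exactly 0 (reported by search tools for very
strong hits) sorts below any positive value. *Novelty* (no database hit
anywhere) is a caller-supplied flag, keeping the package free of network
or database dependencies.

## Gene-tree HGT calling

Trees arrive as Newick with integer branch supports (0–100) as internal
node labels, the dialect written by common ML programs for ultrafast
bootstrap values. Supports that look like fractions in [0, 1] are
rescaled to 0–100 with a warning. Leaf labels follow a configurable
`GROUP|SPECIES|ID` scheme; leaves with the query species marker are the
recipient's sequences.

**Monophyly** uses bipartition semantics: a leaf set is monophyletic when
some branch separates exactly that set from the rest. This makes the
verdict independent of rooting, which the test suite checks explicitly.
Singletons are monophyletic by convention.

**Sister identification** requires an orientation. The rooting chain is:

1. *outgroup* — the full prokaryote leaf set, when it forms a bipartition
   clade disjoint from the query; otherwise a single prokaryote group's
   clade (largest first, then lexicographic);
2. *midpoint* — when branch lengths exist;
3. *farthest-leaf* — root on the non-query leaf topologically farthest
   from the query MRCA (lexicographic tie-break).

The final fallback replaces a pure "bipartition mode": without an
orientation the sibling of the query clade is ambiguous (either side of
its attachment edge could be "up"), so the chain always produces a
deterministic, recorded rooting instead. The strategy actually used is
reported per tree in the `rooting` column.

**The key branch** is the branch subtending the smallest clade containing
all query leaves — the branch whose collapse destroys the query's
grouping. For a single query leaf that branch is terminal and never
carries a support, so the branch subtending the query+sister ancestor is
used instead; the simulator plants its support on exactly the branch the
caller reads, which is what lets the test suite target the support
threshold precisely.

**The call**: the donor is the taxon group holding a strict majority
(> 50%) of sister leaves — a deliberate refusal to invent donors for
balanced mixed sisters, which return `unresolved`. `supported` requires a
donor different from the recipient group and key support at or above
`support_min` (default 60, the conventional ultrafast-bootstrap
confidence floor). Absent supports — including nodes that arise from
polytomies — yield `unsupported`: an uncertain branch cannot certify a
transfer. Families of query leaves are `singleton`, `mono` (monophyletic:
one transfer followed by duplication) or `mixed` (multiple transfers or
horizontal plus vertical transmission).

## Conservative single-replicate fold change

With one library per stage, naive count ratios overstate change for
low-count genes. The estimator places independent Gamma posteriors on the
per-library Poisson rates, `λᵢ ~ Gamma(cᵢ + ½, Nᵢ)` (Jeffreys-style
prior with counts `cᵢ` and library sizes `Nᵢ`), forms the central
credible interval of `log2(λ₂/λ₁)` at `credibility` (default 0.99), and
returns 0 when the interval spans zero, else the endpoint nearer zero.
This is the smallest fold change clearly supported by the data: zero for
uninformative comparisons, shrunk toward zero for weak ones, and
convergent to the true log ratio as counts grow.

The computation is analytic, not sampled: for independent
`G₂ ~ Gamma(a₂)`, `G₁ ~ Gamma(a₁)`, `G₂/(G₁+G₂) ~ Beta(a₂, a₁)`, so
`log2(G₂/G₁) = log2(B) − log2(1−B)` is a monotone transform of a Beta
variate and every quantile comes from `qbeta`. Monte-Carlo posterior
sampling appears only as the independent oracle in the tests. Both counts
zero returns 0 with an `uninformative` attribute. The ½ pseudo-count
enters only through this prior, never the reported RPKM
(`1e9·c/(L·N)`), which stays exact.

Two properties are load-bearing and verified on 10,000 random count
pairs: the magnitude never exceeds the naive pseudo-counted ratio
`log2(((c₂+½)/N₂)/((c₁+½)/N₁))` (the naive value always lies inside a
99% interval, so the nearer endpoint cannot pass it), and the sign, when
non-zero, matches the naive sign.

## Stage-response sets

`Aggup`/`Aggdn` flag substantial change from growth to aggregation,
`Germup`/`Germdn` from aggregation to germination. Each requires
`|DE| ≥ de_min` (default 0.9 log2 units, the boundary conventionally used
for "not substantially changed") **and** expression at or above
`rpkm_floor` (default 10 RPKM) in the stage where the gene is high — the
condition-appropriate stage, a declared choice where a both-stage rule
would also have been defensible. Aggregation-specific genes (`AggSpec`)
are Aggup and Germdn with at least `aggspec_de` (default 1, i.e.,
two-fold) magnitude on both transitions; the definition is the
conjunction with Aggup/Germdn rather than a bare DE rule so the nesting
`AggSpec ⊆ Aggup ∩ Germdn` holds by construction even at the RPKM floor.
Active expression per stage is strict `RPKM > rpkm_floor`. Library sizes
default to count-table column sums and are overridable.

Replicated designs (used for cross-species comparison) are averaged
per-gene (`average_replicates`), with strict/lenient handling of
mismatched replicate gene sets; classified set sizes from the consensus
are bounded by the per-replicate extremes.

## Set summaries

Novelty fractions, orthology-group (OG) membership, per-taxon OG sharing
and focal-taxon uniqueness are plain set algebra over an OG membership
table; absence of a taxon from an OG in the table is treated as absence.
Percentages print to one decimal with round-half-up (`pct_round`), not
banker's rounding, to match how comparative tables are conventionally
printed — the bundled per-set counts
(`inst/extdata/ako_developmental_sets.tsv`) reproduce their published
percentages exactly under this rule. Multi-category functional
annotations are deduplicated first-listed-wins with a warning, since no
standard exists. Category-profile denominators are conserved: counts sum
to the (optionally active-filtered) set size.

## What the synthetic data does and does not emulate

The generators plant the statistical structure the rules assume, not
sequences:

* **Trees** are built directly (no sequence evolution, no birth–death
  process): group clades in a caterpillar arrangement, prokaryotes basal,
  the query attached inside the recipient (vertical) or donor (HGT)
  clade with an all-donor sister. Key-branch supports come from a
  configurable (mean, spread) normal — spread 0 plants exactly — or a
  discrete uniform on 0..100 for threshold-rate experiments; background
  branches draw 75–100 so only the key branch sits near the decision
  boundary.
* **Hit tables** realize each planted pattern class against the two
  e-value tiers by construction (strong hits log-uniform below `e_tree`,
  weak hits between the tiers).
* **Counts** are negative binomial via the Gamma–Poisson mixture with a
  shared dispersion (default 0.05, a typical RNA-seq biological CV² for
  a clean library; 0 gives Poisson), library sizes 5 × 10⁶ per stage,
  gene lengths 500–3000 bp, baselines 100–1000 RPKM log-uniform, planted
  effects 2–4 log2 units. These were fixed once as realistic study
  conditions.

Passing tests therefore demonstrate that the decision rules recover what
they define, at realistic noise — not that the rules are robust to real
data pathologies the generators do not model: contamination, assembly
chimerism, long-branch attraction, incomplete lineage sorting, unequal
database depth across taxon groups, or length-dependent count bias.

A single integer seed drives everything (R's Mersenne-Twister; each
generator reseeds from `seed + offset`, so fixtures are independent of
call order and byte-identical across runs and platforms).

## Numerical and degenerate-input choices

* e-value comparisons are `(evalue, −bitscore)` lexicographic; 0 is a
  legitimate smallest value.
* Trees need ≥ 3 leaves; unknown leaf ids, missing taxon groups and
  malformed table rows fail with located errors rather than silent drops.
* Empty gene sets give `NA` percentages (flagged, not 0); empty count
  tables flow through `stage_expression` without error.
* Queries whose smallest containing clade is the entire tree are
  `unresolved`, never coerced to a call.
* All pipeline outputs carry a `seed=… config=<md5>` header; the manifest
  records per-file checksums, and reruns with the same config are
  byte-identical.

## Problem sizes

The test suite exercises exhaustive topology enumeration at 4–7 leaves
(all unrooted topologies; every non-trivial leaf subset through 6 leaves,
a lattice of subsets at 7) plus 500 random 8–12-leaf trees against
brute-force clade enumeration; 1000 planted trees for caller recovery;
10,000 count pairs for estimator properties; 2000 genes for
stage-classification recovery; and 10,000 queries for screening
agreement — sizes at which the whole suite completes in about two
minutes on one core.

## Known limitations

* Sister identification at heavily polytomous nodes follows the "all
  sibling subtrees jointly" convention; other tools may resolve
  polytomies differently, and no published worked example exists to
  calibrate against.
* The fold-change estimator is a defined conservative estimator, not a
  bit-compatible reimplementation of any particular single-replicate
  tool; only its qualitative contract (shrinkage, zero when
  uninformative) is shared.
* Donor assignment is majority-based and topology-only: no
  reconciliation against a species tree, no transfer dating, and no
  distinction between a transfer into the query lineage and a loss
  pattern mimicking one.
* OG uniqueness is relative to the taxa present in the supplied table;
  it cannot see taxa the clustering never included.
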