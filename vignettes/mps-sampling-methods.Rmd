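---
title: "Multi-protein similarity sampling: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-protein similarity sampling: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsampler)
```

## The problem

Public genome collections are large, redundant and unevenly sampled: a few
heavily sequenced taxa account for most genomes, while much of the real
diversity is represented by single assemblies. Most comparative analyses
therefore start by *dereplicating* the collection — selecting a subset of
representative genomes that preserves the diversity of the whole. Taxonomy-
based selection inherits annotation gaps and errors; tree-based selection
requires inferring a phylogeny over the full collection, which is exactly
what one cannot afford; whole-genome similarity indices (ANI and relatives)
are quadratic in the number of genomes and lose resolution beyond the genus
level.

`mpsampler` takes a different route, a multilocus similarity analysis: the
input is a set of families of homologous single-copy proteins (ribosomal
proteins and universal core families are the typical choice, being
comparable from species to phylum level). Genomes are compared through the
cluster memberships of their sequences, family by family, which keeps the
whole procedure near-linear in the number of genomes and fully agnostic to
taxonomy and phylogeny.

## The procedure

**Step 1 — Lin-clusters.** Within each family, sequences are clustered by a
Linclust-style procedure: a k-mer prefilter proposes candidate pairs (each
sequence contributes its `kmers_per_seq` lowest-hash distinct k-mers, and a
pair must share at least one), each candidate is verified by a local
alignment (BLOSUM62, affine gaps 11/1), and the verified-pair graph is
covered greedily: the unassigned sequence with the most unassigned
neighbours becomes a centroid and absorbs them. A pair is accepted when

* e-value $\le$ `evalue`, with $E = K m n\, e^{-\lambda S}$ ($m$ the query
  length, $n$ the family's total residue count, $\lambda = 0.267$,
  $K = 0.041$, the standard gapped BLOSUM62 constants),
* identity $\ge$ `min_seq_id` (identical aligned positions over alignment
  columns), and
* in coverage mode 0, aligned span over sequence length $\ge$ `min_cov` on
  **both** sequences.

Clusters are labeled $1..C$ from largest to smallest. The built-in
clusterer is deliberately a *simplified* single-round Linclust: it serves
the self-contained pipeline and the test bed, while
`external_cluster_adapter()` accepts the native `rep<TAB>member` cluster
TSV of MMseqs2-style tools whenever exact parity with an external clusterer
is wanted. Reproducing MMseqs2's cascaded indexing is a non-goal.

**Step 2 — EGGs.** Each genome becomes a length-$P$ vector of Lin-cluster
labels ($P$ = number of families), with an explicit missing marker where it
lacks the family. The genomes × families matrix is put into a canonical
order (below), and genomes with *identical* vectors — missingness pattern
included — are fused into elementary groups of genomes (EGGs). The
delineation is strict: one differing label separates two genomes.

**Step 3 — pre-connection (optional).** EGGs are gathered into rough
components before any similarity is computed: an EGG joins a component when
its label set shares at least `min_nb_linclusters` (family, label) entries
with the component's label union, and merging repeats to a fixpoint. The
fixpoint is the monotone closure, so the partition is independent of EGG
order. The union rule (rather than a pairwise-sharing graph) is required:
in the ten-genome worked example, the gD vector shares at most one label
with any *single* other EGG of its component, yet belongs with it through
the union. Pre-connection is an accelerator, off by default. Because two
EGGs can have a high Dice index while sharing fewer than
`min_nb_linclusters` labels, per-component clustering is not guaranteed to
equal the unpartitioned run; the test suite compares both on the worked
example (where they agree at every threshold in the standard ladder).

**Step 4 — Dice similarity and complete linkage.** For two EGGs with
(family, label) sets $A$ and $B$ over their non-missing positions,

$$D(A, B) = \frac{2\,|A \cap B|}{|A| + |B|},$$

so a family absent from one genome counts only against the side where it is
present. The full matrix is computed blockwise from a sparse one-hot
EGG × (family, label) indicator — shared-label counts are an indicator-by-
transposed-block product — which avoids a quadratic pass over explicit
pairs; the block width (default 1024) has no effect on values, and the
suite asserts exact equality with the brute-force double loop. EGGs are
then agglomerated with complete linkage: repeatedly merge the two clusters
with the highest *minimum* pairwise Dice. One dendrogram per component is
built down to similarity 0 and cut once per requested threshold $\Delta$:
all merges with similarity $\ge \Delta$ apply. Complete linkage gives the
sample its guarantee: within an MPS-cluster every pair of EGGs has Dice
$\ge \Delta$; the price is a slight tendency to over-split large diffuse
groups, preferred here to any loss of representativeness. Singleton
clusters are retained deliberately — most are genuinely isolated diversity,
not noise. $\Delta = 1$ degenerates to the EGG partition; the default
ladder is $\Delta \in \{1, 0.9, \dots, 0.1, 0.05\}$, and clustering stages
up to the similarity matrix run once however many thresholds are cut.

**Step 5 — representatives.** One genome per MPS-cluster, filtered tier by
tier: (1) highest user priority score (genomes absent from the table score
0 — the table encodes preferences such as type strains or assembly
quality); (2) highest number of non-missing families; (3) highest
centrality, the sum over the cluster's other genomes of the Dice index
between their EGGs, genomes sharing an EGG contributing 1 to each other;
(4) lowest canonical hash of the genome id. Raising a winner's priority can
never dethrone it (tier 1 is applied first and is monotone).

## Determinism and the canonical hash

The pipeline promises bit-identical output under any permutation of input
genomes, families or FASTA records. Every ordering decision therefore rests
on a single canonical key: the first 8 bytes of the SHA-256 digest of the
UTF-8 identifier, compared as a 16-hex-character string (equivalent to the
big-endian unsigned integer, without 64-bit overflow in R). It breaks ties
when labeling equal-size Lin-clusters (by the hash of the cluster's
lexicographically smallest member), orders the label-matrix columns
(ascending Lin-cluster count, then hash of the family name) and rows
(lexicographic label vector with missing sorting last, then hash of the
genome name), selects prefilter k-mers (lowest-hash `kmers_per_seq`),
picks greedy-set-cover centroids among equal-degree vertices, orders merge
pairs with equal complete-link similarity (smallest canonical EGG index
pair), and is the final pseudo-randomization tier of selection. An 8-byte
collision between distinct ids would be fatal rather than silent; it is
unreachable in practice.

Two ordering choices are arbitrary where any fixed convention works and
are set once: families sort by *ascending* cluster count, and the missing
marker sorts *after* every integer label.

## EGG equality and missingness

Two genomes are fused only when their vectors agree *including* the
missingness pattern. The worked example fuses gB and gC, which share both
their labels and their missing family; vectors whose non-missing positions
agree but whose missing sets differ are kept separate, because the Dice
step can still distinguish them (their label sets have different sizes).
This is the strictest reading consistent with the worked example, and the
only one under which Dice = 1 exactly characterises "same EGG".

## Parameters

| parameter | default | meaning |
|---|---|---|
| `evalue` | 1e-5 | max alignment e-value for accepting a pair |
| `min_cov` | 0.8 | min aligned fraction, on both sequences (mode 0) |
| `min_seq_id` | 0.6 | min fractional identity of the local alignment |
| `coverage_mode` | 0 | 0 = coverage required on both sequences |
| `kmer_size` | 5 | prefilter k-mer length (amino acids) |
| `kmers_per_seq` | 20 | lowest-hash k-mers kept per sequence |
| `deltas` | 1 … 0.05 | threshold ladder for the complete-link cut |
| `min_nb_linclusters` | 2 | pre-connection sharing threshold |

The alignment thresholds are the method's published operating point; the
prefilter constants (`kmer_size`, `kmers_per_seq`) and the e-value
constants ($\lambda$, $K$, gap 11/1) are standard protein-search defaults,
all configurable through `cluster_params()`. The cut boundary is
*inclusive* ($\ge \Delta$): in the worked example the 0.667 and 0.75 merges
survive a $\Delta = 0.5$ cut and the 0.4 merge does not, which is what the
published clusters require.

## The synthetic generator

`simulate_families()` emulates the one property the pipeline's correctness
arguments rest on: families with a known group structure and a wide gap
between within-group and between-group identity. Each family has a random
root; group ancestors are mutated copies of the root placed so that
between-group pairwise identity is approximately `between_identity`
(members at identity $\sqrt{t}$ to a common ancestor sit at $\approx t$ to
each other, substitutions landing independently); group members are drawn
the same way around their ancestor at `within_identity`. Defaults — 3
groups × 5 genomes, within 0.9, between 0.3, 4 families of length 150, no
indels — put within-group pairs far above the 0.6 identity threshold and
between-group pairs far below it. Substitution-only mutation keeps
alignment coverage near 1, so the coverage filter is exercised only by the
dedicated unit tests, not by the simulation. Optional missingness removes
(genome, family) cells uniformly, never emptying a genome.

What passing these tests shows: the clustering, EGG, similarity, linkage
and selection machinery is correct on data whose ground truth is known by
construction. What it does not show: behaviour on real collections, where
identity varies continuously, families recombine or transfer horizontally,
assemblies truncate sequences (coverage failures), and the external
clusterer's exact output matters. The worked ten-genome example and the
adapter contract are the bridge to that setting.

`fixture_families()` generates sequences for the ten-genome worked example
and *re-clusters its own output*, failing loudly unless the resulting label
matrix is exactly the published one — a successful return is
self-certified. The example's two equal-size-tie labelings happen to
coincide with the canonical-hash tie-break, which was verified before the
fixture was frozen.

## Numerical choices and degenerate inputs

Dice values are small-integer ratios computed in double precision; tests
compare them exactly (identical arithmetic on both routes) or at 1e-12.
Merge similarities are non-increasing, so a cut is a prefix of the merge
list. Empty datasets, genomes with no sequence in any family (dropped with
a warning), single-EGG components (empty merge list), all-zero similarity
(single merge at 0), sequences shorter than one k-mer (whole string as
token) and an EGG with no non-missing label (an error — the Dice index is
undefined) are all handled explicitly.

## Evaluation helpers

`taxonomic_report()` scores a sample against a taxonomy: per rank, the
proportion of the input's taxa retained among representatives and the mean
number of sampled genomes per retained taxon (redundancy); unassigned
entries leave the rank's denominator. `phylo_diversity()` prunes a tree to
the sampled tips and returns total branch length per tip — the per-tip
phylogenetic diversity used to monitor dereplication quality.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the ten-genome worked example
end to end from sequences, property checks on random label matrices of up
to a few hundred EGGs (including an exact blockwise-vs-brute-force
similarity comparison above 100 EGGs), and twenty seeded replicates of the
3 × 5-genome simulation. These sizes exercise every code path — including
blocking, pre-connection and multi-threshold cuts — while keeping the whole
suite within a few tens of seconds on one CPU; the method itself scales to
collections many orders of magnitude larger, where step 1 is best delegated
to an external clusterer through the adapter.

## Known limitations

* The built-in clusterer is single-round and aligns all candidate pairs;
  for very large families the external adapter is the intended route.
* Pre-connection can, in principle, separate EGG pairs with high Dice but
  few shared labels; it is off by default and empirically neutral on the
  shipped examples.
* The e-value uses fixed Karlin–Altschul constants rather than
  sequence-composition-adjusted ones; at the default thresholds the
  identity and coverage filters dominate.
* Between-group identity in the simulator is approximate (independent
  substitution placement), intentionally so — only the ordering
  within ≫ threshold ≫ between matters to the tests.
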