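---
title: "Methods: anchor-centred detection and profiling of Fe-S flavoenzyme gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-centred detection and profiling of Fe-S flavoenzyme gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesmgc)
```

`fesmgc` turns an enzyme-family-centred genome-mining idea into a testable
pipeline: pick an enzyme class defined by a characteristic *pair* of Pfam
domains, find every gene encoding it, read off the operon-like gene
neighbourhood around each occurrence, group those neighbourhoods into
families by domain content, and profile the families' likely substrate
classes. This vignette documents the model behind each stage, the
parameters that matter, the synthetic-data design that makes the pipeline
verifiable, and the numerical conventions and limitations a user should
know about.

## The anchor model

The anchor class is the Fe-S flavoenzyme superfamily, operationalised as
the joint presence of Oxidored_FMN (PF00724) and Pyr_redox_2 (PF07992) on
one protein. Given a domain hit table (hmmsearch `--tblout` or
`--domtblout` layout), a protein is an anchor iff for **every** accession
in `required_domains` it has at least one hit with sequence-level E-value
`<= e_threshold`. Conventions worth stating:

* the comparison is inclusive — a hit at exactly `1e-5` counts;
* the filtered quantity is the *sequence-level* E-value, not the per-domain
  conditional value, so either hmmsearch tabular dialect can be consumed;
* several hits of one protein to the same domain count once, and copy
  number counts distinct anchor *proteins* per assembly, so repeated domain
  matches are never double-counted.

Per-taxon profiles report two deliberately separate views: *prevalence*
(fraction of all genomes of a taxon encoding at least one anchor) and the
copy-number mean/sd computed **over encoding genomes only**, with the
sample (n−1) standard deviation left `NA` below two encoding genomes.
Keeping both avoids the ambiguity of blended statements like "X % of
genomes, with Y copies on average".

## Cluster extraction

The metabolic gene cluster (MGC) around an anchor is the maximal run of
genes that share the anchor's strand and are chained by intergenic gaps of
at most `max_intergenic_gap = 400` bp. The gap between consecutive genes is
defined arithmetically as `next_start − prev_end − 1` in 1-based inclusive
coordinates; the bound is inclusive (`<= 400` passes). Further conventions,
each of which was a genuinely open design choice:

* **Overlapping genes count as gap 0.** Overlapping ORFs are common in
  operons; a rule meant to approximate operon structure should not break on
  them.
* **Extension is bidirectional** from the anchor; nothing in the gap rule
  distinguishes upstream from downstream.
* **Genes without strand annotation terminate extension** (treated as a
  strand mismatch), and clusters never span contig ends or join across
  circular replicons — draft assemblies dominate real inputs.
* **Two anchors in one run yield one cluster** carrying both anchor ids,
  so the extracted set is non-redundant by construction. A further
  `deduplicate_clusters()` step collapses clusters with identical ordered
  domain strings (optionally keyed on gene count as well); the key is
  configurable because "non-redundant" has no single canonical definition
  for gene clusters.

Extraction is verified three ways: against a brute-force enumeration of
all valid same-strand windows on random contigs, by direct maximality
assertions (adding the flanking gene always violates strand or gap), and
by exact recovery of planted clusters (below).

## Family networking

Full domain-sequence-similarity machinery (as in BiG-SCAPE) needs
per-domain alignments; this package uses a fully specified two-term
stand-in. Each cluster is reduced to its domain string — per-gene Pfam
accessions (sorted within a gene), concatenated in coordinate order — and
two clusters are compared by

\[ d = 1 - (w_J \cdot J + w_A \cdot AI), \qquad w_J = w_A = 0.5 \]

where \(J\) is the Jaccard index of the two domain-accession sets and
\(AI\) is the Jaccard index of the sets of *unordered adjacent domain
pairs* along the strings. Unordered pairs make the adjacency term
insensitive to the reading orientation of the gene order. Degenerate-content
conventions: an empty-content cluster is at distance 1 from any non-empty
cluster and 0 from another empty one; when neither cluster has two domains,
the adjacency term compares as identical (necessary so that two identical
single-domain clusters get \(d = 0\)). The distance is symmetric and
bounded in \([0, 1]\) but is **not** guaranteed to satisfy the triangle
inequality — it is a network-building score, not a metric.

Families (GCFs) are the connected components of the graph with an edge for
every pair at `d <= network_cutoff` (default 0.3, the customary cutoff for
cluster-family networks). Components — rather than hierarchical or
exemplar-based clustering — match the network-cut semantics and make the
family count provably monotone non-increasing in the cutoff. Weights and
cutoff are exposed in `mgc_params()` so users can tune towards the
behaviour of heavier tools; reproducing any specific external tool's family
assignments is out of scope.

## Function classification

Substrate categories (saccharide, peptide/amino acid, nucleotide, lipid)
are predicted by lookup in a domain→category map: a cluster's categories
are the union over its mapped domains, and a family's the union over its
members. Union (multi-label) semantics are deliberate — category counts may
sum to more than the number of categorized families, which mirrors how
such profiles behave on real data where a family can carry, say, both a
glycoside hydrolase and a lipase domain. The shipped
`default_category_map()` contains only domain assignments with explicit
literature support (PF00128 and PF16738 → saccharide, PF01262 →
peptide/amino acid) and is intentionally minimal: inventing Pfam→category
assignments would be worse than requiring the user to load a curated map.
Transporter and electron-carrier domains can be carried in the same table
with `kind = "annotation"`; they are reported alongside but never counted
as substrate categories, since they indicate *how* a substrate is handled
(diffusible, redox-coupled) rather than what it is.

## The phylogeny toolkit

The sequence workflow mirrors the enzyme-family phylogeny procedure at
desk scale, with two external tools replaced by fully specified algorithms:

* **Greedy centroid clustering** stands in for MMseqs2: sequences are
  scanned longest-first, each joining the first centroid it matches at
  `min_identity >= 0.9`, else founding a new cluster. Identity is computed
  from Needleman–Wunsch global alignment under a flat scoring scheme
  (match +1, mismatch −1, gap open 6, extend 1), with the denominator being
  alignment columns between the first and last doubly-aligned column —
  terminal gaps excluded, internal gaps counted as mismatches. The
  denominator convention is documented and configurable because identity
  definitions differ between tools. The algorithm guarantees every member
  is within threshold of its centroid, which is asserted by brute force in
  the tests.
* **Neighbor joining** (Saitou–Nei Q criterion, standard branch-length
  formulas) stands in for approximate-ML tree building. NJ was chosen
  because it is exactly characterisable: on an additive distance matrix it
  provably recovers the generating tree, which the tests exercise on
  hundreds of random trees to `1e-9`. Ties in Q are broken by lexicographic
  label-pair order and negative branch lengths are clamped to zero (with
  the clamped total recorded), so output is deterministic. Users wanting ML
  trees can export the trimmed merged alignment and use an external tool.
* Representatives (up to `max_representatives = 5` per cluster, singletons
  always kept) are sampled under the pipeline seed, so selection is
  reproducible where the original procedure's random picks were not.
* Alignment post-processing operationalises "remove unaligned and indel
  regions" as gap-fraction column filtering with `max_gap_fraction = 0.5`
  by default (no canonical threshold exists; it is a parameter), and block
  concatenation gap-fills sequences missing from one block with a warning.
* **Rooting:** the midpoint root halves the longest leaf-to-leaf path
  (undefined, hence an error, for all-zero branch lengths); outgroup
  rooting splits the branch separating a monophyletic outgroup evenly and
  errors, naming the leaves, when the outgroup is not separable.
* **N50** is the contig length at which the descending cumulative sum first
  reaches half the assembly total; the quality filter is inclusive at
  `n50_min = 50` kb.

## What the simulator emulates — and what it does not

`generate_genomes()` builds annotated genomes in which the downstream
truth is planted, not estimated:

* **Copy-number laws** per taxon (constant, Poisson, negative binomial)
  emulate the observed contrast between taxa — strongly expanded,
  over-dispersed counts in Clostridia (real profiles range from 0 up to
  ~18–22 copies per genome) versus sparse counts elsewhere. The analysis
  scripts use negative binomial (size 1.2, mean 2.5) for Clostridia and
  small Poisson means (0.05–1.0) for Bacteroides, Bacilli,
  Enterobacteriaceae and Eggerthella; with 60 genomes this yields
  prevalences and means of the same character as real profiles without
  claiming to reproduce any published figure.
* **Cluster geometry:** every planted cluster is a same-strand run with
  internal gaps drawn strictly below the 400 bp threshold (default 20–200
  bp) and flanked by separations above it (600–2000 bp), so planted
  clusters are *exactly maximal* under the extraction ruler. The gap is
  defined during generation by the same arithmetic used during extraction —
  one ruler for planting and measuring — which is what makes
  precision = recall = 1.0 a legitimate assertion rather than a tuned
  outcome.
* **Family architecture is drawn once per family** — size, strand, anchor
  position and the ordered domain profile (category marker domains plus
  family-private filler accessions) are shared by all planted instances of
  a family. Fixing the strand per family keeps within-family domain
  strings identical: a strand flip reverses gene order but not the fixed
  N→C domain order inside a multi-domain gene, so mirrored instances of a
  family would otherwise differ in their gene-boundary adjacency pairs.
  Families at the default sizes then sit at distance 0 from each other
  within a family and ≥ ~0.45 between families, cleanly separated by the
  0.3 cutoff; families of planted size 2 carry only their private filler
  (no category marker) and are deliberately left category-less.
* **Noise channels:** decoys can receive exactly one required domain
  (single-domain rate) — these must never pass the dual-domain filter — or
  spurious off-map domains (false-hit rate). True hits draw E-values
  log-uniformly in \([10^{-20}, 10^{-6}]\), below the threshold; passing a
  law concentrated above `1e-5` verifies that the threshold, not the
  planting, drives recovery.
* **Sequence sets** plant family structure by per-site substitution from
  family centroids, with rates solved numerically (accounting for chance
  agreement at 1/19) to hit target expected pairwise identities; defaults
  0.95 within / 0.5 between straddle the 0.9 clustering threshold.

What the simulator does **not** model: codon structure or realistic
sequence evolution (no indels, no rate heterogeneity), assembly artefacts
beyond multiple contigs, annotation errors (missed or chimeric ORFs),
horizontal transfer mosaicism inside clusters, or partial cluster
degradation. Passing tests therefore demonstrate that the *rules* are
implemented exactly as specified, not that the rules are robust to the
messiness of real annotations — on real data, borderline E-values,
fragmented contigs and sloppy gene calls will all erode the clean
recovery seen here.

## Determinism and problem sizes

Every stochastic step funnels through one seeded RNG wrapper, and every
writer sorts its rows and fixes float formats, so the full pipeline is
byte-identical across runs at a fixed seed — asserted end to end in the
tests. The shipped analysis uses 60 genomes across 5 taxa with 8 planted
families, and the test suite works at 10–50 genomes, 100 random contigs for
the extraction oracle, 200 random trees (n ≤ 8) for NJ exactness and 100
for midpoint balance, and 30-sequence sets for the clustering guarantee —
sizes chosen to exercise every rule path while keeping a full run in the
order of a minute.

## Known limitations

* The two-term domain-content distance ignores domain copy number within
  the set term and all sequence-level similarity; two clusters with the
  same domain inventory in the same adjacencies are indistinguishable even
  if their genes are unrelated by descent.
* Greedy centroid clustering is order-dependent by design (longest-first);
  it approximates, but does not reproduce, the behaviour of
  graph-clustering tools at the same threshold.
* NJ on non-additive (noisy) distances has no optimality guarantee; the
  exactness property holds for additive inputs only.
* The feature-table reader expects the package's documented 6-column
  dialect, not the NCBI `.tbl` submission format.
* Classification quality is bounded by the supplied category map; the
  shipped default is a floor, not a usable annotation resource.
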