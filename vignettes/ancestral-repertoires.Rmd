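---
title: "Inferring ancestral gene-family repertoires from gene trees"
author: "chsLineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestral gene-family repertoires from gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chsLineage)
```

## The problem

Multigene families grow and shrink: genes duplicate, drift into
pseudogenes, and disappear. Given gene models sampled from several
genomes and a rooted gene tree over them, we want to answer two
questions a comparative genomicist asks of any family. How many
distinct gene *lineages* — descendants of distinct gene copies in the
last common ancestor of the sampled species — does the extant diversity
trace back to? And which species retained, lost, or expanded each of
them?

chsLineage implements this inference for chalcone-synthase-like (CHS)
plant gene families, together with the two pieces of scaffolding the
inference needs to be trustworthy: an annotation stage that decides
which candidate gene models are functional members of the family, and a
birth–death simulator that provides gene trees with known ground truth
for validating the reconciliation machinery.

## The model

### LCA reconciliation

Both trees are rooted and binary; every gene-tree leaf carries a
species label. The reconciliation map is the classical
last-common-ancestor (LCA) mapping: a leaf maps to its species, and an
internal node $v$ maps to

$$M(v) = \mathrm{lca}_S\!\left(M(\mathrm{left}(v)),\, M(\mathrm{right}(v))\right),$$

computed bottom-up. A node is labelled a **duplication** iff
$M(v) = M(c)$ for at least one child $c$, otherwise a **speciation**.
This is the standard parsimony criterion; the alternative that requires
both children to share the node's image would miss duplications
followed by loss on one side, and is not used.

### Lineage decomposition

Let $D$ be the set of internal gene-tree nodes that are duplications
mapping to the species-tree **root**. These nodes represent duplication
events in (or before) the last common ancestor of the sampled species,
so the subtrees hanging below them are the ancestral repertoire. The
lineage roots are the gene-tree root when it is not in $D$, plus every
node outside $D$ whose parent is in $D$; each lineage root's clade is
one ancestral lineage and every leaf belongs to exactly one. Lineage
identifiers are assigned deterministically in pre-order of the lineage
roots.

This rule formalizes the verbal criteria used when reading gene
phylogenies by eye: a clade containing all species is one lineage; a
clade spanning the deepest species split, even with taxa missing, is
still one lineage; and a clade confined to a single species or a single
sub-clade of the species tree is a lineage precisely when it branches
off between root-spanning clades.

### Dollo losses

Within each lineage, presence is forced at the species-tree root
(single origin, no regain). A species-tree node is *present* iff it is
the root or an ancestor-or-self of a species carrying the lineage;
losses are the edges from a present parent to an absent child. This is
the minimum loss count compatible with root presence. Because the
decomposition already asserts that each lineage existed at the root,
the unconstrained parsimony alternative (origin at the MRCA of the
carriers) would contradict the decomposition for single-species
lineages; [dolloLosses()] reports the unconstrained count alongside for
comparison.

### Annotation

The canonical CHS architecture is two exons and one intron. The first
exon is variable and encodes 37–64 residues; the second is conserved
and encodes about 340 residues, carrying both the family signature and
the active-site region. [validateStructure()] therefore classifies a
candidate model as

* **functional** — two exons, exon-1 translation within the configured
  bounds, exon-2 translation within `exon2Target` ± `exon2Tol`, an
  intact ORF (start codon, terminal stop, no internal stop, length a
  multiple of three), and both configured motifs present in the exon-2
  translation;
* **pseudogene** — ORF disrupted (premature stop, missing start,
  frameshift-length CDS) but the family signature still detectable in
  at least one of the three forward reading frames of the exon-2
  region, so the model is recognizably a decayed family member;
* **rejected** — anything else, with reason codes for every failed
  check.

Tandem paralogs are named `<chromosome>-T<k>` in 5'→3' chromosomal
order (ascending start coordinate, irrespective of gene strand), with a
`ps` suffix for pseudogenes, which still consume an index. Rejected
models receive no name and no index. Equal start coordinates within a
chromosome are reported as an error rather than broken arbitrarily,
since no defensible tie rule exists.

Tunable parameters, all in `AnnotationConfig`:

| parameter | default | units | rationale |
|---|---|---|---|
| `exon1Min`, `exon1Max` | 37, 64 | aa | observed range of the variable first exon |
| `exon2Target` | 340 | aa | conserved second-exon length |
| `exon2Tol` | 10 | aa | strict equality would reject real paralogs; ±10 accepts small indels while excluding truncations |
| `signaturePattern` | `GCFAGGT` | regex over aa | placeholder in the style of the family's catalytic-cysteine signature |
| `activeSitePattern` | `GFGPG` | regex over aa | placeholder in the style of the conserved GFGPG loop |

The exact residues of the family signature and active site are
configuration, not constants: published gene structure figures shade
these regions without printing residue-level definitions, so the
defaults are stylistic placeholders and every correctness test plants
its own motifs through the generator. Real-data analyses should supply
motifs derived from their own alignment.

## The simulator

[simulateGeneFamily()] evolves `k` independent gene copies from the
species-tree root down a dated species tree: on a branch of length $t$
each live copy duplicates at rate $\lambda$ and dies at rate $\mu$
(exponential waiting times, rates per copy per million years); at
speciations every live copy enters both daughter branches. Extinct
subtrees are pruned and unary nodes suppressed during construction.
The $k$ surviving root copies are joined by zero-length edges at the
root — representing duplications that predate the root ancestor — so
the output is a single binary gene tree whose root-mapped duplications
delimit the true lineages, exactly the structure the decomposition
assumes.

Properties used for validation:

* with $\lambda=\mu=0$ every species carries exactly $k$ genes and each
  true lineage is a topological copy of the species tree;
* the expected copy number per species is $k\,e^{(\lambda-\mu)T}$ for an
  ultrametric tree of depth $T$ (linear birth–death expectation);
* recovered lineage count never exceeds the number of surviving root
  copies, with equality whenever every surviving copy has extant
  members on both sides of the species-root bipartition. When a copy
  survives only on one side, the parsimony decomposition merges it into
  a neighbour — an inherent, conservative bias of the criterion, not an
  implementation artifact.

Total extinction is reported, never resampled, so Monte-Carlo
estimators remain unbiased; per-replicate random streams are derived
deterministically from a single root seed.

What the simulator deliberately does not emulate: sequence evolution,
rate heterogeneity across branches, whole-genome duplications as a
distinct event class, and gene conversion between tandem copies.
Passing recovery tests therefore shows the reconciliation machinery is
correct under a neutral gain/loss process, not that real gene trees —
with alignment and inference error, hybridization, or conversion — will
be decomposed correctly.

## The canonical fixture

The worked example ships as code, not data. `rosidSpeciesTree()`
returns a 12-species ultrametric rosid tree (three Brassicales, cacao,
three Malpighiales, two Rosales, three Fabales) with root depth 107 my.
Node ages between the anchored root and tips are fixed once at
plausible values; the Fabales crown is set to 75 my, inside the
97–57 my window the analysis treats as given. `rosidGeneTree()` builds
the 70-leaf functional gene tree: six lineage subtrees on a backbone
ladder of five root-mapped duplications, within-lineage topologies
congruent with the species tree, and serial duplications for expanded
tandem arrays. Decomposing it yields six lineages whose composition
reproduces the published per-species totals (e.g. barrel medic 17,
soybean 15, the Fabales-restricted lineage 42 copies with sub-clade
counts 14/2 in medic, 11/2 in *Lotus*, and the complementary 2/11 in
soybean).

Choices the printed description leaves open were fixed once and frozen:
the backbone ladder order (red, yellow, brown, blue, green, pink —
any order keeps the five backbone nodes root-mapped duplications);
chromosome layouts per species (constrained only by the published
chromosome counts: soybean's 15 genes on seven chromosomes, single
chromosomes for thale cress, lyrate rockcress and castor bean);
low-copy sub-lineage counts (medic and *Lotus* carry 2 copies each in
their non-expanded Fabales paralog, the unique assignment consistent
with totals of 17, 15 and 42); and field mustard's four genes split 1+3
across the two Brassicales-duplication copies. Pseudogenes (2, 2 and 3
in medic, *Lotus* and field mustard) appear in the annotation inventory
with coordinates — so naming consumes their indices — but not in the
gene tree, matching the convention that repertoire counts cover
putatively functional genes only.

The sequence generator plants a two-exon gene for every inventory
record: exon 1 encodes `M` plus 36–63 random residues, exon 2 encodes
340 residues with the configured motifs at fixed offsets (active site
at residue 55, signature at 160) and a 100-bp `GT..AG` intron between
the exons; strands alternate along each chromosome. Pseudogenes reuse
the scaffold with a planted disruption alternating between an internal
stop codon and a 1-bp deletion, both leaving the signature detectable
by the three-frame scan. Everything is deterministic given one seed.

## Numerical and degenerate-input choices

* LCA images are found as the smallest species-tree clade containing
  the species below a node; test oracles recompute them independently
  by root-path intersection.
* Polytomies are rejected by default; an explicit flag resolves them
  deterministically (children ordered by smallest leaf label,
  zero-length edges) because silent resolution can manufacture or
  destroy duplications.
* Ties in tandem naming (equal start coordinates) are an error.
* An empty reconciled gene set produces a report with zero lineages; a
  single surviving functional gene produces one trivial lineage
  without invoking tree machinery (a one-leaf tree has no `phylo`
  representation).
* The simulator reports a `NULL` gene tree for total extinction and for
  single-gene survivals; the per-species census is authoritative in
  both cases.

## Validation problem sizes

The test suite checks the reconciliation primitives against brute-force
oracles exhaustively over every rooted binary gene-tree topology with
2–4 leaves under every species assignment onto a 4-species tree
(4,048 reconciliations), and over 500 simulated gene trees with up to a
few dozen leaves; Dollo losses are compared against exhaustive
enumeration of all presence labelings. Simulator calibration uses 2,000
pure-birth replicates for the expectation check and 500 replicates for
the recovery bounds. These sizes were chosen so the full suite runs
comfortably on a laptop while still covering the space where
reconciliation edge cases (duplications followed by losses, lineages
confined to one side of the root) actually occur; enumerating all
8-leaf gene trees would multiply the case count by roughly five orders
of magnitude without adding qualitatively new configurations.

## Known limitations

* The decomposition is a parsimony criterion: gene lineages whose
  survivors are confined to one side of the species-root bipartition
  can be absorbed into a sibling lineage, so the recovered count is a
  lower bound on the true root repertoire.
* Reconciliation trusts the input gene-tree topology; weakly supported
  nodes are not rearranged, and no probabilistic (likelihood-based)
  reconciliation is attempted.
* The annotation stage validates structure and motifs only; it neither
  discovers candidate loci (no similarity search) nor predicts
  enzymatic function.
* Duplication node ages are not estimated; dating is read off the
  species-tree calibration when needed.
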