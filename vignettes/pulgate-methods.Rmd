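---
title: "Mining polysaccharide utilization loci: models, rules and design choices"
author: "pulgate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining polysaccharide utilization loci: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulgate)
```

# The biological problem

During phytoplankton blooms, heterotrophic bacteria remineralize a large
share of the algal polysaccharides — soluble storage glucans such as
laminarin (β-1,3-glucan) and α-glucans, and less soluble structural or
secreted polysaccharides such as xylans, pectins, alginates and
fucoidans. The genes for this machinery are co-located in polysaccharide
utilization loci (PULs): in *Bacteroidota*, typically a *susCD* tandem —
a SusC-like TonB-dependent transporter (TBDT) channel gene adjacent to a
SusD-like substrate-binding protein gene — flanked by degradative
carbohydrate-active enzymes (CAZymes) and accessory genes such as
sulfatases. pulgate detects and classifies such loci in annotated contigs
and metagenome-assembled genomes (MAGs), predicts their target
substrates, and provides the coverage-, diversity- and linking statistics
used to compare free-living (FL, 0.2–3 µm) with particle-attached (PA3,
3–10 µm; PA10, > 10 µm) bacterial fractions.

# Cluster detection model

## Markers and the sliding window

A gene is a *marker* when it codes for a degradative CAZyme (a GH, PL or
CE family; GT, CBM and AA families are biosynthetic or auxiliary and do
not count), a sulfatase, a SusC-like or SusD-like protein, or another
TBDT. Detection slides a window of `windowLength` consecutive genes
(default 10) along each contig at step 1; a window containing at least
`minMarkers` markers (default 3) is a hit. The step of one gene is the
maximally sensitive reading of a sliding window and the standard one.

Hit windows overlap heavily, and loci — not windows — are the object of
interest, so overlapping or adjacent hit windows are merged into maximal
runs and each run is trimmed so that its first and last genes are
markers. Trimming makes spans deterministic and prevents double counting.
Windows never span contigs; a contig shorter than the window is assessed
as a single whole-contig window, so short contigs (common in fragmented
metagenome assemblies) are not silently unanalyzable.

## Tiers

Each locus is classified with strict precedence:

1. **PUL** — a susCD gene tandem plus at least one degradative CAZyme;
2. **PUL-like** — at least one susC-like, susD-like or other TBDT gene
   plus at least one degradative CAZyme (no tandem);
3. **CAZyme-rich** — at least three degradative CAZymes and no
   transporter gene;
4. **unclassified** otherwise (e.g. a locus of sulfatases only).

The precedence makes the tiers mutually exclusive, as tier counts
reported from such analyses are. Sulfatase genes count as markers for
*detection* but never as degradative CAZymes for *tier* tests — the two
roles come from two different definitions and we keep both literal.

A *susCD tandem* is operationalized as two genes at consecutive positions
along the contig, one carrying the SusC role and the other SusD, in
either order, on the same strand (`tandemPolicy = "same_strand_adjacent"`,
the default). Same-strand adjacency is the minimal testable form of the
co-transcribed tandem; `adjacent_any_strand` relaxes the strand clause
for annotations with unreliable strand calls. A gene whose strand was
missing in the source GFF is defaulted to "+" with a warning and flagged,
and flagged genes cannot anchor a tandem under the same-strand policy —
an imputed strand is not evidence of co-orientation.

## Multi-domain genes

Whether "at least 3 degradative CAZyme genes" counts genes or domains is
ambiguous for multi-domain proteins. By default every degradative family
instance counts (a GH13+GH31 gene contributes 2), matching how per-family
bar charts tally cluster content; `countGenesNotDomains = TRUE` restores
literal per-gene counting. The default changes tier assignments only for
loci whose degradative content is concentrated on fewer than three genes.

# Substrate prediction

Substrate classes come from a family → substrate map in dbCAN-sub style.
The packaged default (`inst/extdata/substrate_map.tsv`) is a curated
approximation assembled from canonical CAZy family/substrate
associations (e.g. GH16/GH17/GH149/GH158/GH30/GH3 → β-1,3-glucan;
GH13/GH31/GH57/GH65/GH77 → α-glucan; PL6/7/15/17/38 → alginate); the
exact vocabulary used by any particular annotation service is not
standardized, so the map is fully replaceable via
`readSubstrateMap(path)`. Lookups with a subfamily label (GH13_8) fall
back to the base family when no subfamily entry exists. For each class,
the supporting-gene count is the number of cluster genes with ≥ 1
degradative family mapping to it; a multi-substrate gene supports every
one of its classes, genes whose degradative families have no entry tally
under a reserved "unassigned" class, and output is sorted by descending
count then label, so the headline call is deterministic.

## Glucan typologies

Recurrent α-glucan PUL compositions are typed over the restricted
alphabet {GH13, GH31, GH57, GH65, GH77} (subfamilies collapsed, families
outside the alphabet ignored as accessory): type I = {GH13}; type II =
{GH13, GH65} or {GH13, GH65, GH31}; type III = {GH13, GH77, GH57};
type IV = {GH13, GH31}; anything else, including clusters without GH13,
is "none". β-glucan (laminarin) PULs are typed over {GH3, GH16, GH17,
GH30, GH149, GH158} with precedence GH16-only > variant-2 > variant-1:
GH16-only = exactly {GH16}; variant-2 = GH3 with GH16 or GH17 and
nothing else from the alphabet; variant-1 = at least 3 of the 5 hallmark
families {GH149, GH17, GH16, GH158, GH30}. The "≥ 3 of 5" reading
operationalizes variant rosters that occur "with variations" in real
genomes; the threshold is a parameter (`min_hallmarks`). Both typologies
are total functions on their subset lattices — the test suite enumerates
all 2^5 and 2^6 subsets against hand-built truth tables.

# Coverage-weighted gene frequencies

For a sample with per-gene average read-depth coverage, the frequency of
a target gene set is

$$\mathrm{frequency} = \frac{\sum \text{avg coverage of target genes} \times 100}{\sum \text{avg coverage of all genes}}$$

in percent. The statistic is scale-invariant (sequencing depth cancels)
and additive over disjoint target sets, so frequencies of any partition
of all genes sum to exactly 100. Per-substrate profiles are **not** a
partition: a gene mapping to several substrate classes contributes its
full coverage to each, which mirrors per-substrate panel plots where
overlapping membership is unavoidable; the sum-to-100 invariant is
therefore tested on explicit partitions. With taxon grouping, each class
frequency is split by gene taxon labels (missing labels pool under
"unclassified") and the components sum exactly to the class total.
Coverage semantics (per-base mean depth from read mapping) are taken as
given in the input table; pulgate never recomputes them from alignments.

# Community statistics

The alpha-diversity estimators are the classical closed forms, written
here directly because they are part of the package's analytical surface
(the independent cross-check in the tests is vegan): Shannon
$H = -\sum p_i \ln p_i$ (natural log by default — ecology convention —
with the base as a parameter), Gini–Simpson $1 - \sum p_i^2$ (the
dominance form is selectable), bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (default, because the classic
$S_{obs} + F_1^2/(2F_2)$ is undefined at $F_2 = 0$, which small fixtures
hit routinely; the classic form is selectable) and Good's coverage
$1 - F_1/N$. No rarefaction is applied before computing diversity;
`rarefyCounts()` provides seeded subsampling for explicit sensitivity
checks instead.

## ASV–MAG linking

An amplicon sequence variant (ASV) links to a MAG when it occurs as an
exact, mismatch-free substring of a MAG-derived 16S rRNA gene sequence on
either strand — the equivalent of a perfect blastn hit with 100%
identity over 100% of the (shorter) ASV query. Ambiguous bases are not
expanded: an ASV containing N can never link. All 16S copies of a MAG
are scanned and any hit links; strand is immaterial, because amplicon
orientation is a protocol artifact. MAGs without usable 16S genes
inherit links from near-identical relatives: every exact link extends to
MAGs with pairwise ANI ≥ 95% (inclusive — the conventional species
boundary) of the anchoring MAG, recorded with the anchor, without
transitive chaining (two sub-species steps can cross the species
boundary).

# MAG quality tiers

MAG quality follows MIMAG-style gating with the inequalities exactly as
conventionally printed: HQ requires completeness > 90 (strict),
contamination < 5 (strict), presence of 5S, 16S and 23S rRNA genes and
≥ 18 tRNAs; MQ requires completeness ≥ 50 (inclusive) and
contamination < 10 (strict). Genomically HQ-grade MAGs that miss only
the rRNA/tRNA clauses form a separate NEAR_COMPLETE tier rather than
being merged into HQ — they are commonly *treated* like HQ downstream,
so `summarizeTiers()` reports a pooled count, but the information is
preserved. Completeness and contamination are consumed from the input
table, never computed.

# The synthetic-data generator

The generator is the package's substitute for real sequencing data: it
emulates the *shapes* the pipeline consumes (Prokka/dbCAN-style gene
tables, per-gene coverage, ASV count matrices, 16S pools, ANI tables)
with planted ground truth, not the biology of real communities. Planted
clusters use templates drawn from the documented PUL rosters
(susC–susD–GH16/GH17/GH30 for laminarin; susC–susD–GH13/GH65/GH31 for
α-glucan type II; TBDT + alginate lyases; pectin-targeting CAZyme-rich
cassettes). Fixture defaults — 5 contigs × 60 genes, gene lengths
300–2400 bp with 20–200 bp gaps, background marker rate 0 (and 0.02 for
noise experiments), log-normal coverage (meanlog 2, sdlog 1), 16S pools
of random 1,500-mers with ASVs of 250–400 bp cut from them, ANI pairs
planted at 95.0 and 94.9 — are chosen once as realistic desk-scale
analogues of annotated bloom metagenomes. Sequence content is random
uniform because the linking logic is content-agnostic; what the
generator does *not* emulate (assembly fragmentation, chimeric bins,
annotation error beyond the Bernoulli marker noise, phylogenetic
structure, compositionality of counts) bounds what passing tests show
about real data: they validate the computations, not annotation quality.

Every generator derives an independent sub-stream from the master seed,
so adding a generator never perturbs existing fixtures, and all outputs
are byte-identical under a fixed seed. Planted clusters must be separated
by at least one detection window of non-marker genes (`min_separation`,
default 10) so that, at zero background rate, recovery is exact by
construction — recall and precision 1.0 for span, tier and substrate. At
a 2% background marker rate, merging with spurious neighbors can shift
locus boundaries, so recovery is asserted as coverage of the planted span
with recall ≥ 0.95 across seeds.

# Numerical and degenerate-input choices

- Coordinates are 1-based inclusive throughout (GFF convention);
  interval conversions live only in readers/writers.
- `geneFrequency` refuses zero total coverage (undefined ratio) and
  unknown target ids (silent dropping would bias numerators).
- Diversity estimators refuse empty and all-zero vectors; Chao1 requires
  integer counts.
- ANI tables may carry one or both orientations of a pair; where both
  are present they must agree to 1e-6.
- Substrate and tie-break orderings are always count-descending then
  alphabetical, so outputs are reproducible across platforms.
- Detection is invariant to input row order: tables are sorted by
  coordinate and indexed at construction.

# Problem sizes in the test suite

The suite runs entirely on generated data: 100 random contigs of up to
500 genes for the detector-vs-oracle equivalence, exhaustive tier
enumeration for all role/family combinations of loci up to 5 genes
(9,330 cases), the full 2^5 and 2^6 glucan subset lattices, 50 random
target sets over 1,000 genes for the frequency formula, a 100-ASV /
20-MAG linking fixture with 10 planted containments and 10 one-mismatch
decoys, and 1,000 random MAG quality records. These sizes were chosen to
exercise every rule boundary while keeping the whole suite fast on a
single CPU.

# Known limitations

- The packaged substrate map is an approximation; substrate calls are
  only as good as the map and the upstream CAZyme annotations.
- Tier definitions treat annotation flags as ground truth; no attempt is
  made to re-validate SusC/SusD calls from sequence.
- Operon structure, promoters and expression are out of scope: a
  detected PUL is a genomic hypothesis, not a validated function.
- The comparison of fractions (FL vs PA) is descriptive; pulgate provides
  the per-sample statistics, not the ordination or permutation tests
  built on them.
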