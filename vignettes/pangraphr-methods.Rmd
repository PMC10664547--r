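---
title: "Methods: pangenome-graph analytics in pangraphr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome-graph analytics in pangraphr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `pangraphr`,
the parameters that matter, the conventions adopted where several
defensible choices existed, and what the synthetic data used in the test
suite does and does not establish about real pangenomes.

## The graph model

A pangenome graph is a set of *segments* (nodes carrying DNA over
A/C/G/T/N), *links* (oriented edges), and *haplotype paths* — ordered,
oriented traversals, one per assembled haplotype, named by the PanSN
convention `sample#haplotype#contig`. One sample is designated the
reference; its paths define the linear coordinate system.

Conventions:

* **Links are a set.** An edge and its reverse-complement traversal are
  one object; links are stored with the lexicographically smaller
  oriented endpoint first, and duplicates are dropped.
* **Coordinates.** Segments are 0-based internally; every reported
  reference position is 1-based (VCF convention).
* **Strand.** A step traversed `-` contributes the reverse complement of
  its segment's sequence.
* **Mean degree** is links/segments, not the graph-theoretic 2E/N. This
  is the "edges attached to a node" ratio used when summarising
  assembled pangenome graphs, and the one under which 67M/49M and
  45M/33M both round to 1.4. Ratios are reported to one decimal;
  percentages to the nearest integer unless stated otherwise.
* **Path length vs traversed length.** A path may traverse a segment
  several times, so a haplotype carrying a tandem duplication of block B
  has path length A + 2B + C while the graph contains only A + B + C of
  sequence. Both quantities are computed (`pangenome_stats()`), and the
  difference is exactly the duplicated sequence.
* **PanSN fallback.** A path name with no `#` is treated as
  sample = contig = name, haplotype "0", so plain reference contig names
  are tolerated.
* **Projection.** A base inside an off-reference segment projects to the
  position of the last reference base preceding the segment along any
  haplotype path through it, flagged `on_reference = FALSE`. The first
  reference traversal wins for segments the reference path visits more
  than once (which a valid reference path should not do).

GFA v1.0/1.1 and GAF are parsed and written by the package itself: no
installed R package handles these graph formats, and both are simple
tab-separated records. Output ordering is deterministic (segments by id,
links lexicographic, paths by name) so identical graphs produce
byte-identical files. GAF `path_start`/`path_end` offsets are 0-based
with an exclusive end.

## Variant cataloguing from haplotype paths

Variants are derived from the paths, not from reads. The unit is the
*bubble*: a maximal interval between two *anchors* where at least one
haplotype's walk deviates from the reference walk.

**Anchor finding.** Anchors are nodes traversed exactly once by the
reference path and exactly once, in the same orientation, by a
haplotype, matched so that their order is consistent in both paths
(computed as a longest increasing subsequence of haplotype positions
ordered by reference position, O(n log n)); the per-haplotype anchor
sets are then intersected. On graphs whose shared nodes are single-copy
— which the generator guarantees and real bubble-clean graphs
approximate — this equals the longest common subsequence of the node-id
sequences, and it remains well defined when a duplication loop makes
nodes multi-copy in one haplotype (those nodes simply stop being
anchors, so the duplication becomes part of a bubble). A haplotype
sharing no anchors with the reference is reported as uncalled, not an
error.

**Record construction.** Each bubble becomes a variant record: the raw
edit (reference allele = concatenated reference walk, alternate =
haplotype walk, at the position following the left anchor) is normalised
by the standard trim-and-left-shift algorithm and anchored on the
preceding reference base. Consequences of this convention:

* SNVs pass through unchanged; insertions/deletions get a single anchor
  base; a tandem duplication's edit (block → block·block) left-aligns to
  an insertion at the start of the first copy. SVs are reported only as
  insertions and deletions — never inversions or translocations — with
  > 50 bp as the customary "structural" threshold in summaries.
* Ties in left-shifting cannot arise: the shift is deterministic and
  runs as far left as the reference sequence allows.

**Nested variation.** When the carriers of a bubble disagree among
themselves (e.g. an insertion whose copies differ at internal SNV
sites), the alternate walks are decomposed the same way: sub-anchors are
nodes single-copy in every alternate walk; per inter-anchor slot the
*consensus* allele is the one carried by most haplotypes, ties broken by
the lexicographically smaller sequence. The parent record's alternate
allele is the consensus; each deviation becomes a child record with
`PARENT` (the parent's id) and `SUBPOS` (1-based offset of the deviation
within the parent's alt allele string). When no clean nesting structure
exists the bubble is emitted as one multi-allelic record instead. This
mirrors how a graph represents an insertion as a biallelic event
(insertion or not) containing additional variable sites, rather than as
one allele per observed insertion sequence.

**Frequencies and genotypes.** The alternate-allele frequency is
carriers / called haplotypes, with the reference path counting as one
called haplotype — a 5-carrier SNV among 30 haplotypes is 5/30 → 17% at
integer precision. Haplotypes without anchors at a bubble get missing
genotypes and drop out of the denominator.

The *editing oracle* ties the catalogue to the sequences: applying a
haplotype's called alleles (children substituted into their parent's
allele first, edits applied right to left) to the reference sequence
must reproduce that haplotype's path sequence byte-exactly. The test
suite enforces this for every generator output, for both the truth set
and the called records.

## The synthetic pangenome generator

`generate_pangenome()` defines the study conditions for the test suite.
It draws a uniform-random reference, places variants by rejection
sampling, realises them as a graph, and emits the truth set already in
normalised VCF form.

* **Variant classes**: random SNVs (default rate 1e-3/bp) and small
  indels (1e-4/bp, geometric lengths with p = 0.5, insertions and
  deletions equiprobable), plus declared events: insertions with
  optional nested SNVs, deletions, tandem duplications, and a labelled
  element insertion defaulting to 7.5 kb — the scale of an endogenous
  retroviral insertion, an order of magnitude beyond what linear-reference
  short-read genotyping can recover.
* **Carrier sets**: explicit per event, otherwise uniform in size over
  the alternate haplotypes. Nested-SNV carriers are a strict minority of
  the insertion carriers so the consensus convention above is
  unambiguous.
* **Placement constraints** make the truth set exact rather than merely
  plausible: variants are non-overlapping with at least one invariant
  base between bubbles (so anchors exist), and event edges are resampled
  so that no indel can be left-shifted away from its placement (the last
  inserted base differs from the anchor base; the base after a deleted
  block differs from the anchor; the base before a duplicated block
  differs from its last base). Shared flanks are merged maximally, so
  bubbles are minimal.
* **Determinism**: one seeded RNG per run; identical configuration gives
  byte-identical GFA, FASTA and VCF.

What the generator does *not* emulate: real chicken chromosome
structure, repeat families, assembly errors, unphasable inbred lines, or
graph-construction artefacts (clipped non-reference sequence, spurious
edges). Tests passing on generator graphs therefore establish the
correctness of the algorithms under clean bubble topology, not the
behaviour of graph construction tools on real assemblies.

The K-locus fixture is a separate, fixed topology: backbone A–D1–D2–B–C–E
with a spacer-mediated loop (D2→S→D1) whose traversal duplicates the
D1–D2 block, and an optional element V between C and E. The seven
diagnostic links are labelled e1 (enter), e2 (duplication exit), e3/e4
(loop-back), e5 (element skip), e6/e7 (element entry/exit). Each sample
is hemizygous — one haplotype path — as for a Z-linked locus in female
birds.

## Read simulation and alignment accuracy

Fragments are sampled uniformly over valid start positions of the
selected paths, paths weighted by length; mate 1 is the forward prefix,
mate 2 the reverse-complemented suffix. Fragments are wholly contained
in the path (no clipping) so truth origins are unambiguous. Defaults:
150 bp reads, 400 ± 50 bp fragments.

The error model applies substitutions independently per base (default
0.0024, uniform among the three alternatives) and indel events per base
(default 0.00029, geometric lengths, insertion/deletion equiprobable).
Base qualities are a constant Q30 placeholder; downstream stages ignore
them. The empirical substitution rate is *measured*, not read off the
log: indel-free reads (per the event log) are compared base-by-base
against their source substring; the indel-event rate comes from the
event log over all simulated bases.

A read is *correct* if aligned to the truth reference name with a start
within a tolerance (default 100 bp — the windowed definition is assumed
since exact-vs-windowed is a comparison-tool detail); the accuracy curve
reports, for each mapq threshold 0–60, the fraction of **all** simulated
reads that are mapped, pass the threshold, and are correct, so unmapped
and missing reads count against every threshold and the curve is
monotone non-increasing.

## Edge-support SV genotyping

A read supports an edge iff its walk contains the oriented segment pair
(canonical form) *and* its aligned interval covers at least one base on
each side of the junction; a read ending exactly at the junction does
not count. Events may declare several presence (or absence) edges; the
bottleneck rule takes the minimum per-edge count, so an element
insertion requires support on both its entry and exit edges.

The genotyper is a two-hypothesis exact binomial test. With
k = presence-edge reads out of n = presence + absence reads, two-sided
p-values are computed under θ_present and θ_absent, and at level α
(default 0.05):

* `present` — carrier hypothesis retained, non-carrier rejected;
* `absent` — the reverse;
* `inconclusive` — both retained *or both rejected*;
* `no_data` — n below `min_reads` (default 4), distinguishing absence of
  evidence from evidence against.

Defaults: θ_present = 0.98 for a hemizygous insertion (an aligner error
allowance of ε = 0.02 on each side), θ_present = 0.5 for a hemizygous
tandem duplication — the carrier chromosome traverses the loop-back and
the exit junction once each, so informative reads split ~1:1 —
and θ_absent = 0.02 throughout. All are configurable; the published
procedure states the 0.05 cutoff and the inconclusive rule but not the
null probabilities or sidedness, so the symmetric two-sided formulation
was chosen and is documented rather than guessed elsewhere.

A consequence worth stating explicitly: at coverage ~30 the decision
rule *by construction* leaves a small fraction of true events
inconclusive (e.g. a true duplication observing 9 of 30 presence reads
has p = 0.043 under θ = 0.5 and essentially zero under θ = 0.02 — both
hypotheses rejected). The recovery tests therefore assert zero
present↔absent swaps, ≥ 99% correctness among conclusive calls, and an
inconclusive rate below 5%, rather than a raw 99% match rate that the
rule itself cannot attain.

## Reference bias

Pileups are built from aligned (match/mismatch) bases only: mapq < 10
removed, secondary/supplementary records excluded, read insertions
skipped, deletions contributing no base, base qualities ignored, and
depth capped (default 100) *in read order* — the first cap-many reads
overlapping a position are kept and later ones dropped, before any
downstream filtering. The cap-then-filter order is deliberate and
documented: a site whose uncapped depth exceeds the cap is judged on its
capped counts. BAM decoding and SAM→BAM conversion use Rsamtools; the
column counting is done in the package because the htslib iterator's
depth limit is approximate (it can overshoot by a few reads) while this
contract requires an exact cap.

A *putative heterozygous site* has capped depth ≥ 10 and a minor allele
— the second-most-frequent base, reference or not — at ≥ 25% of the
depth. The *alternate allele* is the most frequent non-reference base
(ties broken in A<C<G<T order); these two notions are distinguished
deliberately, since informal usage conflates them. Reference bias is
|mean alt fraction − 0.5| with the direction kept separately, and the
reduction between a linear-alignment and a graph-alignment run is
100·(bias_linear − bias_graph)/bias_linear, computed per sample and then
averaged when several samples are compared.

One estimator subtlety: conditioning on the ≥ 25% minor-fraction filter
truncates the binomial tails, so at depth 30 the conditional mean alt
fraction of sites with true alt probability 0.35 exceeds 0.35 by more
than 0.01 — a property of the filter, not an estimator defect. The
recovery tests therefore evaluate the mean at the *injected* site
positions, and test the filter itself exhaustively (all depth ≤ 30
count splits) against its defining rule.

## Genotype-set concordance

Two records match iff they share contig, position and reference allele
and have at least one alternate allele in common ("some" semantics);
records below the QUAL threshold (default 10) are dropped first, with
missing QUAL kept only when the threshold is 0. Genotype agreement is
computed on allele-*resolved*, unordered multisets — `0/1` equals `1/0`,
and a `2/2` against one ALT list can equal a `1/1` against a reordered
one — so matching survives allele reordering between files. A missing
genotype against a called one counts as disagreement; two missing
genotypes agree. Agreement is summarised per sample over shared sites
(mean and SD across samples) and per variant over samples; a sample with
no shared sites is reported NA and excluded from the mean.

## Accessory-sequence attribution

Given a base sample, all segments any of its paths traverse are removed
first; then, iteratively, each remaining sample's sum of remaining
traversed segment lengths is computed, the largest is recorded and its
segments removed, until no samples remain. "Either haplotype of this
bird" generalises to: any path whose PanSN sample field matches. Ties
are broken lexicographically by sample name (the published description
is silent; determinism is required for testing). Segments traversed by
no path are reported as residual, and the conservation identity
base + Σ contributions + residual = total graph length holds exactly.
Removal is interpreted genome-wide, the natural reading when the graph
holds all communities.

## Orchestration, problem sizes, and limitations

`run_demo()` chains the stages — simulate, catalogue, attribute,
genotype the K-locus fixture from simulated graph alignments, measure
bias on fabricated linear-vs-graph alignments (alt probabilities 0.46 vs
0.50), compare genotype sets — writing every artefact plus a JSON report
with md5 checksums; identical seeds give identical checksums. The
package's function surface, `run_demo()`, and `scripts/acceptance.R`
constitute its interface; no shell wrapper is shipped.

The test suite and acceptance script run at desk scale by design:
reference lengths of 5–100 kb, 6–30 haplotypes, a few thousand read
pairs (≥ 10^6 simulated bases where rate recovery is asserted, giving
3-standard-deviation binomial bounds), 200-graph oracle comparisons, and
2000 heterozygous sites per bias setting. These sizes make every
quantity exactly checkable against brute-force oracles; they are not
statements about runtime at chromosome scale. Known limitations: the
LIS-based anchor finding assumes the reference path is single-copy per
segment; bubble recursion beyond one nesting level is handled by the
same decomposition but is only exercised one level deep; the
multi-allelic fallback record does not attempt allele-tree
reconstruction; and none of the graph-construction, alignment or
surjection steps of a real pipeline are reimplemented here — their
outputs (GFA, GAF, SAM, VCF) are this package's inputs.
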