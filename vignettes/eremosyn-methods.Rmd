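---
title: "Methods: synteny, centromeres, telomeres, and GC landscapes in small yeast genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny, centromeres, telomeres, and GC landscapes in small yeast genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eremosyn)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, what the simulator emulates, and the numerical
and design choices made where the methods literature leaves the definition
open.

## The setting

Pre-WGD yeasts of the *Saccharomyces* complex (the *Eremothecium* clade
among them) carry compact genomes of roughly 4,700 genes on 6–8
chromosomes, with sequence-defined *point* centromeres, short telomeric
tandem repeats, and extensive but fragmented conservation of gene order
with each other and with the reconstructed pre-duplication ancestor.
Comparative questions about such genomes reduce to a small set of
computations: how genes pair up across species, how their order decomposes
into conserved blocks, where the centromeres and telomeres are, how GC
content varies along chromosomes, and what minimal series of rearrangement
events explains an observed block order.

## Data model

Coordinates are 0-based, half-open everywhere; GFF3 input (1-based,
closed) is converted on read. A `genome` is an ordered list of chromosomes,
each with an optional sequence over `{A,C,G,T,N}` and a feature table
(`gene_id`, span, strand, class in `{protein_coding, tRNA, rDNA,
transposon, other}`, and intron sub-intervals). An `ancestral_order` is the
gene-order-only counterpart used for ancestor comparisons: ordered gene
labels with strands and no base-pair coordinates.

Genome statistics follow the conventions of published comparison tables:
genome size excludes rDNA-class spans (rDNA copy number is assembly-
dependent), gene density is size/genes in kb at two decimals, coding DNA is
gene spans minus introns, and GC is computed over non-N bases. The gene
count reports exactly the protein-coding features provided; the package
takes no position on borderline gene models.

## Synteny blocks

An *anchor* is a one-to-one ortholog pair placed at its ordinal gene
position on each genome. A *block* is a maximal run of consecutive anchors
that share both chromosomes, have strictly increasing positions on genome A
(anchors are scanned in A order), strictly monotone positions on genome B
in one direction (the block's orientation), and ordinal gaps of at most
`max_gap_genes` on either side. The literature on these genomes reports
block counts without stating a formal block definition; maximal colinear
anchor chaining is the standard practice this package adopts. Defaults:
`max_gap_genes = 3` (absorbs small species-specific insertions, tRNAs, and
singleton losses), `min_anchors = 2` (a block must be attested by two
genes; leftover single anchors are reported separately as orphan
orthologs). Chaining is greedy left-to-right, so a gene that could extend
either of two adjacent blocks goes to the left one — a deterministic
tie-break. The test suite checks the chain against an independent
brute-force maximal-run enumerator on thousands of random instances.

Block statistics are computed on genome A coordinates only (ancestral
orders have none): per-chromosome counts, mean block span in kb, and the
half-genome block number *H* = the smallest *k* such that the *k* largest
blocks cover at least half the (non-rDNA) genome length. Mean block length
is the mean of block spans; inter-block gaps are excluded by construction,
so this figure is not exactly genome length divided by block count, and no
attempt is made to tune one toward the other.

## GC landscape

Profiles use fixed-step sliding windows (default 5 kb windows every 1 kb —
the trough scale is known, ~15 kb and larger, but no window parameters are
standard, so the window is set well below the target scale). Terminal
windows keep their true length; N bases are excluded from the denominator.
A trough is a maximal run of windows below mean − *z*·sd (defaults
*z* = 1, pooled over all windows), with overlapping runs merged and spans
below `min_trough_bp = 15000` discarded — the minimum reflecting the
reported extent of centromeric GC depressions in these genomes. Troughs
are labelled `centromere`, `telomere`, or `internal` by overlap with
caller-supplied annotations. This sliding-window thresholding deliberately
replaces the cumulative-deviation segmentation of external GC-profiling
tools: it is transparent, has two interpretable parameters, and its recall
and precision on planted dips are testable exactly.

## Telomere repeats

Telomeric arrays are tandem repeats of a short unit (24 bp in the
*E. cymbalariae* style) that degenerate with distance from the end. The
finder anchors at the chromosome end and, for every candidate period *p*
up to half the scan window, counts whole copies inward while adjacent
copies stay ≥ 90 % identical (the tolerance admits telomere degeneracy
while rejecting chance matches). The reported array is the one with the
largest copy number, ties to the shorter period. Copy number, not array
bp length, is the criterion: under a 10 % tolerance a spuriously long
period can absorb flanking non-repeat sequence into a "copy", whereas the
true unit always wins on copies; and if a divisor of a candidate period
generated the same array it would have more copies, so the reported period
is automatically minimal.

Repeat units are rotation- and strand-ambiguous (an array can be read in
any register on either strand), so units are canonicalized to the
lexicographically smallest rotation over both strands; the forward-strand
terminal copy and its reverse complement are also reported. The canonical
form may therefore be a rotation of the form a paper prints. Unit
distances are minimal Hamming distances over all rotations and the reverse
complement, which is what "differs by a single base" means for telomere
repeats.

## Point centromeres

The CDEI–CDEII–CDEIII scan looks for a CDEI consensus hit followed, across
an AT-rich spacer of 120–200 bp, by a CDEIII consensus hit, on both
strands. Defaults: CDEI `RTCACRTG` and a CDEIII core `TGTTTWTGNTTTCCGAA`
(both IUPAC, one mismatch tolerated), spacer AT fraction ≥ 0.7. The CDEII
bounds centre on ~160 bp — the *Eremothecium* spacer is about twice the
*S. cerevisiae* length — and the consensus defaults follow the
*S. cerevisiae* elements, which are strongly conserved across the complex;
all are configurable via `cde_config()`. Candidates are scored by
consensus matches plus spacer AT fraction; the best call per chromosome is
primary, overlapping weaker calls are collapsed, and the rest are kept as
secondary. The scan is strand-symmetric and translation-invariant, both
property-tested.

## Gene content

Presence/absence classification partitions each genome's protein-coding
set into shared (mapped in the A–B ortholog table), species-specific with
an outgroup homolog, and orphans. Tandem duplications are single-linkage
clusters of within-genome paralog pairs (identity ≥ 30 %, at most one
intervening gene by default — permissive enough for the 2–4-gene loci
described in these genomes); a duplication is conserved if at least two
members have orthologs in one duplication locus of the other genome.

Percent identity uses global Needleman–Wunsch alignment with fixed scoring
(match +1, mismatch 0, gap open −10, extend −1; identity = matches /
alignment columns × 100), so values are reproducible bit-exactly;
whether published mean identities derive from global or local alignments
is usually unstated, and global alignment is the choice documented here.
The histogram uses 5 %-wide bins over [20, 100]. Intron validation checks
the splice rule for these species: a 5′ `GT` donor, a 3′ `AG` acceptor,
and a `TACTAAC` branch motif ending at least 3 bp upstream of the
acceptor.

## Rearrangement scenarios

Block orders become signed permutations distributed over chromosomes.
Breakpoints are adjacencies (including chromosome-end caps) present in the
source but not the target, with an adjacency identified with its
reverse-complement reading. The scenario search is an exhaustive
bidirectional breadth-first search over the event vocabulary of this
literature — inversions, reciprocal translocations (prefix/suffix
exchange), telomeric translocations and fusions (the boundary-cut cases of
the same exchange), and fissions; transpositions are deliberately absent.
Every generator's inverse is in the set, so the state graph is undirected
and the meet-in-the-middle search returns a provably minimal scenario; the
search completes the frontier level on which the trees first meet and
takes the meet with the smallest summed depth. States are deduplicated by
a canonical form that sorts chromosomes by their smallest absolute label.
Chromosome orientation is *not* normalized away: a whole chromosome
reversed in the target counts as one inversion, which keeps scenario
lengths aligned with how events are counted in the literature (a single
flipped block is one inversion, not zero). A consequence is that
translocations join arms in their given orientation; an orientation-
flipping join costs one extra inversion. Operations are enumerated in a
fixed deterministic order, so results are reproducible across runs. The
hard cap of 10 elements keeps the search well under a minute; larger
instances should use `breakpoint_count()`.

The simulator's rearrangement events use exactly these semantics, so on
simulated histories the minimal scenario length never exceeds the number
of applied events — a property the tests exercise end to end.

## The simulator and what passing tests show

`sim_config()` defaults describe an *Eremothecium*-like study condition at
one-tenth scale so the full pipeline runs in seconds: 8 chromosomes × 60
genes (~1.5 kb genes, ~0.55 kb intergenics, i.e. ~2 kb/gene density), 40 %
background GC, 20 kb centromeric troughs at 25 % GC around a planted
CDEI + 160 bp AT-rich CDEII + CDEIII element, 24 bp telomere units in
20-copy arrays, a few tRNAs per chromosome, one planted rDNA region, and
occasional valid introns. The descendant history mirrors the inferred
evolution of these genomes: 8 inversions, 3 reciprocal and 1 telomeric
translocation, one centromere-loss arm translocation (both arms moved to
telomere-adjacent positions of two other chromosomes, chromosome count
8 → 7 with no gene loss), 3 % gene loss (~150 genes at full scale),
2 tandem duplications, 20 % intergenic contraction (genome streamlining
concentrated between ORFs), and 40 % per-site protein divergence giving
~60 % mean identity. The planted centromere trough keeps its absolute
15–20 kb scale rather than shrinking with the genome, since the trough
width is a biological constant the detector's `min_trough_bp` relies on;
simulated gene density is accordingly a little lower than the full-scale
figure.

Event cut points fall at intergenic midpoints away from planted
centromeres and telomere arrays, so no event splits a gene; draws that
collide are resampled under a retry cap. Events are applied in a fixed
order (rearrangements, duplications, losses, contraction, protein
divergence), every applied event is recorded with its realized coordinates,
and `replay_log()` reproduces the descendant byte-identically — the truth
log, not the random number generator, is the ground truth the tests
compare against.

Sequences are i.i.d. bases at target GC and proteins are random strings
mutated by substitution only. The simulator therefore does *not* emulate
codon structure, transposon sequence evolution, subtelomeric gene
families, GC-biased gene conversion, or indel evolution in proteins.
Passing tests show the algorithms recover planted structure under the
stated noise model; they do not certify performance on real assemblies,
where annotation error and alignment ambiguity dominate.

## Numerical choices and degenerate inputs

* Zero-gene genomes report an absent (`NA`) gene density; uniform-GC
  genomes (sd = 0) yield no troughs; a chromosome without a terminal array
  yields no repeat call (absence is a value, not an error).
* All-N windows are reported absent rather than zero.
* Many-to-many ortholog tables are rejected with an instruction to resolve
  first; resolution policy is the caller's (identity-ranked resolution is
  the usual choice and is deliberately not hard-coded).
* Ambiguous centromere-based chromosome assignments (one centromere
  matching two partners) raise an error listing the candidates rather than
  guessing; the `flank_bp = 20000` default matches the centromeric trough
  scale.
* Test problem sizes: property tests run on 8–30-anchor instances (1,000
  random trials for the chaining oracle), simulator runs use 2–8
  chromosomes of 8–63 genes, and scenario searches stay at ≤ 10 blocks;
  these sizes were chosen so the whole suite completes in about a minute
  while still exercising every code path at the study's structural scale.

## Known limitations

* Anchors use ordinal gene positions; unannotated intervening DNA does not
  affect chaining (by design), so blocks can bridge large unannotated gaps.
* `minimal_scenario()` is exhaustive by design and limited to desk-scale
  instances; no polynomial-time rearrangement-distance algorithm is
  included, and scenario minimality is relative to the stated operation
  semantics (orientation-preserving translocations).
* The locus-neighborhood comparison classifies relocation with a simple
  modal-chromosome-and-window rule; fine-grained micro-rearrangement
  typing is out of scope.
* Real-data workflows (downloading deposited chromosome accessions,
  resolving BLAST hit tables into one-to-one ortholog maps) are outside
  the package; homology is consumed as an input table.
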