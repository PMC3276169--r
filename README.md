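# eremosyn

Comparative genomics of small pre-whole-genome-duplication (pre-WGD) fungal
genomes in the *Saccharomyces* complex — the *Eremothecium* clade being the
motivating case. Given two annotated genomes (or a genome plus a
reconstructed ancestral gene order) and a one-to-one ortholog table, the
package answers the questions a comparative genome paper answers:

* **Genome statistics** — chromosome counts, genome size without rDNA, gene
  counts, gene density (kb/gene), coding fraction, intron and tRNA counts,
  GC content, laid out as the familiar two-column comparison table.
* **Synteny blocks** — ortholog anchors chained into maximal colinear runs,
  with per-chromosome block counts, mean block length, and the half-genome
  block number *H* (the smallest number of largest blocks jointly covering
  ≥ 50 % of the genome).
* **GC landscape** — sliding-window GC profiles and detection of AT-rich
  troughs (≥ 15 kb below mean − *z*·sd), labelled by overlap with
  centromeres and telomeres; point centromeres of these species sit in such
  troughs.
* **Point centromeres** — a CDEI–CDEII–CDEIII consensus scan (CDEI
  `RTCACRTG`; an AT-rich CDEII spacer of ~160 bp, about twice the
  *S. cerevisiae* length; a TGT-rich CDEIII core with the invariant
  `CCGAA`), on both strands.
* **Telomere repeats** — inference of the tandem-repeat unit at chromosome
  ends (period, copy number, canonical rotation; the *E. cymbalariae*-type
  unit is the 24-mer `CACACCGCTGAGAGACCCGTACAC`), and rotation/strand-aware
  unit distances.
* **Gene content** — shared/specific/orphan classification against an
  outgroup, tandem-duplication detection and cross-species conservation,
  percent-identity distributions from fixed-scoring global alignments, and
  intron validation against the 5′-GT…TACTAAC…AG-3′ splice rule.
* **Rearrangement scenarios** — block orders as signed permutations,
  breakpoint counts, and provably minimal event scenarios (inversions,
  reciprocal and telomeric translocations, fusion, fission) by exhaustive
  bidirectional breadth-first search on desk-scale instances (≤ 10 blocks).
* **A genome-evolution simulator** — ancestor/descendant pairs with planted
  centromeres, telomere arrays, GC structure, and a replayable ground-truth
  event log (inversions, translocations, centromere-loss arm
  translocations, gene losses, tandem duplications, intergenic
  contraction, protein divergence), used throughout the test suite.

## Worked example

Simulate an *Eremothecium*-like history at one-tenth scale (eight ancestral
chromosomes of 60 genes; one centromere-loss event reduces the descendant to
seven chromosomes) and run the analyses:

```r
library(eremosyn)

cfg <- sim_config(seed = 1)
anc <- simulate_ancestor(cfg)
ev  <- evolve(anc, cfg)

genome_statistics(ev$genome)
#> Genome statistics: desc
#>   Chromosomes            7
#>   Size without rDNA      1089 kb
#>   Genes                  457
#>   Gene density           2.38 kb/gene
#>   Gene coding DNA        687 kb (63.10%)
#>   Introns                25
#>   tRNAs                  16
#>   GC content             38.2%

cb <- chain_blocks(build_anchors(anc$genome, ev$genome, ev$orthologs))
block_statistics(cb$blocks, anc$genome)
#> Synteny block statistics
#>   chr1     1
#>   ...
#>   Total    27
#>   Mean block length  40.7 kb
#>   Half-genome block number  5

infer_telomere_repeat(anc$genome$chromosomes$chr1, "right", 2000)
#> <repeat_unit> chr1 right end: (CACACCGCTGAGAGACCCGTACAC)n, period 24 bp, 20.0 copies

tr <- detect_troughs(genome_gc_profiles(anc$genome),
                     centromeres = anc$genome$centromeres,
                     telomeres   = anc$genome$telomeres)
table(tr$label)
#> centromere
#>          8
```

The descendant has seven chromosomes and the full ancestral gene complement
minus the sampled losses; the 27 synteny blocks reflect the simulated
inversions and translocations; all eight planted centromeric AT troughs are
recovered and labelled; the telomere finder returns the planted 24 bp unit
at 20 copies. `run_comparison()` chains all stages and writes
`report.json`, `table1.tsv`, `table2.tsv`, and BED tracks for blocks,
troughs, telomeres, and centromeres.

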