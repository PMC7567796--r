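# HTGTSjunctions

Junction calling and classification for bait-primed translocation
sequencing (LAM-HTGTS) and locus-capture pull-down libraries, plus a
fully seeded synthetic-library generator so that every stage of the
pipeline can be validated against known ground truth without any
deposited data.

## The problem

Linear amplification-mediated high-throughput genome-wide translocation
sequencing (LAM-HTGTS) maps, at nucleotide resolution, the junctions
formed between a fixed "bait" double-strand break (here a RAG-induced
break at a J gene segment of an antigen-receptor locus) and "prey"
breaks genome-wide. Each informative read2 is a chimeric (split) read:
a bait-side segment ending at the bait breakpoint joined to a prey
segment from wherever repair joined the two ends. From such libraries
one can measure:

* **recombination and translocation rates** — junctions as a fraction of
  total bait-mapped reads, cis (V region) versus trans (other
  antigen-receptor loci, or elsewhere);
* **DNA end resection** — the distance from the prey breakpoint to the
  recombination signal sequence (RSS) cut site of the nearest annotated
  gene segment, measured toward both the coding and the signal end and
  capped at 4,000 nt; only V segments at least 4 kb from their nearest
  neighbour are used, so the assignment is unambiguous;
* **microhomology (MH)** — the length of the junction-spanning sequence
  shared by both parents (the junctional ambiguity window), the
  signature of alternative end joining;
* **untemplated insertions** — read bases at the junction that extend
  neither parent.

The package implements the read2 decision tree used for such libraries:
reads are classified as `germline` (unsplit, inside the bait-to-J2
germline window), `mapped_gt75` (unsplit, >75% of the read mapped
elsewhere), `unique_repeat` (split with a breakpoint in an annotated
repeat), `split_join_adjacent_J` (bait alignment crossing the bait RSS,
i.e. a join primed from an upstream J cut), or `split_join_bait` (a
bona fide bait junction, with prey classified as cis V region, trans
AgR, or trans non-AgR). Capture mode classifies merged pull-down reads
into V-V joins (span > 2 kb), V-J joins, germline and short deletions
(span < 2 kb), with 100-bp binning of breakpoints.

## Worked example

```r
library(HTGTSjunctions)

## simulate a library in the long-resection regime of cycling
## XRCC4/p53-deficient cells: mean resection 730.1 nt, 58.5% of joins
## with 2-6 bp MH
sim <- simPreset("xrcc4p53_released", seed = 1L, nPairs = 5000L)
lib <- simulateLibrary(sim)

res <- analyzeLibrary(lib$reads1, lib$reads2, lib$genome, lib$annotation,
                      libraryId = "demo")
res$summary
```

```
LibrarySummary 'demo'
  total mapped reads: 5000
  labels: germline=2804 mapped_gt75=166 unique_repeat=152 split_join_adjacent_J=158 split_join_bait=1720 other_filtered=0
  junctions (cis V region): 1401 (28.020%)
  translocations (trans AgR): 160 (3.2000%)
  junction features: n=1720, mean resection 716.8 nt, MH 2-6 bp 58.7%
```

About 55% of pairs are unrearranged germline reads, ~30% cis V-region
junctions, and a few percent each of translocations, repeat joins,
adjacent-J joins and long mapped reads (the generator's default mix).
The feature summary shows the pipeline-recovered mean resection and MH
fraction for the junction reads; with junction-only libraries of 20,000
reads these recover the configured 730.1 nt and 58.5% within sampling
error (see the acceptance script). Arc tables and bedGraph tracks for
genome browsers come from `exportArcs()` and `exportTrack()`:

```r
exportTrack(res$junctions, binSize = 1000)     # bedGraph data.frame
exportArcs(res$junctions, minReads = 5)        # arc table, sparse bins suppressed
```

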