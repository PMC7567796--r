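---
title: "Calling and classifying bait-primed break-repair junctions"
author: "HTGTSjunctions authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying bait-primed break-repair junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HTGTSjunctions)
```

## The measurement model

In a LAM-HTGTS library, linear amplification from a bait primer at the
3' side of a J gene segment enriches fragments containing the bait
double-strand break. Read1 starts with the bait primer; read2 enters
the fragment from the other end and, for rearranged molecules, spans
the junction between the bait coding end and a prey sequence. After
alignment, an informative read2 decomposes into a bait-side part whose
reference interval lies between the bait primer and the bait RSS
(recombination signal sequence) cut site, and a prey part elsewhere in
the genome.

All coordinates in the package are 0-based half-open; a breakpoint is
the boundary between two bases. SAM input is converted on ingestion and
bedGraph output uses the same convention natively.

The classifier (`classifyReads()`) applies six rules in fixed order;
the order resolves the overlaps the prose definitions leave open (for
instance, a split repeat-joined read that also touches the bait window
is a repeat read, because the repeat rule precedes the bait rule):

1. unsplit and contained in the germline window -> `germline`;
2. unsplit with more than 75% of the (post-trim) read mapped ->
   `mapped_gt75` (strict inequality, computed on the trimmed length);
3. split with a junction-facing alignment edge inside an annotated
   repeat -> `unique_repeat`;
4. split with the bait-side part crossing the bait RSS cut away from
   the primer -> `split_join_adjacent_J` (the break most plausibly
   originated from an upstream J cut followed by resection);
5. split with the bait-side part between the RSS cut and the primer ->
   `split_join_bait`, with the prey categorized by genomic region
   (cis V region / trans AgR / trans non-AgR, resolved with fixed
   priority bait > germline > V region > AgR > repeat > other);
6. anything else -> `other_filtered` (including reads with more than
   three parts).

The bait-side part is the part with the smallest query start, because
read2 always enters from the bait side of the fragment.

### Microhomology and insertions

Microhomology is defined as the junctional ambiguity window: the
maximal stretch of read sequence across the junction that is identical
in both parental genomic sequences, so that the exact breakpoint could
be placed anywhere within it. Junctions are reported *right-anchored*:
the breakpoint pair sits at the bait-most edge of the window, matching
the convention of the built-in aligner, whose parts are maximal exact
matches. `computeMHInsertion()` validates a query overlap base by base
against both parents; overlap bases that fail validation (sequencing
errors) shorten the reported MH, which is part of the measurement
model. For a query gap, gap bases that extend either parent are
reassigned to that side and only the remainder counts as untemplated
insertion. Because external local aligners (e.g. BWA-MEM) do not
guarantee maximal extension, MH can be undercalled on imported SAM
files; the built-in aligner does not have this problem.

### Resection

`computeResection()` assigns each junction to the eligible segment
whose RSS cut is nearest the prey breakpoint on the same chromosome,
within a 4,000 nt cap, and reports the unsigned distance plus the side
(coding or signal, with the cut itself counted as coding; equidistant
cuts resolve to the lexicographically smaller segment name). Segment
eligibility (`eligibleSegments()`) removes V segments closer than 4 kb
to another V segment, so the nearest-cut assignment is well defined;
junctions without a cut within the cap are excluded from resection
statistics but counted separately.

## The synthetic-library generator

The generator exists so that every stage of the pipeline can be tested
against exact ground truth. `buildMiniGenome()` lays out a bait
chromosome (primer, bait J, three downstream Js — the second bounds
the germline window — and an array of V segments), an AgR-like
chromosome with two named loci, and a third chromosome carrying a
planted repeat family plus unique background. The default inter-V gap
is 8,000 bp, more than twice the resection cap, so that no resection
up to the cap can be attributed to the wrong segment; the 4-kb
eligibility filter then keeps every V segment, as it does for the
annotated locus the default 144-segment array mirrors.

Simulated categories and their default mix (55% germline, 30% cis
junctions, 3% each of AgR translocations, non-AgR translocations,
repeat joins, adjacent-J joins and long mapped reads) are configurable
through `simConfig()`. Resection is drawn per junction from a
geometric distribution (short-resection regimes) or a lognormal capped
at 4,000 nt. The lognormal is parameterized by its *post-cap* mean —
`meanlog` is solved numerically so that E[min(X, cap)] equals the
configured mean — because otherwise the cap would silently shift the
realized mean a few percent below the configured value. Insertions
(mutually exclusive with MH > 0) have a configurable probability and a
uniform 1-6 nt length; inserted bases are drawn so they extend neither
parent, making the truth exact.

### Why microhomology needs a tract layout

MH cannot simply be "drawn per junction": it is a property of the
genome at the two breakpoints, and junctions that land near one another
share flank sequence. If breakpoints sit d bases apart, the MH of the
right one is either independent of the left (a fresh tract of length
0..d-1) or exactly the left one's MH plus d (a continued tract). At
the junction densities of the short-resection regimes (tens of
thousands of junctions concentrated within tens of bases of each RSS
cut) these couplings are unavoidable — they are equally present in
real libraries, where MH is genome-determined.

The generator therefore realizes MH structurally:

* the bait coding end terminates in a 12-bp mononucleotide tract
  (a base X different from the base Y at the cut), so every junction's
  MH tract is simply a run of X ending at its prey breakpoint, and
  overlapping tracts of different junctions are consistent by
  construction;
* tract lengths are assigned per distinct breakpoint in one
  left-to-right sweep against a quota pool holding the configured MH
  distribution over the library's junctions (weighted by each
  breakpoint's junction multiplicity). Isolated breakpoints draw from
  the pool directly; dense stretches of consecutive breakpoints are
  solved by a short-horizon dynamic program so that runs can climb
  through short lengths to reach under-filled longer ones;
* run boundaries are explicitly broken (and the junction point itself
  kept different from Y) so every junction is right-anchored with
  exactly its assigned MH.

A final realization pass recomputes MH, insertion, canonical
breakpoints and resection for every record from the finished genome,
so the emitted truth table is exactly consistent with the rendered
reads. At 20,000 junction reads the realized 2-6 bp MH fraction
matches the configured one to within a few tenths of a percentage
point in all three experimental regimes, and the pipeline recovers the truth
table exactly on error-free reads.

What the generator does *not* emulate: PCR duplicates, sonication
fragment-length structure, base-quality profiles (qualities are a
constant Phred 35 and never used), bait-side resection (the bait break
sits at the bait RSS cut), and minus-strand prey fragments (prey
sequence is always read in the plus orientation; the pipeline measures
only the unsigned distance and side label, which are orientation-free).
Passing tests on simulated data therefore validate the calling logic
and its thresholds, not robustness to those real-data features.

## Study-regime presets

`simPreset()` encodes the three regimes used throughout the tests and
the acceptance script:

| preset | resection model | 2-6 bp MH | insertions |
|---|---|---|---|
| `wt_ablki` | geometric, mean 3.5 nt | 17.3% | 32.2% |
| `xrcc4_g1` | geometric, mean 7.5 nt | 43.3% | 7.5% |
| `xrcc4p53_released` | lognormal (sdlog 0.8), post-cap mean 730.1 nt | 58.5% | 5% |

The released-regime insertion fraction is not reported for that
condition and is fixed once at 5%, between the G1 XRCC4-deficient
value and zero, reflecting that alternative end joining products are
poor in TdT additions. The lognormal shape parameter (sdlog 0.8) is a
package choice: it spreads resection over the hundreds-to-thousands of
nucleotides range with a sub-percent tail beyond the 4-kb cap.

## The built-in aligner

`naiveAlign()` is an exact seed-and-extend split-read aligner for
mini-genome work: the first and last 24 bases of each read are matched
exactly (both strands, multi-pattern matching), every hit is extended
to a maximal exact match, and the maximal placement(s) of each end are
kept. Query intervals of the two parts may overlap by up to 20 bases
(the MH window); larger overlaps collapse to the longer single part.
Parts on the same chromosome and strand whose reference gap equals the
query gap are re-merged, which heals reads split by isolated
sequencing errors. `n_candidates` counts equally maximal placements;
multi-candidate parts get mapq 0 (and are tolerated by the quality
filter only when all their placements lie in annotated repeats).
Reads with an error inside a terminal anchor lose that part — at
realistic error rates a few percent of reads — which is acceptable
for validation work but is why production libraries would be aligned
externally and ingested via `loadSAM()`.

## Numerical and edge-case choices

* Thresholds are strict as documented: bait prefix >= 20 nt, merge
  overlap >= 10 nt, mapq < 10 drops, V spacing >= 4,000 bp keeps,
  resection <= 4,000 nt assigns; a capture span of exactly 2,000 bp is
  neither a V-V join nor a short deletion and is left `unclassified`.
* The `mapped_gt75` rule uses strict `>` on 0.75 x the post-trim read
  length.
* Empty inputs yield empty tables or all-zero summaries, never errors;
  a zero reference count in `foldEnrichment()` yields `Inf` with an
  `undefined` attribute rather than an exception.
* Percentages print via IEEE round-half-to-even (`formatPercent()`);
  numeric comparisons in tests use tolerances, not strings.
* All randomness is governed by the single `SimConfig` seed; rerunning
  a simulation reproduces FASTQ/SAM/TSV files byte for byte.

## Problem sizes

The test suite simulates libraries of a few hundred to 3,000 read
pairs for module tests and 20,000 junction reads per regime for the
parameter-recovery checks; the acceptance script uses 20,000 junction
reads per regime. These sizes put sampling error well below the
tolerances being checked while keeping a full run in the minutes
range.

## Known limitations

* MH calling on externally aligned SAM assumes near-maximal local
  alignments; heavily soft-clipped aligners can undercall MH.
* Bait-anchored calls only: prey-to-prey junctions and mate-1-based
  calling are out of scope.
* The capture mode classifies merged reads; unmerged-pair geometry is
  not used.
* The generator's MH layout controls the library-level distribution
  exactly, but in saturated regions neighboring junctions' MH values
  are structurally coupled (descending runs), as they necessarily are
  in any shared-genome model.
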