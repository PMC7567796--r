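## shared in-code fixtures: tiny genomes, annotations and simulated
## libraries built at test time.

## a hand-sized two-chromosome genome with a deterministic sequence
tinyGenome <- function(seed = 11L, lenA = 60000L, lenB = 30000L) {
  set.seed(seed)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  Biostrings::DNAStringSet(c(chrA = mk(lenA), chrB = mk(lenB)))
}

## matching annotation: bait J at 1kb, three downstream Js, V segments with
## configurable gaps
tinyAnnotation <- function(genome, vStarts = c(20000L, 30000L, 40000L),
                           vLen = 300L) {
  jSeg <- data.frame(
    chrom = "chrA", start = c(1020L, 3000L, 5200L, 7500L),
    end = c(1320L, 3300L, 5500L, 7800L),
    name = c("J4", "J3", "J2", "J1"), strand = "+", klass = "J",
    rss_cut = c(1320L, 3000L, 5200L, 7500L),
    coding_side = c("left", "right", "right", "right"))
  vSeg <- data.frame(
    chrom = "chrA", start = vStarts, end = vStarts + vLen,
    name = sprintf("V%03d", seq_along(vStarts)), strand = "+", klass = "V",
    rss_cut = vStarts, coding_side = "right")
  locusAnnotation(
    segments = rbind(jSeg, vSeg),
    baitSegment = "J4", baitPrimerPos = 1000L,
    chromLengths = stats::setNames(Biostrings::width(genome), names(genome)),
    vRegion = data.frame(chrom = "chrA", start = min(vStarts) - 4500L,
                         end = max(vStarts) + vLen + 4500L),
    agrRegions = data.frame(chrom = "chrB", start = 5000L, end = 12000L,
                            name = "Igl"),
    repeatRegions = data.frame(chrom = "chrB", start = 20000L, end = 20400L))
}

## fractions for a junction-only library (acceptance regimes)
junctionOnlyFractions <- c(
  germline = 0, bait_junction_cis = 1, translocation_agr = 0,
  translocation_nonagr = 0, repeat_join = 0, adjacent_j_join = 0,
  long_mapped = 0)

## default mixed-category fractions of simConfig(), by name
mixedFractions <- eval(formals(simConfig)$fractions)

## brute-force junction-ambiguity oracle: number of alternative junction
## placements (shifts) consistent with both parental sequences, minus one.
## Works directly on the genome and the truth breakpoints, independently of
## the alignment-based caller.
mhOracle <- function(genome, baitChrom, baitBreak, preyChrom, preyBreak,
                     window = 30L) {
  gb <- as.character(genome[[baitChrom]])
  gp <- as.character(genome[[preyChrom]])
  consistent <- function(s) {
    if (s == 0L) return(TRUE)
    if (s > 0L)
      substr(gb, baitBreak + 1L, baitBreak + s) ==
        substr(gp, preyBreak + 1L, preyBreak + s)
    else
      substr(gb, baitBreak + s + 1L, baitBreak) ==
        substr(gp, preyBreak + s + 1L, preyBreak)
  }
  n <- 0L
  s <- 1L
  while (s < window && consistent(s)) { n <- n + 1L; s <- s + 1L }
  s <- -1L
  while (s > -window && consistent(s)) { n <- n + 1L; s <- s - 1L }
  n
}

## run the full pipeline on an in-memory simulated library
runPipeline <- function(lib, ...) {
  analyzeLibrary(lib$reads1, lib$reads2, lib$genome, lib$annotation, ...)
}
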