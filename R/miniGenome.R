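## synthetic mini-genome: a bait J cluster plus an upstream-style V array on
## one chromosome, AgR-like loci on a second, and a planted repeat family plus
## unique background on a third. Deterministic for a fixed seed.

#' Build a synthetic mini-genome and its locus annotation
#'
#' The bait chromosome carries, in read direction: the bait primer site, the
#' bait J segment (RSS cut on its far side), two to three further J segments
#' (the second bounds the germline window), then an array of V segments whose
#' RSS cuts face the bait. A second chromosome carries two AgR-like intervals
#' and a third carries a planted repeat family plus unique background used
#' for non-AgR translocations.
#'
#' @param config named list overriding any of: \code{nV} (number of V
#'   segments, default 144), \code{vLen} (300), \code{vGap} (inter-V gap,
#'   default 8000 bp, more than twice the 4-kb resection cap so nearest-RSS
#'   assignment is unambiguous for any resection up to the cap), \code{nJ}
#'   (default 4: bait plus three downstream), \code{repeatCopies} (2),
#'   \code{repeatLen} (400), \code{repeatDivergence} (0.05; 0 makes copies
#'   identical and hence ambiguous to map), \code{chrALen} (optional; error
#'   if the segments do not fit).
#' @param rngSeed integer seed; the genome is byte-identical across runs with
#'   the same seed and config.
#' @return list with \code{genome} (\link[Biostrings]{DNAStringSet}) and
#'   \code{annotation} (\linkS4class{LocusAnnotation}).
#' @export
buildMiniGenome <- function(config = list(), rngSeed = 1L) {
  cfg <- modifyList(list(
    nV = 144L, vLen = 300L, vGap = 8000L, nJ = 4L,
    repeatCopies = 2L, repeatLen = 400L, repeatDivergence = 0.05,
    chrALen = NULL, primerPos = 1000L
  ), config)
  stopifnot(cfg$nV >= 1L, cfg$nJ >= 2L, cfg$nJ <= 4L, cfg$vGap > 0)
  set.seed(as.integer(rngSeed))

  primerPos <- as.integer(cfg$primerPos)
  jNames <- c("J4", "J3", "J2", "J1")[seq_len(cfg$nJ)]
  jStarts <- c(primerPos + 20L, 3000L, 5200L, 7500L)[seq_len(cfg$nJ)]
  jLen <- 300L
  ## bait J: coding between primer and RSS (cut on the far side);
  ## downstream Js: RSS cut on the bait-facing edge.
  jSeg <- data.frame(
    chrom = "chrA", start = jStarts, end = jStarts + jLen, name = jNames,
    strand = "+", klass = "J",
    rss_cut = c(jStarts[1] + jLen, jStarts[-1]),
    coding_side = c("left", rep("right", cfg$nJ - 1L))
  )

  vFirst <- 20000L
  vStarts <- vFirst + (seq_len(cfg$nV) - 1L) * (cfg$vLen + cfg$vGap)
  vSeg <- data.frame(
    chrom = "chrA", start = vStarts, end = vStarts + cfg$vLen,
    name = sprintf("V%03d", seq_len(cfg$nV)),
    strand = "+", klass = "V", rss_cut = vStarts, coding_side = "right"
  )

  needA <- max(vSeg$end) + cfg$vGap + 1000L
  chrALen <- if (is.null(cfg$chrALen)) needA else as.integer(cfg$chrALen)
  if (chrALen < needA)
    stop(sprintf("requested segments exceed chromosome capacity: need %d bp, chrALen = %d",
                 needA, chrALen), call. = FALSE)

  chrBLen <- 60000L
  chrCLen <- 60000L
  randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
  chrA <- randSeq(chrALen)
  chrB <- randSeq(chrBLen)
  chrC <- randSeq(chrCLen)

  ## plant the repeat family on chrC
  unit <- randSeq(cfg$repeatLen)
  copyStarts <- as.integer(seq(5000L, by = 9000L, length.out = cfg$repeatCopies))
  if (max(copyStarts) + cfg$repeatLen > 28000L)
    stop("repeat copies exceed the reserved chrC region", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  for (s in copyStarts) {
    cp <- unit
    if (cfg$repeatDivergence > 0) {
      ch <- strsplit(cp, "")[[1]]
      mut <- which(runif(cfg$repeatLen) < cfg$repeatDivergence)
      for (i in mut) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
      cp <- paste(ch, collapse = "")
    }
    substr(chrC, s + 1L, s + cfg$repeatLen) <- cp
  }

  genome <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB, chrC = chrC))
  ann <- locusAnnotation(
    segments = rbind(jSeg, vSeg),
    baitSegment = "J4",
    baitPrimerPos = primerPos,
    chromLengths = c(chrA = chrALen, chrB = chrBLen, chrC = chrCLen),
    vRegion = data.frame(chrom = "chrA",
                         start = vFirst - 4500L,
                         end = max(vSeg$end) + 4500L),
    agrRegions = data.frame(chrom = "chrB",
                            start = c(10000L, 35000L),
                            end = c(20000L, 45000L),
                            name = c("Igl", "Igh")),
    repeatRegions = data.frame(chrom = "chrC",
                               start = copyStarts,
                               end = copyStarts + cfg$repeatLen)
  )
  list(genome = genome, annotation = ann)
}

#' Bait primer sequence from the genome
#'
#' The primer is the genomic sequence at the bait primer position, read in
#' the bait orientation (toward the bait RSS cut).
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param len primer length in bp.
#' @export
baitPrimerSeq <- function(genome, annotation, len = 20L) {
  chr <- as.character(genome[[baitChrom(annotation)]])
  p <- baitPrimerPos(annotation)
  if (baitRSS(annotation) >= p) {
    substr(chr, p + 1L, p + len)
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chr, p - len + 1L, p))))
  }
}
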