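## end-to-end analysis of a bait-primed library.

#' Analyze a bait-primed junction library
#'
#' Runs the full pipeline on a read-pair library: bait-primer filtering on
#' read1, optional 3' adapter trimming, split-read alignment of read2 (the
#' built-in aligner, or parts supplied from a SAM file), mapping-quality
#' filtering, the read2 decision tree, microhomology/insertion calling,
#' RSS-anchored resection, and a library summary.
#'
#' @param reads1,reads2 named character vectors (e.g. from [readFastq()]).
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param annotation \linkS4class{LocusAnnotation}.
#' @param libraryId identifier for the summary.
#' @param baitSeq bait sequence for the read1 filter; default: genomic
#'   sequence at the primer site.
#' @param adapter optional adapter to trim from 3' ends.
#' @param parts optional pre-computed alignment parts (e.g. [loadSAM()]);
#'   when NULL read2 is aligned with [naiveAlign()].
#' @param minBait,maxMismatch bait-filter settings.
#' @param minMapq mapping-quality threshold.
#' @param resectionCap resection cap in nt.
#' @param minSpacing eligibility spacing for resection segments.
#' @param translocationLoci AgR names counted as translocations (default
#'   all).
#' @return list: \code{summary} (\linkS4class{LibrarySummary}),
#'   \code{classes}, \code{junctions} (with features), \code{featureSummary},
#'   \code{log} (per-stage read accounting).
#' @export
analyzeLibrary <- function(reads1, reads2, genome, annotation,
                           libraryId = "library", baitSeq = NULL,
                           adapter = NULL, parts = NULL,
                           minBait = 20L, maxMismatch = 2L, minMapq = 10L,
                           resectionCap = 4000, minSpacing = 4000,
                           translocationLoci = NULL) {
  stopifnot(identical(names(reads1), names(reads2)))
  log <- list(input = length(reads1))
  if (is.null(baitSeq))
    baitSeq <- baitPrimerSeq(genome, annotation, len = max(minBait, 20L))
  keep <- baitFilter(reads1, baitSeq, minBait = minBait,
                     maxMismatch = maxMismatch)
  reads2 <- reads2[keep]
  log$bait_filtered <- sum(!keep)
  if (!is.null(adapter)) reads2 <- trimAdapter(reads2, adapter)
  if (is.null(parts)) {
    parts <- naiveAlign(reads2, genome)
  } else {
    parts <- parts[parts$read_id %in% names(reads2) & parts$mate == 2L, ,
                   drop = FALSE]
  }
  log$unmapped <- sum(!names(reads2) %in% parts$read_id)
  qf <- qualityFilter(parts, annotation, minMapq = minMapq)
  log$quality_filtered <- nrow(qf$log)
  cl <- classifyReads(qf$parts, annotation, readLens = nchar(reads2))
  junctions <- computeMHInsertion(cl$junctions, reads2, genome)
  junctions <- computeResection(junctions,
                                eligibleSegments(annotation, minSpacing),
                                cap = resectionCap)
  feats <- summarizeFeatures(junctions, cap = resectionCap)
  tab <- tabulateClasses(cl$classes)
  log$classified <- tab$total
  list(summary = librarySummary(libraryId, tab, junctions, feats,
                                translocationLoci = translocationLoci),
       classes = cl$classes,
       junctions = junctions,
       featureSummary = feats,
       log = log)
}
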