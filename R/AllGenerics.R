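#' @rdname LocusAnnotation-class
#' @param x a \linkS4class{LocusAnnotation}
#' @export
setGeneric("geneSegments", function(x) standardGeneric("geneSegments"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("baitSegment", function(x) standardGeneric("baitSegment"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("baitPrimerPos", function(x) standardGeneric("baitPrimerPos"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("baitRSS", function(x) standardGeneric("baitRSS"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("baitChrom", function(x) standardGeneric("baitChrom"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("baitWindow", function(x) standardGeneric("baitWindow"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("germlineWindow", function(x) standardGeneric("germlineWindow"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("vRegion", function(x) standardGeneric("vRegion"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("agrRegions", function(x) standardGeneric("agrRegions"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("repeatRegions", function(x) standardGeneric("repeatRegions"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname LocusAnnotation-class
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

setMethod("geneSegments", "LocusAnnotation", function(x) x@segments)
setMethod("baitSegment", "LocusAnnotation", function(x) x@baitSegment)
setMethod("baitPrimerPos", "LocusAnnotation", function(x) x@baitPrimerPos)
setMethod("baitRSS", "LocusAnnotation", function(x) {
  x@segments$rss_cut[x@segments$name == x@baitSegment]
})
setMethod("baitChrom", "LocusAnnotation", function(x) {
  x@segments$chrom[x@segments$name == x@baitSegment]
})
setMethod("baitWindow", "LocusAnnotation", function(x) {
  r <- baitRSS(x)
  c(min(x@baitPrimerPos, r), max(x@baitPrimerPos, r))
})
setMethod("germlineWindow", "LocusAnnotation", function(x) x@germlineWindow)
setMethod("vRegion", "LocusAnnotation", function(x) x@vRegion)
setMethod("agrRegions", "LocusAnnotation", function(x) x@agrRegions)
setMethod("repeatRegions", "LocusAnnotation", function(x) x@repeatRegions)
setMethod("chromLengths", "LocusAnnotation", function(x) x@chromLengths)

#' @describeIn LocusAnnotation-class gene segments as a 1-based
#'   \link[GenomicRanges]{GRanges} for interoperability.
setMethod("segmentRanges", "LocusAnnotation", function(x) {
  seg <- x@segments
  GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges   = IRanges::IRanges(start = seg$start + 1L, end = seg$end),
    strand   = seg$strand,
    name     = seg$name,
    klass    = seg$klass,
    rss_cut  = seg$rss_cut,
    coding_side = seg$coding_side,
    seqlengths  = x@chromLengths
  )
})

setMethod("show", "LocusAnnotation", function(object) {
  seg <- object@segments
  bw <- baitWindow(object)
  cat("LocusAnnotation\n")
  cat(sprintf("  %d segments (%d V, %d J) on %s\n",
              nrow(seg), sum(seg$klass == "V"), sum(seg$klass == "J"),
              paste(unique(seg$chrom), collapse = ", ")))
  cat(sprintf("  bait: %s on %s, RSS cut %d, primer %d, window [%d, %d)\n",
              object@baitSegment, baitChrom(object), baitRSS(object),
              object@baitPrimerPos, bw[1], bw[2]))
  cat(sprintf("  germline window: [%d, %d); v_region: %s:[%d, %d)\n",
              object@germlineWindow[1], object@germlineWindow[2],
              object@vRegion$chrom, object@vRegion$start, object@vRegion$end))
  cat(sprintf("  %d AgR interval(s), %d repeat interval(s)\n",
              nrow(object@agrRegions), nrow(object@repeatRegions)))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  seed %d, %d pairs, read length %d\n",
              object@seed, object@nPairs, object@readLen))
  f <- object@fractions
  cat("  fractions:", paste(sprintf("%s=%.3g", names(f), f), collapse = " "), "\n")
  rm_ <- object@resectionModel
  cat(sprintf("  resection: %s(mean=%.4g), cap %d nt\n",
              rm_$family, rm_$mean, as.integer(rm_$cap)))
  cat(sprintf("  MH 2-6 bp mass %.3f; insertion prob %.3f (len %d-%d)\n",
              sum(object@mhModel[as.character(2:min(6, length(object@mhModel) - 1))]),
              object@insertionModel$prob, object@insertionModel$minLen,
              object@insertionModel$maxLen))
  cat(sprintf("  per-base error rate %.4g\n", object@seqErrorRate))
})

setMethod("show", "LibrarySummary", function(object) {
  cat(sprintf("LibrarySummary '%s'\n", object@libraryId))
  cat(sprintf("  total mapped reads: %d\n", as.integer(object@totalMapped)))
  lc <- object@labelCounts
  cat("  labels:", paste(sprintf("%s=%d", lc$label, lc$count), collapse = " "), "\n")
  cat(sprintf("  junctions (cis V region): %d (%.3f%%)\n",
              as.integer(object@junctionCount), object@junctionPct))
  cat(sprintf("  translocations (trans AgR): %d (%.4f%%)\n",
              as.integer(object@translocationCount), object@translocationPct))
  if (!is.null(object@features$n) && object@features$n > 0) {
    cat(sprintf("  junction features: n=%d, mean resection %.1f nt, MH 2-6 bp %.1f%%\n",
                object@features$n, object@features$resection_mean,
                100 * object@features$mh_hist[["2-6"]]))
  }
})
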