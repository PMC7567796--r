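## capture mode: classification of merged pull-down reads into V-V joins,
## V-J joins, germline and short deletions, plus 100-bp binning.

#' Classify capture-mode reads
#'
#' Each read (typically a merged pair) receives exactly one label:
#' \itemize{
#'   \item unsplit read overlapping an annotated segment -> \code{germline};
#'   \item split read with both parts in V segments and an inter-part
#'     reference distance > 2000 bp -> \code{vv_join};
#'   \item split read with parts in a V and a J segment -> \code{vj_join};
#'   \item split read with distance < 2000 bp (and > 0) ->
#'     \code{short_deletion};
#'   \item otherwise \code{unclassified}. A distance of exactly 2000 bp is
#'     deliberately unclassified (the cutoffs are strict in both
#'     directions).
#' }
#' The distance is measured between the nearest reference edges of the two
#' parts.
#'
#' @param parts alignment-part data.frame of the capture reads.
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param cutoff V-V distance cutoff in bp (default 2000).
#' @return data.frame: read_id, label, left_break, right_break (facing
#'   edges; NA for unsplit reads), span.
#' @export
classifyCapture <- function(parts, annotation, cutoff = 2000L) {
  parts <- as.data.table(parts)
  seg <- geneSegments(annotation)
  segOverlap <- function(chrom, s, e, klass = NULL) {
    sel <- if (is.null(klass)) rep(TRUE, nrow(seg)) else seg$klass == klass
    hit <- rep(FALSE, length(chrom))
    sg <- seg[sel, , drop = FALSE]
    for (i in seq_len(nrow(sg)))
      hit <- hit | (chrom == sg$chrom[i] & s < sg$end[i] & e > sg$start[i])
    hit
  }
  if (!nrow(parts))
    return(data.frame(read_id = character(), label = character(),
                      left_break = integer(), right_break = integer(),
                      span = integer(), stringsAsFactors = FALSE))
  setorder(parts, read_id, query_start)
  out <- parts[, {
    np <- .N
    label <- "unclassified"
    lb <- NA_integer_; rb <- NA_integer_; span <- NA_integer_
    if (np == 1L) {
      if (segOverlap(chrom[1], ref_start[1], ref_end[1]))
        label <- "germline"
    } else if (np == 2L && chrom[1] == chrom[2]) {
      lo <- if (ref_start[1] <= ref_start[2]) 1L else 2L
      hi <- 3L - lo
      span <- ref_start[hi] - ref_end[lo]
      lb <- ref_end[lo]; rb <- ref_start[hi]
      inV <- segOverlap(chrom, ref_start, ref_end, "V")
      inJ <- segOverlap(chrom, ref_start, ref_end, "J")
      if (all(inV) && span > cutoff) {
        label <- "vv_join"
      } else if (any(inV) && any(inJ)) {
        label <- "vj_join"
      } else if (span > 0L && span < cutoff) {
        label <- "short_deletion"
      }
    }
    .(label = label, chrom = chrom[1], left_break = lb, right_break = rb,
      span = span)
  }, by = read_id]
  setDF(out)
  out
}

#' Bin capture-call breakpoints
#'
#' Half-open bins of \code{binSize} bp anchored at \code{anchor}; each
#' non-NA breakpoint (left and right) increments its bin.
#'
#' @param calls data.frame from [classifyCapture()] plus a \code{chrom}
#'   column, or any data.frame with \code{chrom}, \code{left_break},
#'   \code{right_break}.
#' @param binSize bin width in bp (default 100).
#' @param anchor bin origin (default 0).
#' @return data.frame (chrom, bin_start, bin_end, count) sorted by position.
#' @export
binJoins <- function(calls, binSize = 100L, anchor = 0L) {
  stopifnot(binSize > 0L)
  pts <- data.table(
    chrom = rep(calls$chrom, 2L),
    pos = c(calls$left_break, calls$right_break))
  pts <- pts[!is.na(pos)]
  if (!nrow(pts))
    return(data.frame(chrom = character(), bin_start = integer(),
                      bin_end = integer(), count = integer()))
  pts[, bin_start := anchor + (as.integer(floor((pos - anchor) / binSize))) * binSize]
  out <- pts[, .(count = .N), by = .(chrom, bin_start)]
  out[, bin_end := bin_start + binSize]
  setorder(out, chrom, bin_start)
  setcolorder(out, c("chrom", "bin_start", "bin_end", "count"))
  setDF(out)
  out
}
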