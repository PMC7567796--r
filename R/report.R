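## library-level reporting: percentages, fold enrichment, arc and track
## exports, and the LibrarySummary container.

#' Percentage of a count over a total
#'
#' @param count,total nonnegative counts; \code{count <= total},
#'   \code{total > 0}.
#' @return numeric percentage (100 * count / total).
#' @export
percentOf <- function(count, total) {
  if (any(total <= 0)) stop("undefined denominator: total must be > 0",
                            call. = FALSE)
  if (any(count > total)) stop("count exceeds total", call. = FALSE)
  100 * count / total
}

#' Format a percentage at fixed precision
#'
#' Rounds half to even (IEEE) via \code{sprintf}.
#'
#' @param pct numeric percentage.
#' @param decimals digits after the decimal point.
#' @export
formatPercent <- function(pct, decimals = 2L) {
  sprintf(paste0("%.", decimals, "f"), pct)
}

#' Fold enrichment of one rate over another
#'
#' @param countA,totalA numerator library.
#' @param countB,totalB reference library.
#' @return \code{(countA/totalA) / (countB/totalB)}; when \code{countB} is
#'   zero the result is \code{Inf} with attribute \code{undefined = TRUE}
#'   rather than an error.
#' @export
foldEnrichment <- function(countA, totalA, countB, totalB) {
  stopifnot(totalA > 0, totalB > 0)
  if (countB == 0) {
    out <- Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (countA / totalA) / (countB / totalB)
}

#' Per-bin prey counts for arc plots
#'
#' Junction preys are binned (half-open, anchored at 0) and bins with fewer
#' than \code{minReads} junctions are suppressed, matching the display rule
#' of circular rearrangement plots.
#'
#' @param junctions junction table (needs \code{prey_chrom},
#'   \code{prey_break}).
#' @param binSize bin width (default 1000).
#' @param minReads minimum junctions per emitted bin (default 5).
#' @param baitLabel label for the bait anchor column.
#' @return data.frame (bait, prey_chrom, bin_start, bin_end, count).
#' @export
exportArcs <- function(junctions, binSize = 1000L, minReads = 5L,
                       baitLabel = "bait") {
  stopifnot(binSize > 0L)
  if (!nrow(junctions))
    return(data.frame(bait = character(), prey_chrom = character(),
                      bin_start = integer(), bin_end = integer(),
                      count = integer()))
  dt <- data.table(chrom = junctions$prey_chrom, pos = junctions$prey_break)
  dt[, bin_start := (as.integer(floor(pos / binSize))) * binSize]
  out <- dt[, .(count = .N), by = .(chrom, bin_start)]
  out <- out[count >= minReads]
  out[, `:=`(bin_end = bin_start + binSize, bait = baitLabel)]
  setorder(out, chrom, bin_start)
  setcolorder(out, c("bait", "chrom", "bin_start", "bin_end", "count"))
  setnames(out, "chrom", "prey_chrom")
  setDF(out)
  out
}

#' Export binned junction counts as a bedGraph track
#'
#' bedGraph is 0-based half-open (chrom, start, end, value), matching the
#' internal convention; rows are sorted by chromosome and start.
#'
#' @param junctions junction table.
#' @param binSize bin width (default 1000).
#' @param path optional output file; lines are written without a track
#'   header.
#' @return the track as a data.frame (invisibly when \code{path} given).
#' @export
exportTrack <- function(junctions, binSize = 1000L, path = NULL) {
  stopifnot(binSize > 0L)
  if (!nrow(junctions)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), count = integer())
  } else {
    dt <- data.table(chrom = junctions$prey_chrom, pos = junctions$prey_break)
    dt[, start := (as.integer(floor(pos / binSize))) * binSize]
    out <- dt[, .(count = .N), by = .(chrom, start)]
    out[, end := start + binSize]
    setorder(out, chrom, start)
    setcolorder(out, c("chrom", "start", "end", "count"))
    setDF(out)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Build a library summary
#'
#' The percentage denominator is the number of reads passing the bait and
#' quality filters whose read2 mapped, i.e. all classified reads including
#' germline. The translocation count is restricted to trans-AgR junctions,
#' optionally to named AgR loci.
#'
#' @param libraryId identifier.
#' @param tab output of [tabulateClasses()].
#' @param junctions junction table (with \code{prey_region_label}).
#' @param features output of [summarizeFeatures()].
#' @param translocationLoci character vector of AgR names to count (default
#'   all trans-AgR junctions).
#' @return a \linkS4class{LibrarySummary}.
#' @export
librarySummary <- function(libraryId, tab, junctions, features,
                           translocationLoci = NULL) {
  total <- tab$total
  jc <- tab$prey$count[tab$prey$prey_category == "cis_v_region"]
  if (is.null(translocationLoci)) {
    tc <- tab$prey$count[tab$prey$prey_category == "trans_agr"]
  } else {
    tc <- sum(junctions$prey_region_label %in%
                paste0("agr:", translocationLoci), na.rm = TRUE)
  }
  new("LibrarySummary",
      libraryId = libraryId,
      totalMapped = as.numeric(total),
      labelCounts = tab$labels,
      preyCounts = tab$prey,
      junctionCount = as.numeric(jc),
      translocationCount = as.numeric(tc),
      junctionPct = if (total > 0) percentOf(jc, total) else 0,
      translocationPct = if (total > 0) percentOf(tc, total) else 0,
      features = features)
}
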