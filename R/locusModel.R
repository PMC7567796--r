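## locus model: reference genome + segment annotation loading and queries.
## All coordinates are 0-based half-open; a breakpoint is the boundary
## between position pos-1 and pos.

SEGMENT_COLUMNS <- c("chrom", "start", "end", "name", "strand", "klass",
                     "rss_cut", "coding_side")

#' Construct a LocusAnnotation from in-memory tables
#'
#' @param segments data.frame with columns
#'   \code{chrom,start,end,name,strand,klass,rss_cut,coding_side}
#'   (0-based half-open).
#' @param baitSegment name of the bait J segment.
#' @param baitPrimerPos 0-based primer coordinate near the bait segment.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param germlineBoundary name of the J segment ending the germline window;
#'   default: the second J segment downstream of the bait (on the RSS side,
#'   away from the primer).
#' @param vRegion data.frame (chrom, start, end): the cis V-region interval.
#' @param agrRegions data.frame (chrom, start, end, name) of AgR loci;
#'   may be empty.
#' @param repeatRegions data.frame (chrom, start, end); may be empty.
#' @return a validated \linkS4class{LocusAnnotation} with segments sorted by
#'   (chrom, start).
#' @export
locusAnnotation <- function(segments, baitSegment, baitPrimerPos, chromLengths,
                            germlineBoundary = NULL, vRegion,
                            agrRegions = emptyRegions(named = TRUE),
                            repeatRegions = emptyRegions()) {
  miss <- setdiff(SEGMENT_COLUMNS, names(segments))
  if (length(miss))
    stop(sprintf("segment table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  segments <- as.data.frame(segments)[, SEGMENT_COLUMNS]
  for (col in c("start", "end", "rss_cut")) segments[[col]] <- as.integer(segments[[col]])
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (anyDuplicated(segments$name))
    stop("duplicate segment names: ",
         paste(unique(segments$name[duplicated(segments$name)]), collapse = ", "),
         call. = FALSE)
  gw <- computeGermlineWindow(segments, baitSegment, baitPrimerPos, germlineBoundary)
  ann <- new("LocusAnnotation",
             segments = segments,
             baitSegment = baitSegment,
             baitPrimerPos = as.numeric(baitPrimerPos),
             germlineWindow = gw,
             vRegion = as.data.frame(vRegion),
             agrRegions = as.data.frame(agrRegions),
             repeatRegions = as.data.frame(repeatRegions),
             chromLengths = structure(as.integer(chromLengths),
                                      names = names(chromLengths)))
  validObject(ann)
  ann
}

emptyRegions <- function(named = FALSE) {
  df <- data.frame(chrom = character(), start = integer(), end = integer())
  if (named) df$name <- character()
  df
}

## Germline window: from the bait primer through the far edge of a boundary
## J segment on the RSS side of the bait (default: the second J downstream).
computeGermlineWindow <- function(segments, baitSegment, baitPrimerPos,
                                  germlineBoundary) {
  bait <- segments[segments$name == baitSegment, ]
  if (nrow(bait) != 1L)
    stop(sprintf("bait segment '%s' not found", baitSegment), call. = FALSE)
  dir <- if (bait$rss_cut >= baitPrimerPos) 1L else -1L
  js <- segments[segments$klass == "J" & segments$chrom == bait$chrom &
                 segments$name != baitSegment, , drop = FALSE]
  if (is.null(germlineBoundary)) {
    down <- js[sign(js$start - bait$rss_cut) == dir | js$start == bait$rss_cut, , drop = FALSE]
    if (nrow(down) == 0L)
      stop("no J segment downstream of the bait to bound the germline window; ",
           "pass germlineBoundary explicitly", call. = FALSE)
    down <- down[order(dir * down$start), , drop = FALSE]
    boundary <- down[min(2L, nrow(down)), ]
  } else {
    boundary <- segments[segments$name == germlineBoundary, ]
    if (nrow(boundary) != 1L)
      stop(sprintf("germline boundary segment '%s' not found", germlineBoundary),
           call. = FALSE)
  }
  far <- if (dir > 0) boundary$end else boundary$start
  c(min(baitPrimerPos, far), max(baitPrimerPos, far))
}

#' Load a reference genome and locus annotation from files
#'
#' Reads a FASTA genome, a tab-separated segment table
#' (\code{chrom,start,end,name,strand,klass,rss_cut,coding_side}; 0-based
#' half-open) and a configuration mapping that defines the bait and the
#' optional region tracks.
#'
#' @param genome_path FASTA file.
#' @param segments_path TSV file with a header row.
#' @param config a named list, or the path to a YAML file, with entries
#'   \code{bait_segment}, \code{bait_primer_pos}, \code{v_region} (list with
#'   \code{chrom,start,end}), optional \code{germline_boundary}, optional
#'   \code{agr_bed} and \code{repeat_bed} (BED3+name / BED3 paths).
#' @return list with elements \code{genome}
#'   (\link[Biostrings]{DNAStringSet}) and \code{annotation}
#'   (\linkS4class{LocusAnnotation}).
#' @export
loadAnnotation <- function(genome_path, segments_path, config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (p in c(genome_path, segments_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seg <- read.delim(segments_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(SEGMENT_COLUMNS, names(seg))
  if (length(miss))
    stop(sprintf("segment table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  agr <- if (!is.null(config$agr_bed)) readBed(config$agr_bed, named = TRUE)
         else emptyRegions(named = TRUE)
  rep_ <- if (!is.null(config$repeat_bed)) readBed(config$repeat_bed)
          else emptyRegions()
  vr <- as.data.frame(config$v_region[c("chrom", "start", "end")])
  ann <- locusAnnotation(
    segments = seg,
    baitSegment = config$bait_segment,
    baitPrimerPos = config$bait_primer_pos,
    chromLengths = setNames(Biostrings::width(genome), names(genome)),
    germlineBoundary = config$germline_boundary,
    vRegion = vr,
    agrRegions = agr,
    repeatRegions = rep_
  )
  list(genome = genome, annotation = ann)
}

readBed <- function(path, named = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bed <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  out <- data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
                    end = as.integer(bed[[3]]))
  if (named)
    out$name <- if (ncol(bed) >= 4) as.character(bed[[4]])
                else sprintf("region%d", seq_len(nrow(bed)))
  out
}

#' Select segments eligible for resection analysis
#'
#' V segments closer than \code{minSpacing} (gap between segment intervals)
#' to another V segment on the same chromosome are removed, so that a
#' resected breakpoint can be attributed to a unique RSS cut site. J segments
#' are always retained.
#'
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param minSpacing minimum inter-segment gap in bp (default 4000).
#' @return data.frame of retained segments (same columns as
#'   [geneSegments()]).
#' @export
eligibleSegments <- function(annotation, minSpacing = 4000) {
  stopifnot(minSpacing > 0)
  seg <- geneSegments(annotation)
  vs <- seg[seg$klass == "V", , drop = FALSE]
  keep <- character()
  for (chr in unique(vs$chrom)) {
    v <- vs[vs$chrom == chr, , drop = FALSE]
    v <- v[order(v$start), , drop = FALSE]
    n <- nrow(v)
    if (n == 1L) { keep <- c(keep, v$name); next }
    gap_prev <- c(Inf, v$start[-1] - v$end[-n])
    gap_next <- c(v$start[-1] - v$end[-n], Inf)
    keep <- c(keep, v$name[gap_prev >= minSpacing & gap_next >= minSpacing])
  }
  out <- seg[seg$klass == "J" | seg$name %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label a genomic position by locus region
#'
#' Overlapping region definitions are resolved by fixed priority:
#' bait > germline_window > v_region > agr > repeat > other.
#'
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param chrom chromosome name (vectorized with \code{pos}).
#' @param pos 0-based position.
#' @return character vector of labels: \code{"bait"},
#'   \code{"germline_window"}, \code{"v_region"}, \code{"agr:<name>"},
#'   \code{"repeat"} or \code{"other"}.
#' @export
regionOf <- function(annotation, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  unk <- setdiff(chrom, names(chromLengths(annotation)))
  if (length(unk))
    stop("unknown chromosome(s): ", paste(unk, collapse = ", "), call. = FALSE)
  bw <- baitWindow(annotation); gw <- germlineWindow(annotation)
  bchr <- baitChrom(annotation)
  vr <- vRegion(annotation); agr <- agrRegions(annotation)
  rep_ <- repeatRegions(annotation)
  out <- rep("other", n)
  inReg <- function(df, chrom, pos) {
    hit <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(df))) {
      sel <- is.na(hit) & chrom == df$chrom[i] & pos >= df$start[i] & pos < df$end[i]
      hit[sel] <- i
    }
    hit
  }
  if (nrow(rep_)) out[!is.na(inReg(rep_, chrom, pos))] <- "repeat"
  if (nrow(agr)) {
    h <- inReg(agr, chrom, pos)
    out[!is.na(h)] <- paste0("agr:", agr$name[h[!is.na(h)]])
  }
  if (nrow(vr))
    out[chrom == vr$chrom[1] & pos >= vr$start[1] & pos < vr$end[1]] <- "v_region"
  out[chrom == bchr & pos >= gw[1] & pos < gw[2]] <- "germline_window"
  out[chrom == bchr & pos >= bw[1] & pos < bw[2]] <- "bait"
  out
}
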