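## alignment-part acquisition: a built-in exact seed-and-extend split-read
## aligner for mini-genomes, SAM ingestion, and the mapping-quality filter.
## Parts are rows of a data.frame: read_id, mate, chrom, ref_start, ref_end
## (0-based half-open), query_start, query_end (0-based half-open on the
## read), strand, mapq, n_candidates.

#' Exact seed-and-extend split-read alignment against a small genome
#'
#' Anchors the first and last \code{seedLen} bases of each read with exact
#' multi-pattern matching on both strands, extends every anchor hit to a
#' maximal exact match, and keeps the maximal placement(s) of each end.
#' Reads covered by one placement yield a single part; otherwise the prefix
#' and suffix parts are reported, with query intervals allowed to overlap by
#' up to \code{mhWindow} bases (the microhomology window). Adjacent parts on
#' the same chromosome and strand whose reference gap equals the query gap
#' (sequencing-error islands inside a contiguous read) are merged back into
#' one part.
#'
#' \code{n_candidates} counts equally maximal placements of a part; parts
#' with more than one candidate get mapq 0, unique parts mapq 60. For
#' multi-candidate parts the alternative placements are kept in the list
#' column \code{alt} (used by the repeat exception of [qualityFilter()]).
#'
#' @param reads named character vector of read sequences.
#' @param genome \link[Biostrings]{DNAStringSet}; mini-genome scale.
#' @param seedLen anchor length (default 24).
#' @param minPart minimum part length to report (default 20).
#' @param mhWindow maximum query-interval overlap between split parts
#'   (default 20).
#' @param mate mate number recorded in the output (default 2).
#' @return data.frame of alignment parts; unalignable reads are absent.
#' @export
naiveAlign <- function(reads, genome, seedLen = 24L, minPart = 20L,
                       mhWindow = 20L, mate = 2L) {
  stopifnot(length(reads) > 0L, !is.null(names(reads)))
  len <- nchar(reads)
  usable <- len >= pmax(seedLen, minPart)
  spaces <- alignSpaces(genome)

  pre <- anchorHits(substr(reads, 1L, seedLen), usable, spaces)
  suf <- anchorHits(substr(reads, pmax(1L, len - seedLen + 1L), len),
                    usable, spaces)
  ## suffix anchor end position in space coordinates
  if (nrow(suf)) suf[, send := spos + seedLen - 1L]

  p1 <- bestEndPlacement(pre, reads, len, spaces, end = "prefix")
  p2 <- bestEndPlacement(suf, reads, len, spaces, end = "suffix")

  assembleParts(p1, p2, reads, len, minPart, mhWindow, mate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## forward and reverse-complement search spaces as plain character strings
alignSpaces <- function(genome) {
  chroms <- names(genome)
  fwd <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  rc <- lapply(seq_along(genome), function(i)
    as.character(Biostrings::reverseComplement(genome[[i]])))
  names(fwd) <- names(rc) <- chroms
  list(chroms = chroms, len = setNames(Biostrings::width(genome), chroms),
       fwd = fwd, rc = rc)
}

## match one fixed-width anchor per read against every chromosome and strand;
## positions are 1-based within the strand-specific space string
anchorHits <- function(anchors, usable, spaces) {
  ok <- usable & grepl("^[ACGT]+$", anchors) &
    nchar(anchors) == max(nchar(anchors))
  idx <- which(ok)
  out <- list()
  if (length(idx)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(anchors[idx]))
    for (chr in spaces$chroms) {
      for (std in c("+", "-")) {
        subj <- if (std == "+") spaces$fwd[[chr]] else spaces$rc[[chr]]
        m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
        st <- Biostrings::startIndex(m)
        nh <- lengths(st)
        if (sum(nh) == 0L) next
        out[[length(out) + 1L]] <- data.table(
          read = rep(idx, nh), chrom = chr, strand = std,
          spos = unlist(st[nh > 0L], use.names = FALSE))
      }
    }
  }
  if (length(out)) rbindlist(out) else
    data.table(read = integer(), chrom = character(), strand = character(),
               spos = integer())
}

## longest common prefix of `read` and the space string starting at spos
lcpFwd <- function(space, spos, read) {
  L <- nchar(read)
  gs <- substr(space, spos, spos + L - 1L)
  if (gs == read) return(L)
  a <- charToRaw(gs); b <- charToRaw(read)
  n <- min(length(a), L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) d[1] - 1L else n
}

## longest common suffix of `read` and the space string ending at pe
lcpRev <- function(space, pe, read) {
  L <- nchar(read)
  sstart <- max(1L, pe - L + 1L)
  gs <- substr(space, sstart, pe)
  k <- nchar(gs)
  a <- charToRaw(gs); b <- charToRaw(read)[(L - k + 1L):L]
  d <- which(a != b)
  if (length(d)) k - d[length(d)] else k
}

## extend all hits of one read end and keep the maximal placement(s).
## Returns one row per read: chosen placement + n_candidates + alternatives.
bestEndPlacement <- function(hits, reads, len, spaces, end) {
  empty <- data.table(read = integer(), chrom = character(),
                      strand = character(), ref_start = integer(),
                      ref_end = integer(), query_start = integer(),
                      query_end = integer(), n_candidates = integer(),
                      alt = list())
  if (!nrow(hits)) return(empty)
  n <- nrow(hits)
  ext <- integer(n)
  for (i in seq_len(n)) {
    space <- if (hits$strand[i] == "+") spaces$fwd[[hits$chrom[i]]]
             else spaces$rc[[hits$chrom[i]]]
    rd <- reads[hits$read[i]]
    ext[i] <- if (end == "prefix") lcpFwd(space, hits$spos[i], rd)
              else lcpRev(space, hits$send[i], rd)
  }
  hits <- copy(hits); hits[, ext := ext]
  ## convert to genome coordinates (0-based half-open) and query intervals
  hits[, clen := spaces$len[chrom]]
  if (end == "prefix") {
    hits[, `:=`(query_start = 0L, query_end = ext)]
    hits[strand == "+", `:=`(ref_start = spos - 1L, ref_end = spos - 1L + ext)]
    hits[strand == "-", `:=`(ref_start = clen - spos - ext + 1L,
                             ref_end = clen - spos + 1L)]
  } else {
    hits[, rl := len[read]]
    hits[, `:=`(query_start = rl - ext, query_end = rl)]
    hits[strand == "+", `:=`(ref_start = send - ext, ref_end = send)]
    hits[strand == "-", `:=`(ref_start = clen - send,
                             ref_end = clen - send + ext)]
  }
  setorder(hits, read, chrom, strand, ref_start)
  hits[, maxext := max(ext), by = read]
  best <- hits[ext == maxext]
  best[, n_candidates := .N, by = read]
  out <- best[, {
    alt <- if (.N > 1L) list(data.frame(chrom = chrom[-1L],
                                        ref_start = ref_start[-1L],
                                        ref_end = ref_end[-1L],
                                        strand = strand[-1L])) else list(NULL)
    .(chrom = chrom[1L], strand = strand[1L], ref_start = ref_start[1L],
      ref_end = ref_end[1L], query_start = query_start[1L],
      query_end = query_end[1L], n_candidates = n_candidates[1L], alt = alt)
  }, by = read]
  out
}

## combine the prefix and suffix placements of every read into parts
assembleParts <- function(p1, p2, reads, len, minPart, mhWindow, mate) {
  ids <- names(reads)
  emptyParts <- function() {
    data.frame(read_id = character(), mate = integer(),
               chrom = character(), ref_start = integer(),
               ref_end = integer(), query_start = integer(),
               query_end = integer(), strand = character(),
               mapq = integer(), n_candidates = integer())
  }
  renameEnd <- function(p, tag) {
    p <- copy(p)
    p <- p[query_end - query_start >= minPart]
    setnames(p, setdiff(names(p), "read"),
             paste0(setdiff(names(p), "read"), tag))
    p
  }
  ab <- merge(renameEnd(p1, ".a"), renameEnd(p2, ".b"), by = "read",
              all = TRUE)
  if (!nrow(ab)) return(emptyParts())
  ab[, rl := len[read]]
  hasA <- !is.na(ab$chrom.a); hasB <- !is.na(ab$chrom.b)
  fullA <- hasA & ab$query_end.a >= ab$rl
  fullB <- hasB & ab$query_start.b <= 0L
  overlap <- ab$query_end.a - ab$query_start.b
  samePlace <- hasA & hasB & ab$chrom.a == ab$chrom.b &
    ab$strand.a == ab$strand.b
  refgap <- ifelse(samePlace, ab$ref_start.b - ab$ref_end.a, NA_integer_)
  remerge <- !fullA & hasA & hasB & !fullB & samePlace & !is.na(refgap) &
    -overlap >= 0L & refgap >= 0L & refgap <= 60L &
    abs(refgap - (-overlap)) <= 3L
  ## one-part reads: full prefix coverage, a missing end, a full suffix, a
  ## beyond-window overlap (keep the longer end), or an error re-merge
  aOnly <- hasA & (fullA | !hasB)
  bOnly <- !hasA & hasB
  bFull <- hasA & !fullA & hasB & fullB & !remerge
  rest <- hasA & hasB & !fullA & !fullB & !remerge
  keepLonger <- rest & !is.na(overlap) & overlap > mhWindow
  twoPart <- rest & !keepLonger
  longerIsA <- (ab$query_end.a - ab$query_start.a) >=
    (ab$query_end.b - ab$query_start.b)

  takeEnd <- function(sel, tag) {
    if (!any(sel)) return(NULL)
    s <- ab[sel]
    data.table(read_id = ids[s$read], mate = mate,
               chrom = s[[paste0("chrom", tag)]],
               ref_start = s[[paste0("ref_start", tag)]],
               ref_end = s[[paste0("ref_end", tag)]],
               query_start = s[[paste0("query_start", tag)]],
               query_end = s[[paste0("query_end", tag)]],
               strand = s[[paste0("strand", tag)]],
               mapq = ifelse(s[[paste0("n_candidates", tag)]] > 1L, 0L, 60L),
               n_candidates = s[[paste0("n_candidates", tag)]],
               alt = s[[paste0("alt", tag)]])
  }
  mergedRows <- NULL
  if (any(remerge)) {
    s <- ab[remerge]
    nc <- pmax(s$n_candidates.a, s$n_candidates.b)
    mergedRows <- data.table(read_id = ids[s$read], mate = mate,
                             chrom = s$chrom.a, ref_start = s$ref_start.a,
                             ref_end = s$ref_end.b,
                             query_start = s$query_start.a,
                             query_end = s$query_end.b, strand = s$strand.a,
                             mapq = ifelse(nc > 1L, 0L, 60L),
                             n_candidates = nc, alt = s$alt.a)
  }
  out <- rbindlist(list(
    takeEnd(aOnly | (keepLonger & longerIsA), ".a"),
    takeEnd(bOnly | bFull | (keepLonger & !longerIsA), ".b"),
    takeEnd(twoPart, ".a"),
    takeEnd(twoPart, ".b"),
    mergedRows), use.names = TRUE)
  if (!nrow(out)) return(emptyParts())
  setorder(out, read_id, query_start)
  setDF(out)
  out
}

#' Load alignment parts from a SAM/BAM file
#'
#' Groups primary and supplementary alignments per read, converts 1-based
#' reference positions to the internal 0-based half-open convention and
#' resolves soft/hard clips to query coordinates on the original read.
#' mapq 0 records are treated as multi-mapped (\code{n_candidates = 2}),
#' following the BWA convention; unmapped and secondary records are
#' excluded.
#'
#' @param path SAM (converted on the fly) or BAM file.
#' @return data.frame of alignment parts as in [naiveAlign()].
#' @export
loadSAM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- suppressMessages(Rsamtools::asBam(path, tempfile(),
                                             indexDestination = FALSE))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!length(ga))
    return(data.frame(read_id = character(), mate = integer(),
                      chrom = character(), ref_start = integer(),
                      ref_end = integer(), query_start = integer(),
                      query_end = integer(), strand = character(),
                      mapq = integer(), n_candidates = integer()))
  cig <- GenomicAlignments::cigar(ga)
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cig)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable CIGAR skipped")
    ga <- ga[!bad]; cig <- cig[!bad]
  }
  lead <- integer(length(cig))
  hasClip <- grepl("^[0-9]+[SH]", cig)
  lead[hasClip] <- as.integer(sub("^([0-9]+)[SH].*$", "\\1", cig[hasClip]))
  qcons <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  qtot <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, before.hard.clipping = TRUE)
  flag <- S4Vectors::mcols(ga)$flag
  strand <- as.character(BiocGenerics::strand(ga))
  qs <- lead; qe <- lead + qcons
  minus <- strand == "-"
  qs2 <- ifelse(minus, qtot - qe, qs)
  qe2 <- ifelse(minus, qtot - qs, qe)
  mapq <- S4Vectors::mcols(ga)$mapq
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)
  out <- data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    mate = mate,
    chrom = as.character(GenomicRanges::seqnames(ga)),
    ref_start = BiocGenerics::start(ga) - 1L,
    ref_end = BiocGenerics::end(ga),
    query_start = as.integer(qs2), query_end = as.integer(qe2),
    strand = strand,
    mapq = as.integer(mapq),
    n_candidates = ifelse(!is.na(mapq) & mapq == 0L, 2L, 1L),
    stringsAsFactors = FALSE)
  out <- out[order(out$read_id, out$query_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mapping-quality filter with the repeat exception
#'
#' Drops a read if any of its parts has mapq below \code{minMapq} or more
#' than one equally good placement, except that a part is tolerated when it
#' lies within an annotated repeat interval and all of its candidate
#' placements do (such reads are routed to the repeat category downstream).
#'
#' @param parts alignment-part data.frame ([naiveAlign()] / [loadSAM()]).
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param minMapq minimum mapping quality (default 10).
#' @return list with \code{parts} (kept parts, plus a logical column
#'   \code{in_repeat}) and \code{log} (data.frame read_id, reason for
#'   dropped reads).
#' @export
qualityFilter <- function(parts, annotation, minMapq = 10L) {
  parts <- as.data.table(parts)
  if (!nrow(parts))
    return(list(parts = setDF(parts),
                log = data.frame(read_id = character(), reason = character())))
  reps <- repeatRegions(annotation)
  inRep <- function(chrom, s, e) {
    hit <- rep(FALSE, length(chrom))
    for (i in seq_len(nrow(reps)))
      hit <- hit | (chrom == reps$chrom[i] & s < reps$end[i] & e > reps$start[i])
    hit
  }
  parts[, in_repeat := inRep(chrom, ref_start, ref_end)]
  altOk <- rep(TRUE, nrow(parts))
  if ("alt" %in% names(parts)) {
    multi <- which(parts$n_candidates > 1L)
    for (i in multi) {
      alt <- parts$alt[[i]]
      altOk[i] <- is.null(alt) ||
        all(inRep(alt$chrom, alt$ref_start, alt$ref_end))
    }
  }
  exempt <- parts$in_repeat & altOk
  partBad <- (parts$mapq < minMapq | parts$n_candidates > 1L) & !exempt
  badReads <- unique(parts$read_id[partBad])
  reasonByRead <- parts[partBad, .(reason = ifelse(any(n_candidates > 1L),
                                                   "multi_mapped", "low_mapq")),
                        by = read_id]
  keep <- parts[!read_id %in% badReads]
  if ("alt" %in% names(keep)) keep[, alt := NULL]
  setDF(keep)
  list(parts = keep,
       log = data.frame(read_id = reasonByRead$read_id,
                        reason = reasonByRead$reason,
                        stringsAsFactors = FALSE))
}
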