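## read-pair intake: FASTQ reading, bait-primer filtering, adapter trimming
## and (capture mode) 3'-3' overlap merging.

#' Read a FASTQ file into a named character vector
#'
#' Base qualities are not used anywhere in the pipeline and are discarded.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return named character vector of read sequences.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Bait-primer filter on read1
#'
#' A pair is kept iff the 5' end of read1 matches at least \code{minBait}
#' consecutive bases of the bait sequence with at most \code{maxMismatch}
#' mismatches. Empty or too-short read1 drops the pair.
#'
#' @param reads1 character vector of read1 sequences.
#' @param baitSeq bait (primer-proximal) sequence, length >= \code{minBait}.
#' @param minBait minimum matched prefix length in bp (default 20).
#' @param maxMismatch mismatches tolerated inside the prefix (default 2;
#'   set 0 for exact matching).
#' @return logical vector, TRUE = keep.
#' @export
baitFilter <- function(reads1, baitSeq, minBait = 20L, maxMismatch = 2L) {
  stopifnot(nchar(baitSeq) >= minBait)
  bait <- substr(baitSeq, 1L, minBait)
  pref <- substr(reads1, 1L, minBait)
  ok <- nchar(pref) == minBait
  mm <- rep(NA_integer_, length(reads1))
  mm[ok] <- hammingDist(pref[ok], bait)
  !is.na(mm) & mm <= maxMismatch
}

## vectorized Hamming distance of equal-length strings against one pattern
hammingDist <- function(x, pattern) {
  pr <- charToRaw(pattern)
  vapply(x, function(s) sum(charToRaw(s) != pr), 0L, USE.NAMES = FALSE)
}

#' Trim a 3' adapter
#'
#' Removes the longest read suffix that equals a prefix of the adapter of
#' length at least \code{minMatch}; no internal trimming.
#'
#' @param seqs character vector of read sequences.
#' @param adapter adapter sequence.
#' @param minMatch minimum suffix/prefix overlap to trim.
#' @return character vector of trimmed sequences.
#' @export
trimAdapter <- function(seqs, adapter, minMatch = 10L) {
  stopifnot(nchar(adapter) > 0L)
  len <- nchar(seqs)
  out <- seqs
  done <- rep(FALSE, length(seqs))
  kmax <- min(nchar(adapter), max(len))
  if (kmax < minMatch) return(out)
  for (k in seq(kmax, minMatch)) {
    sel <- !done & len >= k &
      substr(seqs, len - k + 1L, len) == substr(adapter, 1L, k)
    out[sel] <- substr(seqs[sel], 1L, len[sel] - k)
    done <- done | sel
  }
  out
}

#' Merge a read pair by 3'-3' overlap
#'
#' Scans overlaps from the longest down to \code{minOverlap} and merges at
#' the first (i.e. longest) overlap whose mismatch rate is at most
#' \code{maxMismatchRate}; the merged sequence takes read1's base where the
#' mates disagree (base qualities are constant). Pairs without a qualifying
#' overlap are returned unmerged.
#'
#' @param seq1,seq2 mate sequences (read2 in sequencing orientation; it is
#'   reverse-complemented internally).
#' @param minOverlap minimum overlap in bp (default 10).
#' @param maxMismatchRate maximum fraction of mismatches in the overlap.
#' @return data.frame with columns \code{merged} (logical) and \code{seq}
#'   (merged sequence, or NA when unmerged).
#' @export
mergeOverlap <- function(seq1, seq2, minOverlap = 10L, maxMismatchRate = 0.1) {
  stopifnot(length(seq1) == length(seq2), all(nchar(seq1) > 0L),
            all(nchar(seq2) > 0L))
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq2)))
  n <- length(seq1)
  merged <- logical(n); out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s1 <- seq1[i]; s2 <- r2[i]
    l1 <- nchar(s1); l2 <- nchar(s2)
    if (min(l1, l2) < minOverlap) next
    for (o in seq(min(l1, l2), minOverlap)) {
      mm <- sum(charToRaw(substr(s1, l1 - o + 1L, l1)) !=
                charToRaw(substr(s2, 1L, o)))
      if (mm / o <= maxMismatchRate) {
        merged[i] <- TRUE
        out[i] <- paste0(s1, substr(s2, o + 1L, l2))
        break
      }
    }
  }
  data.frame(merged = merged, seq = out, stringsAsFactors = FALSE)
}
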