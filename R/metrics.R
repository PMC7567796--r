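## junction features: microhomology, untemplated insertion, RSS-anchored
## resection, and distribution summaries.

#' Call microhomology and untemplated insertion at junctions
#'
#' For a query overlap (negative query gap) the candidate microhomology is
#' validated base by base: an overlap base counts only while the read base
#' equals \emph{both} parental genomic continuations. For a positive query
#' gap the gap bases are the insertion candidate; bases that extend a parent
#' are reassigned to that side and only the remainder is reported as
#' untemplated insertion. A blunt join yields (0, "").
#'
#' The aligned parts of the built-in aligner are maximal exact matches, so
#' validated overlap equals the full junction-ambiguity window; local
#' alignments from external mappers that stop short of maximality can
#' undercall MH.
#'
#' @param junctions junction table from [classifyReads()].
#' @param reads named character vector of read2 sequences.
#' @param genome \link[Biostrings]{DNAStringSet} (the one reads were aligned
#'   to).
#' @return \code{junctions} with columns \code{mh_len},
#'   \code{insertion_seq}, \code{insertion_len} added. Junctions whose bait
#'   part is not on the plus strand are left NA (not produced by the
#'   bait-primed library structure).
#' @export
computeMHInsertion <- function(junctions, reads, genome) {
  n <- nrow(junctions)
  mh <- rep(NA_integer_, n); ins <- rep(NA_character_, n)
  if (!n) {
    junctions$mh_len <- integer(0); junctions$insertion_seq <- character(0)
    junctions$insertion_len <- integer(0)
    return(junctions)
  }
  gstr <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(gstr) <- names(genome)
  glen <- setNames(Biostrings::width(genome), names(genome))
  gc <- function(chrom, pos) {
    if (pos < 0L || pos >= glen[[chrom]]) return("?")
    substr(gstr[[chrom]], pos + 1L, pos + 1L)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `?` = "?")
  ridx <- match(junctions$read_id, names(reads))
  bstrand <- junctions$bait_strand; pstrand <- junctions$prey_strand
  bchrom <- junctions$bait_chrom; pchrom <- junctions$prey_chrom
  bbreak <- junctions$bait_break; pbreak <- junctions$prey_break
  bqend <- junctions$bait_qend; pqstart <- junctions$prey_qstart
  qgap <- junctions$query_gap
  for (k in seq_len(n)) {
    if (is.na(bstrand[k]) || bstrand[k] != "+") next
    read <- reads[[ridx[k]]]
    ## parental continuation characters, in read orientation
    baitBack <- function(i) gc(bchrom[k], bbreak[k] - i)      # before junction
    baitFwd <- function(i) gc(bchrom[k], bbreak[k] + i - 1L)  # after junction
    if (pstrand[k] == "+") {
      preyBack <- function(i) gc(pchrom[k], pbreak[k] - i)
    } else {
      preyBack <- function(i) comp[[gc(pchrom[k], pbreak[k] + i - 1L)]]
    }
    g <- qgap[k]
    if (g < 0L) {
      o <- -g
      run <- 0L
      while (run < o) {
        rb <- substr(read, bqend[k] - run, bqend[k] - run)
        if (rb == baitBack(run + 1L) && rb == preyBack(run + 1L))
          run <- run + 1L else break
      }
      mh[k] <- run; ins[k] <- ""
    } else if (g > 0L) {
      gap <- substr(read, bqend[k] + 1L, pqstart[k])
      e1 <- 0L
      while (e1 < g && substr(gap, e1 + 1L, e1 + 1L) == baitFwd(e1 + 1L))
        e1 <- e1 + 1L
      rest <- g - e1
      e2 <- 0L
      while (e2 < rest && substr(gap, g - e2, g - e2) == preyBack(e2 + 1L))
        e2 <- e2 + 1L
      mh[k] <- 0L
      ins[k] <- substr(gap, e1 + 1L, g - e2)
    } else {
      mh[k] <- 0L; ins[k] <- ""
    }
  }
  junctions$mh_len <- mh
  junctions$insertion_seq <- ins
  junctions$insertion_len <- ifelse(is.na(ins), NA_integer_, nchar(ins))
  junctions
}

#' Assign resection length relative to the nearest eligible RSS cut
#'
#' Each junction is assigned the eligible segment whose RSS cut is nearest
#' the prey breakpoint on the same chromosome, within \code{cap}. The
#' resection length is the unsigned distance from breakpoint to cut; the
#' side label is \code{coding} when the breakpoint lies on the segment's
#' coding side of the cut (the cut itself counts as coding). Junctions with
#' no cut within \code{cap} are unassigned (NA) and excluded from resection
#' statistics. Equidistant cuts are resolved toward the lexicographically
#' smaller segment name.
#'
#' @param junctions junction table.
#' @param eligible segment data.frame from [eligibleSegments()].
#' @param cap maximum resection length in nt (default 4000).
#' @return \code{junctions} with columns \code{assigned_segment},
#'   \code{resection_side}, \code{resection_len} added.
#' @export
computeResection <- function(junctions, eligible, cap = 4000) {
  n <- nrow(junctions)
  segn <- rep(NA_character_, n)
  side <- rep(NA_character_, n)
  rlen <- rep(NA_integer_, n)
  for (chr in unique(junctions$prey_chrom)) {
    seg <- eligible[eligible$chrom == chr, , drop = FALSE]
    idx <- which(junctions$prey_chrom == chr)
    if (!nrow(seg) || !length(idx)) next
    seg <- seg[order(seg$rss_cut, seg$name), , drop = FALSE]
    b <- junctions$prey_break[idx]
    cuts <- seg$rss_cut
    lo <- findInterval(b, cuts)                 # nearest cut at/below
    hi <- pmin(lo + 1L, length(cuts))           # nearest cut above
    lo <- pmax(lo, 1L)
    dlo <- abs(b - cuts[lo]); dhi <- abs(b - cuts[hi])
    ## break distance ties toward the lexicographically smaller name
    useLo <- dlo < dhi | (dlo == dhi & seg$name[lo] <= seg$name[hi])
    best <- ifelse(useLo, lo, hi)
    d <- pmin(dlo, dhi)
    ok <- d <= cap
    segn[idx[ok]] <- seg$name[best[ok]]
    rlen[idx[ok]] <- d[ok]
    cdir <- ifelse(seg$coding_side[best] == "right", 1L, -1L)
    side[idx[ok]] <- ifelse((b[ok] - cuts[best[ok]]) * cdir[ok] >= 0L,
                            "coding", "signal")
  }
  junctions$assigned_segment <- segn
  junctions$resection_side <- side
  junctions$resection_len <- rlen
  junctions
}

#' Summarize junction features
#'
#' @param junctions junction table with \code{mh_len}, \code{insertion_len}
#'   and \code{resection_len} columns filled.
#' @return list: \code{n} junctions; \code{n_assigned}, \code{n_unassigned},
#'   \code{n_capped} over resection assignment; \code{resection_mean},
#'   \code{resection_median}, \code{resection_frac_gt100} over assigned
#'   junctions; \code{mh_hist} fractions over bins \{0, 1, 2-6, >=7\};
#'   \code{insertion_fraction}. Statistics are NA when empty.
#' @param cap cap used in [computeResection()] (reported as
#'   \code{n_capped}).
#' @export
summarizeFeatures <- function(junctions, cap = 4000) {
  n <- nrow(junctions)
  if (!n) {
    return(list(n = 0L, n_assigned = 0L, n_unassigned = 0L, n_capped = 0L,
                resection_mean = NA_real_, resection_median = NA_real_,
                resection_frac_gt100 = NA_real_,
                mh_hist = c(`0` = NA_real_, `1` = NA_real_, `2-6` = NA_real_,
                            `>=7` = NA_real_),
                insertion_fraction = NA_real_))
  }
  r <- junctions$resection_len
  assigned <- !is.na(r)
  mh <- junctions$mh_len
  mhv <- mh[!is.na(mh)]
  hist <- c(`0` = mean(mhv == 0L), `1` = mean(mhv == 1L),
            `2-6` = mean(mhv >= 2L & mhv <= 6L), `>=7` = mean(mhv >= 7L))
  insl <- junctions$insertion_len
  list(
    n = n,
    n_assigned = sum(assigned),
    n_unassigned = sum(!assigned),
    n_capped = sum(r[assigned] >= cap),
    resection_mean = if (any(assigned)) mean(r[assigned]) else NA_real_,
    resection_median = if (any(assigned)) median(r[assigned]) else NA_real_,
    resection_frac_gt100 = if (any(assigned)) mean(r[assigned] > 100) else NA_real_,
    mh_hist = hist,
    insertion_fraction = mean(insl[!is.na(insl)] > 0L)
  )
}
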