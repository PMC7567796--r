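## read rendering: realize the drawn microhomology/insertion values in the
## genome, then emit FASTQ read pairs, a truth SAM and a realized truth table.

BASES <- c("A", "C", "G", "T")

otherBase <- function(ch) {
  c(A = "C", C = "G", G = "T", T = "A", N = "A")[[ch]]
}

#' Render a simulated library as read pairs plus truth alignments
#'
#' Read1 begins with the bait primer followed by bait-side genomic sequence;
#' read2 spans the junction so that split alignment recovers the truth
#' breakpoints. Microhomology is realized as genuine sequence identity
#' between the two parents: the generator plants the homology by locally
#' mutating the prey-side flank of the genome (and breaks accidental
#' homology just outside it), so the returned genome differs from the input
#' at those positions and is the one that must be used for alignment. When
#' two junctions share a prey breakpoint the first planted MH length wins
#' and later records adopt it; a final realization pass recomputes MH,
#' insertion and resection for every record from the finished genome, so the
#' returned truth is exactly consistent with the rendered reads.
#'
#' Junctions are reported right-anchored: the breakpoint pair is placed at
#' the bait-most position of the microhomology ambiguity window, matching
#' the convention of the junction caller.
#'
#' @param truth data.frame from [simulateTruth()].
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param annotation \linkS4class{LocusAnnotation}.
#' @param sim \linkS4class{SimConfig}.
#' @param dir if non-NULL, write \code{reads_R1.fastq}, \code{reads_R2.fastq},
#'   \code{truth.sam} and \code{truth.tsv} there.
#' @return list with \code{reads1}, \code{reads2} (named character vectors),
#'   \code{truth} (realized truth data.frame including the true alignment
#'   part coordinates), \code{genome} (the locally mutated genome) and
#'   \code{files}.
#' @export
renderReads <- function(truth, genome, annotation, sim, dir = NULL) {
  set.seed(sim@seed + 1L)
  truth <- as.data.frame(truth)
  n <- nrow(truth)
  readLen <- sim@readLen
  gstr <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(gstr) <- names(genome)
  bchr <- baitChrom(annotation)
  bw <- baitWindow(annotation)
  rss <- baitRSS(annotation)

  ## working vectors (written back to truth at the end)
  baitBreak <- truth$bait_break
  preyBreak <- truth$prey_break
  preyChrom <- truth$prey_chrom
  mhLen <- truth$mh_len
  insLen <- truth$insertion_len
  resPrey <- truth$resection_prey
  resSide <- truth$resection_side
  insSeqDrawn <- rep(NA_character_, n)   # as rendered into the read
  insSeqReal <- rep(NA_character_, n)    # after realization
  p1_qend <- p1_rstart <- p1_rend <- rep(NA_integer_, n)
  p2_qstart <- p2_rstart <- p2_rend <- rep(NA_integer_, n)

  ij <- which(!is.na(preyBreak))
  L1 <- rep(NA_integer_, n)
  if (length(ij)) {
    ## Precondition the bait coding end: the flankW bases before the bait
    ## RSS cut become a mononucleotide tract of X (chosen != the base at the
    ## cut). Every microhomology plant then writes the same character, so
    ## overlapping plants of different junctions are consistent by
    ## construction, and a junction's MH is simply the X-run length ending
    ## at its prey breakpoint.
    flankW <- 12L
    Y <- substr(gstr[[bchr]], rss + 1L, rss + 1L)
    X <- setdiff(BASES, Y)[1L]
    brk <- setdiff(BASES, c(X, Y))[1L]   # character used to break runs
    substr(gstr[[bchr]], rss - flankW + 1L, rss) <- strrep(X, flankW)

    ## first-wins single-base edit store; a locked position is never rewritten
    edits <- new.env(hash = TRUE)
    gchar <- function(chrom, pos) {
      v <- edits[[paste0(chrom, ":", pos)]]
      if (!is.null(v)) v else substr(gstr[[chrom]], pos + 1L, pos + 1L)
    }
    tryWrite <- function(chrom, pos, ch) {
      key <- paste0(chrom, ":", pos)
      v <- edits[[key]]
      if (!is.null(v)) return(v)
      assign(key, ch, envir = edits)
      ch
    }
    ## lock a position whose value must stay off the homology tract; a
    ## natural X or Y is rewritten to the break character so the position
    ## can also serve as a junction point (which requires != Y)
    lockOffTract <- function(chrom, pos) {
      v <- gchar(chrom, pos)
      if (v == X || v == Y) tryWrite(chrom, pos, brk) else tryWrite(chrom, pos, v)
    }

    ## bait-side query length; adjacent-J joins must cross the bait RSS
    off <- pmax(0L, baitBreak[ij] - as.integer(rss))
    maxL <- pmin(140L, baitBreak[ij] - as.integer(bw[1]) - 2L)
    L1[ij] <- off + as.integer(floor(runif(length(ij), 40,
                                           pmin(140, maxL - off) + 1)))
    maxM <- length(sim@mhModel) - 1L

    ## --- microhomology tract layout ------------------------------------
    ## A junction's MH is an X-run ending at its prey breakpoint, so MH
    ## lengths of nearby junctions are coupled through the shared flank:
    ## with breakpoints d bases apart, the right one can take any length
    ## 0..d-1 (its run starts inside the gap) or continue the left one's
    ## run (length m_left + d). The layout is therefore assigned per
    ## distinct breakpoint in one left-to-right sweep, drawing each length
    ## from a finite pool that holds the configured MH distribution over
    ## the library's junctions (largest-remainder apportionment, weighted
    ## by each breakpoint's junction multiplicity). Unconstrained
    ## breakpoints draw from the configured distribution directly, and the
    ## pool steers later draws so the realized library-level distribution
    ## matches the configured one even at high junction density.
    mhRows <- ij[insLen[ij] == 0L & baitBreak[ij] == rss]
    if (length(mhRows)) {
      posW <- data.table(chrom = preyChrom[mhRows], b = preyBreak[mhRows])
      posW <- posW[, .(w = .N), by = .(chrom, b)]
      setorder(posW, chrom, b)
      np <- nrow(posW)
      mAssign <- assignTractLengths(posW, sim@mhModel, length(mhRows))
      ## write the tract structure: X-runs, then run breaks
      for (i in seq_len(np)) {
        ch <- posW$chrom[i]; bi <- posW$b[i]; m <- mAssign[i]
        if (m > 0L) for (j in seq_len(m)) tryWrite(ch, bi - j, X)
        lockOffTract(ch, bi - m - 1L)
      }
      ## junction points must differ from the bait cut base so the junction
      ## is right-anchored (v = 0); inside a continued run they are X != Y
      for (i in seq_len(np)) {
        ch <- posW$chrom[i]; bi <- posW$b[i]
        if (gchar(ch, bi) == Y) tryWrite(ch, bi, brk)
      }
      mMap <- setNames(mAssign, paste(posW$chrom, posW$b))
      mhLen[mhRows] <- unname(mMap[paste(preyChrom[mhRows],
                                         preyBreak[mhRows])])
    }

    ## --- adjacent-J joins: plant by copying the local bait flank --------
    ## (first-wins: the tract layout above is never overwritten; these
    ## reads carry no junction call, so their MH is whatever the
    ## realization pass reports). Never plant Y into a prey flank: it
    ## would block junction anchoring there.
    for (k in ij[insLen[ij] == 0L & baitBreak[ij] != rss]) {
      a <- baitBreak[k]; b <- preyBreak[k]; pchr <- preyChrom[k]
      m <- mhLen[k]
      if (m > 0L) for (i in seq_len(m)) {
        bc <- gchar(bchr, a - i)
        if (bc == Y) bc <- brk
        tryWrite(pchr, b - i, bc)
      }
      lockOffTract(pchr, b - m - 1L)
      bca <- gchar(bchr, a)
      if (gchar(pchr, b) == bca) tryWrite(pchr, b, brk)
    }

    ## --- untemplated insertions: drawn so they extend neither parent ----
    for (k in ij[insLen[ij] > 0L]) {
      a <- baitBreak[k]; b <- preyBreak[k]; pchr <- preyChrom[k]
      len <- insLen[k]
      ins <- sample(BASES, len, replace = TRUE)
      ba <- gchar(bchr, a)
      if (ins[1] == ba) ins[1] <- sample(setdiff(BASES, ba), 1L)
      pb <- gchar(pchr, b - 1L)
      forb <- if (len == 1L) unique(c(ba, pb)) else pb
      if (ins[len] %in% forb) ins[len] <- sample(setdiff(BASES, forb), 1L)
      insSeqDrawn[k] <- paste(ins, collapse = "")
    }

    ## apply the collected single-base edits
    keys <- ls(edits)
    if (length(keys)) {
      km <- matrix(unlist(strsplit(keys, ":", fixed = TRUE)), ncol = 2L,
                   byrow = TRUE)
      echrom <- km[, 1]; epos <- as.integer(km[, 2])
      echar <- vapply(keys, function(k) edits[[k]], "", USE.NAMES = FALSE)
      for (chr in unique(echrom)) {
        ch <- strsplit(gstr[[chr]], "")[[1]]
        sel <- echrom == chr
        ch[epos[sel] + 1L] <- echar[sel]
        gstr[[chr]] <- paste(ch, collapse = "")
      }
    }
  }

  ## realization pass on the finished genome
  maxW <- 25L
  gc2 <- function(chrom, pos) substr(gstr[[chrom]], pos + 1L, pos + 1L)
  elig <- eligibleSegments(annotation)
  for (k in ij) {
    a0 <- baitBreak[k]; b0 <- preyBreak[k]; pchr <- preyChrom[k]
    l1 <- L1[k]; insl <- insLen[k]
    l2 <- readLen - l1 - insl
    p1_rstart[k] <- a0 - l1
    p2_rend[k] <- b0 + l2
    if (insl > 0L) {
      ins <- insSeqDrawn[k]
      e1 <- 0L
      while (e1 < insl && substr(ins, e1 + 1L, e1 + 1L) == gc2(bchr, a0 + e1))
        e1 <- e1 + 1L
      rest <- insl - e1
      e2 <- 0L
      while (e2 < rest &&
             substr(ins, insl - e2, insl - e2) == gc2(pchr, b0 - 1L - e2))
        e2 <- e2 + 1L
      I <- substr(ins, e1 + 1L, insl - e2)
      a <- a0 + e1; b <- b0 - e2
      if (nchar(I) > 0L) {
        mhLen[k] <- 0L
        insSeqReal[k] <- I
        baitBreak[k] <- a; preyBreak[k] <- b
        p1_qend[k] <- l1 + e1;        p1_rend[k] <- a
        p2_qstart[k] <- l1 + insl - e2; p2_rstart[k] <- b
      } else {
        ## the whole insertion was absorbed by the parents (collision case)
        u <- 0L; v <- 0L
        while (u < maxW && gc2(bchr, a - 1L - u) == gc2(pchr, b - 1L - u))
          u <- u + 1L
        while (v < maxW && gc2(bchr, a + v) == gc2(pchr, b + v)) v <- v + 1L
        mhLen[k] <- u + v
        insSeqReal[k] <- ""
        baitBreak[k] <- a + v; preyBreak[k] <- b + v
        p1_qend[k] <- l1 + e1 + v;      p1_rend[k] <- a + v
        p2_qstart[k] <- l1 + insl - e2 - u; p2_rstart[k] <- b - u
      }
    } else {
      insSeqReal[k] <- ""
      u <- 0L; v <- 0L
      while (u < maxW && gc2(bchr, a0 - 1L - u) == gc2(pchr, b0 - 1L - u))
        u <- u + 1L
      while (v < maxW && gc2(bchr, a0 + v) == gc2(pchr, b0 + v)) v <- v + 1L
      mhLen[k] <- u + v
      baitBreak[k] <- a0 + v; preyBreak[k] <- b0 + v
      p1_qend[k] <- l1 + v;  p1_rend[k] <- a0 + v
      p2_qstart[k] <- l1 - u; p2_rstart[k] <- b0 - u
    }
    ## realized resection: distance to the nearest eligible RSS cut within
    ## the cap (what an ideal measurer would report), ties toward the
    ## lexicographically smaller name
    cand <- elig[elig$chrom == pchr, , drop = FALSE]
    resPrey[k] <- NA_integer_; resSide[k] <- NA_character_
    if (nrow(cand)) {
      d <- abs(preyBreak[k] - cand$rss_cut)
      best <- which(d == min(d))
      if (length(best) > 1L) best <- best[order(cand$name[best])][1L]
      if (d[best] <= sim@resectionModel$cap) {
        resPrey[k] <- d[best]
        cdir <- if (cand$coding_side[best] == "right") 1L else -1L
        resSide[k] <- if ((preyBreak[k] - cand$rss_cut[best]) * cdir >= 0L)
          "coding" else "signal"
      }
    }
  }

  ## build the reads
  reads2 <- character(n)
  contig <- which(!is.na(truth$contig_start))
  for (k in contig) {
    s <- truth$contig_start[k]
    reads2[k] <- substr(gstr[[truth$contig_chrom[k]]], s + 1L, s + readLen)
    p1_qend[k] <- readLen
    p1_rstart[k] <- s; p1_rend[k] <- s + readLen
  }
  for (k in ij) {
    l1 <- L1[k]
    ins <- insSeqDrawn[k]; if (is.na(ins)) ins <- ""
    a0 <- p1_rstart[k] + l1                       # original bait break
    b0 <- p2_rend[k] - (readLen - l1 - nchar(ins))  # original prey break
    reads2[k] <- paste0(
      substr(gstr[[bchr]], a0 - l1 + 1L, a0),
      ins,
      substr(gstr[[preyChrom[k]]], b0 + 1L, p2_rend[k]))
  }
  primer <- baitPrimerPos(annotation)
  reads1 <- rep(substr(gstr[[bchr]], primer + 1L, primer + readLen), n)
  nb <- which(!truth$has_bait)
  if (length(nb)) {
    sp <- sampleOtherPositions(length(nb), annotation, margin = readLen + 100L)
    reads1[nb] <- vapply(seq_along(nb), function(i)
      substr(gstr[[sp$chrom[i]]], sp$pos[i] + 1L, sp$pos[i] + readLen), "")
  }
  reads1 <- mutateReads(reads1, sim@seqErrorRate)
  reads2 <- mutateReads(reads2, sim@seqErrorRate)
  names(reads1) <- names(reads2) <- truth$read_id

  truth$bait_break <- baitBreak
  truth$prey_break <- preyBreak
  truth$mh_len <- mhLen
  truth$insertion_seq <- insSeqReal
  truth$insertion_len <- ifelse(is.na(insSeqReal), NA_integer_,
                                nchar(insSeqReal))
  truth$resection_prey <- resPrey
  truth$resection_side <- resSide
  truth$p1_qend <- p1_qend; truth$p1_rstart <- p1_rstart
  truth$p1_rend <- p1_rend
  truth$p2_qstart <- p2_qstart; truth$p2_rstart <- p2_rstart
  truth$p2_rend <- p2_rend

  genomeOut <- Biostrings::DNAStringSet(unlist(gstr))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    f1 <- file.path(dir, "reads_R1.fastq"); f2 <- file.path(dir, "reads_R2.fastq")
    fs <- file.path(dir, "truth.sam"); ft <- file.path(dir, "truth.tsv")
    writeFastq(reads1, f1)
    writeFastq(reads2, f2)
    writeTruthSam(truth, reads2, genomeOut, fs, seed = sim@seed)
    con <- file(ft, "w")
    writeLines(sprintf("# seed: %d", sim@seed), con)
    suppressWarnings(write.table(truth, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
    files <- list(fastq1 = f1, fastq2 = f2, sam = fs, truth = ft)
  }
  list(reads1 = reads1, reads2 = reads2, truth = truth, genome = genomeOut,
       files = files)
}

## Assign a microhomology tract length to every distinct prey breakpoint.
##
## A breakpoint's MH is the X-run ending just left of it, so lengths of
## breakpoints d bases apart are coupled: the right one can take any length
## 0..d-1 (a fresh run starting inside the gap) or continue the left one's
## run (length m_left + d). Breakpoints further than the model support
## apart are independent.
##
## Lengths are drawn against a quota urn holding the configured MH
## distribution over the library's junctions, weighted by each breakpoint's
## junction multiplicity: isolated breakpoints sample from the urn
## directly, while dense stretches of consecutive breakpoints are assigned
## by a short-horizon dynamic program (maximizing remaining-quota scores)
## so that runs can climb through small lengths to reach under-filled
## longer ones. The realized library-level MH distribution thus tracks the
## configured one across junction densities.
assignTractLengths <- function(posW, probs, nTotal, horizon = 10L) {
  maxM <- length(probs) - 1L
  quota <- probs * nTotal
  urn <- quota
  np <- nrow(posW)
  mAssign <- integer(np)
  newBlock <- c(TRUE, posW$chrom[-1] != posW$chrom[-np] |
                  (posW$b[-1] - posW$b[-np]) > maxM)
  drawUrn <- function(feas, w) {
    wts <- pmax(urn[feas + 1L], 0)
    m <- if (sum(wts) > 0) {
      if (length(feas) == 1L) feas else sample(feas, 1L, prob = wts)
    } else {
      pr <- probs[feas + 1L]
      if (length(feas) == 1L || sum(pr) == 0) feas[1L]
      else sample(feas, 1L, prob = pr)
    }
    urn[m + 1L] <<- urn[m + 1L] - w
    m
  }
  for (blk in split(seq_len(np), cumsum(newBlock))) {
    if (length(blk) == 1L) {
      mAssign[blk] <- drawUrn(0:maxM, posW$w[blk])
      next
    }
    gaps <- c(NA_integer_, diff(posW$b[blk]))
    prevM <- NA_integer_
    i0 <- 1L
    while (i0 <= length(blk)) {
      win <- blk[seq(i0, min(i0 + horizon - 1L, length(blk)))]
      B <- length(win)
      wgt <- posW$w[win]
      d <- gaps[seq(i0, i0 + B - 1L)]
      score <- pmax(urn, 0) / pmax(quota, 1e-9)
      NEG <- -1e18
      val <- matrix(NEG, B, maxM + 1L)
      ptr <- matrix(0L, B, maxM + 1L)
      feas1 <- if (is.na(prevM)) 0:maxM else {
        f <- 0:min(d[1] - 1L, maxM)
        if (prevM + d[1] <= maxM) f <- c(f, prevM + d[1])
        f
      }
      val[1L, feas1 + 1L] <- wgt[1] * score[feas1 + 1L]
      if (B > 1L) for (i in 2:B) {
        base <- val[i - 1L, ]
        bestPrev <- max(base); fromBest <- which.max(base)
        for (v in 0:maxM) {
          cand <- NEG; from <- 0L
          if (v <= d[i] - 1L) { cand <- bestPrev; from <- fromBest }
          pv <- v - d[i]
          if (pv >= 0L && pv <= maxM && base[pv + 1L] > cand) {
            cand <- base[pv + 1L]; from <- pv + 1L
          }
          if (cand > NEG) {
            val[i, v + 1L] <- cand + wgt[i] * score[v + 1L]
            ptr[i, v + 1L] <- from
          }
        }
      }
      ms <- integer(B)
      ms[B] <- which.max(val[B, ]) - 1L
      if (B > 1L) for (i in B:2) ms[i - 1L] <- ptr[i, ms[i] + 1L] - 1L
      mAssign[win] <- ms
      for (i in seq_len(B)) urn[ms[i] + 1L] <- urn[ms[i] + 1L] - wgt[i]
      prevM <- ms[B]
      i0 <- i0 + B
    }
  }
  mAssign
}

## apply per-base substitution errors
mutateReads <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  counts <- rbinom(length(seqs), len, rate)
  for (i in which(counts > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(len[i], counts[i])
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

writeFastq <- function(reads, path) {
  qual <- strrep("D", nchar(reads))  # constant Phred 35
  out <- character(4L * length(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", names(reads))
  out[c(FALSE, TRUE, FALSE, FALSE)] <- unname(reads)
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(out, path)
}

## truth split alignments for read2, primary + supplementary records
writeTruthSam <- function(truth, reads2, genome, path, seed) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)),
           sprintf("@CO\tsimulated truth alignments; seed: %d", seed))
  readLen <- nchar(reads2[1])
  contig <- !is.na(truth$contig_start)
  junct <- !is.na(truth$prey_break)
  recs <- character(0)
  if (any(contig)) {
    tc <- truth[contig, ]
    recs <- c(recs, sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                            tc$read_id, tc$contig_chrom, tc$p1_rstart + 1L,
                            readLen, reads2[tc$read_id]))
  }
  if (any(junct)) {
    tj <- truth[junct, ]
    cig1 <- sprintf("%dM%dS", tj$p1_qend, readLen - tj$p1_qend)
    cig2 <- sprintf("%dS%dM", tj$p2_qstart, readLen - tj$p2_qstart)
    recs <- c(recs,
              sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                      tj$read_id, tj$bait_chrom, tj$p1_rstart + 1L, cig1,
                      reads2[tj$read_id]),
              sprintf("%s\t2048\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                      tj$read_id, tj$prey_chrom, tj$p2_rstart + 1L, cig2,
                      reads2[tj$read_id]))
  }
  writeLines(c(hdr, recs), path)
}

#' Simulate a complete library: genome, truth, reads and files
#'
#' Convenience wrapper: builds a mini-genome, simulates truth, renders reads
#' (which realizes microhomology in the genome), and optionally writes
#' FASTA/FASTQ/SAM/TSV outputs.
#'
#' @param sim a \linkS4class{SimConfig}.
#' @param genomeConfig passed to [buildMiniGenome()].
#' @param dir output directory or NULL for in-memory only.
#' @return list with \code{genome}, \code{annotation}, \code{truth},
#'   \code{reads1}, \code{reads2}, \code{files}.
#' @export
simulateLibrary <- function(sim, genomeConfig = list(), dir = NULL) {
  mg <- buildMiniGenome(genomeConfig, rngSeed = sim@seed + 11L)
  truth <- simulateTruth(sim, mg$annotation, mg$genome)
  rr <- renderReads(truth, mg$genome, mg$annotation, sim, dir = dir)
  files <- rr$files
  if (!is.null(dir)) {
    fg <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(rr$genome, fg)
    files$genome <- fg
  }
  list(genome = rr$genome, annotation = mg$annotation, truth = rr$truth,
       reads1 = rr$reads1, reads2 = rr$reads2, files = files)
}
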