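## synthetic junction-library generator: ground truth, microhomology
## planting, and FASTQ/SAM/TSV rendering.

#' Construct a simulator configuration
#'
#' @param seed integer RNG seed (mandatory).
#' @param nPairs number of read pairs.
#' @param readLen read length (default 250).
#' @param fractions named proportions over
#'   \code{germline, bait_junction_cis, translocation_agr,
#'   translocation_nonagr, repeat_join, adjacent_j_join, long_mapped}.
#' @param resectionModel list(family, mean, sdlog, cap); see
#'   \linkS4class{SimConfig}.
#' @param mhModel probability vector over MH lengths 0..k, named "0","1",...
#' @param insertionModel list(prob, minLen, maxLen).
#' @param seqErrorRate per-base substitution probability.
#' @param adapterSeq bridge adapter sequence.
#' @param baitPrimerLen bait primer length on read1.
#' @param codingSideProb probability of coding-side resection.
#' @param noBaitFraction fraction of pairs lacking the bait primer.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed,
                      nPairs = 10000L,
                      readLen = 250L,
                      fractions = c(germline = 0.55, bait_junction_cis = 0.30,
                                    translocation_agr = 0.03,
                                    translocation_nonagr = 0.03,
                                    repeat_join = 0.03, adjacent_j_join = 0.03,
                                    long_mapped = 0.03),
                      resectionModel = list(family = "geometric", mean = 3.5,
                                            cap = 4000),
                      mhModel = mhProbsFromBinFraction(0.173, 0.322),
                      insertionModel = list(prob = 0.322, minLen = 1L,
                                            maxLen = 6L),
                      seqErrorRate = 0,
                      adapterSeq = "AGATCGGAAGAGCACACGTC",
                      baitPrimerLen = 20L,
                      codingSideProb = 0.5,
                      noBaitFraction = 0) {
  if (is.null(resectionModel$cap)) resectionModel$cap <- 4000
  obj <- new("SimConfig",
             seed = as.integer(seed), nPairs = as.integer(nPairs),
             readLen = as.integer(readLen),
             fractions = fractions[SIM_CATEGORIES],
             resectionModel = resectionModel,
             mhModel = mhModel,
             insertionModel = insertionModel,
             seqErrorRate = seqErrorRate,
             adapterSeq = adapterSeq,
             baitPrimerLen = as.integer(baitPrimerLen),
             codingSideProb = codingSideProb,
             noBaitFraction = noBaitFraction)
  validObject(obj)
  obj
}

#' MH length distribution with a prescribed 2-6 bp bin mass
#'
#' Builds a probability vector over MH lengths 0..8 such that, after
#' accounting for the insertion probability (insertions force MH = 0), the
#' overall fraction of junctions with 2-6 bp MH equals \code{frac26}. Mass
#' inside 2-6 is uniform; the remainder is split 0.55/0.30/0.10/0.05 over
#' lengths 0, 1, 7, 8.
#'
#' @param frac26 target overall fraction of junctions with MH in [2, 6].
#' @param insertionProb the configured insertion probability.
#' @export
mhProbsFromBinFraction <- function(frac26, insertionProb = 0) {
  cmass <- frac26 / (1 - insertionProb)
  if (cmass > 1 || cmass < 0)
    stop("requested 2-6 bp MH fraction is not attainable at this insertion probability",
         call. = FALSE)
  rest <- 1 - cmass
  p <- c(0.55 * rest, 0.30 * rest, rep(cmass / 5, 5), 0.10 * rest, 0.05 * rest)
  names(p) <- as.character(0:8)
  p
}

#' Preset simulator regimes matching the study conditions
#'
#' \describe{
#'   \item{wt_ablki}{G1-arrested NHEJ-proficient cells: mean resection 3.5 nt
#'     (geometric), 32.2\% of joins with untemplated insertions, 17.3\% with
#'     2-6 bp MH.}
#'   \item{xrcc4_g1}{G1-arrested XRCC4-deficient cells: mean resection 7.5 nt
#'     (geometric), 7.5\% insertions, 43.3\% 2-6 bp MH.}
#'   \item{xrcc4p53_released}{released XRCC4/p53-deficient cells: long
#'     resection, mean 730.1 nt (lognormal capped at 4000 nt, parameterized
#'     by its post-cap mean), 58.5\% 2-6 bp MH; the insertion fraction is not
#'     reported for this condition and defaults to 5\%.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param ... further arguments to [simConfig()] (e.g. \code{nPairs},
#'   \code{fractions}).
#' @return a \linkS4class{SimConfig}.
#' @export
simPreset <- function(name = c("wt_ablki", "xrcc4_g1", "xrcc4p53_released"),
                      seed, ...) {
  name <- match.arg(name)
  args <- switch(name,
    wt_ablki = list(
      resectionModel = list(family = "geometric", mean = 3.5, cap = 4000),
      insertionModel = list(prob = 0.322, minLen = 1L, maxLen = 6L),
      mhModel = mhProbsFromBinFraction(0.173, 0.322)),
    xrcc4_g1 = list(
      resectionModel = list(family = "geometric", mean = 7.5, cap = 4000),
      insertionModel = list(prob = 0.075, minLen = 1L, maxLen = 6L),
      mhModel = mhProbsFromBinFraction(0.433, 0.075)),
    xrcc4p53_released = list(
      resectionModel = list(family = "lognormal", mean = 730.1, sdlog = 0.8,
                            cap = 4000),
      insertionModel = list(prob = 0.05, minLen = 1L, maxLen = 6L),
      mhModel = mhProbsFromBinFraction(0.585, 0.05))
  )
  do.call(simConfig, modifyList(c(list(seed = seed), args), list(...)))
}

## mean of min(X, cap) for X ~ lognormal(mu, sdlog)
cappedLnormMean <- function(mu, sdlog, cap) {
  lk <- log(cap)
  exp(mu + sdlog^2 / 2) * pnorm((lk - mu - sdlog^2) / sdlog) +
    cap * (1 - pnorm((lk - mu) / sdlog))
}

## meanlog such that the capped distribution has the requested mean
lnormMeanlogForCappedMean <- function(target, sdlog, cap) {
  if (target >= cap) stop("target mean must be below the cap", call. = FALSE)
  uniroot(function(mu) cappedLnormMean(mu, sdlog, cap) - target,
          lower = log(target) - 6, upper = log(cap) + 6, tol = 1e-9)$root
}

## draw n resection lengths from the configured family, capped
drawResection <- function(model, n) {
  cap <- model$cap
  r <- switch(model$family,
    geometric = rgeom(n, 1 / (1 + model$mean)),
    lognormal = {
      mu <- lnormMeanlogForCappedMean(model$mean, model$sdlog, cap)
      as.integer(round(rlnorm(n, mu, model$sdlog)))
    },
    stop("unknown resection family: ", model$family, call. = FALSE))
  pmin(as.integer(r), as.integer(cap))
}

## rejection-sample positions whose region label is "other"
sampleOtherPositions <- function(n, annotation, margin = 600L) {
  lens <- chromLengths(annotation)
  out_chrom <- character(0); out_pos <- integer(0)
  while (length(out_pos) < n) {
    m <- max(2L * (n - length(out_pos)), 32L)
    chr <- sample(names(lens), m, replace = TRUE, prob = as.numeric(lens))
    pos <- as.integer(floor(runif(m, margin, lens[chr] - margin)))
    ok <- regionOf(annotation, chr, pos) == "other"
    out_chrom <- c(out_chrom, chr[ok]); out_pos <- c(out_pos, pos[ok])
  }
  list(chrom = out_chrom[seq_len(n)], pos = out_pos[seq_len(n)])
}

#' Simulate ground truth for a junction library
#'
#' Draws a category for every read pair and, for junction-bearing
#' categories, the prey breakpoint (an RSS cut shifted by a capped resection
#' draw toward the coding or signal side), the microhomology length or
#' untemplated insertion length (mutually exclusive), and the prey region
#' label. The bait break sits at the bait RSS cut; adjacent-J joins carry a
#' bait-side alignment crossing the bait RSS.
#'
#' Microhomology and insertion values recorded here are the \emph{drawn}
#' values; [renderReads()] realizes them in the genome and returns the truth
#' table with the realized (and exactly consistent) values.
#'
#' @param sim a \linkS4class{SimConfig}.
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param genome the matching \link[Biostrings]{DNAStringSet}.
#' @return a data.frame, one row per read pair.
#' @export
simulateTruth <- function(sim, annotation, genome) {
  set.seed(sim@seed)
  n <- sim@nPairs
  cat_ <- sample(SIM_CATEGORIES, n, replace = TRUE, prob = sim@fractions)
  truth <- data.table(
    read_id = sprintf("sim%06d", seq_len(n)),
    category = cat_,
    has_bait = runif(n) >= sim@noBaitFraction,
    bait_chrom = NA_character_, bait_break = NA_integer_, bait_strand = "+",
    prey_chrom = NA_character_, prey_break = NA_integer_, prey_strand = "+",
    resection_bait = 0L, resection_prey = NA_integer_,
    resection_side = NA_character_, segment = NA_character_,
    mh_len = NA_integer_, insertion_len = NA_integer_,
    insertion_seq = NA_character_,
    prey_region_label = NA_character_,
    contig_chrom = NA_character_, contig_start = NA_integer_
  )
  gw <- germlineWindow(annotation)
  rss <- baitRSS(annotation)
  bchr <- baitChrom(annotation)
  junctionCats <- c("bait_junction_cis", "translocation_agr",
                    "translocation_nonagr", "repeat_join", "adjacent_j_join")

  ## contiguous categories
  ig <- which(cat_ == "germline")
  if (length(ig)) {
    truth[ig, `:=`(contig_chrom = bchr,
                   contig_start = as.integer(floor(runif(length(ig), gw[1],
                                                         gw[2] - sim@readLen))))]
  }
  il <- which(cat_ == "long_mapped")
  if (length(il)) {
    sp <- sampleOtherPositions(length(il), annotation,
                               margin = sim@readLen + 100L)
    truth[il, `:=`(contig_chrom = sp$chrom, contig_start = sp$pos)]
  }

  ij <- which(cat_ %in% junctionCats)
  if (length(ij)) {
    m <- length(ij)
    truth[ij, `:=`(bait_chrom = bchr, bait_break = as.integer(rss))]
    ## adjacent-J joins: bait-side alignment crosses the bait RSS
    ia <- which(cat_ == "adjacent_j_join")
    if (length(ia))
      truth[ia, bait_break := as.integer(rss + sample(5:100, length(ia),
                                                      replace = TRUE))]
    ## prey breakpoints
    elig <- eligibleSegments(annotation)
    vseg <- elig[elig$klass == "V", , drop = FALSE]
    if (!nrow(vseg)) stop("no eligible V segments in annotation", call. = FALSE)
    iv <- which(cat_ %in% c("bait_junction_cis", "adjacent_j_join"))
    if (length(iv)) {
      pick <- sample(nrow(vseg), length(iv), replace = TRUE)
      side_coding <- runif(length(iv)) < sim@codingSideProb
      r <- drawResection(sim@resectionModel, length(iv))
      codingDir <- ifelse(vseg$coding_side[pick] == "right", 1L, -1L)
      dir <- ifelse(side_coding, codingDir, -codingDir)
      truth[iv, `:=`(
        prey_chrom = vseg$chrom[pick],
        prey_break = as.integer(vseg$rss_cut[pick] + dir * r),
        resection_prey = r,
        resection_side = ifelse(side_coding, "coding", "signal"),
        segment = vseg$name[pick])]
    }
    iagr <- which(cat_ == "translocation_agr")
    if (length(iagr)) {
      agr <- agrRegions(annotation)
      if (!nrow(agr)) stop("annotation has no AgR regions", call. = FALSE)
      row <- sample(nrow(agr), length(iagr), replace = TRUE)
      truth[iagr, `:=`(
        prey_chrom = agr$chrom[row],
        prey_break = as.integer(floor(runif(length(iagr), agr$start[row] + 20,
                                            agr$end[row] - sim@readLen))))]
    }
    inon <- which(cat_ == "translocation_nonagr")
    if (length(inon)) {
      sp <- sampleOtherPositions(length(inon), annotation,
                                 margin = sim@readLen + 100L)
      truth[inon, `:=`(prey_chrom = sp$chrom, prey_break = sp$pos)]
    }
    irep <- which(cat_ == "repeat_join")
    if (length(irep)) {
      reps <- repeatRegions(annotation)
      if (!nrow(reps)) stop("annotation has no repeat regions", call. = FALSE)
      row <- sample(nrow(reps), length(irep), replace = TRUE)
      truth[irep, `:=`(
        prey_chrom = reps$chrom[row],
        prey_break = as.integer(floor(runif(length(irep), reps$start[row] + 20,
                                            reps$end[row] - 40))))]
    }
    ## MH or insertion, mutually exclusive
    hasIns <- runif(m) < sim@insertionModel$prob
    mh <- sample(seq_along(sim@mhModel) - 1L, m, replace = TRUE,
                 prob = sim@mhModel)
    insLen <- sample(sim@insertionModel$minLen:sim@insertionModel$maxLen, m,
                     replace = TRUE)
    truth[ij, `:=`(mh_len = ifelse(hasIns, 0L, mh),
                   insertion_len = ifelse(hasIns, insLen, 0L))]
    truth[ij, prey_region_label := regionOf(annotation, prey_chrom, prey_break)]
  }
  setDF(truth)
  truth
}
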