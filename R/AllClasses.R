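#' @import methods
#' @import data.table
#' @importFrom stats rbinom rgeom rlnorm rmultinom runif median pnorm uniroot setNames
#' @importFrom utils head read.delim write.table
NULL

## read categories the simulator can emit and the classifier must recover
SIM_CATEGORIES <- c(
  "germline", "bait_junction_cis", "translocation_agr", "translocation_nonagr",
  "repeat_join", "adjacent_j_join", "long_mapped"
)

READ_LABELS <- c(
  "germline", "mapped_gt75", "unique_repeat", "split_join_adjacent_J",
  "split_join_bait", "other_filtered"
)

PREY_CATEGORIES <- c("cis_v_region", "trans_agr", "trans_non_agr", "none")

#' LocusAnnotation: a validated model of the bait locus
#'
#' Holds the annotated V and J gene segments (with their RSS cut coordinates),
#' the bait definition (segment, primer position, bait window), the germline
#' window, the V-region interval, and antigen-receptor (AgR) and repeat
#' intervals. All coordinates are 0-based half-open.
#'
#' @slot segments data.frame with columns \code{chrom, start, end, name,
#'   strand, klass, rss_cut, coding_side}, sorted by (chrom, start).
#' @slot baitSegment name of the bait J segment.
#' @slot baitPrimerPos 0-based bait primer coordinate on the bait chromosome.
#' @slot germlineWindow numeric length-2 \code{c(start, end)} on the bait
#'   chromosome; unsplit reads fully inside it are germline.
#' @slot vRegion data.frame (chrom, start, end), the cis V-region interval.
#' @slot agrRegions data.frame (chrom, start, end, name) of AgR loci.
#' @slot repeatRegions data.frame (chrom, start, end) of annotated repeats.
#' @slot chromLengths named integer vector of chromosome lengths.
#' @export
setClass("LocusAnnotation", representation(
  segments      = "data.frame",
  baitSegment   = "character",
  baitPrimerPos = "numeric",
  germlineWindow = "numeric",
  vRegion       = "data.frame",
  agrRegions    = "data.frame",
  repeatRegions = "data.frame",
  chromLengths  = "integer"
))

setValidity("LocusAnnotation", function(object) {
  seg <- object@segments
  msgs <- character()
  need <- c("chrom", "start", "end", "name", "strand", "klass", "rss_cut", "coding_side")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    return(sprintf("segment table is missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(seg$name))
    msgs <- c(msgs, "duplicate segment names")
  if (any(seg$end <= seg$start))
    msgs <- c(msgs, sprintf("segment with end <= start: %s",
                            paste(seg$name[seg$end <= seg$start], collapse = ", ")))
  if (!all(seg$klass %in% c("V", "J")))
    msgs <- c(msgs, "klass must be V or J")
  if (!all(seg$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be + or -")
  if (!all(seg$coding_side %in% c("left", "right")))
    msgs <- c(msgs, "coding_side must be left or right")
  bad_rss <- seg$rss_cut < seg$start - 1L | seg$rss_cut > seg$end + 1L
  if (any(bad_rss))
    msgs <- c(msgs, sprintf("rss_cut outside segment boundary window for: %s",
                            paste(seg$name[bad_rss], collapse = ", ")))
  if (length(object@chromLengths)) {
    unk <- setdiff(seg$chrom, names(object@chromLengths))
    if (length(unk))
      msgs <- c(msgs, sprintf("segment chromosome(s) not in genome: %s",
                              paste(unique(unk), collapse = ", ")))
    oob <- seg$rss_cut < 0 | seg$rss_cut > object@chromLengths[seg$chrom]
    if (any(oob, na.rm = TRUE))
      msgs <- c(msgs, sprintf("rss_cut outside chromosome for segment: %s",
                              paste(seg$name[which(oob)], collapse = ", ")))
  }
  if (!object@baitSegment %in% seg$name) {
    msgs <- c(msgs, sprintf("bait segment '%s' not found", object@baitSegment))
  } else {
    bs <- seg[seg$name == object@baitSegment, ]
    if (bs$klass != "J")
      msgs <- c(msgs, "bait segment must have klass J")
    margin <- 2000
    if (object@baitPrimerPos < bs$start - margin || object@baitPrimerPos > bs$end + margin)
      msgs <- c(msgs, "bait primer position is not near the bait segment")
  }
  if (nrow(object@vRegion) == 1 && length(msgs) == 0L) {
    bw <- baitWindow(object)
    if (object@vRegion$chrom == seg$chrom[seg$name == object@baitSegment] &&
        object@vRegion$start < bw[2] && object@vRegion$end > bw[1])
      msgs <- c(msgs, "v_region overlaps the bait window")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SimConfig: parameters of the synthetic junction-library generator
#'
#' @slot seed integer RNG seed; the whole library is a deterministic function
#'   of the configuration.
#' @slot nPairs number of read pairs to simulate.
#' @slot readLen read length in bp (default 250, 2x250 chemistry).
#' @slot fractions named proportions over the read categories
#'   \code{germline, bait_junction_cis, translocation_agr,
#'   translocation_nonagr, repeat_join, adjacent_j_join, long_mapped};
#'   must sum to 1.
#' @slot resectionModel list describing the prey-side resection distribution:
#'   \code{family} ("geometric" or "lognormal"), \code{mean} (nt; for the
#'   lognormal family this is the mean of the capped distribution),
#'   \code{sdlog} (lognormal only) and \code{cap} (default 4000 nt).
#' @slot mhModel named numeric vector of probabilities over microhomology
#'   lengths 0..k (names "0", "1", ...).
#' @slot insertionModel list \code{prob, minLen, maxLen}: probability that a
#'   junction carries an untemplated insertion (mutually exclusive with
#'   MH > 0) and the uniform length range.
#' @slot seqErrorRate per-base substitution error probability.
#' @slot adapterSeq bridge-adapter sequence (available to preprocessing
#'   tests; rendered fragments span the full read so reads carry no adapter).
#' @slot baitPrimerLen length of the bait primer at the 5' end of read1.
#' @slot codingSideProb probability that prey resection runs toward the
#'   coding side of the RSS cut (else signal side).
#' @slot noBaitFraction fraction of pairs rendered without the bait primer
#'   on read1 (they must be removed by the bait filter).
#' @export
setClass("SimConfig", representation(
  seed           = "integer",
  nPairs         = "integer",
  readLen        = "integer",
  fractions      = "numeric",
  resectionModel = "list",
  mhModel        = "numeric",
  insertionModel = "list",
  seqErrorRate   = "numeric",
  adapterSeq     = "character",
  baitPrimerLen  = "integer",
  codingSideProb = "numeric",
  noBaitFraction = "numeric"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  f <- object@fractions
  if (!setequal(names(f), SIM_CATEGORIES))
    msgs <- c(msgs, sprintf("fractions must be named over: %s",
                            paste(SIM_CATEGORIES, collapse = ", ")))
  if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9)
    msgs <- c(msgs, "fractions must lie in [0,1] and sum to 1")
  rm_ <- object@resectionModel
  if (!rm_$family %in% c("geometric", "lognormal"))
    msgs <- c(msgs, "resection family must be geometric or lognormal")
  if (is.null(rm_$cap) || rm_$cap <= 0)
    msgs <- c(msgs, "resection cap must be > 0")
  mh <- object@mhModel
  if (any(mh < 0) || abs(sum(mh) - 1) > 1e-9)
    msgs <- c(msgs, "mhModel probabilities must be nonnegative and sum to 1")
  if (!identical(names(mh), as.character(seq_along(mh) - 1L)))
    msgs <- c(msgs, "mhModel must be named '0','1',... contiguously")
  im <- object@insertionModel
  if (im$prob < 0 || im$prob > 1 || im$minLen < 1 || im$maxLen < im$minLen)
    msgs <- c(msgs, "invalid insertionModel")
  if (object@seqErrorRate < 0 || object@seqErrorRate > 0.2)
    msgs <- c(msgs, "seqErrorRate must be in [0, 0.2]")
  if (object@readLen < 2 * (length(mh) - 1 + 20))
    msgs <- c(msgs, "readLen too short for the configured MH range")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' LibrarySummary: per-library category counts and junction statistics
#'
#' @slot libraryId library identifier.
#' @slot totalMapped denominator: reads passing the bait and quality filters
#'   whose read2 mapped (all classification labels, including germline).
#' @slot labelCounts data.frame (label, count) over read classes.
#' @slot preyCounts data.frame (prey_category, count) over bait junctions.
#' @slot junctionCount number of cis V-region junctions.
#' @slot translocationCount number of trans AgR junctions (optionally
#'   restricted to named loci).
#' @slot junctionPct,translocationPct percentages of \code{totalMapped}.
#' @slot features junction feature summary from [summarizeFeatures()].
#' @export
setClass("LibrarySummary", representation(
  libraryId          = "character",
  totalMapped        = "numeric",
  labelCounts        = "data.frame",
  preyCounts         = "data.frame",
  junctionCount      = "numeric",
  translocationCount = "numeric",
  junctionPct        = "numeric",
  translocationPct   = "numeric",
  features           = "list"
))

setValidity("LibrarySummary", function(object) {
  if (object@totalMapped > 0 &&
      abs(object@junctionPct - 100 * object@junctionCount / object@totalMapped) > 1e-6)
    return("junctionPct inconsistent with counts")
  if (object@junctionPct < 0 || object@junctionPct > 100)
    return("percentages must lie in [0, 100]")
  TRUE
})
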