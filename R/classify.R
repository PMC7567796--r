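## read2 decision tree: per-read category labels and bait->prey junction
## calls.

#' Classify read2 alignments and call bait junctions
#'
#' Applies the read2 decision tree in fixed order:
#' \enumerate{
#'   \item not split and fully inside the germline window -> \code{germline};
#'   \item not split and mapped query length > 75\% of the read length ->
#'     \code{mapped_gt75};
#'   \item split and some part uniquely within annotated repeats ->
#'     \code{unique_repeat};
#'   \item split and the bait-side part crosses the bait RSS cut away from
#'     the primer -> \code{split_join_adjacent_J};
#'   \item split with the bait-side part between the bait RSS cut and the
#'     primer -> \code{split_join_bait}, emitting a junction call whose prey
#'     is the next query part; the prey category follows [regionOf()]
#'     (v_region -> \code{cis_v_region}, AgR -> \code{trans_agr}, else
#'     \code{trans_non_agr});
#'   \item otherwise \code{other_filtered}.
#' }
#' Reads with more than three parts are \code{other_filtered} (reason
#' \code{multi_split}). The bait-side part is the part with the smallest
#' query start: by library construction read2 begins nearest the bait.
#'
#' Junctions are reported right-anchored: the bait breakpoint is the
#' RSS-facing edge of the bait part, and the prey breakpoint is the prey
#' part's junction-facing edge shifted past the query overlap, so that a
#' microhomology tract is attributed to the bait side.
#'
#' @param parts alignment parts of the surviving reads (from
#'   [qualityFilter()]).
#' @param annotation a \linkS4class{LocusAnnotation}.
#' @param readLens named integer vector of (post-trim) read2 lengths.
#' @return list with \code{classes} (data.frame read_id, label,
#'   prey_category) and \code{junctions} (one row per split_join_bait read:
#'   breakpoints, query gap, prey category and the part coordinates needed
#'   by the feature callers).
#' @export
classifyReads <- function(parts, annotation, readLens) {
  parts <- as.data.table(parts)
  emptyClasses <- data.frame(read_id = character(), label = character(),
                             prey_category = character(),
                             stringsAsFactors = FALSE)
  if (!nrow(parts)) return(list(classes = emptyClasses,
                                junctions = emptyJunctions()))
  if (!"in_repeat" %in% names(parts)) parts[, in_repeat := FALSE]
  setorder(parts, read_id, query_start)
  bchr <- baitChrom(annotation)
  rss <- baitRSS(annotation)
  bw <- baitWindow(annotation)
  gw <- germlineWindow(annotation)
  reps <- repeatRegions(annotation)
  ptInRep <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(reps)))
      hit <- hit | (chrom == reps$chrom[i] & pos >= reps$start[i] &
                    pos < reps$end[i])
    hit
  }

  ## one row per read: first (bait-side) and second part side by side
  parts[, pidx := seq_len(.N), by = read_id]
  parts[, nparts := .N, by = read_id]
  ## junction-facing edge of each part, for the repeat-join test
  parts[, inner := ifelse(pidx == 1L,
                          ifelse(strand == "+", ref_end, ref_start),
                          ifelse(strand == "+", ref_start, ref_end))]
  parts[, inner_rep := ptInRep(chrom, inner)]
  w1 <- parts[pidx == 1L]
  w2 <- parts[pidx == 2L]
  cls <- w1[, .(read_id, nparts, chrom1 = chrom, strand1 = strand,
                rs1 = ref_start, re1 = ref_end, qs1 = query_start,
                qe1 = query_end)]
  cls <- merge(cls, w2[, .(read_id, chrom2 = chrom, strand2 = strand,
                           rs2 = ref_start, re2 = ref_end,
                           qs2 = query_start, qe2 = query_end)],
               by = "read_id", all.x = TRUE)
  anyRep <- parts[, .(any_rep = any(inner_rep)), by = read_id]
  cls <- merge(cls, anyRep, by = "read_id")
  cls[, rl := unname(readLens[read_id])]

  unsplit <- cls$nparts == 1L
  germ <- unsplit & cls$chrom1 == bchr & cls$rs1 >= gw[1] & cls$re1 <= gw[2]
  gt75 <- unsplit & !germ & !is.na(cls$rl) &
    (cls$qe1 - cls$qs1) > 0.75 * cls$rl
  splitOk <- cls$nparts %in% c(2L, 3L)
  repJoin <- splitOk & cls$any_rep
  crosses <- splitOk & !repJoin & cls$chrom1 == bchr &
    cls$rs1 < rss & cls$re1 > rss
  inBait <- splitOk & !repJoin & !crosses & cls$chrom1 == bchr &
    cls$rs1 >= bw[1] & cls$re1 <= bw[2]

  cls[, label := "other_filtered"]
  cls[germ, label := "germline"]
  cls[gt75, label := "mapped_gt75"]
  cls[repJoin, label := "unique_repeat"]
  cls[crosses, label := "split_join_adjacent_J"]
  cls[inBait, label := "split_join_bait"]

  ## junction calls for split_join_bait reads
  primerLeft <- rss >= baitPrimerPos(annotation)
  cls[, `:=`(bait_chrom = NA_character_, bait_break = NA_integer_,
             bait_strand = NA_character_, prey_chrom = NA_character_,
             prey_break = NA_integer_, prey_strand = NA_character_,
             query_gap = NA_integer_, bait_qend = NA_integer_,
             prey_qstart = NA_integer_, prey_rstart = NA_integer_,
             prey_rend = NA_integer_)]
  if (any(inBait)) {
    o <- pmax(0L, cls$qe1[inBait] - cls$qs2[inBait])
    cls[inBait, `:=`(
      bait_chrom = chrom1,
      bait_break = if (primerLeft) re1 else rs1,
      bait_strand = strand1,
      prey_chrom = chrom2,
      prey_break = ifelse(strand2 == "+", rs2 + o, re2 - o),
      prey_strand = strand2,
      query_gap = qs2 - qe1,
      bait_qend = qe1,
      prey_qstart = qs2,
      prey_rstart = rs2, prey_rend = re2)]
  }

  cls[, prey_category := "none"]
  isj <- cls$label == "split_join_bait"
  if (any(isj)) {
    lab <- regionOf(annotation, cls$prey_chrom[isj], cls$prey_break[isj])
    cls$prey_category[isj] <- ifelse(lab == "v_region", "cis_v_region",
                              ifelse(startsWith(lab, "agr:"), "trans_agr",
                                     "trans_non_agr"))
    cls$prey_region_label <- NA_character_
    cls$prey_region_label[isj] <- lab
  } else {
    cls[, prey_region_label := NA_character_]
  }
  junctions <- cls[isj, c("read_id", "bait_chrom", "bait_break", "bait_strand",
                          "prey_chrom", "prey_break", "prey_strand",
                          "query_gap", "prey_category", "prey_region_label",
                          "bait_qend", "prey_qstart", "prey_rstart",
                          "prey_rend"), with = FALSE]
  classes <- cls[, .(read_id, label, prey_category)]
  setDF(classes); setDF(junctions)
  list(classes = classes, junctions = junctions)
}

emptyJunctions <- function() {
  data.frame(read_id = character(), bait_chrom = character(),
             bait_break = integer(), bait_strand = character(),
             prey_chrom = character(), prey_break = integer(),
             prey_strand = character(), query_gap = integer(),
             prey_category = character(), prey_region_label = character(),
             bait_qend = integer(), prey_qstart = integer(),
             prey_rstart = integer(), prey_rend = integer(),
             stringsAsFactors = FALSE)
}

#' Tabulate read-class labels and prey categories
#'
#' @param classes data.frame from [classifyReads()].
#' @return list with \code{labels} (data.frame label, count over all labels,
#'   zeros included) and \code{prey} (data.frame prey_category, count);
#'   \code{total} is the number of classified reads.
#' @export
tabulateClasses <- function(classes) {
  lab <- table(factor(classes$label, levels = READ_LABELS))
  prey <- table(factor(classes$prey_category, levels = PREY_CATEGORIES))
  list(labels = data.frame(label = names(lab), count = as.integer(lab),
                           stringsAsFactors = FALSE),
       prey = data.frame(prey_category = names(prey),
                         count = as.integer(prey), stringsAsFactors = FALSE),
       total = nrow(classes))
}
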