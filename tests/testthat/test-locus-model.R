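test_that("annotation files load, validate and sort", {
  mg <- buildMiniGenome(list(nV = 10L), rngSeed = 3L)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); tsv <- file.path(dir, "seg.tsv")
  Biostrings::writeXStringSet(mg$genome, fa)
  seg <- geneSegments(mg$annotation)
  write.table(seg[sample(nrow(seg)), ], tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- list(bait_segment = "J4", bait_primer_pos = 1000,
              v_region = as.list(vRegion(mg$annotation)))
  got <- loadAnnotation(fa, tsv, cfg)
  gs <- geneSegments(got$annotation)
  expect_equal(nrow(gs), 14L)
  expect_true(!is.unsorted(gs$start[gs$chrom == "chrA"]))
  expect_equal(baitRSS(got$annotation), baitRSS(mg$annotation))

  ## missing column reported by name
  bad <- seg; bad$rss_cut <- NULL
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadAnnotation(fa, tsv, cfg), "rss_cut")

  ## end <= start rejected
  bad <- seg; bad$end[1] <- bad$start[1]
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadAnnotation(fa, tsv, cfg), "end <= start")
})

test_that("segment eligibility follows the 4-kb spacing rule", {
  g <- tinyGenome()
  ## gaps of 5000 between consecutive V segments: all kept
  ann <- tinyAnnotation(g, vStarts = c(20000L, 25300L, 30600L))
  expect_equal(sum(eligibleSegments(ann)$klass == "V"), 3L)

  ## gap of 3999 removes both members; the distant third stays
  ann <- tinyAnnotation(g, vStarts = c(20000L, 20300L + 3999L, 40000L))
  keep <- eligibleSegments(ann)
  expect_equal(keep$name[keep$klass == "V"], "V003")
  ## at exactly 4000 both flip back in
  ann <- tinyAnnotation(g, vStarts = c(20000L, 20300L + 4000L, 40000L))
  expect_equal(sum(eligibleSegments(ann)$klass == "V"), 3L)

  ## single V segment is kept; J segments always retained
  ann <- tinyAnnotation(g, vStarts = 20000L)
  keep <- eligibleSegments(ann)
  expect_equal(sum(keep$klass == "V"), 1L)
  expect_equal(sum(keep$klass == "J"), 4L)
})

test_that("a mini-genome with 144 spaced V segments keeps all of them", {
  mg <- buildMiniGenome(list(nV = 144L), rngSeed = 5L)
  keep <- eligibleSegments(mg$annotation)
  expect_equal(sum(keep$klass == "V"), 144L)
})

test_that("region labels resolve overlaps by fixed priority", {
  g <- tinyGenome()
  ann <- tinyAnnotation(g)
  expect_equal(regionOf(ann, "chrA", 1100L), "bait")       # inside germline too
  expect_equal(regionOf(ann, "chrA", 4000L), "germline_window")
  expect_equal(regionOf(ann, "chrA", 25000L), "v_region")
  expect_equal(regionOf(ann, "chrB", 6000L), "agr:Igl")
  expect_equal(regionOf(ann, "chrB", 20100L), "repeat")
  expect_equal(regionOf(ann, "chrB", 29000L), "other")
  expect_error(regionOf(ann, "chrZ", 10L), "unknown chromosome")

  ## total over random in-bounds positions; eligibility is idempotent and
  ## order-independent
  set.seed(1)
  chrom <- sample(c("chrA", "chrB"), 200, replace = TRUE)
  pos <- ifelse(chrom == "chrA", sample(60000L, 200), sample(30000L, 200))
  labs <- regionOf(ann, chrom, pos)
  expect_true(all(labs %in% c("bait", "germline_window", "v_region",
                              "agr:Igl", "repeat", "other")))
  e1 <- eligibleSegments(ann)
  expect_identical(eligibleSegments(ann), e1)
})

test_that("genome slices match segment widths", {
  mg <- buildMiniGenome(list(nV = 8L), rngSeed = 9L)
  seg <- geneSegments(mg$annotation)
  for (i in seq_len(nrow(seg))) {
    sl <- Biostrings::subseq(mg$genome[[seg$chrom[i]]],
                             seg$start[i] + 1L, seg$end[i])
    expect_equal(length(sl), seg$end[i] - seg$start[i])
  }
})
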