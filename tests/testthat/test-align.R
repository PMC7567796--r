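test_that("exact substrings align as one full-coverage part", {
  g <- tinyGenome(seed = 2L)
  gA <- as.character(g[["chrA"]])
  reads <- c(r1 = substr(gA, 10001, 10080))
  parts <- naiveAlign(reads, g)
  expect_equal(nrow(parts), 1L)
  expect_equal(parts$ref_start, 10000L)
  expect_equal(parts$ref_end, 10080L)
  expect_equal(parts$query_end - parts$query_start, 80L)
  expect_equal(parts$mapq, 60L)
  expect_equal(parts$n_candidates, 1L)
})

test_that("chimeric reads split into two adjacent query parts", {
  g <- tinyGenome(seed = 2L)
  gA <- as.character(g[["chrA"]]); gB <- as.character(g[["chrB"]])
  reads <- c(chim = paste0(substr(gA, 5001, 5040), substr(gB, 15001, 15040)))
  parts <- naiveAlign(reads, g)
  expect_equal(nrow(parts), 2L)
  expect_equal(parts$chrom, c("chrA", "chrB"))
  ## brute-force substring oracle agrees with the reported intervals
  expect_equal(regexpr(substr(reads, 1, 40), gA, fixed = TRUE)[1] - 1L,
               parts$ref_start[1])
  expect_equal(regexpr(substr(reads, 41, 80), gB, fixed = TRUE)[1] - 1L,
               parts$ref_start[2])
  ## query intervals adjacent up to the MH window
  expect_lte(parts$query_start[2] - parts$query_end[1], 0L)
})

test_that("reads from identical repeat copies are multi-candidate", {
  mg <- buildMiniGenome(list(nV = 6L, repeatDivergence = 0), rngSeed = 12L)
  reps <- repeatRegions(mg$annotation)
  gC <- as.character(mg$genome[[reps$chrom[1]]])
  rd <- c(rep1 = substr(gC, reps$start[1] + 51L, reps$start[1] + 130L))
  parts <- naiveAlign(rd, mg$genome)
  expect_equal(nrow(parts), 1L)
  expect_equal(parts$n_candidates, 2L)
  expect_equal(parts$mapq, 0L)
})

test_that("minus-strand reads are placed with correct coordinates", {
  g <- tinyGenome(seed = 2L)
  gA <- as.character(g[["chrA"]])
  fwd <- substr(gA, 8001, 8080)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  parts <- naiveAlign(c(m = rc), g)
  expect_equal(nrow(parts), 1L)
  expect_equal(parts$strand, "-")
  expect_equal(parts$ref_start, 8000L)
  expect_equal(parts$ref_end, 8080L)
})

test_that("SAM round trip recovers the truth alignment parts", {
  sim <- simConfig(seed = 23L, nPairs = 200L)
  dir <- withr::local_tempdir()
  lib <- simulateLibrary(sim, genomeConfig = list(nV = 10L), dir = dir)
  parts <- loadSAM(lib$files$sam)
  tr <- lib$truth
  ## junction reads: two parts matching the truth intervals exactly
  jr <- tr[!is.na(tr$prey_break), ]
  for (k in head(seq_len(nrow(jr)), 40)) {
    p <- parts[parts$read_id == jr$read_id[k], ]
    expect_equal(nrow(p), 2L)
    expect_equal(p$ref_start, c(jr$p1_rstart[k], jr$p2_rstart[k]))
    expect_equal(p$ref_end, c(jr$p1_rend[k], jr$p2_rend[k]))
    expect_equal(p$query_start, c(0L, jr$p2_qstart[k]))
    expect_equal(p$query_end, c(jr$p1_qend[k], nchar(lib$reads2[[1]])))
  }
  ## contiguous reads: one full part
  cr <- tr[!is.na(tr$contig_start), ][1, ]
  p <- parts[parts$read_id == cr$read_id, ]
  expect_equal(nrow(p), 1L)
  expect_equal(p$ref_start, cr$contig_start)
})

test_that("the mapping-quality filter drops at 10 with a repeat exception", {
  g <- tinyGenome()
  ann <- tinyAnnotation(g)
  mkparts <- function(mapq, n_candidates = 1L, chrom = "chrA",
                      rs = 25000L, re = 25100L) {
    data.frame(read_id = "r", mate = 2L, chrom = chrom, ref_start = rs,
               ref_end = re, query_start = 0L, query_end = 100L,
               strand = "+", mapq = mapq, n_candidates = n_candidates)
  }
  expect_equal(nrow(qualityFilter(mkparts(60L), ann)$parts), 1L)
  expect_equal(nrow(qualityFilter(mkparts(10L), ann)$parts), 1L)
  qf <- qualityFilter(mkparts(9L), ann)
  expect_equal(nrow(qf$parts), 0L)
  expect_equal(qf$log$reason, "low_mapq")
  qf <- qualityFilter(mkparts(0L, n_candidates = 2L), ann)
  expect_equal(qf$log$reason, "multi_mapped")
  ## multi-candidate part inside an annotated repeat is kept and flagged
  rp <- mkparts(0L, n_candidates = 2L, chrom = "chrB",
                rs = 20050L, re = 20150L)
  rp$alt <- I(list(data.frame(chrom = "chrB", ref_start = 20060L,
                              ref_end = 20160L, strand = "+")))
  qf <- qualityFilter(rp, ann)
  expect_equal(nrow(qf$parts), 1L)
  expect_true(qf$parts$in_repeat)
})
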