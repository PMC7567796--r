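test_that("MH and insertion calls round-trip the simulator truth", {
  sim <- simConfig(seed = 37L, nPairs = 600L,
                   fractions = junctionOnlyFractions,
                   insertionModel = list(prob = 0.25, minLen = 1L,
                                         maxLen = 6L),
                   mhModel = mhProbsFromBinFraction(0.45, 0.25))
  lib <- simulateLibrary(sim, genomeConfig = list(nV = 30L))
  res <- runPipeline(lib)
  j <- merge(res$junctions, lib$truth, by = "read_id",
             suffixes = c(".call", ".true"))
  expect_equal(nrow(j), 600L)
  expect_equal(j$mh_len.call, j$mh_len.true)
  expect_equal(j$insertion_seq.call, j$insertion_seq.true)
  ## blunt joins report (0, "")
  blunt <- j[j$mh_len.true == 0 & j$insertion_len.true == 0, ]
  expect_gt(nrow(blunt), 0)
  expect_true(all(blunt$mh_len.call == 0L & blunt$insertion_seq.call == ""))
})

test_that("resection is measured from the nearest eligible RSS cut", {
  g <- tinyGenome()
  ann <- tinyAnnotation(g, vStarts = c(20000L, 30000L, 40000L))
  elig <- eligibleSegments(ann)
  jt <- function(b) data.frame(
    read_id = "r", bait_chrom = "chrA", bait_break = 1320L,
    bait_strand = "+", prey_chrom = "chrA", prey_break = b,
    prey_strand = "+", query_gap = 0L, stringsAsFactors = FALSE)
  ## exactly at the cut
  r <- computeResection(jt(30000L), elig)
  expect_equal(r$resection_len, 0L)
  expect_equal(r$assigned_segment, "V002")
  expect_equal(r$resection_side, "coding")
  ## 730 bp into the coding side (coding_side = right)
  r <- computeResection(jt(30730L), elig)
  expect_equal(r$resection_len, 730L)
  expect_equal(r$resection_side, "coding")
  ## 500 bp on the signal side
  r <- computeResection(jt(29500L), elig)
  expect_equal(r$resection_len, 500L)
  expect_equal(r$resection_side, "signal")
  ## cap boundary: 4000 assigned, 4001 unassigned
  r <- computeResection(jt(40000L + 4000L), elig)
  expect_equal(r$resection_len, 4000L)
  r <- computeResection(jt(40000L + 4001L), elig)
  expect_true(is.na(r$resection_len))
  ## equidistant cuts resolve to the lexicographically smaller name
  r <- computeResection(jt(25000L), elig)   # 5000 from both V001/V002 > cap
  expect_true(is.na(r$assigned_segment))
  r <- computeResection(jt(22000L), elig)   # 2000 vs 8000
  expect_equal(r$assigned_segment, "V001")
  ann2 <- tinyAnnotation(g, vStarts = c(20000L, 26000L))
  r <- computeResection(jt(23000L), eligibleSegments(ann2))  # tie at 3000
  expect_equal(r$assigned_segment, "V001")
})

test_that("feature summaries report the documented statistics", {
  j <- data.frame(resection_len = c(0L, 10L, 20L), mh_len = c(3L, 3L, 3L),
                  insertion_len = c(0L, 0L, 2L))
  s <- summarizeFeatures(j)
  expect_equal(s$resection_mean, 10)
  expect_equal(s$resection_median, 10)
  expect_equal(s$mh_hist[["2-6"]], 1.0)
  expect_equal(s$insertion_fraction, 1 / 3)
  empty <- summarizeFeatures(j[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$resection_mean))
})

test_that("raising the resection mean raises the summarized mean", {
  means <- c(5, 50, 500)
  got <- vapply(means, function(m) {
    sim <- simConfig(seed = 41L, nPairs = 800L,
                     fractions = junctionOnlyFractions,
                     resectionModel = list(family = "lognormal", mean = m,
                                           sdlog = 0.8, cap = 4000))
    lib <- simulateLibrary(sim, genomeConfig = list(nV = 30L))
    runPipeline(lib)$featureSummary$resection_mean
  }, 0)
  expect_true(all(diff(got) > 0))
  expect_true(all(got <= 4000))
})
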