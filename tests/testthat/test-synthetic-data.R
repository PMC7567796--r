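test_that("the generator is byte-deterministic for a fixed seed", {
  sim <- simConfig(seed = 21L, nPairs = 120L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateLibrary(sim, genomeConfig = list(nV = 12L), dir = d1)
  simulateLibrary(sim, genomeConfig = list(nV = 12L), dir = d2)
  for (f in c("reads_R1.fastq", "reads_R2.fastq", "genome.fa", "truth.sam")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("category counts are conserved and follow the fractions", {
  sim <- simConfig(seed = 8L, nPairs = 2000L)
  mg <- buildMiniGenome(list(nV = 20L), rngSeed = 2L)
  truth <- simulateTruth(sim, mg$annotation, mg$genome)
  expect_equal(nrow(truth), 2000L)
  tab <- table(truth$category)
  expect_equal(sum(tab), 2000L)
  f <- sim@fractions
  for (ct in names(f)[f > 0]) {
    expected <- 2000 * f[[ct]]
    sigma <- sqrt(2000 * f[[ct]] * (1 - f[[ct]]))
    expect_lt(abs(tab[[ct]] - expected), 3 * sigma + 1)
  }
})

test_that("germline-only truth has no breakpoints", {
  sim <- simConfig(seed = 3L, nPairs = 50L,
                   fractions = c(germline = 1, bait_junction_cis = 0,
                                 translocation_agr = 0,
                                 translocation_nonagr = 0, repeat_join = 0,
                                 adjacent_j_join = 0, long_mapped = 0))
  mg <- buildMiniGenome(list(nV = 6L), rngSeed = 2L)
  truth <- simulateTruth(sim, mg$annotation, mg$genome)
  expect_true(all(is.na(truth$prey_break)))
  expect_true(all(truth$category == "germline"))
})

test_that("truth resection means track the configured model", {
  mg <- buildMiniGenome(list(nV = 40L), rngSeed = 4L)
  for (m in c(3.5, 7.5)) {
    sim <- simConfig(seed = 13L, nPairs = 5000L,
                     fractions = junctionOnlyFractions,
                     resectionModel = list(family = "geometric", mean = m,
                                           cap = 4000))
    truth <- simulateTruth(sim, mg$annotation, mg$genome)
    r <- truth$resection_prey
    se <- stats::sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - m), 3 * se)
  }
  ## the capped lognormal is parameterized by its post-cap mean
  sim <- simConfig(seed = 13L, nPairs = 5000L,
                   fractions = junctionOnlyFractions,
                   resectionModel = list(family = "lognormal", mean = 730.1,
                                         sdlog = 0.8, cap = 4000))
  truth <- simulateTruth(sim, mg$annotation, mg$genome)
  r <- truth$resection_prey
  expect_lt(abs(mean(r) - 730.1), 3 * stats::sd(r) / sqrt(length(r)))
  expect_lte(max(r), 4000)
})

test_that("a point-mass MH model yields that MH at isolated junctions", {
  ## few junctions over many segments: breakpoints stay isolated, so every
  ## realized MH equals the drawn point mass
  mh <- stats::setNames(c(0, 0, 0, 1, 0, 0, 0, 0, 0), as.character(0:8))
  sim <- simConfig(seed = 5L, nPairs = 60L,
                   fractions = junctionOnlyFractions,
                   resectionModel = list(family = "lognormal", mean = 900,
                                         sdlog = 0.8, cap = 4000),
                   mhModel = mh,
                   insertionModel = list(prob = 0, minLen = 1L, maxLen = 6L))
  lib <- simulateLibrary(sim, genomeConfig = list(nV = 60L))
  expect_true(all(lib$truth$mh_len == 3L))
})

test_that("a 3-kb V array leaves no eligible V segment", {
  mg <- buildMiniGenome(list(nV = 10L, vGap = 3000L), rngSeed = 6L)
  keep <- eligibleSegments(mg$annotation)
  expect_equal(sum(keep$klass == "V"), 0L)
})

test_that("planted repeat copies are labeled repeat", {
  mg <- buildMiniGenome(list(nV = 6L, repeatCopies = 3L), rngSeed = 7L)
  reps <- repeatRegions(mg$annotation)
  expect_equal(nrow(reps), 3L)
  mid <- reps$start + 200L
  expect_true(all(regionOf(mg$annotation, reps$chrom, mid) == "repeat"))
})

test_that("rendered junction reads embed the truth junction structure", {
  sim <- simConfig(seed = 31L, nPairs = 150L,
                   fractions = junctionOnlyFractions, seqErrorRate = 0)
  lib <- simulateLibrary(sim, genomeConfig = list(nV = 30L))
  tr <- lib$truth
  gA <- as.character(lib$genome[["chrA"]])
  for (k in head(which(tr$insertion_len == 0), 25)) {
    rd <- lib$reads2[[tr$read_id[k]]]
    ## bait part is an exact genomic prefix ending at the bait break
    expect_identical(substr(rd, 1L, tr$p1_qend[k]),
                     substr(gA, tr$p1_rstart[k] + 1L, tr$p1_rend[k]))
    ## prey part is an exact genomic suffix starting u bases before the break
    gP <- as.character(lib$genome[[tr$prey_chrom[k]]])
    expect_identical(substr(rd, tr$p2_qstart[k] + 1L, nchar(rd)),
                     substr(gP, tr$p2_rstart[k] + 1L, tr$p2_rend[k]))
  }
  ## insertions appear verbatim between the mapped parts
  for (k in head(which(tr$insertion_len > 0), 10)) {
    rd <- lib$reads2[[tr$read_id[k]]]
    expect_identical(substr(rd, tr$p1_qend[k] + 1L, tr$p2_qstart[k]),
                     tr$insertion_seq[k])
  }
})
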