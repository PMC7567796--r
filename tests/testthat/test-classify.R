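## constructed part tables exercising each rule of the read2 decision tree

mkpart <- function(read_id, chrom, rs, re, qs, qe, strand = "+",
                   in_repeat = FALSE) {
  data.frame(read_id = read_id, mate = 2L, chrom = chrom, ref_start = rs,
             ref_end = re, query_start = qs, query_end = qe, strand = strand,
             mapq = 60L, n_candidates = 1L, in_repeat = in_repeat,
             stringsAsFactors = FALSE)
}

test_that("the decision tree applies its rules in fixed order", {
  g <- tinyGenome()
  ann <- tinyAnnotation(g)        # bait RSS 1320, primer 1000, gw [1000,5500)
  rl <- c(a = 250L, b = 250L, c = 250L, d = 250L, e = 250L, f = 250L,
          h = 250L)
  parts <- rbind(
    ## a: unsplit, inside the germline window
    mkpart("a", "chrA", 2000L, 2250L, 0L, 250L),
    ## b: unsplit, outside germline, >75% mapped
    mkpart("b", "chrA", 45000L, 45200L, 0L, 200L),
    ## c: unsplit, outside germline, short mapping (<=75%)
    mkpart("c", "chrA", 45000L, 45100L, 0L, 100L),
    ## d: split, prey breakpoint inside a repeat
    rbind(mkpart("d", "chrA", 1200L, 1320L, 0L, 120L),
          mkpart("d", "chrB", 20100L, 20230L, 120L, 250L,
                 in_repeat = TRUE)),
    ## e: split, bait part crossing the RSS by 15 bp
    rbind(mkpart("e", "chrA", 1220L, 1335L, 0L, 115L),
          mkpart("e", "chrA", 25000L, 25135L, 115L, 250L)),
    ## f: split, bait part within the bait window, prey in the V region
    rbind(mkpart("f", "chrA", 1200L, 1320L, 0L, 120L),
          mkpart("f", "chrA", 30000L, 30130L, 120L, 250L)),
    ## h: split, bait part within window, prey on the AgR chromosome
    rbind(mkpart("h", "chrA", 1200L, 1320L, 0L, 120L),
          mkpart("h", "chrB", 6000L, 6130L, 120L, 250L))
  )
  out <- classifyReads(parts, ann, readLens = rl)
  lab <- stats::setNames(out$classes$label, out$classes$read_id)
  expect_equal(lab[["a"]], "germline")
  expect_equal(lab[["b"]], "mapped_gt75")
  expect_equal(lab[["c"]], "other_filtered")
  expect_equal(lab[["d"]], "unique_repeat")
  expect_equal(lab[["e"]], "split_join_adjacent_J")
  expect_equal(lab[["f"]], "split_join_bait")
  expect_equal(lab[["h"]], "split_join_bait")
  j <- out$junctions
  expect_equal(j$prey_category[j$read_id == "f"], "cis_v_region")
  expect_equal(j$prey_category[j$read_id == "h"], "trans_agr")
  expect_equal(j$bait_break[j$read_id == "f"], 1320L)
  expect_equal(j$prey_break[j$read_id == "f"], 30000L)
})

test_that("a query overlap shifts the prey breakpoint past the MH", {
  g <- tinyGenome(); ann <- tinyAnnotation(g)
  parts <- rbind(mkpart("x", "chrA", 1200L, 1320L, 0L, 120L),
                 mkpart("x", "chrA", 29996L, 30130L, 116L, 250L))
  out <- classifyReads(parts, ann, readLens = c(x = 250L))
  j <- out$junctions
  expect_equal(j$query_gap, -4L)
  expect_equal(j$prey_break, 30000L)   # ref_start + overlap
})

test_that("more than three parts fall through to other_filtered", {
  g <- tinyGenome(); ann <- tinyAnnotation(g)
  parts <- do.call(rbind, lapply(0:3, function(i)
    mkpart("m", "chrA", 10000L + 400L * i, 10060L + 400L * i,
           60L * i, 60L * (i + 1L))))
  out <- classifyReads(parts, ann, readLens = c(m = 250L))
  expect_equal(out$classes$label, "other_filtered")
})

test_that("tabulation conserves totals and reports empty streams", {
  empty <- tabulateClasses(data.frame(read_id = character(),
                                      label = character(),
                                      prey_category = character()))
  expect_equal(empty$total, 0L)
  expect_true(all(empty$labels$count == 0L))

  sim <- simConfig(seed = 19L, nPairs = 1200L)
  lib <- simulateLibrary(sim, genomeConfig = list(nV = 20L))
  res <- runPipeline(lib)
  tab <- tabulateClasses(res$classes)
  expect_equal(sum(tab$labels$count), tab$total)
  ## counts stay within multinomial 3-sigma of the configured fractions
  f <- sim@fractions
  truthToLabel <- c(germline = "germline", long_mapped = "mapped_gt75",
                    repeat_join = "unique_repeat",
                    adjacent_j_join = "split_join_adjacent_J")
  for (ct in names(truthToLabel)) {
    n <- tab$labels$count[tab$labels$label == truthToLabel[[ct]]]
    expect_lt(abs(n - 1200 * f[[ct]]),
              3 * sqrt(1200 * f[[ct]] * (1 - f[[ct]])) + 1)
  }
  jn <- sum(f[c("bait_junction_cis", "translocation_agr",
                "translocation_nonagr")])
  n <- tab$labels$count[tab$labels$label == "split_join_bait"]
  expect_lt(abs(n - 1200 * jn), 3 * sqrt(1200 * jn * (1 - jn)) + 1)
})

test_that("germline-only libraries yield zero junction categories", {
  sim <- simConfig(seed = 29L, nPairs = 300L,
                   fractions = c(germline = 1, bait_junction_cis = 0,
                                 translocation_agr = 0,
                                 translocation_nonagr = 0, repeat_join = 0,
                                 adjacent_j_join = 0, long_mapped = 0))
  lib <- simulateLibrary(sim, genomeConfig = list(nV = 8L))
  res <- runPipeline(lib)
  expect_equal(nrow(res$junctions), 0L)
  expect_true(all(res$classes$label == "germline"))
})
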