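mkcap <- function(read_id, chrom, rs, re, qs, qe) {
  data.frame(read_id = read_id, mate = 2L, chrom = chrom, ref_start = rs,
             ref_end = re, query_start = qs, query_end = qe, strand = "+",
             mapq = 60L, n_candidates = 1L, stringsAsFactors = FALSE)
}

test_that("capture reads partition into the documented labels", {
  g <- tinyGenome()
  ann <- tinyAnnotation(g, vStarts = c(20000L, 30000L, 40000L))
  parts <- rbind(
    ## V001 -> V003 join, ~20 kb apart
    rbind(mkcap("vv", "chrA", 20100L, 20250L, 0L, 150L),
          mkcap("vv", "chrA", 40050L, 40200L, 150L, 300L)),
    ## split 1,500 bp apart: short deletion
    rbind(mkcap("sd", "chrA", 20100L, 20250L, 0L, 150L),
          mkcap("sd", "chrA", 21750L, 21900L, 150L, 300L)),
    ## V -> J join
    rbind(mkcap("vj", "chrA", 20100L, 20250L, 0L, 150L),
          mkcap("vj", "chrA", 5250L, 5400L, 150L, 300L)),
    ## unsplit read over a J segment: germline
    mkcap("g", "chrA", 5100L, 5400L, 0L, 300L),
    ## unsplit read in intergenic space: unclassified
    mkcap("u", "chrA", 45000L, 45300L, 0L, 300L)
  )
  out <- classifyCapture(parts, ann)
  lab <- stats::setNames(out$label, out$read_id)
  expect_equal(lab[["vv"]], "vv_join")
  expect_equal(lab[["sd"]], "short_deletion")
  expect_equal(lab[["vj"]], "vj_join")
  expect_equal(lab[["g"]], "germline")
  expect_equal(lab[["u"]], "unclassified")
  expect_equal(out$span[out$read_id == "vv"], 40050L - 20250L)
})

test_that("the 2-kb span cutoff is strict on both sides", {
  g <- tinyGenome()
  ann <- tinyAnnotation(g, vStarts = c(20000L, 30000L, 40000L))
  spanRead <- function(id, span) {
    ## both parts inside V002 and V003-side coordinates chosen so only the
    ## span changes; anchor the left part at the V002 interval
    rbind(mkcap(id, "chrA", 30000L, 30150L, 0L, 150L),
          mkcap(id, "chrA", 30150L + span, 30300L + span, 150L, 300L))
  }
  lab <- function(span, vStarts = NULL) {
    classifyCapture(spanRead("x", span), ann)$label
  }
  expect_equal(lab(1999L), "short_deletion")
  expect_equal(lab(2000L), "unclassified")
  ## 2001 with both parts in V segments is a V-V join: move the right part
  ## into V004 territory via a wider annotation
  ann2 <- tinyAnnotation(g, vStarts = c(30000L, 32300L))
  p <- rbind(mkcap("y", "chrA", 30000L, 30150L, 0L, 150L),
             mkcap("y", "chrA", 32151L, 32500L, 150L, 300L))
  expect_equal(classifyCapture(p, ann2)$label, "vv_join")
})

test_that("breakpoint binning is half-open and conserves counts", {
  calls <- data.frame(chrom = "chrA",
                      left_break = c(0L, 99L, 100L),
                      right_break = c(250L, 260L, 305L))
  bins <- binJoins(calls, binSize = 100L)
  b0 <- bins$count[bins$bin_start == 0L]
  expect_equal(b0, 2L)                      # 0 and 99 share a bin
  expect_equal(bins$count[bins$bin_start == 100L], 1L)  # 100 starts the next
  expect_equal(sum(bins$count), 6L)         # two breakpoints per join
  ## randomized conservation
  set.seed(7)
  calls <- data.frame(chrom = "chrA",
                      left_break = sample(10000L, 500L),
                      right_break = sample(10000L, 500L))
  bins <- binJoins(calls, binSize = 100L)
  expect_equal(sum(bins$count), 1000L)
})
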