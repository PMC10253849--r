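test_that("randomized regions preserve the length multiset and obey mask and seed", {
  lens <- c(chr1 = 1e5, chr2 = 1e5)
  gr <- gr0("chr1", c(0, 1000, 5000), c(100, 1200, 5300))
  r1 <- randomizeRegions(gr, lens, seed = 4)
  expect_equal(GenomicRanges::width(r1), GenomicRanges::width(gr))
  r2 <- randomizeRegions(gr, lens, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  ## full-chromosome mask forces placement on the other chromosome
  mask <- gr0("chr1", 0, 1e5)
  r3 <- randomizeRegions(gr, lens, mask = mask, seed = 4)
  expect_true(all(as.character(GenomicRanges::seqnames(r3)) == "chr2"))
  ## an interval longer than every allowed segment errors
  expect_error(randomizeRegions(gr0("chr1", 0, 2e5), lens), "fit")
})

test_that("random placement is uniform over allowed positions", {
  lens <- c(chr1 = 1000L)
  r <- randomizeRegions(rep(gr0("chr1", 0, 10), 4000), lens, seed = 12)
  s0 <- GenomicRanges::start(r) - 1L
  ## valid starts 0..990; chi-squared goodness of fit over 10 deciles
  h <- table(cut(s0, breaks = seq(0, 991, length.out = 11),
                 include.lowest = TRUE))
  p <- suppressWarnings(stats::chisq.test(as.vector(h))$p.value)
  expect_gt(p, 1e-4)
})

test_that("overlap flags respect half-open adjacency and min overlap", {
  expect_true(overlapFlags(gr0("chr1", 0, 10), gr0("chr1", 9, 20)))
  expect_false(overlapFlags(gr0("chr1", 0, 10), gr0("chr1", 10, 20)))
  expect_false(overlapFlags(gr0("chr1", 0, 10), gr0("chr2", 0, 10)))
  expect_false(overlapFlags(gr0("chr1", 0, 10), gr0("chr1", 8, 20),
                            minOverlap = 3))
  expect_true(overlapFlags(gr0("chr1", 0, 10), gr0("chr1", 7, 20),
                           minOverlap = 3))
})

test_that("overlap flags equal the brute-force all-pairs oracle", {
  set.seed(21)
  for (rep in 1:20) {
    A <- randomIntervals(40)
    B <- randomIntervals(25)
    expect_identical(overlapFlags(A, B), bruteOverlapFlags(A, B))
  }
})

test_that("peak annotation applies promoter > gene > intergenic precedence", {
  genes <- gr0("chr1", c(10000, 50000), c(20000, 60000), c("+", "-"),
               gene_id = c("g1", "g2"), cpm = c(1, 1),
               expressed = c(TRUE, TRUE))
  ## overlaps TSS +- 1 kb of g1 (TSS = 10000) and the first exon: promoter
  expect_equal(as.character(annotatePeaks(gr0("chr1", 9500, 10500), genes)),
               "promoter")
  ## inside the gene body, > 1 kb from the TSS
  expect_equal(as.character(annotatePeaks(gr0("chr1", 15000, 15500), genes)),
               "gene")
  ## far from any gene
  expect_equal(as.character(annotatePeaks(gr0("chr1", 90000, 90500), genes)),
               "intergenic")
  ## Crick gene: TSS at the gene end
  expect_equal(as.character(annotatePeaks(gr0("chr1", 60500, 60900), genes)),
               "promoter")
  expect_error(annotatePeaks(gr0("chr1", 0, 10), gr0("chr1", 0, 100, "*")),
               "unstranded")
  ## moving all genes far away sends every peak to intergenic
  peaks <- gr0("chr1", seq(0, 90000, 10000), seq(500, 90500, 10000))
  far <- GenomicRanges::shift(genes, 10e6)
  expect_true(all(annotatePeaks(peaks, far) == "intergenic"))
})

test_that("GC content excludes N bases and is additive over partitions", {
  f <- withr::local_tempfile(lines = c(">chr1", "GGCCATGCANGTACGT"))
  g <- readGenome(f)
  expect_equal(gcContent(gr0("chr1", 0, 4), g), 1.0)
  expect_equal(gcContent(gr0("chr1", 4, 8), g), 0.5)
  expect_equal(gcContent(gr0("chr1", 8, 12), g), 1 / 3)
  expect_error(gcContent(gr0("chr1", 0, 100), g), "exceeds")
  ## additivity: GC of [0, 8) equals the length-weighted mean of halves
  whole <- gcContent(gr0("chr1", 0, 8), g)
  parts <- gcContent(gr0("chr1", c(0, 4), c(4, 8)), g)
  expect_equal(whole, mean(parts))
})

test_that("2x2 enrichment tests match hand-computed statistics", {
  r <- enrichmentTest(30, 100, 10, 100, "chi-squared")
  expect_equal(r$statistic, 12.5)   # sum((O - E)^2 / E), E = 20/80/20/80
  expect_equal(r$direction, 1)
  ## identical observed and control rows: statistic 0, Fisher p = 1
  expect_equal(enrichmentTest(20, 100, 20, 100, "chi-squared")$statistic, 0)
  expect_equal(enrichmentTest(20, 100, 20, 100, "fisher")$p_value, 1)
  expect_error(enrichmentTest(0, 0, 0, 0), "zero")
  ## zero margin reported as NA rather than an error
  expect_true(is.na(enrichmentTest(0, 50, 0, 50)$p_value))
})
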