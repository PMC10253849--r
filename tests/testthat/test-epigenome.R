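mkClass <- function(starts0, ends0, classes, chrom = "chr1") {
  gr <- gr0(chrom, starts0, ends0)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    leftCrick = 1L, leftWatson = 0L, rightCrick = 0L, rightWatson = 1L,
    fL = 1, fR = 0, class = classes)
  methods::new("OriClassification", peaks = gr,
               proportions = c(ORI = 1, CO = 0, WO = 0, OTHER = 0,
                               unidirectional = 0),
               orientation = "figure1b")
}

test_that("RPKM is CPM per kilobase and the expressed cut is strict", {
  expr <- data.frame(gene_id = c("a", "b", "c"),
                     cpm = c(10, 10, 0), length = c(2000, 1000, 500),
                     strand = c("+", "-", "+"))
  out <- rpkmFilter(expr)
  expect_equal(out$rpkm, c(5, 10, 0))
  expect_identical(out$expressed, c(FALSE, TRUE, FALSE))  # 5 is NOT > 5
  expect_error(rpkmFilter(data.frame(gene_id = "a", cpm = 1, length = 0)),
               "length")
  ## linear in CPM, inverse in length
  expect_equal(rpkmFilter(transform(expr, cpm = cpm * 3))$rpkm,
               out$rpkm * 3)
  expect_equal(rpkmFilter(transform(expr, length = length * 2))$rpkm,
               out$rpkm / 2)
})

test_that("ATAC counts reads by midpoint and degenerate tests are handled", {
  cl <- mkClass(0, 1000, "ORI")
  atac <- readsAt("chr1", c(seq(50, 950, length.out = 7), 1500, 2500),
                  rep("+", 9), len = 50)
  ctrl <- gr0("chr1", 5000, 6000)
  S4Vectors::mcols(ctrl)$class <- "ORI"
  res <- atacDistribution(cl, atac, ctrl)
  expect_equal(res$counts$count, 7L)
  ## single peak per side: t undefined, reported NA
  expect_true(is.na(res$tests$t))
  ## identical count vectors: t = 0, p = 1
  cl2 <- mkClass(c(0, 2000), c(1000, 3000), c("ORI", "ORI"))
  ctrl2 <- cl2@peaks
  res2 <- atacDistribution(cl2, atac, ctrl2)
  expect_equal(res2$tests$t, 0)
  expect_equal(res2$tests$p_value, 1)
})

test_that("RT is read at the peak midpoint and identical samples give KS D = 0", {
  rt <- gr0("chr1", seq(0, 9000, 1000), seq(1000, 10000, 1000),
            score = rep(-0.5, 10))
  cl <- mkClass(c(0, 4000), c(2000, 6000), c("ORI", "ORI"))
  res <- rtDistribution(cl, rt)
  expect_equal(res$values$rt, c(-0.5, -0.5))
  ## all values equal the (constant) genome background: D = 0, p = 1
  expect_equal(unname(res$tests$D[1]), 0)
  expect_equal(unname(res$tests$p_value[1]), 1)
  ## uncovered midpoints are dropped with a warning
  clOff <- mkClass(50000, 52000, "ORI")
  expect_warning(res2 <- rtDistribution(clOff, rt), "not covered")
  expect_equal(res2$nDropped, 1L)
})

test_that("the KS comparison is invariant under monotone RT transforms", {
  set.seed(41)
  vals <- rnorm(30)
  rt <- gr0("chr1", seq(0, 29000, 1000), seq(1000, 30000, 1000),
            score = vals)
  cl <- mkClass(seq(0, 8000, 2000) + 100, seq(0, 8000, 2000) + 300,
                rep("ORI", 5))
  d1 <- rtDistribution(cl, rt)$tests$D[1]
  rt2 <- rt
  S4Vectors::mcols(rt2)$score <- exp(vals)     # strictly monotone transform
  d2 <- rtDistribution(cl, rt2)$tests$D[1]
  expect_equal(d1, d2)
})

test_that("opposite-strand transcription tallies single-gene peaks by class", {
  genes <- gr0("chr1", c(10000, 30000), c(15000, 35000), c("+", "-"),
               gene_id = c("g1", "g2"))
  cl <- mkClass(c(11000, 31000, 50000), c(12000, 32000, 51000),
                c("CO", "WO", "CO"))
  res <- oppositeStrandTranscription(cl, genes)
  expect_equal(res$table["CO", "+"], 1L)
  expect_equal(res$table["WO", "-"], 1L)
  expect_equal(res$nExcluded, 1L)   # the peak overlapping no expressed gene
  ## swapping gene strands transposes the strand columns
  res2 <- oppositeStrandTranscription(cl, swapStrands(genes))
  expect_equal(res2$table[, "+"], res$table[, "-"])
  expect_equal(res2$table[, "-"], res$table[, "+"])
})

test_that("expressed-gene overlap joins expression to gene intervals", {
  genes <- gr0("chr1", c(0, 10000), c(5000, 15000), c("+", "-"),
               gene_id = c("g1", "g2"))
  expr <- rpkmFilter(data.frame(gene_id = c("g1", "g2"),
                                cpm = c(100, 1), length = c(5000, 5000),
                                strand = c("+", "-")))
  eg <- expressedGenes(genes, expr)
  expect_equal(S4Vectors::mcols(eg)$gene_id, "g1")
  expect_error(
    expressedGenes(gr0("chr1", 0, 10, "+", gene_id = "zz"), expr),
    "missing")
})
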