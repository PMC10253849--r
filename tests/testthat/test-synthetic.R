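test_that("spec building is deterministic and respects limit parameters", {
  s1 <- buildSyntheticSpec(list(nORI = 20L, nCO = 5L, nWO = 5L,
                                chromLength = 2e6), seed = 7)
  s2 <- buildSyntheticSpec(list(nORI = 20L, nCO = 5L, nWO = 5L,
                                chromLength = 2e6), seed = 7)
  expect_identical(as.data.frame(originMap(s1)), as.data.frame(originMap(s2)))
  expect_identical(as.data.frame(s1@g4), as.data.frame(s2@g4))
  expect_equal(length(originMap(s1)), 30L)

  ## beta = 1: every G4 in a CO flank is Watson, every WO flank Crick
  sb <- buildSyntheticSpec(list(nORI = 0L, nCO = 30L, nWO = 30L,
                                chromLength = 2e6, g4Beta = 1,
                                g4BackgroundPerMb = 0), seed = 7)
  oriCls <- S4Vectors::mcols(originMap(sb))$planted_class
  g4 <- sb@g4
  ov <- GenomicRanges::findOverlaps(
    g4, GenomicRanges::resize(originMap(sb), 2001, fix = "center"),
    ignore.strand = TRUE)
  cls <- oriCls[S4Vectors::subjectHits(ov)]
  sd <- as.character(GenomicRanges::strand(g4))[S4Vectors::queryHits(ov)]
  expect_true(all(sd[cls == "CO"] == "+"))
  expect_true(all(sd[cls == "WO"] == "-"))

  ## spacing that cannot be satisfied errors
  expect_error(buildSyntheticSpec(list(nChrom = 1L, chromLength = 50e3,
                                       nORI = 40L, nCO = 0L, nWO = 0L),
                                  seed = 1),
               "spacing|short")
})

test_that("minimum origin spacing is enforced within chromosomes", {
  spec <- buildSyntheticSpec(list(nORI = 50L, nCO = 10L, nWO = 10L), seed = 3)
  ori <- originMap(spec)
  byChrom <- split(GenomicRanges::start(ori),
                   as.character(GenomicRanges::seqnames(ori)))
  gaps <- unlist(lapply(byChrom, function(x) diff(sort(x))))
  expect_true(all(gaps >= spec@params$minSpacing))
})

test_that("noise-free SSDS reads encode the planted class exactly", {
  spec <- oracleSpec(nORI = 10L, nCO = 10L, nWO = 10L, chromLength = 2e6)
  sim <- simulateSSDS(spec)
  expect_equal(length(sim$peaks), 30L)
  ov <- GenomicRanges::findOverlaps(sim$reads, sim$peaks,
                                    ignore.strand = TRUE)
  cls <- sim$truth$planted_class[S4Vectors::subjectHits(ov)]
  sd <- as.character(GenomicRanges::strand(sim$reads))[S4Vectors::queryHits(ov)]
  expect_true(all(sd[cls == "CO"] == "-"))
  expect_true(all(sd[cls == "WO"] == "+"))
  ## bidirectional origins: Crick reads left of the origin, Watson right
  oriIdx <- which(sim$truth$planted_class == "ORI")
  ovO <- GenomicRanges::findOverlaps(sim$reads, sim$peaks[oriIdx],
                                     ignore.strand = TRUE)
  pos <- sim$truth$origin_pos[oriIdx][S4Vectors::subjectHits(ovO)]
  rmid <- (GenomicRanges::start(sim$reads) - 1L +
             GenomicRanges::end(sim$reads))[S4Vectors::queryHits(ovO)] %/% 2
  rsd <- as.character(
    GenomicRanges::strand(sim$reads))[S4Vectors::queryHits(ovO)]
  ## reads start uniformly inside the flank, so a Crick read's midpoint can
  ## spill at most half a read length right of the origin
  expect_true(all(rmid[rsd == "-"] < pos[rsd == "-"] +
                    spec@params$snsReadLength))
  expect_true(all(rmid[rsd == "+"] >= pos[rsd == "+"]))
})

test_that("SSDS read counts follow the Poisson firing model", {
  spec <- oracleSpec(nORI = 200L, nCO = 0L, nWO = 0L, efficiency = 50)
  sim <- simulateSSDS(spec)
  ## 200 ORI origins x 2 sides x Poisson(50): mean total 20000, SE sqrt(20000)
  n <- length(sim$reads)
  expect_lt(abs(n - 20000), 3 * sqrt(20000))
  perPeak <- GenomicRanges::countOverlaps(sim$peaks, sim$reads,
                                          ignore.strand = TRUE)
  expect_lt(abs(mean(perPeak) - 100), 3 * sqrt(100 / 200))
})

test_that("OK-seq strand equals the analytic fork direction when noise-free", {
  spec <- oracleSpec(nORI = 8L, nCO = 4L, nWO = 4L, chromLength = 4e6,
                     okDensity = 0.002)
  ok <- simulateOKSeq(spec)
  ori <- originMap(spec)
  oriPos <- split(GenomicRanges::start(ori) - 1L,
                  as.character(GenomicRanges::seqnames(ori)))
  rmid <- (GenomicRanges::start(ok) - 1L + GenomicRanges::end(ok)) %/% 2
  rchr <- as.character(GenomicRanges::seqnames(ok))
  expected <- vapply(seq_along(ok), function(i) {
    pos <- sort(oriPos[[rchr[i]]])
    d <- rmid[i] - pos
    nearestLeft <- suppressWarnings(min(abs(d[d >= 0])))
    nearestRight <- suppressWarnings(min(abs(d[d < 0])))
    if (nearestLeft <= nearestRight) "-" else "+"   # rightward fork -> Crick
  }, "")
  expect_identical(as.character(GenomicRanges::strand(ok)), expected)
  ## a chromosome with no origin has no defined fork direction
  spec2 <- oracleSpec(nChrom = 2L, nORI = 3L, nCO = 0L, nWO = 0L,
                      chromLength = 2e6)
  spec2@origins <- spec2@origins[
    as.character(GenomicRanges::seqnames(spec2@origins)) == "chr1"]
  expect_error(simulateOKSeq(spec2), "no origins")
})

test_that("feature tracks carry the planted structure", {
  spec <- oracleSpec(nChrom = 1L, chromLength = 2e6, nORI = 10L, nCO = 5L,
                     nWO = 5L, cpgBackgroundPerMb = 0)
  tr <- emitTracks(spec, what = c("rt", "expression", "genome"))
  ## RT at an origin midpoint = baseline + amplitude (+- segment noise)
  rt <- tr$rt
  ori <- originMap(spec)
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(ori),
                                IRanges::IRanges(GenomicRanges::start(ori), width = 1))
  hit <- GenomicRanges::findOverlaps(pts, rt, select = "first")
  vals <- S4Vectors::mcols(rt)$score[hit]
  p <- spec@params
  expect_true(all(abs(vals - (p$rtBaseline + p$rtAmplitude)) <
                    5 * p$rtNoiseSd))
  ## expression table mirrors the gene models exactly
  g <- spec@genes
  expect_equal(tr$expression$length, GenomicRanges::width(g))
  expect_equal(tr$expression$cpm, S4Vectors::mcols(g)$cpm)
  ## realized GC tracks the planted probabilities (binomial SE)
  gfa <- tr$genome
  oriSeq <- Biostrings::DNAStringSet(
    gfa[["chr1"]],
    start = GenomicRanges::start(ori) - 999L,
    end = GenomicRanges::start(ori) + 1000L)
  fr <- Biostrings::letterFrequency(oriSeq, c("G", "C"))
  gcOri <- sum(fr) / (2000 * length(ori))
  expect_lt(abs(gcOri - spec@params$gcOrigin), 0.03)
})

test_that("the full simulation is byte-identical under a fixed seed", {
  cfg <- list(nChrom = 1L, chromLength = 1e6, nORI = 10L, nCO = 3L,
              nWO = 3L, okDensity = 0.002)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateStudy(buildSyntheticSpec(cfg, seed = 9), outdir = d1)
  simulateStudy(buildSyntheticSpec(cfg, seed = 9), outdir = d2)
  f <- sort(list.files(d1))
  expect_identical(f, sort(list.files(d2)))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})
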