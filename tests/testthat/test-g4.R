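mkClassified <- function(starts0, ends0, classes, chrom = "chr1") {
  gr <- gr0(chrom, starts0, ends0)
  S4Vectors::mcols(gr)$class <- classes
  gr
}

test_that("exclusive-strand G4 calls follow single-strand overlap", {
  peaks <- mkClassified(c(0, 2000, 4000, 6000),
                        c(1000, 3000, 5000, 7000),
                        c("CO", "WO", "ORI", "ORI"))
  g4 <- c(gr0("chr1", 100, 130, "+"),           # Watson only in peak 1
          gr0("chr1", 2100, 2130, "-"),         # Crick only in peak 2
          gr0("chr1", 4100, 4130, "+"),         # both strands in peak 3
          gr0("chr1", 4200, 4230, "-"))
  res <- g4ExclusiveCall(peaks, g4)
  expect_equal(res$calls,
               c("G4_Watson_only", "G4_Crick_only", "both", "none"))
  co <- res$byClass[res$byClass$class == "CO", ]
  expect_equal(co$watson_only, 1L)
  ori <- res$byClass[res$byClass$class == "ORI", ]
  expect_equal(ori$n_both, 1L)
  expect_equal(ori$n_none, 1L)
  expect_error(g4ExclusiveCall(peaks, gr0("chr1", 0, 30, "*")), "unstranded")
})

test_that("flank counting uses the 2 kb window around the peak center", {
  peaks <- mkClassified(0, 2000, "ORI")        # center at 1000
  g4in <- gr0("chr1", 1500 - 15, 1500 + 15, "-")   # center + 500, right
  g4out <- gr0("chr1", 2500 - 15, 2500 + 15, "-")  # center + 1500: outside
  res <- g4FlankCounts(peaks, c(g4in, g4out), flank = 1000)
  expect_equal(res$crick, 1L)
  expect_equal(res$right_crick, 1L)
  expect_equal(res$watson, 0L)
  ## strand swap exchanges the Watson/Crick columns exactly
  res2 <- g4FlankCounts(peaks, swapStrands(c(g4in, g4out)), flank = 1000)
  expect_equal(res2$watson, res$crick)
  expect_equal(res2$crick, res$watson)
  expect_equal(res2$right_watson, res$right_crick)
})

test_that("duplicating the peak list doubles every flank count", {
  set.seed(31)
  peaks <- mkClassified(seq(0, 18000, 2000), seq(1000, 19000, 2000),
                        rep(c("ORI", "CO"), 5))
  g4 <- randomIntervals(100, chroms = "chr1", maxPos = 2e4, maxLen = 40)
  one <- g4FlankCounts(peaks, g4)
  two <- g4FlankCounts(c(peaks, peaks), g4)
  expect_equal(two$watson, 2L * one$watson)
  expect_equal(two$crick, 2L * one$crick)
})

test_that("strand-bias chi-squared matches the hand goodness-of-fit formula", {
  counts <- data.frame(class = c("CO", "WO"), watson = c(80, 50),
                       crick = c(20, 50))
  res <- strandBiasTest(counts)
  expect_equal(res$perClass$statistic[1], 36)   # (80-50)^2/50 + (20-50)^2/50
  expect_equal(res$perClass$statistic[2], 0)
  expect_equal(res$perClass$p_value[2], 1)
  expect_equal(nrow(res$betweenClasses), 1L)
  expect_error(strandBiasTest(data.frame(class = "CO", watson = 0,
                                         crick = 0)), "zero")
})

test_that("leading/lagging labels follow the two-fork strand convention", {
  oriPeaks <- mkClassified(0, 2000, "ORI")       # center 1000
  rightWatson <- gr0("chr1", 1400, 1430, "+")    # leading (Watson leads right)
  leftWatson <- gr0("chr1", 400, 430, "+")       # lagging
  leftCrick <- gr0("chr1", 500, 530, "-")        # leading (Crick leads left)
  res <- leadingLaggingSplit(oriPeaks, c(rightWatson, leftWatson, leftCrick))
  expect_equal(res$table["right", "leading"], 1L)
  expect_equal(res$table["left", "lagging"], 1L)
  expect_equal(res$table["left", "leading"], 1L)
  notOri <- mkClassified(0, 2000, "CO")
  expect_error(leadingLaggingSplit(notOri, rightWatson), "ORI")
})

test_that("global G4 strand swap transposes every output table", {
  set.seed(32)
  peaks <- mkClassified(seq(0, 38000, 2000), seq(1000, 39000, 2000),
                        sample(c("ORI", "CO", "WO"), 20, replace = TRUE))
  g4 <- randomIntervals(200, chroms = "chr1", maxPos = 4e4, maxLen = 40)
  a <- g4ExclusiveCall(peaks, g4)$byClass
  b <- g4ExclusiveCall(peaks, swapStrands(g4))$byClass
  expect_equal(a$watson_only, b$crick_only)
  expect_equal(a$crick_only, b$watson_only)
  expect_equal(a$n_both, b$n_both)
})
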