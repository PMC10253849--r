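## Matched random controls and genomic-feature association: overlap flags,
## promoter/gene/intergenic annotation, GC content, 2x2 enrichment tests.

#' Length-matched random genomic regions
#'
#' Produces regions with exactly the same count and multiset of lengths as
#' the input, each placed uniformly over all allowed genome-wide start
#' positions (not per-chromosome), outside an optional mask. Output regions
#' may overlap each other. Deterministic under `seed`.
#'
#' @param gr GRanges whose widths are matched
#' @param chromLengths named vector of chromosome lengths (bp)
#' @param mask optional GRanges of excluded intervals
#' @param seed optional integer seed
#' @return unstranded GRanges, in input order (i-th output has the i-th
#'   input's width)
#' @export
randomizeRegions <- function(gr, chromLengths, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(gr)
  if (n == 0) return(GenomicRanges::GRanges())
  ## allowed gaps: chromosome complements of the (reduced) mask, 0-based
  gaps <- list()
  for (cn in names(chromLengths)) {
    len <- chromLengths[[cn]]
    if (is.null(mask)) {
      gaps[[length(gaps) + 1L]] <- c(0, len)
      names(gaps)[length(gaps)] <- cn
      next
    }
    m <- GenomicRanges::reduce(mask[as.character(
      GenomicRanges::seqnames(mask)) == cn])
    cuts <- c(0, as.vector(rbind(GenomicRanges::start(m) - 1L,
                                 GenomicRanges::end(m))), len)
    for (j in seq_len(length(cuts) / 2)) {
      lo <- cuts[2 * j - 1]; hi <- cuts[2 * j]
      if (hi > lo) {
        gaps[[length(gaps) + 1L]] <- c(lo, hi)
        names(gaps)[length(gaps)] <- cn
      }
    }
  }
  gapChrom <- names(gaps)
  gapLo <- vapply(gaps, `[[`, 0, 1L)
  gapHi <- vapply(gaps, `[[`, 0, 2L)
  gapW <- gapHi - gapLo

  w <- GenomicRanges::width(gr)
  chromOut <- character(n); startOut <- numeric(n)
  for (i in seq_len(n)) {
    slots <- gapW - w[i] + 1           # valid starts per gap
    slots[slots < 0] <- 0
    if (sum(slots) == 0)
      stop("region of length ", w[i],
           " does not fit in any unmasked chromosome segment")
    g <- sample.int(length(slots), 1L, prob = slots)
    startOut[i] <- gapLo[g] + floor(runif(1, 0, slots[g]))
    chromOut[i] <- gapChrom[g]
  }
  GenomicRanges::GRanges(chromOut,
                         IRanges::IRanges(startOut + 1L, width = w))
}

#' Flag peaks overlapping a feature set
#'
#' TRUE for each peak sharing at least `minOverlap` bases with some
#' feature interval (strand-blind, half-open adjacency does not count).
#'
#' @param peaks GRanges
#' @param features GRanges
#' @param minOverlap minimum shared bases (default 1)
#' @return logical vector along `peaks`
#' @export
overlapFlags <- function(peaks, features, minOverlap = 1L) {
  suppressWarnings(
    GenomicRanges::countOverlaps(GenomicRanges::granges(peaks),
                                 GenomicRanges::granges(features),
                                 minoverlap = as.integer(minOverlap),
                                 ignore.strand = TRUE)) > 0
}

#' Annotate peaks as promoter / gene / intergenic
#'
#' Promoter = within `tssWindow` bp of a gene's TSS (TSS at the gene start
#' for Watson genes, gene end for Crick genes); precedence is
#' promoter > gene > intergenic, so every peak gets exactly one category.
#'
#' @param peaks GRanges
#' @param genes stranded GRanges of gene bodies (unstranded genes are an
#'   error: the TSS is undefined without a strand)
#' @param tssWindow promoter half-width in bp (default 1000)
#' @return factor with levels promoter, gene, intergenic
#' @export
annotatePeaks <- function(peaks, genes, tssWindow = 1000L) {
  if (length(genes)) stopIfUnstranded(genes, "gene")
  cat <- factor(rep("intergenic", length(peaks)),
                levels = c("promoter", "gene", "intergenic"))
  if (!length(genes)) return(cat)
  promoters <- promoterWindows(genes, tssWindow)
  cat[overlapFlags(peaks, genes)] <- "gene"
  cat[overlapFlags(peaks, promoters)] <- "promoter"
  cat
}

#' Promoter windows (TSS +/- tssWindow) of stranded genes
#'
#' @inheritParams annotatePeaks
#' @return GRanges of promoter windows, clipped at position 0
#' @export
promoterWindows <- function(genes, tssWindow = 1000L) {
  stopIfUnstranded(genes, "gene")
  t0 <- .tss0(genes)
  lo <- pmax(0, t0 - tssWindow)
  hi <- t0 + tssWindow
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                         IRanges::IRanges(lo + 1L, hi))
}

#' Per-interval GC content
#'
#' `GC = (#G + #C) / (#A + #C + #G + #T)` over each interval's sequence; N
#' bases are excluded from numerator and denominator; all-N intervals give
#' NA.
#'
#' @param gr GRanges within the genome
#' @param genome a [Biostrings::DNAStringSet] as from [readGenome()]
#' @return numeric vector of GC fractions
#' @export
gcContent <- function(gr, genome) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bad <- !chrom %in% names(genome)
  if (any(bad)) stop("interval on unknown chromosome: ", chrom[which(bad)[1]])
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(GenomicRanges::end(gr) > lens))
    stop("interval exceeds chromosome length")
  out <- numeric(length(gr))
  for (cn in unique(chrom)) {
    sel <- which(chrom == cn)
    seqs <- Biostrings::DNAStringSet(
      genome[[cn]],
      start = GenomicRanges::start(gr)[sel],
      end = GenomicRanges::end(gr)[sel])
    freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    out[sel] <- ifelse(denom > 0,
                       (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
  }
  out
}

#' 2x2 enrichment test of observed vs control overlap
#'
#' Builds the table [[overlap, non-overlap] x [observed, control]] and
#' applies a chi-squared test without continuity correction or Fisher's
#' exact two-sided test. A margin of zero (all or none overlapping in both
#' groups) yields NA statistic and p-value.
#'
#' @param nObsOverlap,nObs overlapping / total observed peaks
#' @param nCtrlOverlap,nCtrl overlapping / total control regions
#' @param test `"chi-squared"` (default) or `"fisher"`
#' @return one-row data.frame: test, statistic (NA for Fisher), p_value,
#'   obs_rate, ctrl_rate, direction (+1 enriched, -1 depleted, 0 equal)
#' @export
enrichmentTest <- function(nObsOverlap, nObs, nCtrlOverlap, nCtrl,
                           test = c("chi-squared", "fisher")) {
  test <- match.arg(test)
  if (nObs <= 0 || nCtrl <= 0) stop("zero totals in enrichment test")
  if (nObsOverlap > nObs || nCtrlOverlap > nCtrl || nObsOverlap < 0 ||
      nCtrlOverlap < 0)
    stop("inconsistent counts in enrichment test")
  tab <- matrix(c(nObsOverlap, nObs - nObsOverlap,
                  nCtrlOverlap, nCtrl - nCtrlOverlap),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("observed", "control"),
                                c("overlap", "no_overlap")))
  obsRate <- nObsOverlap / nObs
  ctrlRate <- nCtrlOverlap / nCtrl
  if (any(colSums(tab) == 0)) {
    stat <- NA_real_; pval <- NA_real_
  } else if (test == "chi-squared") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic); pval <- ht$p.value
  } else {
    ht <- stats::fisher.test(tab)
    stat <- NA_real_; pval <- ht$p.value
  }
  data.frame(test = test, statistic = stat, p_value = pval,
             obs_rate = obsRate, ctrl_rate = ctrlRate,
             direction = sign(obsRate - ctrlRate),
             stringsAsFactors = FALSE)
}

#' Per-class feature enrichment against matched controls
#'
#' Convenience wrapper: for each peak class, compares the fraction of
#' peaks overlapping `features` with the fraction among the class's
#' matched control regions.
#'
#' @param classification an [OriClassification-class]
#' @param features GRanges of a feature set
#' @param controls GRanges of control regions with a `class` mcol matching
#'   the peak classes (as from [matchedControls()])
#' @param feature label written into the result
#' @inheritParams enrichmentTest
#' @param minOverlap minimum shared bases
#' @return data.frame, one row per class
#' @export
classEnrichment <- function(classification, features, controls,
                            feature = "feature",
                            test = c("chi-squared", "fisher"),
                            minOverlap = 1L) {
  test <- match.arg(test)
  peaks <- classification@peaks
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  ctrlCls <- as.character(S4Vectors::mcols(controls)$class)
  rows <- list()
  for (cl in intersect(c("ORI", "CO", "WO", "OTHER"), unique(cls))) {
    pk <- peaks[cls == cl]
    ct <- controls[ctrlCls == cl]
    if (!length(pk) || !length(ct)) next
    res <- enrichmentTest(sum(overlapFlags(pk, features, minOverlap)),
                          length(pk),
                          sum(overlapFlags(ct, features, minOverlap)),
                          length(ct), test = test)
    rows[[cl]] <- cbind(data.frame(class = cl, feature = feature,
                                   n_peaks = length(pk),
                                   n_controls = length(ct),
                                   stringsAsFactors = FALSE), res)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Length-matched random controls per peak class
#'
#' @param classification an [OriClassification-class]
#' @param chromLengths named chromosome lengths
#' @param mask optional excluded intervals
#' @param seed integer seed
#' @param setsPerClass randomizations pooled per class
#' @return GRanges with a `class` mcol
#' @export
matchedControls <- function(classification, chromLengths, mask = NULL,
                            seed = 1L, setsPerClass = 1L) {
  peaks <- classification@peaks
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  keep <- cls != "UNASSIGNED"
  src <- rep(GenomicRanges::granges(peaks[keep]), setsPerClass)
  ctrl <- randomizeRegions(src, chromLengths, mask = mask, seed = seed)
  S4Vectors::mcols(ctrl)$class <- rep(cls[keep], setsPerClass)
  ctrl
}
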