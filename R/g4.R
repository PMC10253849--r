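## Strand-specific G4 quadruplex analysis: exclusive-strand calls per
## peak, stranded flank counting, strand-bias tests, leading/lagging
## assignment at bidirectional origins.

#' Exclusive-strand G4 call per peak
#'
#' Overlap (>= 1 base) is determined separately against Watson- and
#' Crick-strand G4 intervals; each peak is called `G4_Watson_only`,
#' `G4_Crick_only`, `both` or `none`. Peaks touching G4s on both strands
#' are excluded from the per-class two-way summary, mirroring the
#' exclusive-strand analysis design.
#'
#' @param classification an [OriClassification-class] (or GRanges with a
#'   `class` mcol)
#' @param g4 stranded GRanges of G4 intervals (`+`/`-` only)
#' @return list: `calls` (character per peak) and `byClass` (data.frame of
#'   Watson-only / Crick-only counts per class, both/none excluded)
#' @export
g4ExclusiveCall <- function(classification, g4) {
  peaks <- if (methods::is(classification, "OriClassification"))
    classification@peaks else classification
  stopIfUnstranded(g4, "G4 interval")
  w <- overlapFlags(peaks, g4[strandChr(g4) == "+"])
  k <- overlapFlags(peaks, g4[strandChr(g4) == "-"])
  calls <- ifelse(w & k, "both",
                  ifelse(w, "G4_Watson_only",
                         ifelse(k, "G4_Crick_only", "none")))
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  if (is.null(cls)) cls <- rep("all", length(peaks))
  classes <- unique(cls)
  byClass <- data.frame(
    class = classes,
    watson_only = vapply(classes, function(x)
      sum(calls == "G4_Watson_only" & cls == x), 0L),
    crick_only = vapply(classes, function(x)
      sum(calls == "G4_Crick_only" & cls == x), 0L),
    n_both = vapply(classes, function(x)
      sum(calls == "both" & cls == x), 0L),
    n_none = vapply(classes, function(x)
      sum(calls == "none" & cls == x), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(calls = calls, byClass = byClass)
}

#' Stranded G4 counts in fixed flanks around peak centers
#'
#' Counts every G4 interval overlapping the window
#' `[center - flank, center + flank)` once, under its own strand, with a
#' side breakdown (left/right of the peak center by the G4's midpoint;
#' midpoint exactly at the center counts right).
#'
#' @inheritParams g4ExclusiveCall
#' @param flank half-width of the window in bp (default 1000, i.e. the
#'   2 kb surrounding the center)
#' @return data.frame per class: watson / crick totals and per-(side,
#'   strand) breakdown
#' @export
g4FlankCounts <- function(classification, g4, flank = 1000L) {
  peaks <- if (methods::is(classification, "OriClassification"))
    classification@peaks else classification
  stopIfUnstranded(g4, "G4 interval")
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  if (is.null(cls)) cls <- rep("all", length(peaks))
  c0 <- mid0(peaks)
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(pmax(0, c0 - flank) + 1L,
                                                 c0 + flank))
  ov <- GenomicRanges::findOverlaps(win, GenomicRanges::granges(g4),
                                    ignore.strand = TRUE)
  pk <- S4Vectors::queryHits(ov); gq <- S4Vectors::subjectHits(ov)
  gWatson <- strandChr(g4)[gq] == "+"
  gRight <- mid0(g4)[gq] >= c0[pk]
  cl <- factor(cls[pk], levels = unique(cls))
  cnt <- function(sel) as.vector(table(cl[sel]))
  data.frame(class = levels(cl),
             watson = cnt(gWatson), crick = cnt(!gWatson),
             left_watson = cnt(gWatson & !gRight),
             left_crick = cnt(!gWatson & !gRight),
             right_watson = cnt(gWatson & gRight),
             right_crick = cnt(!gWatson & gRight),
             stringsAsFactors = FALSE)
}

#' Chi-squared strand-bias tests on Watson vs Crick counts
#'
#' Per class, a goodness-of-fit test of the Watson:Crick split against
#' 50:50; for each pair of classes, a 2x2 test of differing bias.
#'
#' @param counts data.frame with columns `class`, `watson`, `crick`
#' @return list: `perClass` (class, watson, crick, statistic, p_value) and
#'   `betweenClasses` (class1, class2, statistic, p_value)
#' @export
strandBiasTest <- function(counts) {
  stopifnot(all(c("class", "watson", "crick") %in% names(counts)))
  if (any(counts$watson < 0 | counts$crick < 0))
    stop("negative strand counts")
  per <- lapply(seq_len(nrow(counts)), function(i) {
    w <- counts$watson[i]; k <- counts$crick[i]
    if (w + k == 0) stop("zero total strand count for class ",
                         counts$class[i])
    ht <- suppressWarnings(stats::chisq.test(c(w, k), p = c(0.5, 0.5)))
    data.frame(class = counts$class[i], watson = w, crick = k,
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  pairs <- if (nrow(counts) >= 2)
    utils::combn(seq_len(nrow(counts)), 2, simplify = FALSE)
  else list()
  between <- lapply(pairs, function(ij) {
    tab <- as.matrix(counts[ij, c("watson", "crick")])
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(class1 = counts$class[ij[1]], class2 = counts$class[ij[2]],
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  list(perClass = do.call(rbind, per),
       betweenClasses = if (length(between)) do.call(rbind, between)
                        else NULL)
}

#' Leading/lagging-strand assignment of flanking G4s at bidirectional origins
#'
#' At a bidirectional origin the nascent leading strand left of the center
#' is the Crick strand and right of the center the Watson strand. Each G4
#' in the flank window is labelled `leading` if its strand equals the
#' leading-strand label of its side, else `lagging`. Returns the 2x2
#' (side x label) table with a chi-squared test of the leading:lagging
#' split.
#'
#' @param oriPeaks GRanges of ORI-class peaks only (other classes are an
#'   error: sides have no two-fork interpretation there)
#' @param g4 stranded GRanges
#' @param flank half-width of the window in bp
#' @return list: `table` (2x2 matrix side x label), `statistic`, `p_value`
#' @export
leadingLaggingSplit <- function(oriPeaks, g4, flank = 1000L) {
  cls <- S4Vectors::mcols(oriPeaks)$class
  if (!is.null(cls) && any(cls != "ORI"))
    stop("leadingLaggingSplit expects ORI-class peaks only")
  stopIfUnstranded(g4, "G4 interval")
  c0 <- mid0(oriPeaks)
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(oriPeaks),
                                IRanges::IRanges(pmax(0, c0 - flank) + 1L,
                                                 c0 + flank))
  ov <- GenomicRanges::findOverlaps(win, GenomicRanges::granges(g4),
                                    ignore.strand = TRUE)
  pk <- S4Vectors::queryHits(ov); gq <- S4Vectors::subjectHits(ov)
  right <- mid0(g4)[gq] >= c0[pk]
  leadStrand <- ifelse(right, "+", "-")  # Watson leads right, Crick left
  leading <- strandChr(g4)[gq] == leadStrand
  tab <- table(side = factor(ifelse(right, "right", "left"),
                             levels = c("left", "right")),
               label = factor(ifelse(leading, "leading", "lagging"),
                              levels = c("leading", "lagging")))
  tot <- margin.table(tab, 2)
  ht <- if (sum(tot) > 0)
    suppressWarnings(stats::chisq.test(as.vector(tot), p = c(0.5, 0.5)))
  else list(statistic = NA_real_, p.value = NA_real_)
  list(table = as.matrix(tab), statistic = unname(ht$statistic),
       p_value = ht$p.value)
}
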