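## Core classification: split each ori-SSDS peak at its middle, compute
## per-side Crick fractions, and call ORI / CO / WO / OTHER.

#' Per-peak strand counts on the left and right halves
#'
#' Splits each peak at its middle (the 0-based position
#' `m = floor((start + end) / 2)`) and counts reads by (side, strand). A
#' read belongs to a peak iff the read's own midpoint lies inside the peak
#' (half-open), and to the left side iff its midpoint < m; a midpoint
#' exactly at m counts right. Left/right Crick fractions `fL`, `fR` are NA
#' when the side has no reads.
#'
#' @param peaks GRanges of peaks (any mcols are carried through)
#' @param reads stranded GRanges of SNS reads; unstranded reads are an
#'   error, since strandness is the method's premise
#' @return `peaks` with added mcols `leftCrick`, `leftWatson`,
#'   `rightCrick`, `rightWatson`, `fL`, `fR`
#' @export
splitCounts <- function(peaks, reads) {
  stopIfUnstranded(reads, "read")
  n <- length(peaks)
  lc <- lw <- rc <- rw <- integer(n)
  if (length(reads) && n) {
    pts <- midpointRanges(reads)
    ov <- GenomicRanges::findOverlaps(pts, GenomicRanges::granges(peaks),
                                      ignore.strand = TRUE)
    pk <- S4Vectors::subjectHits(ov)
    rd <- S4Vectors::queryHits(ov)
    m <- mid0(peaks)[pk]
    leftSide <- mid0(reads)[rd] < m
    crick <- strandChr(reads)[rd] == "-"
    tally <- function(sel) tabulate(pk[sel], nbins = n)
    lc <- tally(leftSide & crick)
    lw <- tally(leftSide & !crick)
    rc <- tally(!leftSide & crick)
    rw <- tally(!leftSide & !crick)
  }
  out <- peaks
  S4Vectors::mcols(out)$leftCrick <- lc
  S4Vectors::mcols(out)$leftWatson <- lw
  S4Vectors::mcols(out)$rightCrick <- rc
  S4Vectors::mcols(out)$rightWatson <- rw
  S4Vectors::mcols(out)$fL <- ifelse(lc + lw > 0, lc / (lc + lw), NA_real_)
  S4Vectors::mcols(out)$fR <- ifelse(rc + rw > 0, rc / (rc + rw), NA_real_)
  out
}

#' Classify peaks from left/right Crick fractions
#'
#' With `fL`, `fR` the Crick-read fractions on the left and right halves:
#' CO iff both > 0.5; WO iff both < 0.5. Under the default `"figure1b"`
#' orientation (Crick reads on the left half, Watson on the right half of a
#' bidirectional origin) ORI iff `fL > 0.5 & fR < 0.5` and OTHER iff
#' `fL < 0.5 & fR > 0.5`; `"methods_literal"` swaps ORI and OTHER. Any
#' fraction undefined or exactly 0.5 gives UNASSIGNED.
#'
#' @param profiles GRanges from [splitCounts()] (or anything with `fL`,
#'   `fR` mcols)
#' @param orientation `"figure1b"` (default) or `"methods_literal"`
#' @return character vector of classes
#' @export
classifyPeaks <- function(profiles, orientation = c("figure1b",
                                                    "methods_literal")) {
  orientation <- match.arg(orientation)
  mc <- S4Vectors::mcols(profiles)
  fL <- mc$fL; fR <- mc$fR
  cls <- rep("UNASSIGNED", length(profiles))
  def <- !is.na(fL) & !is.na(fR) & fL != 0.5 & fR != 0.5
  cls[def & fL > 0.5 & fR > 0.5] <- "CO"
  cls[def & fL < 0.5 & fR < 0.5] <- "WO"
  crickLeft <- def & fL > 0.5 & fR < 0.5
  crickRight <- def & fL < 0.5 & fR > 0.5
  if (orientation == "figure1b") {
    cls[crickLeft] <- "ORI"; cls[crickRight] <- "OTHER"
  } else {
    cls[crickRight] <- "ORI"; cls[crickLeft] <- "OTHER"
  }
  cls
}

#' Classify every peak and summarize class proportions
#'
#' Runs [splitCounts()] and [classifyPeaks()] and reports per-class
#' fractions among classified (non-UNASSIGNED) peaks, including the
#' unidirectional fraction `(CO + WO) / (ORI + CO + WO + OTHER)`.
#'
#' @inheritParams splitCounts
#' @inheritParams classifyPeaks
#' @return an [OriClassification-class]
#' @export
classifyAll <- function(peaks, reads, orientation = c("figure1b",
                                                      "methods_literal")) {
  orientation <- match.arg(orientation)
  prof <- splitCounts(peaks, reads)
  cls <- classifyPeaks(prof, orientation)
  S4Vectors::mcols(prof)$class <- cls
  classified <- cls[cls != "UNASSIGNED"]
  props <- if (length(classified)) {
    tab <- table(factor(classified, levels = c("ORI", "CO", "WO", "OTHER")))
    pr <- as.numeric(tab) / length(classified)
    names(pr) <- names(tab)
    c(pr, unidirectional = unname(pr["CO"] + pr["WO"]))
  } else {
    c(ORI = 0, CO = 0, WO = 0, OTHER = 0, unidirectional = 0)
  }
  methods::new("OriClassification", peaks = prof, proportions = props,
               orientation = orientation)
}
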