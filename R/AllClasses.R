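## Central S4 containers. All interval slots are GRanges (1-based closed,
## converted from/to BED 0-based half-open at the I/O boundary).

#' SyntheticSpec: a fully specified synthetic replication-origin study
#'
#' Holds chromosome lengths, the planted origin map (position, class,
#' efficiency, nascent-strand halfwidth, barrier strength), gene models with
#' expression, CpG islands, stranded G4 intervals, and all scalar generator
#' parameters. Built by [buildSyntheticSpec()]; consumed by
#' [simulateSSDS()], [simulateOKSeq()] and [emitTracks()].
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp)
#' @slot origins width-1 GRanges of origin positions with mcols
#'   `planted_class` (ORI/CO/WO), `efficiency`, `halfwidth`, `barrier`
#' @slot genes GRanges of gene bodies with strand and mcols `gene_id`,
#'   `cpm`, `expressed`
#' @slot cpg GRanges of CpG islands
#' @slot g4 stranded GRanges of G4 quadruplex intervals
#' @slot params named list of scalar generator parameters
#'   (see [syntheticDefaults()])
#' @slot seed integer seed governing every downstream simulation
#' @export
setClass("SyntheticSpec",
  representation(chromLengths = "integer", origins = "GRanges",
                 genes = "GRanges", cpg = "GRanges", g4 = "GRanges",
                 params = "list", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  p <- object@params
  msg <- character()
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be a named positive integer vector")
  for (nm in c("g4Beta", "strandSwapNoise", "barrierStrength"))
    if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  if (!is.null(p$snsHalfwidth) && p$snsHalfwidth <= 0)
    msg <- c(msg, "snsHalfwidth must be positive")
  inBounds <- function(gr) {
    if (length(gr) == 0) return(TRUE)
    len <- object@chromLengths[as.character(GenomicRanges::seqnames(gr))]
    all(GenomicRanges::start(gr) >= 1 & GenomicRanges::end(gr) <= len)
  }
  for (slotName in c("origins", "genes", "cpg", "g4"))
    if (!inBounds(slot(object, slotName)))
      msg <- c(msg, sprintf("%s placements exceed chromosome bounds", slotName))
  if (length(msg)) msg else TRUE
})

#' OriClassification: classified ori-SSDS peaks
#'
#' One row per peak with left/right x Watson/Crick read counts, left/right
#' Crick fractions and the assigned class (ORI, CO, WO, OTHER, UNASSIGNED).
#'
#' @slot peaks GRanges with mcols `leftCrick`, `leftWatson`, `rightCrick`,
#'   `rightWatson`, `fL`, `fR`, `class` (and any truth columns carried along)
#' @slot proportions named numeric: per-class fraction among classified
#'   (non-UNASSIGNED) peaks plus `unidirectional`
#' @slot orientation `"figure1b"` or `"methods_literal"`
#' @export
setClass("OriClassification",
  representation(peaks = "GRanges", proportions = "numeric",
                 orientation = "character"))

setValidity("OriClassification", function(object) {
  need <- c("leftCrick", "leftWatson", "rightCrick", "rightWatson",
            "fL", "fR", "class")
  if (!all(need %in% names(S4Vectors::mcols(object@peaks))))
    return("peaks must carry count, fraction and class columns")
  cls <- as.character(S4Vectors::mcols(object@peaks)$class)
  if (!all(cls %in% c("ORI", "CO", "WO", "OTHER", "UNASSIGNED")))
    return("unknown peak class label")
  TRUE
})

#' RFDTrack: binned strand counts and replication fork direction
#'
#' Chromosome-tiling bins with forward (F, Watson) and reverse (R, Crick)
#' OK-seq read counts; [computeRFD()] adds `rfd = (R - F) / (F + R)`
#' (NA where F + R = 0).
#'
#' @slot bins GRanges tiling each chromosome from 0 with mcols `F`, `R`
#'   (and `rfd` after [computeRFD()])
#' @slot binSize bin width in bp
#' @export
setClass("RFDTrack",
  representation(bins = "GRanges", binSize = "integer"))

setValidity("RFDTrack", function(object) {
  mc <- S4Vectors::mcols(object@bins)
  if (!all(c("F", "R") %in% names(mc)))
    return("bins must carry F and R counts")
  if (any(mc$F < 0) || any(mc$R < 0)) return("negative strand counts")
  if (object@binSize <= 0) return("binSize must be positive")
  TRUE
})

#' MetaProfile: windowed RFD meta-profile around classified peaks
#'
#' Mean RFD in `nWindows` fixed-width windows anchored at peak midpoints,
#' one row per peak class plus a `"random"` row for the matched control set.
#'
#' @slot means numeric matrix (class x window); columns named by window
#'   index (-nWindows/2 .. nWindows/2 - 1)
#' @slot nPeaks integer matrix of contributing peaks per (class, window)
#' @slot windowSize window width in bp
#' @export
setClass("MetaProfile",
  representation(means = "matrix", nPeaks = "matrix",
                 windowSize = "integer"))

setValidity("MetaProfile", function(object) {
  ok <- is.na(object@means) | (object@means >= -1 & object@means <= 1)
  if (!all(ok)) return("meta-profile means must lie in [-1, 1]")
  if (!identical(dim(object@means), dim(object@nPeaks)))
    return("means and nPeaks dimensions differ")
  TRUE
})
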