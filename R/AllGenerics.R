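#' @rdname OriClassification-class
#' @param object an S4 object from this package
#' @export
setGeneric("peakClasses", function(object) standardGeneric("peakClasses"))

#' @rdname OriClassification-class
#' @export
setGeneric("classProportions",
           function(object) standardGeneric("classProportions"))

#' @rdname OriClassification-class
#' @export
setGeneric("profileTable", function(object) standardGeneric("profileTable"))

#' @rdname RFDTrack-class
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname RFDTrack-class
#' @export
setGeneric("rfdValues", function(object) standardGeneric("rfdValues"))

#' @rdname MetaProfile-class
#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))

#' @rdname SyntheticSpec-class
#' @export
setGeneric("originMap", function(object) standardGeneric("originMap"))

## ---- methods -------------------------------------------------------------

#' @rdname OriClassification-class
#' @export
setMethod("peakClasses", "OriClassification", function(object) {
  stats::setNames(as.character(S4Vectors::mcols(object@peaks)$class), NULL)
})

#' @rdname OriClassification-class
#' @export
setMethod("classProportions", "OriClassification",
          function(object) object@proportions)

#' @rdname OriClassification-class
#' @export
setMethod("profileTable", "OriClassification", function(object) {
  gr <- object@peaks
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             as.data.frame(S4Vectors::mcols(gr)),
             stringsAsFactors = FALSE)
})

#' @rdname RFDTrack-class
#' @export
setMethod("binCounts", "RFDTrack", function(object) object@bins)

#' @rdname RFDTrack-class
#' @export
setMethod("rfdValues", "RFDTrack", function(object) {
  mc <- S4Vectors::mcols(object@bins)
  if (is.null(mc$rfd)) stop("run computeRFD() first")
  mc$rfd
})

#' @rdname MetaProfile-class
#' @export
setMethod("profileMatrix", "MetaProfile", function(object) object@means)

#' @rdname SyntheticSpec-class
#' @export
setMethod("originMap", "SyntheticSpec", function(object) object@origins)

setMethod("show", "OriClassification", function(object) {
  n <- length(object@peaks)
  cls <- table(factor(S4Vectors::mcols(object@peaks)$class,
                      levels = c("ORI", "CO", "WO", "OTHER", "UNASSIGNED")))
  cat(sprintf("OriClassification (%s orientation): %d peaks\n",
              object@orientation, n))
  print(cls)
  cat(sprintf("unidirectional fraction (CO+WO among classified): %.3f\n",
              object@proportions[["unidirectional"]]))
})

setMethod("show", "RFDTrack", function(object) {
  mc <- S4Vectors::mcols(object@bins)
  cat(sprintf("RFDTrack: %d bins of %d bp; F = %d, R = %d reads%s\n",
              length(object@bins), object@binSize,
              sum(mc$F), sum(mc$R),
              if (is.null(mc$rfd)) " (RFD not yet computed)" else ""))
})

setMethod("show", "MetaProfile", function(object) {
  cat(sprintf("MetaProfile: %d windows of %d bp, rows: %s\n",
              ncol(object@means), object@windowSize,
              paste(rownames(object@means), collapse = ", ")))
})

setMethod("show", "SyntheticSpec", function(object) {
  cls <- table(S4Vectors::mcols(object@origins)$planted_class)
  cat(sprintf(
    "SyntheticSpec: %d chromosomes (%.1f Mb), %d origins (%s), %d genes, %d G4s, seed %d\n",
    length(object@chromLengths), sum(object@chromLengths) / 1e6,
    length(object@origins),
    paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = " "),
    length(object@genes), length(object@g4), object@seed))
})
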