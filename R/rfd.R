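## OK-seq replication fork direction: binned strand counts, RFD tracks and
## class-wise meta-profiles around classified peaks.

#' Bin stranded OK-seq reads into fixed-width windows
#'
#' Each read is assigned to the bin containing its midpoint (bin
#' `floor(mid / binSize)`, bins tiling each chromosome from 0). Totals are
#' conserved: the F column sums to the number of Watson reads.
#'
#' @param reads stranded GRanges of OK-seq reads
#' @param chromLengths named vector of chromosome lengths (bp)
#' @param binSize bin width in bp (default 1000)
#' @return an [RFDTrack-class] with per-bin `F` (Watson) and `R` (Crick)
#'   counts
#' @export
binStrandCounts <- function(reads, chromLengths, binSize = 1000L) {
  stopIfUnstranded(reads, "OK-seq read")
  binSize <- as.integer(binSize)
  mids <- mid0(reads)
  rChrom <- as.character(GenomicRanges::seqnames(reads))
  watson <- strandChr(reads) == "+"
  out <- list()
  for (cn in names(chromLengths)) {
    len <- chromLengths[[cn]]
    nBin <- as.integer(ceiling(len / binSize))
    sel <- rChrom == cn
    b <- mids[sel] %/% binSize + 1L          # 1-based bin index
    Fc <- tabulate(b[watson[sel]], nbins = nBin)
    Rc <- tabulate(b[!watson[sel]], nbins = nBin)
    s0 <- (seq_len(nBin) - 1L) * binSize
    out[[cn]] <- GenomicRanges::GRanges(
      cn, IRanges::IRanges(s0 + 1L, pmin(s0 + binSize, len)),
      F = Fc, R = Rc)
  }
  bins <- suppressWarnings(do.call(c, unname(out)))
  GenomeInfoDb::seqlengths(bins) <-
    as.integer(chromLengths[GenomeInfoDb::seqlevels(bins)])
  methods::new("RFDTrack", bins = bins, binSize = binSize)
}

#' Compute replication fork directionality per bin
#'
#' `RFD = (R - F) / (F + R)` with R the Crick (reverse) and F the Watson
#' (forward) read count; NA where `F + R = 0`. RFD = +1 marks purely
#' rightward-moving forks.
#'
#' @param track an [RFDTrack-class] from [binStrandCounts()]
#' @return the track with an `rfd` column added to its bins
#' @export
computeRFD <- function(track) {
  stopifnot(methods::is(track, "RFDTrack"))
  mc <- S4Vectors::mcols(track@bins)
  tot <- mc$F + mc$R
  S4Vectors::mcols(track@bins)$rfd <-
    ifelse(tot > 0, (mc$R - mc$F) / tot, NA_real_)
  track
}

#' Write an RFD track as bedGraph (bins with coverage only)
#'
#' @param track an [RFDTrack-class]; RFD is computed if absent
#' @param path output path
#' @export
writeRFD <- function(track, path) {
  if (is.null(S4Vectors::mcols(track@bins)$rfd)) track <- computeRFD(track)
  keep <- !is.na(S4Vectors::mcols(track@bins)$rfd)
  gr <- track@bins[keep]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    score = round(S4Vectors::mcols(gr)$rfd, 6))
  writeIntervals(gr, path, "bedGraph")
}

#' RFD meta-profile around classified peaks
#'
#' For each peak midpoint m, anchors `nWindows` windows
#' `[m + (i - nWindows/2) * windowSize, ...)`; per window, F and R are
#' summed over the constituent bins (windows are snapped to the bin grid at
#' the anchor bin) and RFD computed from the sums, then averaged over the
#' peaks of each class. Windows falling off the chromosome or with zero
#' coverage are skipped for that peak, not truncated. A matched random
#' control profile (same interval lengths, `controlSets` randomizations) is
#' computed alongside under the `"random"` row.
#'
#' @param track an [RFDTrack-class]
#' @param classification an [OriClassification-class] (UNASSIGNED peaks are
#'   ignored)
#' @param nWindows number of windows (default 40)
#' @param windowSize window width in bp (default 50000); must be a multiple
#'   of the track's bin size
#' @param controlSets how many length-matched random peak sets to pool into
#'   the control profile (0 disables it)
#' @param seed seed for the random control placement
#' @return a [MetaProfile-class]
#' @export
metaProfile <- function(track, classification, nWindows = 40L,
                        windowSize = 50000L, controlSets = 1L, seed = 1L) {
  stopifnot(methods::is(track, "RFDTrack"),
            methods::is(classification, "OriClassification"))
  k <- windowSize / track@binSize
  if (k != round(k))
    stop("windowSize must be a multiple of the track bin size")
  k <- as.integer(k)
  chromLengths <- GenomeInfoDb::seqlengths(track@bins)

  peaks <- classification@peaks
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  keep <- cls != "UNASSIGNED"
  peaks <- peaks[keep]; cls <- cls[keep]

  anchors <- list()
  for (cl in unique(cls)) anchors[[cl]] <- peaks[cls == cl]
  if (controlSets > 0 && length(peaks)) {
    ctrl <- randomizeRegions(
      rep(GenomicRanges::granges(peaks), controlSets),
      chromLengths, seed = seed)
    anchors[["random"]] <- ctrl
  }

  ## per-chromosome cumulative F/R over the complete bins
  cum <- list()
  binChrom <- as.character(GenomicRanges::seqnames(track@bins))
  mc <- S4Vectors::mcols(track@bins)
  for (cn in names(chromLengths)) {
    sel <- binChrom == cn
    cum[[cn]] <- list(F = c(0, cumsum(mc$F[sel])),
                      R = c(0, cumsum(mc$R[sel])),
                      nFull = as.integer(chromLengths[[cn]] %/% track@binSize))
  }

  half <- nWindows %/% 2L
  offsets <- seq_len(nWindows) - half - 1L       # window indices -half..half-1
  means <- matrix(NA_real_, length(anchors), nWindows,
                  dimnames = list(names(anchors),
                                  as.character(offsets)))
  counts <- matrix(0L, length(anchors), nWindows,
                   dimnames = dimnames(means))
  for (a in seq_along(anchors)) {
    gr <- anchors[[a]]
    if (!length(gr)) next
    b <- mid0(gr) %/% track@binSize            # 0-based anchor bin
    cn <- as.character(GenomicRanges::seqnames(gr))
    for (w in seq_len(nWindows)) {
      lo <- b + offsets[w] * k                 # 0-based first bin
      hi <- lo + k                             # one past last bin
      vals <- rep(NA_real_, length(gr))
      for (cc in unique(cn)) {
        sel <- which(cn == cc)
        cu <- cum[[cc]]
        ok <- lo[sel] >= 0L & hi[sel] <= cu$nFull
        s <- sel[ok]
        if (!length(s)) next
        Fs <- cu$F[hi[s] + 1L] - cu$F[lo[s] + 1L]
        Rs <- cu$R[hi[s] + 1L] - cu$R[lo[s] + 1L]
        tot <- Fs + Rs
        vals[s] <- ifelse(tot > 0, (Rs - Fs) / tot, NA_real_)
      }
      counts[a, w] <- sum(!is.na(vals))
      if (counts[a, w] > 0) means[a, w] <- mean(vals, na.rm = TRUE)
    }
  }
  methods::new("MetaProfile", means = means, nPeaks = counts,
               windowSize = as.integer(windowSize))
}

#' Tidy data.frame view of a meta-profile
#'
#' @param profile a [MetaProfile-class]
#' @return data.frame: class, window_index, mean_rfd, n_peaks
#' @export
metaProfileTable <- function(profile) {
  stopifnot(methods::is(profile, "MetaProfile"))
  m <- profile@means
  data.frame(class = rep(rownames(m), ncol(m)),
             window_index = rep(as.integer(colnames(m)), each = nrow(m)),
             mean_rfd = as.vector(m),
             n_peaks = as.vector(profile@nPeaks),
             stringsAsFactors = FALSE)[order(rep(rownames(m), ncol(m))), ]
}
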