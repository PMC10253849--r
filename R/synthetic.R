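## Synthetic study generator: genome, planted origin map, stranded SNS and
## OK-seq reads, feature tracks -- all with truth labels and full
## determinism under a single seed.

#' Default generator parameters
#'
#' The defaults define the study conditions emulated by the generator:
#' 2 chromosomes of 10 Mb; 200 bidirectional (ORI), 50 Crick-only (CO) and
#' 50 Watson-only (WO) origins with ~50 nascent-strand reads per firing
#' side; absolute fork barriers at unidirectional origins; 5% strand-swap
#' noise; dense gene models with half the genes expressed; G4s planted in
#' the firing flanks with Watson-strand probability 0.75 at CO origins
#' (mirrored at WO); early replication-timing bumps at origins; 3x ATAC
#' density inside origin peaks.
#'
#' @return named list of parameters, overridable via [buildSyntheticSpec()]
#' @export
syntheticDefaults <- function() {
  list(
    nChrom = 2L, chromLength = 10e6,
    nORI = 200L, nCO = 50L, nWO = 50L,
    snsHalfwidth = 1000, snsReadLength = 150,
    efficiency = 50, barrierStrength = 1,
    strandSwapNoise = 0.05, backgroundRate = 1e-7,
    minSpacing = NA_real_,           # default: 4 * snsHalfwidth
    geneSlot = 10000, geneDensity = 0.8,
    geneLengthMin = 4000, geneLengthMax = 6000,
    expressedFraction = 0.5,
    promoterPlacement = 0.45,        # fraction of origins planted in promoters
    expressedPlacement = 0.25,       # fraction planted in expressed gene bodies
    oppositeTxnBias = 0.6,           # P(host gene on opposite strand) for CO/WO
    tssWindow = 1000,
    g4PerOrigin = 2L, g4Length = 30, g4Beta = 0.75,
    g4BackgroundPerMb = 2,
    cpgAtOriginFraction = 0.6, cpgLength = 1000, cpgBackgroundPerMb = 5,
    rtBaseline = 0, rtNoiseSd = 0.3, rtAmplitude = 2,
    rtSegment = 10000, rtBumpHalfwidth = 20000,
    okDensity = 0.01, okReadLength = 150,
    atacDensity = 0.005, atacFold = 3, atacReadLength = 50,
    gcBackground = 0.4, gcOrigin = 0.6)
}

#' Build a synthetic study specification
#'
#' Places gene models, then origins of each planted class (with minimum
#' spacing and configurable promoter / expressed-gene placement
#' preference), then CpG islands and stranded G4 intervals whose strand at
#' CO origins is Watson with probability `g4Beta` (mirrored at WO, 0.5 at
#' ORI). Deterministic under `seed`: rebuilding with the same config and
#' seed is identical.
#'
#' @param config named list overriding entries of [syntheticDefaults()]
#' @param seed integer seed stored in the spec and governing all
#'   simulation stages
#' @return a [SyntheticSpec-class] object
#' @export
buildSyntheticSpec <- function(config = list(), seed = 1L) {
  p <- syntheticDefaults()
  unknown <- setdiff(names(config), names(p))
  if (length(unknown))
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "))
  p[names(config)] <- config
  if (is.na(p$minSpacing)) p$minSpacing <- 4 * p$snsHalfwidth
  set.seed(as.integer(seed))

  chromLengths <- stats::setNames(rep(as.integer(p$chromLength), p$nChrom),
                                  paste0("chr", seq_len(p$nChrom)))
  genes <- .placeGenes(chromLengths, p)
  origins <- .placeOrigins(chromLengths, genes, p)
  cpg <- .placeCpG(chromLengths, origins, p)
  g4 <- .placeG4(chromLengths, origins, p)

  methods::new("SyntheticSpec", chromLengths = chromLengths,
               origins = origins, genes = genes, cpg = cpg, g4 = g4,
               params = p, seed = as.integer(seed))
}

## Genes on a fixed slot grid (one candidate slot per geneSlot bp, occupied
## with probability geneDensity), alternating-random strand, lognormal-ish
## expression with `expressedFraction` of genes above the RPKM > 5 line.
.placeGenes <- function(chromLengths, p) {
  out <- list()
  gid <- 0L
  for (chrom in names(chromLengths)) {
    len <- chromLengths[[chrom]]
    nSlot <- max(0L, as.integer(len %/% p$geneSlot) - 1L)
    if (nSlot == 0) next
    occupied <- which(runif(nSlot) < p$geneDensity)
    if (!length(occupied)) next
    gl <- as.integer(round(runif(length(occupied),
                                 p$geneLengthMin, p$geneLengthMax)))
    slotStart <- (occupied - 1L) * as.integer(p$geneSlot)
    offset <- as.integer(floor(runif(length(occupied), 0,
                                     pmax(1, p$geneSlot - gl))))
    s0 <- slotStart + offset
    e0 <- pmin(s0 + gl, len)
    strand <- ifelse(runif(length(occupied)) < 0.5, "+", "-")
    expressed <- runif(length(occupied)) < p$expressedFraction
    rpkm <- ifelse(expressed,
                   exp(runif(length(occupied), log(6), log(60))),
                   runif(length(occupied), 0, 4))
    cpm <- rpkm * (e0 - s0) / 1000
    ids <- sprintf("gene%05d", gid + seq_along(occupied))
    gid <- gid + length(occupied)
    out[[chrom]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(s0 + 1L, e0), strand = strand,
      gene_id = ids, cpm = cpm, expressed = expressed)
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

## 0-based TSS position of each gene: start for Watson genes, end for Crick.
.tss0 <- function(genes) {
  ifelse(strandChr(genes) == "+",
         GenomicRanges::start(genes) - 1L,
         GenomicRanges::end(genes))
}

## Sequential rejection placement of origins with minimum spacing and a
## promoter / expressed-gene placement mixture. CO/WO origins prefer host
## genes on the strand opposite their read strand with prob oppositeTxnBias.
.placeOrigins <- function(chromLengths, genes, p) {
  classes <- c(rep("ORI", p$nORI), rep("CO", p$nCO), rep("WO", p$nWO))
  n <- length(classes)
  if (n == 0) return(GenomicRanges::GRanges())
  hw <- p$snsHalfwidth
  margin <- hw + p$snsReadLength
  if (any(chromLengths < 2 * margin + 1))
    stop("chromosomes too short for the requested origin halfwidth")
  tss <- if (length(genes)) .tss0(genes) else numeric(0)
  geneChrom <- as.character(GenomicRanges::seqnames(genes))
  exprIdx <- if (length(genes)) which(S4Vectors::mcols(genes)$expressed)
             else integer(0)
  placedPos <- lapply(names(chromLengths), function(x) numeric(0))
  names(placedPos) <- names(chromLengths)
  resChrom <- character(n); resPos <- numeric(n)

  pickGene <- function(cls, pool) {
    if (!length(pool)) return(NA_integer_)
    if (cls %in% c("CO", "WO")) {
      ## opposite strand of a CO peak (reads on Crick) is Watson and v.v.
      want <- if (cls == "CO") "+" else "-"
      sub <- pool[strandChr(genes)[pool] ==
                    (if (runif(1) < p$oppositeTxnBias) want
                     else setdiff(c("+", "-"), want))]
      if (length(sub)) pool <- sub
    }
    pool[sample.int(length(pool), 1L)]
  }

  maxTries <- 400L * n
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > maxTries)
        stop(sprintf(
          "cannot place %d origins with minimum spacing %g on this genome",
          n, p$minSpacing))
      u <- runif(1)
      if (u < p$promoterPlacement && length(genes)) {
        g <- pickGene(classes[i], seq_along(genes))
        chrom <- geneChrom[g]
        pos <- round(tss[g] + runif(1, -p$tssWindow, p$tssWindow))
      } else if (u < p$promoterPlacement + p$expressedPlacement &&
                 length(exprIdx)) {
        g <- pickGene(classes[i], exprIdx)
        chrom <- geneChrom[g]
        pos <- round(runif(1, GenomicRanges::start(genes)[g] - 1L,
                           GenomicRanges::end(genes)[g]))
      } else {
        chrom <- names(chromLengths)[
          sample.int(length(chromLengths), 1L,
                     prob = as.numeric(chromLengths))]
        pos <- round(runif(1, margin, chromLengths[[chrom]] - margin))
      }
      if (pos < margin || pos > chromLengths[[chrom]] - margin) next
      if (length(placedPos[[chrom]]) &&
          min(abs(placedPos[[chrom]] - pos)) < p$minSpacing) next
      placedPos[[chrom]] <- c(placedPos[[chrom]], pos)
      resChrom[i] <- chrom; resPos[i] <- pos
      break
    }
  }
  gr <- GenomicRanges::GRanges(
    resChrom, IRanges::IRanges(resPos + 1L, width = 1L),
    planted_class = classes,
    efficiency = rep(p$efficiency, n),
    halfwidth = rep(hw, n),
    barrier = rep(p$barrierStrength, n))
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

.placeCpG <- function(chromLengths, origins, p) {
  out <- list()
  atOri <- which(runif(length(origins)) < p$cpgAtOriginFraction)
  if (length(atOri)) {
    pos <- mid0(origins)[atOri]
    s0 <- pmax(0, pos - p$cpgLength %/% 2)
    out$ori <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(origins)[atOri],
      IRanges::IRanges(s0 + 1L, width = p$cpgLength))
  }
  for (chrom in names(chromLengths)) {
    len <- chromLengths[[chrom]]
    nBg <- rpois(1, p$cpgBackgroundPerMb * len / 1e6)
    if (nBg > 0) {
      s0 <- floor(runif(nBg, 0, len - p$cpgLength))
      out[[paste0("bg.", chrom)]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(s0 + 1L, width = p$cpgLength))
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

## G4 intervals: g4PerOrigin per origin, uniform within the firing
## flank(s); strand Watson with prob g4Beta at CO origins, Crick with prob
## g4Beta at WO, 0.5 at ORI; plus a sparse unstranded-bias background.
.placeG4 <- function(chromLengths, origins, p) {
  out <- list()
  if (length(origins) && p$g4PerOrigin > 0) {
    k <- p$g4PerOrigin
    cls <- rep(S4Vectors::mcols(origins)$planted_class, each = k)
    hw <- rep(S4Vectors::mcols(origins)$halfwidth, each = k)
    pos <- rep(mid0(origins), each = k)
    chrom <- rep(as.character(GenomicRanges::seqnames(origins)), each = k)
    lo <- ifelse(cls == "WO", pos, pos - hw)
    hi <- ifelse(cls == "CO", pos, pos + hw) - p$g4Length
    s0 <- floor(runif(length(cls), lo, pmax(lo + 1, hi)))
    pWatson <- ifelse(cls == "CO", p$g4Beta,
                      ifelse(cls == "WO", 1 - p$g4Beta, 0.5))
    strand <- ifelse(runif(length(cls)) < pWatson, "+", "-")
    out$ori <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(s0 + 1L, width = p$g4Length), strand = strand)
  }
  for (chrom in names(chromLengths)) {
    len <- chromLengths[[chrom]]
    nBg <- rpois(1, p$g4BackgroundPerMb * len / 1e6)
    if (nBg > 0) {
      s0 <- floor(runif(nBg, 0, len - p$g4Length))
      out[[paste0("bg.", chrom)]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(s0 + 1L, width = p$g4Length),
        strand = ifelse(runif(nBg) < 0.5, "+", "-"))
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

#' Simulate strand-specific short-nascent-strand (ori-SSDS) reads
#'
#' Each origin fires Poisson(`efficiency`) fixed-length reads per firing
#' side: a bidirectional (ORI) origin emits Crick-strand reads with starts
#' uniform in `[pos - halfwidth, pos)` and Watson-strand reads in
#' `[pos, pos + halfwidth)`; a CO origin emits only the Crick (left) side
#' and a WO origin only the Watson (right) side, the blocked side firing
#' anyway with probability `1 - barrier`. Each read's strand is flipped
#' with probability `strandSwapNoise`; uniform Poisson background reads are
#' added on both strands. The emitted peak interval spans the nominal
#' flank(s) that fired; the truth table records the planted class.
#'
#' @param spec a [SyntheticSpec-class]
#' @return list with `reads` (stranded GRanges), `peaks` (GRanges), and
#'   `truth` (data.frame: chrom, start, end, planted_class, origin_pos)
#' @export
simulateSSDS <- function(spec) {
  methods::validObject(spec)
  p <- spec@params
  set.seed(spec@seed + 101L)
  ori <- spec@origins
  n <- length(ori)
  cls <- S4Vectors::mcols(ori)$planted_class
  pos <- mid0(ori)
  hw <- S4Vectors::mcols(ori)$halfwidth
  chrom <- as.character(GenomicRanges::seqnames(ori))
  rl <- p$snsReadLength

  ## which sides fire: left emits Crick, right emits Watson
  blockedFires <- runif(n) < (1 - S4Vectors::mcols(ori)$barrier)
  leftFires <- cls %in% c("ORI", "CO") | (cls == "WO" & blockedFires)
  rightFires <- cls %in% c("ORI", "WO") | (cls == "CO" & blockedFires)

  emitSide <- function(fires, flankLo, flankHi, strandChar) {
    idx <- which(fires)
    counts <- rpois(length(idx), S4Vectors::mcols(ori)$efficiency[idx])
    oriIdx <- rep(idx, counts)
    if (!length(oriIdx)) return(GenomicRanges::GRanges())
    s0 <- floor(runif(length(oriIdx), flankLo[oriIdx],
                      pmax(flankLo[oriIdx] + 1, flankHi[oriIdx] - rl + 1)))
    GenomicRanges::GRanges(chrom[oriIdx],
                           IRanges::IRanges(s0 + 1L, width = rl),
                           strand = strandChar)
  }
  left <- emitSide(leftFires, pos - hw, pos, "-")
  right <- emitSide(rightFires, pos, pos + hw, "+")

  ## uniform background, Poisson per strand per chromosome
  bg <- list()
  for (cn in names(spec@chromLengths)) {
    len <- spec@chromLengths[[cn]]
    for (sd in c("+", "-")) {
      nb <- rpois(1, p$backgroundRate * len)
      if (nb > 0) {
        s0 <- floor(runif(nb, 0, len - rl))
        bg[[paste(cn, sd)]] <- GenomicRanges::GRanges(
          cn, IRanges::IRanges(s0 + 1L, width = rl), strand = sd)
      }
    }
  }
  reads <- suppressWarnings(c(left, right, if (length(bg)) do.call(c, unname(bg))))
  reads <- .flipStrands(reads, p$strandSwapNoise)

  peakLo <- ifelse(leftFires, pos - hw, pos)
  peakHi <- ifelse(rightFires, pos + hw, pos)
  peaks <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(peakLo + 1L, peakHi),
                                  planted_class = cls, origin_pos = pos)
  truth <- data.frame(chrom = chrom, start = peakLo, end = peakHi,
                      planted_class = cls, origin_pos = pos,
                      stringsAsFactors = FALSE)
  list(reads = reads, peaks = peaks, truth = truth)
}

.flipStrands <- function(reads, eps) {
  if (length(reads) == 0 || eps <= 0) return(reads)
  flip <- runif(length(reads)) < eps
  sd <- strandChr(reads)
  sd[flip] <- ifelse(sd[flip] == "+", "-", "+")
  GenomicRanges::strand(reads) <- sd
  reads
}

#' Simulate Okazaki-fragment (OK-seq) reads
#'
#' Fork direction at any position points away from the nearest origin on
#' the chromosome (termination at midpoints between adjacent origins); all
#' origins, including CO and WO, propagate forks on both sides, modelling
#' blocked forks that resume. A rightward fork emits a Crick-strand
#' (reverse, R) read, a leftward fork a Watson-strand (forward, F) read.
#' Read positions are uniform at density `okDensity` reads/bp; strands are
#' flipped with probability `strandSwapNoise`.
#'
#' @param spec a [SyntheticSpec-class]
#' @return stranded GRanges of reads
#' @export
simulateOKSeq <- function(spec) {
  methods::validObject(spec)
  p <- spec@params
  set.seed(spec@seed + 202L)
  oriChrom <- as.character(GenomicRanges::seqnames(spec@origins))
  rl <- p$okReadLength
  out <- list()
  for (cn in names(spec@chromLengths)) {
    len <- spec@chromLengths[[cn]]
    oriPos <- sort(mid0(spec@origins)[oriChrom == cn])
    if (length(oriPos) == 0)
      stop("chromosome ", cn,
           " has no origins: fork direction undefined everywhere")
    nReads <- rpois(1, p$okDensity * len)
    if (nReads == 0) next
    s0 <- floor(runif(nReads, 0, len - rl))
    mids <- s0 + rl %/% 2
    rightward <- .forkRightward(mids, oriPos)
    strand <- ifelse(rightward, "-", "+")  # rightward fork -> Crick (R)
    out[[cn]] <- GenomicRanges::GRanges(
      cn, IRanges::IRanges(s0 + 1L, width = rl), strand = strand)
  }
  reads <- suppressWarnings(do.call(c, unname(out)))
  .flipStrands(reads, p$strandSwapNoise)
}

## TRUE where the fork at position x moves rightward, i.e. the nearest
## origin lies at or left of x; exact termination-midpoint ties go right.
.forkRightward <- function(x, oriPos) {
  i <- findInterval(x, oriPos)           # index of nearest origin <= x
  dLeft <- ifelse(i >= 1, x - oriPos[pmax(i, 1)], Inf)
  dRight <- ifelse(i < length(oriPos), oriPos[pmin(i + 1, length(oriPos))] - x,
                   Inf)
  dLeft <= dRight
}

#' Emit feature tracks for a synthetic study
#'
#' Builds (and optionally writes) the annotation inputs of the analysis:
#' gene BED + expression TSV, CpG island BED, stranded G4 BED, a
#' replication-timing bedGraph (baseline plus positive bumps of
#' `rtAmplitude` within `rtBumpHalfwidth` of each origin -- origins are
#' early-replicating), ATAC read positions (`atacFold` denser inside origin
#' peaks), and a genome FASTA with elevated G+C in origin and CpG regions.
#'
#' @param spec a [SyntheticSpec-class]
#' @param outdir optional directory; when given, files are written with the
#'   standard names (genes.bed, expression.tsv, cpg.bed, g4.bed,
#'   rt.bedgraph, atac.bed, genome.fa)
#' @param what subset of tracks to build
#' @return named list of in-memory objects
#' @export
emitTracks <- function(spec, outdir = NULL,
                       what = c("genes", "expression", "cpg", "g4", "rt",
                                "atac", "genome")) {
  methods::validObject(spec)
  p <- spec@params
  set.seed(spec@seed + 303L)
  res <- list()
  if ("genes" %in% what) res$genes <- spec@genes
  if ("expression" %in% what && length(spec@genes)) {
    g <- spec@genes
    res$expression <- data.frame(
      gene_id = S4Vectors::mcols(g)$gene_id,
      cpm = S4Vectors::mcols(g)$cpm,
      length = GenomicRanges::width(g),
      strand = strandChr(g), stringsAsFactors = FALSE)
  }
  if ("cpg" %in% what) res$cpg <- spec@cpg
  if ("g4" %in% what) res$g4 <- spec@g4
  if ("rt" %in% what) res$rt <- .rtTrack(spec)
  if ("atac" %in% what) res$atac <- .atacReads(spec)
  if ("genome" %in% what) res$genome <- .genomeSequence(spec)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    if (!is.null(res$genes)) writeIntervals(res$genes, fp("genes.bed"), "BED6")
    if (!is.null(res$expression)) writeTSV(res$expression, fp("expression.tsv"))
    if (!is.null(res$cpg)) writeIntervals(res$cpg, fp("cpg.bed"), "BED3")
    if (!is.null(res$g4)) writeIntervals(res$g4, fp("g4.bed"), "BED6")
    if (!is.null(res$rt)) writeIntervals(res$rt, fp("rt.bedgraph"), "bedGraph")
    if (!is.null(res$atac)) writeIntervals(res$atac, fp("atac.bed"), "BED6")
    if (!is.null(res$genome))
      Biostrings::writeXStringSet(res$genome, fp("genome.fa"))
  }
  res
}

.rtTrack <- function(spec) {
  p <- spec@params
  oriChrom <- as.character(GenomicRanges::seqnames(spec@origins))
  out <- list()
  for (cn in names(spec@chromLengths)) {
    len <- spec@chromLengths[[cn]]
    seg <- as.integer(p$rtSegment)
    nSeg <- as.integer(len %/% seg)
    if (nSeg == 0) next
    s0 <- (seq_len(nSeg) - 1L) * seg
    centers <- s0 + seg / 2
    val <- p$rtBaseline + rnorm(nSeg, 0, p$rtNoiseSd)
    oriPos <- mid0(spec@origins)[oriChrom == cn]
    if (length(oriPos)) {
      near <- vapply(centers, function(x) min(abs(oriPos - x)), 0)
      val <- val + ifelse(near <= p$rtBumpHalfwidth, p$rtAmplitude, 0)
    }
    out[[cn]] <- GenomicRanges::GRanges(
      cn, IRanges::IRanges(s0 + 1L, width = seg), score = round(val, 4))
  }
  suppressWarnings(do.call(c, unname(out)))
}

.atacReads <- function(spec) {
  p <- spec@params
  rl <- as.integer(p$atacReadLength)
  ori <- spec@origins
  hw <- S4Vectors::mcols(ori)$halfwidth
  oriChrom <- as.character(GenomicRanges::seqnames(ori))
  pos <- mid0(ori)
  out <- list()
  for (cn in names(spec@chromLengths)) {
    len <- spec@chromLengths[[cn]]
    nBg <- rpois(1, p$atacDensity * len)
    s0 <- floor(runif(nBg, 0, len - rl))
    ## extra reads inside origin peak regions bring density to atacFold x
    sel <- which(oriChrom == cn)
    if (length(sel)) {
      w <- 2 * hw[sel]
      nEx <- rpois(length(sel), (p$atacFold - 1) * p$atacDensity * w)
      oriIdx <- rep(sel, nEx)
      if (length(oriIdx)) {
        e0 <- floor(runif(length(oriIdx), pos[oriIdx] - hw[oriIdx],
                          pos[oriIdx] + hw[oriIdx] - rl))
        s0 <- c(s0, e0)
      }
    }
    if (length(s0))
      out[[cn]] <- GenomicRanges::GRanges(
        cn, IRanges::IRanges(sort(s0) + 1L, width = rl), strand = "*")
  }
  suppressWarnings(do.call(c, unname(out)))
}

.genomeSequence <- function(spec) {
  p <- spec@params
  hiGC <- GenomicRanges::reduce(c(
    GenomicRanges::resize(GenomicRanges::granges(spec@origins),
                          width = 2 * spec@params$snsHalfwidth, fix = "center"),
    GenomicRanges::granges(spec@cpg)))
  seqs <- character(length(spec@chromLengths))
  for (k in seq_along(spec@chromLengths)) {
    cn <- names(spec@chromLengths)[k]
    len <- spec@chromLengths[[k]]
    pGC <- rep(p$gcBackground, len)
    hi <- hiGC[as.character(GenomicRanges::seqnames(hiGC)) == cn]
    if (length(hi)) {
      st <- pmax(1L, GenomicRanges::start(hi))
      en <- pmin(len, GenomicRanges::end(hi))
      for (j in seq_along(hi)) pGC[st[j]:en[j]] <- p$gcOrigin
    }
    isGC <- runif(len) < pGC
    second <- runif(len) < 0.5
    base <- ifelse(isGC, ifelse(second, "G", "C"), ifelse(second, "A", "T"))
    seqs[k] <- paste(base, collapse = "")
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(spec@chromLengths)
  dss
}

#' Simulate a complete synthetic study and optionally write all files
#'
#' Runs [simulateSSDS()], [simulateOKSeq()] and [emitTracks()] and, when
#' `outdir` is given, writes ssds_reads.bed, peaks.bed, truth.tsv,
#' okseq.bed plus every feature track.
#'
#' @inheritParams simulateSSDS
#' @param outdir optional output directory
#' @param tracks which feature tracks to emit (see [emitTracks()])
#' @return named list of all simulated objects
#' @export
simulateStudy <- function(spec, outdir = NULL,
                          tracks = c("genes", "expression", "cpg", "g4",
                                     "rt", "atac", "genome")) {
  ssds <- simulateSSDS(spec)
  ok <- simulateOKSeq(spec)
  feat <- emitTracks(spec, outdir = outdir, what = tracks)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeIntervals(ssds$reads, file.path(outdir, "ssds_reads.bed"), "BED6")
    writeIntervals(ssds$peaks, file.path(outdir, "peaks.bed"), "BED6")
    writeTSV(ssds$truth, file.path(outdir, "truth.tsv"))
    writeIntervals(ok, file.path(outdir, "okseq.bed"), "BED6")
  }
  c(list(spec = spec, reads = ssds$reads, peaks = ssds$peaks,
         truth = ssds$truth, okseq = ok), feat)
}
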