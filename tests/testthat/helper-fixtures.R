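## Shared fixture builders: everything is generated in code at test time.

## GRanges from 0-based half-open coordinates (the BED convention used in
## all spec'd examples).
gr0 <- function(chrom, start0, end0, strand = "*", ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, ...)
}

## A fixed-length read whose 0-based midpoint is `mid`.
readAt <- function(chrom, mid, strand, len = 100L) {
  gr0(chrom, mid - len %/% 2L, mid - len %/% 2L + len, strand)
}

## n reads with given midpoints/strands on one chromosome.
readsAt <- function(chrom, mids, strands, len = 100L) {
  do.call(c, mapply(readAt, mid = mids, strand = strands,
                    MoreArgs = list(chrom = chrom, len = len),
                    SIMPLIFY = FALSE))
}

## Brute-force all-pairs overlap oracle (>= minOverlap shared bases,
## 0-based half-open arithmetic, strand-blind).
bruteOverlapFlags <- function(A, B, minOverlap = 1L) {
  aC <- as.character(GenomicRanges::seqnames(A))
  bC <- as.character(GenomicRanges::seqnames(B))
  aS <- GenomicRanges::start(A) - 1L; aE <- GenomicRanges::end(A)
  bS <- GenomicRanges::start(B) - 1L; bE <- GenomicRanges::end(B)
  vapply(seq_along(A), function(i) {
    any(bC == aC[i] & pmin(aE[i], bE) - pmax(aS[i], bS) >= minOverlap)
  }, logical(1))
}

## Random interval set for property tests.
randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 1e5,
                            maxLen = 500) {
  s0 <- floor(runif(n, 0, maxPos - maxLen))
  gr0(sample(chroms, n, replace = TRUE), s0,
      s0 + ceiling(runif(n, 1, maxLen)),
      sample(c("+", "-"), n, replace = TRUE))
}

## Swap Watson and Crick on every record.
swapStrands <- function(gr) {
  sd <- as.character(GenomicRanges::strand(gr))
  sd[sd == "+"] <- "x"; sd[sd == "-"] <- "+"; sd[sd == "x"] <- "-"
  GenomicRanges::strand(gr) <- sd
  gr
}

## Tiny noise-free oracle study: planted classes perfectly recoverable.
oracleSpec <- function(seed = 42L, ...) {
  buildSyntheticSpec(
    utils::modifyList(list(strandSwapNoise = 0, backgroundRate = 0,
                           barrierStrength = 1), list(...)),
    seed = seed)
}
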