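## Epigenomic association: expression (RPKM filter), chromatin
## accessibility (ATAC read counts), replication timing at peak midpoints,
## and transcription-direction association for unidirectional origins.

#' Compute RPKM and flag expressed genes
#'
#' `RPKM = CPM / (length / 1000)`; a gene is expressed iff `RPKM > 5`
#' (strict). Non-positive lengths are an error.
#'
#' @param expr data.frame with columns gene_id, cpm, length, strand
#' @param threshold RPKM threshold (default 5, strict inequality)
#' @return `expr` with added `rpkm` and `expressed` columns
#' @export
rpkmFilter <- function(expr, threshold = 5) {
  stopifnot(all(c("gene_id", "cpm", "length") %in% names(expr)))
  if (any(expr$length <= 0)) stop("non-positive gene length")
  if (any(expr$cpm < 0)) stop("negative CPM")
  expr$rpkm <- expr$cpm / (expr$length / 1000)
  expr$expressed <- expr$rpkm > threshold
  expr
}

#' Expressed-gene intervals for a classified study
#'
#' Joins an expression table to gene intervals by gene_id and keeps the
#' expressed ones.
#'
#' @param genes GRanges with a `gene_id` mcol
#' @param expr output of [rpkmFilter()]
#' @return GRanges subset of expressed genes
#' @export
expressedGenes <- function(genes, expr) {
  hit <- match(S4Vectors::mcols(genes)$gene_id, expr$gene_id)
  if (any(is.na(hit)))
    stop("gene(s) missing from the expression table")
  genes[expr$expressed[hit]]
}

#' Per-class overlap with expressed genes vs matched controls
#'
#' Overlap by >= 1 base; per-class 2x2 chi-squared against the class's
#' matched controls. Zero margins are reported as NA.
#'
#' @param classification an [OriClassification-class]
#' @param expressed GRanges of expressed genes
#' @param controls GRanges with a `class` mcol ([matchedControls()])
#' @return data.frame, one row per class
#' @export
expressedOverlap <- function(classification, expressed, controls) {
  classEnrichment(classification, expressed, controls,
                  feature = "expressed_gene", test = "chi-squared")
}

#' ATAC read-count distributions per class vs matched controls
#'
#' A read counts toward a region iff the read midpoint lies inside it.
#' Welch two-tailed t-test per class against the class's matched controls;
#' classes with fewer than 2 peaks are reported NA.
#'
#' @param classification an [OriClassification-class]
#' @param atac GRanges of ATAC reads (positions or intervals)
#' @param controls GRanges with a `class` mcol
#' @return list: `counts` (per-peak read counts, with class), `tests`
#'   (data.frame: class, mean_obs, mean_ctrl, t, p_value)
#' @export
atacDistribution <- function(classification, atac, controls) {
  peaks <- classification@peaks
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  countIn <- function(regions) {
    GenomicRanges::countOverlaps(GenomicRanges::granges(regions),
                                 midpointRanges(atac),
                                 ignore.strand = TRUE)
  }
  obs <- countIn(peaks)
  ctl <- countIn(controls)
  ctrlCls <- as.character(S4Vectors::mcols(controls)$class)
  rows <- list()
  for (cl in intersect(c("ORI", "CO", "WO", "OTHER"), unique(cls))) {
    x <- obs[cls == cl]; y <- ctl[ctrlCls == cl]
    if (length(x) < 2 || length(y) < 2) {
      stat <- NA_real_; pv <- NA_real_
    } else if (stats::var(x) == 0 && stats::var(y) == 0) {
      ## degenerate: constant counts on both sides
      stat <- if (mean(x) == mean(y)) 0 else NA_real_
      pv <- if (mean(x) == mean(y)) 1 else NA_real_
    } else {
      tt <- stats::t.test(x, y, alternative = "two.sided")
      stat <- unname(tt$statistic); pv <- tt$p.value
    }
    rows[[cl]] <- data.frame(class = cl, n_peaks = length(x),
                             mean_obs = mean(x), mean_ctrl = mean(y),
                             t = stat, p_value = pv,
                             stringsAsFactors = FALSE)
  }
  list(counts = data.frame(class = cls, count = obs,
                           stringsAsFactors = FALSE),
       tests = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Replication timing at peak midpoints vs the genome background
#'
#' RT is assigned to each peak's midpoint from the covering track segment;
#' uncovered midpoints are dropped (their number is reported). The genome
#' background is the track's segment values weighted by segment length.
#' Two-sample KS tests compare each class with the genome and ORI with CO
#' and WO.
#'
#' @param classification an [OriClassification-class]
#' @param rt GRanges signal track with a numeric `score` (higher = earlier
#'   by the input's convention)
#' @return list: `values` (class, rt per retained peak), `background`
#'   (numeric), `tests` (data.frame: comparison, D, p_value), `nDropped`
#' @export
rtDistribution <- function(classification, rt) {
  peaks <- classification@peaks
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  pts <- midpointRanges(peaks)
  ov <- GenomicRanges::findOverlaps(pts, rt, ignore.strand = TRUE,
                                    select = "first")
  covered <- !is.na(ov)
  nDropped <- sum(!covered)
  if (nDropped > 0)
    warning(nDropped, " peak midpoint(s) not covered by the RT track")
  vals <- S4Vectors::mcols(rt)$score[ov[covered]]
  vcls <- cls[covered]

  ## length-weighted genome background: replicate each segment value in
  ## proportion to its width (unit = the smallest segment width)
  w <- GenomicRanges::width(rt)
  unit <- min(w)
  bg <- rep(S4Vectors::mcols(rt)$score, pmax(1L, as.integer(round(w / unit))))

  ks <- function(x, y) {
    if (length(x) < 2 || length(y) < 2)
      return(c(D = NA_real_, p = NA_real_))
    ht <- suppressWarnings(stats::ks.test(x, y))
    c(D = unname(ht$statistic), p = ht$p.value)
  }
  rows <- list()
  for (cl in intersect(c("ORI", "CO", "WO", "OTHER"), unique(vcls))) {
    r <- ks(vals[vcls == cl], bg)
    rows[[paste0(cl, "_vs_genome")]] <-
      data.frame(comparison = paste0(cl, "_vs_genome"),
                 D = r["D"], p_value = r["p"], stringsAsFactors = FALSE)
  }
  for (cl in intersect(c("CO", "WO"), unique(vcls))) {
    if (!"ORI" %in% vcls) break
    r <- ks(vals[vcls == "ORI"], vals[vcls == cl])
    rows[[paste0("ORI_vs_", cl)]] <-
      data.frame(comparison = paste0("ORI_vs_", cl),
                 D = r["D"], p_value = r["p"], stringsAsFactors = FALSE)
  }
  list(values = data.frame(class = vcls, rt = vals,
                           stringsAsFactors = FALSE),
       background = bg,
       tests = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       nDropped = nDropped)
}

#' Transcription-direction association for unidirectional origins
#'
#' For each CO/WO peak overlapping exactly one expressed gene, records the
#' gene's strand; peaks overlapping zero or >= 2 expressed genes are
#' excluded (and counted). Returns the CO/WO x gene-strand 2x2 table with
#' a chi-squared test. This single-overlapping-gene reading of the
#' transcription-direction analysis is one defensible contract and is
#' labelled as such in pipeline output.
#'
#' @param classification an [OriClassification-class]
#' @param expressed stranded GRanges of expressed genes
#' @return list: `table` (2x2 class x gene strand), `statistic`,
#'   `p_value`, `nExcluded`
#' @export
oppositeStrandTranscription <- function(classification, expressed) {
  stopIfUnstranded(expressed, "gene")
  peaks <- classification@peaks
  cls <- as.character(S4Vectors::mcols(peaks)$class)
  uni <- which(cls %in% c("CO", "WO"))
  nHits <- GenomicRanges::countOverlaps(
    GenomicRanges::granges(peaks[uni]), GenomicRanges::granges(expressed),
    ignore.strand = TRUE)
  one <- uni[nHits == 1]
  ov <- GenomicRanges::findOverlaps(GenomicRanges::granges(peaks[one]),
                                    GenomicRanges::granges(expressed),
                                    ignore.strand = TRUE)
  geneStrand <- strandChr(expressed)[S4Vectors::subjectHits(ov)]
  tab <- table(class = factor(cls[one][S4Vectors::queryHits(ov)],
                              levels = c("CO", "WO")),
               gene_strand = factor(geneStrand, levels = c("+", "-")))
  ht <- if (all(margin.table(tab, 1) > 0) && all(margin.table(tab, 2) > 0))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  else list(statistic = NA_real_, p.value = NA_real_)
  list(table = as.matrix(tab), statistic = unname(ht$statistic),
       p_value = ht$p.value, nExcluded = length(uni) - length(one))
}
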