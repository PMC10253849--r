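## Plain-text genomic formats. BED is 0-based half-open; GRanges objects
## returned/accepted here are 1-based closed per the Bioconductor
## convention, converted at this boundary and nowhere else.

.skipLine <- function(x) {
  grepl("^(#|track\\b|browser\\b)", x) | !nzchar(trimws(x))
}

#' Read genomic intervals from BED3 / BED6 / bedGraph text
#'
#' Track, browser and comment lines are tolerated. BED3 records get
#' unstranded (`*`) strand; BED "." maps to `*`. bedGraph returns a signal
#' track: a GRanges with a numeric `score` column, validated to be sorted
#' and non-overlapping within each chromosome.
#'
#' @param path file path
#' @param format one of `"auto"`, `"BED3"`, `"BED6"`, `"bedGraph"`;
#'   `"auto"` picks by column count (3 -> BED3, 4 -> bedGraph, >=6 -> BED6)
#' @return GRanges; BED6 carries `name` and `score` mcols, bedGraph `score`
#' @export
readIntervals <- function(path, format = c("auto", "BED3", "BED6", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !.skipLine(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    gr <- GenomicRanges::GRanges()
    if (format %in% c("BED6", "auto"))
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = character(0),
                                                   score = numeric(0))
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (format == "auto") {
    format <- if (ncols[1] >= 6) "BED6"
              else if (ncols[1] == 4) "bedGraph"
              else "BED3"
  }
  need <- c(BED3 = 3L, BED6 = 6L, bedGraph = 4L)[[format]]
  bad <- which(ncols < need)
  if (length(bad))
    stop(sprintf("line %d: expected >= %d tab-separated fields for %s, got %d",
                 idx[bad[1]], need, format, ncols[bad[1]]))
  getCol <- function(j) vapply(fields, `[[`, "", j)
  chrom <- getCol(1)
  start0 <- suppressWarnings(as.numeric(getCol(2)))
  end0 <- suppressWarnings(as.numeric(getCol(3)))
  bad <- which(is.na(start0) | is.na(end0) | !nzchar(chrom))
  if (length(bad))
    stop(sprintf("line %d: malformed coordinates", idx[bad[1]]))
  bad <- which(start0 < 0 | end0 <= start0)
  if (length(bad))
    stop(sprintf("line %d: invalid interval [%s, %s) (need 0 <= start < end)",
                 idx[bad[1]], getCol(2)[bad[1]], getCol(3)[bad[1]]))
  if (format == "bedGraph") {
    value <- suppressWarnings(as.numeric(getCol(4)))
    bad <- which(is.na(value))
    if (length(bad))
      stop(sprintf("line %d: non-numeric bedGraph value", idx[bad[1]]))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                                 score = value)
    .validateSignalTrack(gr)
    return(gr)
  }
  if (format == "BED6") {
    strand <- getCol(6)
    bad <- which(!strand %in% c("+", "-", "."))
    if (length(bad))
      stop(sprintf("line %d: unknown strand symbol '%s'",
                   idx[bad[1]], strand[bad[1]]))
    strand[strand == "."] <- "*"
    score <- suppressWarnings(as.numeric(getCol(5)))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                                 strand = strand,
                                 name = getCol(4), score = score)
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  }
  gr
}

.validateSignalTrack <- function(gr) {
  sp <- split(gr, GenomicRanges::seqnames(gr))
  for (s in sp) {
    if (length(s) < 2) next
    st <- GenomicRanges::start(s); en <- GenomicRanges::end(s)
    o <- order(st)
    if (any(en[o][-length(s)] >= st[o][-1]))
      stop("signal track intervals overlap within a chromosome")
  }
  invisible(gr)
}

#' Write genomic intervals as BED3 / BED6 / bedGraph text
#'
#' Inverse of [readIntervals()]: reading a written file reproduces the
#' records field-for-field. Unstranded (`*`) is written as BED ".".
#'
#' @param gr GRanges (for bedGraph, with a numeric `score` column)
#' @param path output file path
#' @param format `"BED3"`, `"BED6"` or `"bedGraph"`
#' @return `path`, invisibly
#' @export
writeIntervals <- function(gr, path, format = c("BED6", "BED3", "bedGraph")) {
  format <- match.arg(format)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  mc <- S4Vectors::mcols(gr)
  lines <- switch(format,
    BED3 = if (length(gr)) paste(chrom, start0, end0, sep = "\t")
           else character(0),
    bedGraph = {
      if (length(gr) && is.null(mc$score))
        stop("bedGraph output requires a 'score' column")
      if (length(gr))
        paste(chrom, start0, end0,
              format(mc$score, trim = TRUE, scientific = FALSE, digits = 15),
              sep = "\t")
      else character(0)
    },
    BED6 = {
      nm <- if (!is.null(mc$name)) as.character(mc$name)
            else rep(".", length(gr))
      sc <- if (!is.null(mc$score)) {
        ifelse(is.na(mc$score), "0",
               format(mc$score, trim = TRUE, scientific = FALSE, digits = 15))
      } else rep("0", length(gr))
      sd <- strandChr(gr)
      sd[sd == "*"] <- "."
      if (length(gr)) paste(chrom, start0, end0, nm, sc, sd, sep = "\t")
      else character(0)
    })
  con <- file(path, open = "wb")  # fixed EOLs for byte-identical reruns
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Sequences are upper-cased; duplicate record names and empty files are
#' errors. Record names are truncated at the first whitespace.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] with per-chromosome lengths
#'   available via `Biostrings::width()`
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name: ",
         names(seqs)[duplicated(names(seqs))][1])
  ## DNAStringSet preserves case flags; force uppercase via character round trip
  up <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(up) <- names(seqs)
  up
}

#' Read a gene expression table (TSV: gene_id, cpm, length, strand)
#'
#' @param path TSV with a header line
#' @return data.frame with columns gene_id, cpm, length, strand
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "cpm", "length", "strand")
  if (!all(need %in% names(df)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  df
}

## Deterministic TSV writer shared by all report stages.
writeTSV <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
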