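## One-command orchestration: simulate (or load) -> classify -> RFD ->
## enrichment -> G4 -> epigenome, with a consolidated report, a plain-text
## run log, and byte-identical reruns under a fixed config + seed.

#' Default pipeline configuration
#'
#' Thresholds carry the method's standard constants: classification cut
#' 0.5, expressed RPKM > 5, G4 flank 1000 bp (2 kb window), OK-seq bin
#' 1000 bp, 40 meta-profile windows of 50 kb, promoter TSS window 1000 bp,
#' minimum overlap 1 base.
#'
#' @return named list; `simulate` entries override [syntheticDefaults()],
#'   `inputs` entries give file paths when `mode = "files"`
#' @export
pipelineDefaults <- function() {
  list(mode = "simulate",            # "simulate" or "files"
       seed = 1L,
       orientation = "figure1b",
       simulate = list(),            # overrides for syntheticDefaults()
       inputs = list(),              # paths: peaks, ssds_reads, okseq, genes,
                                     # expression, cpg, g4, rt, atac, genome
       chromLengths = NULL,          # required in files mode
       binSize = 1000L, nWindows = 40L, windowSize = 50000L,
       metaControlSets = 1L,
       tssWindow = 1000L, flank = 1000L, minOverlap = 1L,
       rpkmThreshold = 5, controlsPerSet = 1L,
       writeGenome = TRUE)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path YAML file with keys from [pipelineDefaults()]
#' @return config list merged over the defaults
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  mergeConfig(cfg)
}

mergeConfig <- function(config) {
  def <- pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  def[names(config)] <- config
  def
}

#' Run the full origin-direction analysis pipeline
#'
#' Executes every stage in dependency order, writes all intermediate files
#' and report tables into `outdir`, and returns the consolidated report.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config list (merged over [pipelineDefaults()]) or path to a YAML
#'   config file
#' @param outdir output directory (created if needed)
#' @return invisible list (the run report): classification, proportions,
#'   metaProfile, enrichment, g4, epigenome, config echo, version
#' @export
runPipeline <- function(config = list(), outdir) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else mergeConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  note <- function(fmt, ...) {
    logLines[[length(logLines) + 1L]] <<- sprintf(fmt, ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ## ---- stage: inputs -----------------------------------------------------
  if (cfg$mode == "simulate") {
    spec <- stage("simulate", buildSyntheticSpec(cfg$simulate,
                                                 seed = cfg$seed))
    tracks <- c("genes", "expression", "cpg", "g4", "rt", "atac",
                if (isTRUE(cfg$writeGenome)) "genome")
    sim <- stage("simulate", simulateStudy(spec, outdir = outdir,
                                           tracks = tracks))
    dat <- sim
    chromLengths <- spec@chromLengths
    note("simulate: %d origins, %d SNS reads, %d OK-seq reads",
         length(spec@origins), length(dat$reads), length(dat$okseq))
  } else {
    inp <- cfg$inputs
    req <- function(nm, what) {
      if (is.null(inp[[nm]]))
        stop(sprintf("pipeline stage '%s' aborted: input '%s' missing",
                     what, nm), call. = FALSE)
      inp[[nm]]
    }
    dat <- list()
    dat$peaks <- stage("classify",
                       readIntervals(req("peaks", "classify"), "auto"))
    dat$reads <- stage("classify",
                       readIntervals(req("ssds_reads", "classify"), "BED6"))
    dat$okseq <- stage("rfd", readIntervals(req("okseq", "rfd"), "BED6"))
    dat$genes <- stage("enrichment",
                       readIntervals(req("genes", "enrichment"), "BED6"))
    dat$expression <- stage("epigenome",
                            readExpressionTable(req("expression",
                                                    "epigenome")))
    dat$cpg <- stage("enrichment",
                     readIntervals(req("cpg", "enrichment"), "auto"))
    dat$g4 <- stage("g4", readIntervals(req("g4", "g4"), "BED6"))
    dat$rt <- stage("rt", readIntervals(req("rt", "rt"), "bedGraph"))
    dat$atac <- stage("epigenome",
                      readIntervals(req("atac", "epigenome"), "auto"))
    if (!is.null(inp$genome))
      dat$genome <- stage("enrichment", readGenome(inp$genome))
    if (is.null(cfg$chromLengths))
      stop("pipeline stage 'rfd' aborted: chromLengths required in files mode",
           call. = FALSE)
    chromLengths <- unlist(cfg$chromLengths)
    note("inputs: %d peaks, %d SNS reads, %d OK-seq reads read from files",
         length(dat$peaks), length(dat$reads), length(dat$okseq))
  }

  ## ---- stage: classify ---------------------------------------------------
  cl <- stage("classify",
              classifyAll(dat$peaks, dat$reads, orientation = cfg$orientation))
  writeTSV(profileTable(cl), file.path(outdir, "classes.tsv"))
  nUn <- sum(peakClasses(cl) == "UNASSIGNED")
  note("classify: %d peaks in, %d UNASSIGNED", length(dat$peaks), nUn)

  ## ---- stage: rfd --------------------------------------------------------
  track <- stage("rfd", computeRFD(binStrandCounts(dat$okseq, chromLengths,
                                                   cfg$binSize)))
  writeRFD(track, file.path(outdir, "rfd.bedgraph"))
  prof <- stage("rfd", metaProfile(track, cl, nWindows = cfg$nWindows,
                                   windowSize = cfg$windowSize,
                                   controlSets = cfg$metaControlSets,
                                   seed = cfg$seed + 11L))
  writeTSV(metaProfileTable(prof), file.path(outdir, "profile.tsv"))
  note("rfd: %d bins, meta-profile over %d anchors + random control",
       length(binCounts(track)), sum(peakClasses(cl) != "UNASSIGNED"))

  ## ---- stage: controls + enrichment --------------------------------------
  controls <- stage("enrichment",
                    matchedControls(cl, chromLengths, seed = cfg$seed + 22L,
                                    setsPerClass = cfg$controlsPerSet))
  enrich <- list()
  enrich$promoter <- stage("enrichment", classEnrichment(
    cl, promoterWindows(dat$genes, cfg$tssWindow), controls, "promoter",
    minOverlap = cfg$minOverlap))
  enrich$gene <- stage("enrichment", classEnrichment(
    cl, dat$genes, controls, "gene", minOverlap = cfg$minOverlap))
  enrich$cpg <- stage("enrichment", classEnrichment(
    cl, dat$cpg, controls, "cpg_island", minOverlap = cfg$minOverlap))
  enrich$g4 <- stage("enrichment", classEnrichment(
    cl, dat$g4, controls, "g4_any_strand", minOverlap = cfg$minOverlap))
  enrichTab <- do.call(rbind, c(unname(enrich), list(make.row.names = FALSE)))
  anno <- stage("enrichment", annotatePeaks(cl@peaks, dat$genes,
                                            cfg$tssWindow))
  annoTab <- as.data.frame.matrix(
    100 * prop.table(table(peakClasses(cl), anno), margin = 1))
  annoTab <- cbind(class = rownames(annoTab), annoTab)
  rownames(annoTab) <- NULL
  writeTSV(enrichTab, file.path(outdir, "enrichment.tsv"))
  writeTSV(annoTab, file.path(outdir, "annotation.tsv"))
  if (!is.null(dat$genome)) {
    gcObs <- gcContent(cl@peaks, dat$genome)
    gcCtl <- gcContent(controls, dat$genome)
    note("enrichment: mean peak GC %.3f vs control %.3f",
         mean(gcObs, na.rm = TRUE), mean(gcCtl, na.rm = TRUE))
  }
  note("enrichment: %d feature sets vs %d matched controls",
       length(enrich), length(controls))

  ## ---- stage: g4 ---------------------------------------------------------
  excl <- stage("g4", g4ExclusiveCall(cl, dat$g4))
  biasIn <- excl$byClass[excl$byClass$class %in% c("ORI", "CO", "WO"), ]
  biasIn <- data.frame(class = biasIn$class, watson = biasIn$watson_only,
                       crick = biasIn$crick_only)
  g4bias <- stage("g4", strandBiasTest(biasIn))
  flanks <- stage("g4", g4FlankCounts(cl, dat$g4, flank = cfg$flank))
  flankCtrl <- stage("g4", g4FlankCounts(controls, dat$g4,
                                         flank = cfg$flank))
  oriPk <- cl@peaks[peakClasses(cl) == "ORI"]
  leadlag <- if (length(oriPk))
    stage("g4", leadingLaggingSplit(oriPk, dat$g4, flank = cfg$flank))
  else NULL
  g4Tab <- merge(excl$byClass, flanks, by = "class")
  writeTSV(g4Tab, file.path(outdir, "g4_report.tsv"))
  note("g4: %d peaks excluded as both-strand, %d exclusive calls",
       sum(excl$calls == "both"),
       sum(excl$calls %in% c("G4_Watson_only", "G4_Crick_only")))

  ## ---- stage: epigenome --------------------------------------------------
  expr <- stage("epigenome", rpkmFilter(dat$expression,
                                        threshold = cfg$rpkmThreshold))
  exprG <- stage("epigenome", expressedGenes(dat$genes, expr))
  eo <- stage("epigenome", expressedOverlap(cl, exprG, controls))
  at <- stage("epigenome", atacDistribution(cl, dat$atac, controls))
  rtRes <- stage("epigenome", suppressWarnings(rtDistribution(cl, dat$rt)))
  ost <- stage("epigenome", oppositeStrandTranscription(cl, exprG))
  epiTab <- rbind(
    data.frame(analysis = "expressed_overlap", class = eo$class,
               statistic = eo$statistic, p_value = eo$p_value,
               stringsAsFactors = FALSE),
    data.frame(analysis = "atac_ttest", class = at$tests$class,
               statistic = at$tests$t, p_value = at$tests$p_value,
               stringsAsFactors = FALSE),
    data.frame(analysis = "rt_ks", class = rtRes$tests$comparison,
               statistic = rtRes$tests$D, p_value = rtRes$tests$p_value,
               stringsAsFactors = FALSE),
    data.frame(analysis = "opposite_strand_txn_single_gene_reading",
               class = "CO_vs_WO", statistic = ost$statistic,
               p_value = ost$p_value, stringsAsFactors = FALSE))
  writeTSV(epiTab, file.path(outdir, "epigenome_report.tsv"))
  note("epigenome: %d expressed genes; %d peaks dropped for uncovered RT",
       length(exprG), rtRes$nDropped)

  ## ---- report ------------------------------------------------------------
  report <- list(version = as.character(utils::packageVersion("oriSSDS")),
                 config = cfg,
                 proportions = classProportions(cl),
                 classification = cl, metaProfile = prof,
                 enrichment = enrichTab, annotation = annoTab,
                 g4 = list(exclusive = excl$byClass, bias = g4bias,
                           flanks = flanks, flanksControl = flankCtrl,
                           leadingLagging = leadlag),
                 epigenome = list(expressed = eo, atac = at$tests,
                                  rt = rtRes$tests,
                                  oppositeStrand = ost))
  propTab <- data.frame(class = names(report$proportions),
                        fraction = round(unname(report$proportions), 6))
  writeTSV(propTab, file.path(outdir, "proportions.tsv"))
  con <- file(file.path(outdir, "run_log.txt"), open = "wb")
  writeLines(c(sprintf("oriSSDS %s run, seed %d", report$version,
                       as.integer(cfg$seed)), logLines), con, sep = "\n")
  close(con)
  invisible(report)
}
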