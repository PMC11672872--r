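#' @include annotation-io.R deg.R length-stats.R switching.R mechanisms.R
NULL

# tiny deterministic checksum of the analysis options (not of paths or data
# objects, so reruns elsewhere stamp the same hash), for output headers
configHash <- function(cfg) {
  key <- list(fcMin = cfg$fcMin, pMax = cfg$pMax, alpha = cfg$alpha,
              direction = cfg$direction, test = cfg$test, scale = cfg$scale,
              pairs = cfg$pairs, seed = cfg$seed)
  txt <- paste(deparse(key), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' Collects paths, thresholds and options for [runPipeline()]. Defaults match
#' the analysis conditions the pipeline is designed around: volcano filter at
#' FC >= 2.0 and p <= 0.05, downregulated transcripts, alpha 0.05, Welch
#' t-test on log10 lengths.
#'
#' @param annotation path to an annotation file or a
#'   [TranscriptModelSet-class].
#' @param degTables named list (condition -> TSV path, record data.frame or
#'   [ConditionList-class]).
#' @param outDir output directory.
#' @param genome optional FASTA path or [Biostrings::DNAStringSet] (enables
#'   splice-signal columns later).
#' @param fcMin,pMax volcano thresholds.
#' @param alpha significance level for length comparisons.
#' @param direction regulation direction analysed (default "down").
#' @param test,scale options of [compareLengths()].
#' @param pairs named list of condition pairs (earlier, later) to scan for
#'   isoform switching.
#' @param seed integer seed stamped into outputs.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(annotation, degTables, outDir,
                           genome = NULL, fcMin = 2.0, pMax = 0.05,
                           alpha = 0.05, direction = "down",
                           test = "welch", scale = "log10",
                           pairs = list(C10_C24 = c("C10", "C24"),
                                        T10_T24 = c("T10", "T24")),
                           seed = 1L) {
  cfg <- list(annotation = annotation, degTables = degTables,
              outDir = outDir, genome = genome, fcMin = fcMin, pMax = pMax,
              alpha = alpha, direction = direction, test = test,
              scale = scale, pairs = pairs, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Every key of [pipelineConfig()] can be given in the file; `deg_tables`
#' must map condition labels to TSV paths.
#'
#' @param path YAML file.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pairs <- if (!is.null(y$pairs)) lapply(y$pairs, unlist) else
    list(C10_C24 = c("C10", "C24"), T10_T24 = c("T10", "T24"))
  pipelineConfig(annotation = y$annotation, degTables = y$deg_tables,
                 outDir = y$out_dir, genome = y$genome,
                 fcMin = y$fc_min %||% 2.0, pMax = y$p_max %||% 0.05,
                 alpha = y$alpha %||% 0.05,
                 direction = y$direction %||% "down",
                 test = y$test %||% "welch", scale = y$scale %||% "log10",
                 pairs = pairs, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stamp <- function(path, tab, cfg) {
  con <- file(path, "w")
  writeLines(c(sprintf("# seed: %d", cfg$seed),
               sprintf("# config: %s", configHash(cfg))), con)
  suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full length-ome pipeline
#'
#' Executes, in order: volcano filtering of every condition table, region
#' lengths from the annotation, query-vs-reference length-distribution
#' comparisons per region and condition, exon-count spectra, isoform-switch
#' detection for each configured condition pair, per-pair switch tables and
#' mechanism classification, and a report written to the output directory.
#' Per-stage record counts are logged via `message()`; every output TSV
#' carries the seed and a config checksum in comment headers.
#'
#' The reference exome for length statistics is the set of all coding
#' transcripts in the annotation. Query transcripts that do not resolve in
#' the annotation are dropped from length statistics with a logged count
#' (switch *detection* uses the expression lists only, so unresolved
#' seqnames still switch; mechanism classification requires models).
#'
#' @param cfg a [pipelineConfig()] or path to a YAML config.
#' @return a result bundle: `lists`, `lengths`, `comparisons`, `spectra`,
#'   `switches`, `switchTables`, `mechanisms`, `apaCount` and `files`.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  models <- stage("annotation", {
    if (inherits(cfg$annotation, "TranscriptModelSet")) cfg$annotation
    else readAnnotation(cfg$annotation)
  })
  message("annotation: ", length(models), " transcript model(s)")

  lists <- stage("filter", {
    out <- list()
    for (cond in names(cfg$degTables)) {
      x <- cfg$degTables[[cond]]
      rec <- if (inherits(x, "ConditionList")) x@records
             else if (is.character(x)) readDegTable(x, cond)
             else x
      cl <- volcanoFilter(rec, cfg$fcMin, cfg$pMax, cfg$direction)
      cl@condition <- cond
      if (nrow(cl@records)) cl@records$condition <- cond
      methods::validObject(cl)
      message("filter ", cond, ": ", nrow(cl@records), " record(s) kept")
      out[[cond]] <- cl
    }
    out
  })

  rl <- stage("lengths", regionLengths(models))
  ref <- rl[rl$coding, , drop = FALSE]
  regionCols <- c(full = "len_full", utr5 = "len_5utr", cds = "len_cds",
                  utr3 = "len_3utr")

  comparisons <- stage("compare", {
    out <- list()
    for (cond in names(lists)) {
      seqs <- lists[[cond]]@records$seqname
      hit <- intersect(seqs, ref$transcript_id)
      if (length(seqs) > length(hit))
        message("compare ", cond, ": ", length(seqs) - length(hit),
                " seqname(s) not in annotation, dropped")
      if (length(hit) < 3) { message("compare ", cond, ": skipped (<3)"); next }
      q <- ref[match(hit, ref$transcript_id), ]
      for (rg in names(regionCols)) {
        res <- tryCatch(
          compareLengths(q[[regionCols[rg]]], ref[[regionCols[rg]]],
                         region = rg, alpha = cfg$alpha, test = cfg$test,
                         scale = cfg$scale),
          error = function(e) NULL)
        if (!is.null(res)) out[[paste(cond, rg, sep = "_")]] <- res
      }
    }
    out
  })

  spectra <- stage("spectra", {
    out <- list()
    for (cond in names(lists)) {
      seqs <- intersect(lists[[cond]]@records$seqname, names(models))
      if (length(seqs) < 3) next
      qGenes <- unique(vapply(seqs, function(s) geneSymbol(models[[s]]),
                              character(1)))
      qModels <- TranscriptModelSet(as.list(models)[
        vapply(models, function(m) geneSymbol(m) %in% qGenes, logical(1))])
      out[[cond]] <- exonCountSpectrum(qModels, models)
    }
    out
  })

  switches <- list(); switchTabs <- list(); mech <- list()
  for (pname in names(cfg$pairs)) {
    conds <- cfg$pairs[[pname]]
    if (!all(conds %in% names(lists))) next
    ev <- stage(paste0("switch:", pname),
                detectSwitches(lists[[conds[1]]], lists[[conds[2]]]))
    nsw <- sum(ev$switch_class != "no_switch")
    message("switch ", pname, ": ", nrow(ev), " shared gene(s), ",
            nsw, " switching")
    switches[[pname]] <- ev
    sw <- ev[ev$switch_class != "no_switch", , drop = FALSE]
    pairsTab <- switchPairs(sw)
    if (!is.null(pairsTab) && nrow(pairsTab)) {
      resolvable <- pairsTab$old_id %in% names(models) &
                    pairsTab$new_id %in% names(models)
      if (any(!resolvable))
        message("mechanisms ", pname, ": ",
                sum(!resolvable), " pair(s) without models, dropped")
      pairsTab <- pairsTab[resolvable, , drop = FALSE]
    }
    if (!is.null(pairsTab) && nrow(pairsTab)) {
      switchTabs[[pname]] <- stage(paste0("codes:", pname),
                                   switchTable(sw, rl))
      mech[[pname]] <- stage(paste0("mechanisms:", pname),
                             classifyMechanismPairs(pairsTab, models))
    }
  }
  apa <- countApaEvents(unlist(mech, recursive = FALSE))
  message("alternative-polyadenylation calls: ", apa)

  files <- stage("report", {
    f <- character()
    for (pname in names(switches)) {
      ev <- switches[[pname]]
      tab <- data.frame(gene_symbol = ev$gene_symbol,
                        isoforms_a = vapply(ev$isoforms_a, paste,
                                            character(1), collapse = ","),
                        isoforms_b = vapply(ev$isoforms_b, paste,
                                            character(1), collapse = ","),
                        switch_class = ev$switch_class,
                        stringsAsFactors = FALSE)
      f <- c(f, stamp(file.path(cfg$outDir, paste0("switches_", pname, ".tsv")),
                      tab, cfg))
      if (!is.null(mech[[pname]]))
        f <- c(f, stamp(file.path(cfg$outDir,
                                  paste0("mechanisms_", pname, ".tsv")),
                        mechanismTable(mech[[pname]]), cfg))
    }
    if (length(comparisons))
      f <- c(f, lengthomeReport(comparisons, spectra, cfg$outDir))
    else message("report: 0 comparisons, no length report written")
    f
  })

  list(lists = lists, lengths = rl, comparisons = comparisons,
       spectra = spectra, switches = switches, switchTables = switchTabs,
       mechanisms = mech, apaCount = apa, files = files, config = cfg)
}
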