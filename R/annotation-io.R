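#' @include transcript-models.R
NULL

# inverse of txToGenome: genomic position -> transcript coordinate
genomeToTx <- function(x, gpos) {
  widths <- x@exonEnds - x@exonStarts + 1L
  txends <- cumsum(widths)
  txstarts <- txends - widths + 1L
  vapply(as.integer(gpos), function(g) {
    i <- which(g >= x@exonStarts & g <= x@exonEnds)
    if (length(i) != 1L)
      stop("genomic position ", g, " not exonic in ", x@transcriptId)
    if (x@strand == "+") txstarts[i] + (g - x@exonStarts[i])
    else txstarts[i] + (x@exonEnds[i] - g)
  }, integer(1))
}

# genomic intervals covered by the CDS (tx span intersected with exons)
cdsGenomicRanges <- function(x) {
  if (!isCoding(x)) return(NULL)
  widths <- x@exonEnds - x@exonStarts + 1L
  txends <- cumsum(widths)
  txstarts <- txends - widths + 1L
  out <- NULL
  for (i in seq_along(widths)) {
    lo <- max(txstarts[i], x@cdsStartTx)
    hi <- min(txends[i], x@cdsEndTx)
    if (lo > hi) next
    g1 <- txToGenome(x, lo); g2 <- txToGenome(x, hi)
    out <- rbind(out, c(min(g1, g2), max(g1, g2)))
  }
  out
}

#' Read a transcript annotation
#'
#' Parses gene models from GTF, GFF3 or the package's tabular dialect into a
#' [TranscriptModelSet-class]. For GTF/GFF3, exon and CDS features are grouped
#' by transcript; the CDS genomic span is converted to transcript coordinates.
#' `stop_codon` features, when present, are appended to the CDS so that the
#' stored CDS always includes the stop codon (RefSeq convention).
#'
#' The tabular dialect is a TSV with columns `transcript_id`, `gene_symbol`,
#' `chrom`, `strand`, `exon_starts`, `exon_ends` (comma-joined, transcription
#' order, genomic start <= end per exon) and `cds_start_tx`, `cds_end_tx`
#' (transcript coordinates, `NA` for non-coding).
#'
#' @param path annotation file.
#' @param dialect "table", "gtf" or "gff3"; guessed from the file extension
#'   when missing.
#' @return a [TranscriptModelSet-class].
#' @seealso [writeAnnotationTable()], [writeAnnotationGtf()]
#' @export
readAnnotation <- function(path, dialect = c("table", "gtf", "gff3")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (missing(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3", "table")
  }
  dialect <- match.arg(dialect)
  switch(dialect,
         table = readAnnotationTable(path),
         gtf   = readAnnotationGxf(path, "gtf"),
         gff3  = readAnnotationGxf(path, "gff3"))
}

readAnnotationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("transcript_id", "gene_symbol", "chrom", "strand",
           "exon_starts", "exon_ends", "cds_start_tx", "cds_end_tx")
  if (!all(req %in% names(tab)))
    stop("tabular annotation must have columns: ", paste(req, collapse = ", "))
  models <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    s <- suppressWarnings(as.integer(strsplit(row$exon_starts, ",")[[1]]))
    e <- suppressWarnings(as.integer(strsplit(row$exon_ends, ",")[[1]]))
    if (any(is.na(s)) || any(is.na(e)))
      stop("malformed exon coordinates on line ", i + 1L, " of ", path)
    cs <- suppressWarnings(as.integer(row$cds_start_tx))
    ce <- suppressWarnings(as.integer(row$cds_end_tx))
    TranscriptModel(row$transcript_id, row$gene_symbol, row$chrom, row$strand,
                    s, e, cs, ce)
  })
  TranscriptModelSet(models)
}

readAnnotationGxf <- function(path, format) {
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  txid <- if (format == "gtf") {
    as.character(md$transcript_id)
  } else {
    p <- md$Parent
    vapply(seq_along(gr), function(i) {
      pp <- if (is.null(p)) character() else as.character(unlist(p[i]))
      if (length(pp)) pp[1] else as.character(md$ID[i])
    }, character(1))
  }
  gene <- if (format == "gtf") {
    g <- if (!is.null(md$gene_name)) as.character(md$gene_name)
         else as.character(md$gene_id)
    g
  } else NULL
  keep <- type %in% c("exon", "CDS", "stop_codon")
  if (!any(keep)) stop("no exon/CDS features found in ", path)
  gr <- gr[keep]; type <- type[keep]; txid <- txid[keep]
  if (!is.null(gene)) gene <- gene[keep]
  if (anyNA(txid)) stop("exon/CDS features without transcript attribute in ", path)
  # gene symbol per transcript for gff3: map transcript features' Parent
  geneOf <- if (format == "gff3") {
    full <- rtracklayer::import(path, format = format)
    fmd <- S4Vectors::mcols(full)
    ftype <- as.character(fmd$type)
    tsel <- ftype %in% c("mRNA", "transcript")
    ids <- as.character(fmd$ID[tsel])
    par <- vapply(which(tsel), function(i) {
      pp <- as.character(unlist(fmd$Parent[i]))
      if (length(pp)) sub("^gene[:-]?", "", pp[1]) else ids[match(i, which(tsel))]
    }, character(1))
    stats::setNames(par, ids)
  } else NULL

  models <- lapply(split(seq_along(gr), txid), function(idx) {
    sub <- gr[idx]; st <- type[idx]
    chrom <- as.character(GenomicRanges::seqnames(sub))[1]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    if (!strand %in% c("+", "-"))
      stop("missing strand for transcript ", txid[idx][1])
    ex <- sub[st == "exon"]
    ord <- order(GenomicRanges::start(ex), decreasing = (strand == "-"))
    ex <- ex[ord]
    gsym <- if (!is.null(gene)) gene[idx][1]
            else {
              g <- geneOf[txid[idx][1]]
              if (is.na(g) || is.null(g)) txid[idx][1] else unname(g)
            }
    m <- TranscriptModel(txid[idx][1], gsym, chrom, strand,
                         GenomicRanges::start(ex), GenomicRanges::end(ex))
    cds <- sub[st %in% c("CDS", "stop_codon")]
    if (length(cds)) {
      gp <- sort(c(GenomicRanges::start(cds), GenomicRanges::end(cds)))
      g5 <- if (strand == "+") gp[1] else gp[length(gp)]
      g3 <- if (strand == "+") gp[length(gp)] else gp[1]
      cs <- tryCatch(genomeToTx(m, g5), error = function(e)
        stop("CDS of transcript ", transcriptId(m),
             " is not contained in its exons"))
      width <- sum(GenomicRanges::width(cds))
      m@cdsStartTx <- cs
      m@cdsEndTx <- cs + as.integer(width) - 1L
      methods::validObject(m)
    }
    m
  })
  TranscriptModelSet(unname(models))
}

#' Write a TranscriptModelSet in the tabular dialect
#'
#' @param models a [TranscriptModelSet-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(transcript_id = m@transcriptId, gene_symbol = m@geneSymbol,
               chrom = m@chrom, strand = m@strand,
               exon_starts = paste(m@exonStarts, collapse = ","),
               exon_ends = paste(m@exonEnds, collapse = ","),
               cds_start_tx = m@cdsStartTx, cds_end_tx = m@cdsEndTx,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), gene_symbol = character(),
               chrom = character(), strand = character(),
               exon_starts = character(), exon_ends = character(),
               cds_start_tx = integer(), cds_end_tx = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a TranscriptModelSet as GTF
#'
#' Emits exon and CDS lines with `transcript_id`/`gene_id` attributes. The
#' CDS lines include the stop codon, matching the package's storage
#' convention, so a round trip through [readAnnotation()] is lossless.
#'
#' @param models a [TranscriptModelSet-class].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGtf <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in as.list(models)) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m@geneSymbol, m@transcriptId)
    for (i in seq_along(m@exonStarts))
      writeLines(paste(m@chrom, "lengthome", "exon", m@exonStarts[i],
                       m@exonEnds[i], ".", m@strand, ".", attrs, sep = "\t"),
                 con)
    cg <- cdsGenomicRanges(m)
    if (!is.null(cg))
      for (i in seq_len(nrow(cg)))
        writeLines(paste(m@chrom, "lengthome", "CDS", cg[i, 1], cg[i, 2],
                         ".", m@strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
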