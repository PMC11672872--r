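#' @include AllGenerics.R
NULL

#' @describeIn TranscriptModel transcript identifier.
#' @param x a TranscriptModel.
#' @aliases transcriptId
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)

#' @describeIn TranscriptModel gene symbol.
#' @aliases geneSymbol
#' @export
setMethod("geneSymbol", "TranscriptModel", function(x) x@geneSymbol)

#' @describeIn TranscriptModel exon chain as a [GenomicRanges::GRanges], in
#'   transcription order.
#' @aliases exons
#' @export
setMethod("exons", "TranscriptModel", function(x) {
  GenomicRanges::GRanges(
    seqnames = x@chrom,
    ranges = IRanges::IRanges(start = pmin(x@exonStarts, x@exonEnds),
                              end = pmax(x@exonStarts, x@exonEnds)),
    strand = x@strand)
})

#' @describeIn TranscriptModel TRUE if a CDS is annotated.
#' @aliases isCoding
#' @export
setMethod("isCoding", "TranscriptModel", function(x) !is.na(x@cdsStartTx))

#' @describeIn TranscriptModel length of the spliced mRNA in nt.
#' @aliases splicedLength
#' @export
setMethod("splicedLength", "TranscriptModel", function(x)
  sum(x@exonEnds - x@exonStarts + 1L))

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (isCoding(object))
    sprintf("CDS %d-%d (tx)", object@cdsStartTx, object@cdsEndTx)
  else "non-coding"
  cat(sprintf("TranscriptModel %s (%s) %s:%s, %d exon(s), %d nt spliced, %s\n",
              object@transcriptId, object@geneSymbol, object@chrom,
              object@strand, length(object@exonStarts),
              splicedLength(object), cds))
})

setMethod("show", "TranscriptModelSet", function(object) {
  nc <- sum(vapply(object, isCoding, logical(1)))
  cat(sprintf("TranscriptModelSet with %d transcript(s) (%d coding) from %d gene(s)\n",
              length(object), nc,
              length(unique(vapply(object, geneSymbol, character(1))))))
})

regionLengthsOne <- function(x) {
  L <- splicedLength(x)
  coding <- isCoding(x)
  if (coding) {
    l5 <- x@cdsStartTx - 1L
    lc <- x@cdsEndTx - x@cdsStartTx + 1L
    l3 <- L - x@cdsEndTx
  } else {
    l5 <- lc <- l3 <- 0L
  }
  data.frame(transcript_id = x@transcriptId, gene_symbol = x@geneSymbol,
             len_full = L, len_5utr = l5, len_cds = lc, len_3utr = l3,
             n_exons = length(x@exonStarts), coding = coding,
             stringsAsFactors = FALSE)
}

#' @rdname regionLengths
#' @export
setMethod("regionLengths", "TranscriptModel", regionLengthsOne)

#' @rdname regionLengths
#' @export
setMethod("regionLengths", "TranscriptModelSet", function(x) {
  if (length(x) == 0L)
    return(data.frame(transcript_id = character(), gene_symbol = character(),
                      len_full = integer(), len_5utr = integer(),
                      len_cds = integer(), len_3utr = integer(),
                      n_exons = integer(), coding = logical()))
  out <- do.call(rbind, lapply(x, regionLengthsOne))
  rownames(out) <- NULL
  out
})

#' @rdname splicedSequence
#' @export
setMethod("splicedSequence", signature("TranscriptModel", "DNAStringSet"),
  function(x, genome) {
    if (!x@chrom %in% names(genome))
      stop("contig '", x@chrom, "' not found in the genome")
    ctg <- genome[[x@chrom]]
    if (max(x@exonEnds) > length(ctg) || min(x@exonStarts) < 1L)
      stop("exon interval outside contig '", x@chrom, "' for ",
           x@transcriptId)
    pieces <- lapply(seq_along(x@exonStarts), function(i) {
      s <- Biostrings::subseq(ctg, x@exonStarts[i], x@exonEnds[i])
      if (x@strand == "-") Biostrings::reverseComplement(s) else s
    })
    out <- pieces[[1]]
    for (p in pieces[-1]) out <- Biostrings::xscat(out, p)
    Biostrings::DNAString(as.character(out))
  })

# Map transcript coordinates (1-based on the spliced mRNA) to genomic
# positions. Exons are stored with genomic start <= end and rows ordered by
# transcription (descending genomically on '-'), so the tx 5' bound of an
# exon is its genomic end on the minus strand.
txToGenome <- function(x, txpos) {
  widths <- x@exonEnds - x@exonStarts + 1L
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  vapply(as.integer(txpos), function(p) {
    i <- which(p >= starts & p <= ends)
    if (length(i) != 1L)
      stop("transcript position ", p, " outside ", x@transcriptId)
    off <- p - starts[i]
    if (x@strand == "+") x@exonStarts[i] + off else x@exonEnds[i] - off
  }, integer(1))
}

#' @rdname junctions
#' @export
setMethod("junctions", "TranscriptModel", function(x) {
  n <- length(x@exonStarts)
  if (n < 2L)
    return(data.frame(donor = integer(), acceptor = integer()))
  if (x@strand == "+") {
    data.frame(donor = x@exonEnds[-n], acceptor = x@exonStarts[-1])
  } else {
    data.frame(donor = x@exonStarts[-n], acceptor = x@exonEnds[-1])
  }
})
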