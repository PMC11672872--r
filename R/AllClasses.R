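#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
REGIONS <- c("full", "utr5", "cds", "utr3")

#' TranscriptModel: one mRNA isoform on a genome
#'
#' A `TranscriptModel` holds the exon chain and (for coding transcripts) the
#' CDS span of a single transcript isoform. Exons are stored as genomic
#' 1-based inclusive intervals in *transcription order*: ascending along the
#' genome on the `+` strand, descending on the `-` strand, so that
#' concatenating exon sequences (reverse-complemented on `-`) yields the
#' spliced mRNA 5'->3'. The CDS is annotated in transcript coordinates
#' (1 = first base of the spliced mRNA) and *includes the stop codon*, the
#' RefSeq convention; the 3'UTR therefore starts at the base after the stop.
#'
#' @slot transcriptId unique isoform identifier (RefSeq-style "seqname").
#' @slot geneSymbol gene identifier shared by all isoforms of a gene.
#' @slot chrom contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot exonStarts,exonEnds integer vectors of genomic interval bounds,
#'   parallel, in transcription order.
#' @slot cdsStartTx,cdsEndTx transcript coordinates of the first base of the
#'   start codon and the last base of the stop codon; `NA` for non-coding.
#'
#' @examples
#' tm <- TranscriptModel("tx1", "GENE1", "chr1", "+",
#'                       exonStarts = c(1L, 201L), exonEnds = c(100L, 300L),
#'                       cdsStartTx = 51L, cdsEndTx = 150L)
#' regionLengths(tm)
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneSymbol   = "character",
    chrom        = "character",
    strand       = "character",
    exonStarts   = "integer",
    exonEnds     = "integer",
    cdsStartTx   = "integer",
    cdsEndTx     = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  s <- object@exonStarts; e <- object@exonEnds
  if (length(object@transcriptId) != 1L || is.na(object@transcriptId))
    msg <- c(msg, "transcriptId must be a single string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(s) != length(e) || length(s) < 1L)
    msg <- c(msg, "need at least one exon with parallel starts/ends")
  else {
    if (any(is.na(s)) || any(is.na(e)) || any(s > e))
      msg <- c(msg, "exon starts must be <= ends and non-missing")
    if (length(s) > 1L) {
      ord <- if (object@strand == "+") all(diff(s) > 0) && all(s[-1] > e[-length(e)])
             else all(diff(s) < 0) && all(e[-1] < s[-length(s)])
      if (!ord)
        msg <- c(msg, paste0("exons of ", object@transcriptId,
                             " must be non-overlapping and in transcription order"))
    }
    L <- sum(e - s + 1L)
    cs <- object@cdsStartTx; ce <- object@cdsEndTx
    if (is.na(cs) != is.na(ce))
      msg <- c(msg, "cdsStartTx and cdsEndTx must both be set or both NA")
    if (!is.na(cs) && !is.na(ce)) {
      if (!(cs >= 1L && cs < ce && ce <= L))
        msg <- c(msg, paste0("CDS span of ", object@transcriptId,
                             " must satisfy 1 <= start < end <= spliced length"))
      # codon-exactness (CDS length divisible by 3) is deliberately not
      # enforced here: published isoform records are not always codon-exact;
      # the simulator guarantees it for generated models
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneSymbol,chrom,strand,exonStarts,exonEnds,cdsStartTx,cdsEndTx
#'   see the class slots.
#' @return a validated [TranscriptModel-class] object.
#' @export
TranscriptModel <- function(transcriptId, geneSymbol, chrom, strand,
                            exonStarts, exonEnds,
                            cdsStartTx = NA_integer_, cdsEndTx = NA_integer_) {
  new("TranscriptModel",
      transcriptId = as.character(transcriptId),
      geneSymbol   = as.character(geneSymbol),
      chrom        = as.character(chrom),
      strand       = as.character(strand),
      exonStarts   = as.integer(exonStarts),
      exonEnds     = as.integer(exonEnds),
      cdsStartTx   = as.integer(cdsStartTx),
      cdsEndTx     = as.integer(cdsEndTx))
}

#' TranscriptModelSet: a collection of transcript models
#'
#' A thin [S4Vectors::SimpleList] of [TranscriptModel-class] objects, named by
#' transcript id, as returned by [readAnnotation()] and the simulator.
#'
#' @export
setClass("TranscriptModelSet",
  contains = "SimpleList",
  prototype = prototype(elementType = "TranscriptModel")
)

setValidity("TranscriptModelSet", function(object) {
  if (length(object) == 0L) return(TRUE)
  ids <- vapply(object, function(x) x@transcriptId, character(1))
  if (is.null(names(object)) || !identical(unname(ids), unname(names(object))))
    return("set must be named by transcriptId")
  if (anyDuplicated(ids))
    return(paste("duplicated transcript ids:",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' @param models a list of [TranscriptModel-class] objects.
#' @rdname TranscriptModelSet-class
#' @export
TranscriptModelSet <- function(models = list()) {
  models <- as.list(models)
  names(models) <- vapply(models, function(x) x@transcriptId, character(1))
  new("TranscriptModelSet", S4Vectors::SimpleList(models))
}

#' ConditionList: one filtered differential-expression list
#'
#' The set of transcripts called differentially expressed (one direction only)
#' in one experimental condition, after volcano filtering. Records are a
#' data.frame with columns `seqname`, `gene_symbol`, `fold_change_abs`,
#' `p_value`, `direction`, `condition`; seqnames are unique within the list.
#'
#' @slot condition condition label, e.g. "C10".
#' @slot direction `"up"` or `"down"`.
#' @slot records the record data.frame.
#' @export
setClass("ConditionList",
  representation(condition = "character", direction = "character",
                 records = "data.frame"))

setValidity("ConditionList", function(object) {
  msg <- character()
  req <- c("seqname", "gene_symbol", "fold_change_abs", "p_value",
           "direction", "condition")
  if (!all(req %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(req, collapse = ", ")))
  else if (nrow(object@records)) {
    if (!all(object@records$direction == object@direction))
      msg <- c(msg, "all records must share the list direction")
    if (!all(object@records$condition == object@condition))
      msg <- c(msg, "all records must share the list condition")
    if (anyDuplicated(object@records$seqname))
      msg <- c(msg, "seqnames must be unique within a condition list")
  }
  if (!object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' DistributionComparison: query vs reference length-distribution test
#'
#' Result of [compareLengths()]: a two-sample location test on (by default
#' log10-transformed) region lengths, plus kernel density estimates of both
#' samples on a shared grid.
#'
#' @slot region one of "full", "utr5", "cds", "utr3".
#' @slot nQuery,nReference sample sizes after zero-exclusion.
#' @slot nZeroQuery,nZeroReference zero-length records excluded from the
#'   log-scale test, reported separately.
#' @slot tStatistic,pValue test statistic and p-value.
#' @slot direction "longer", "shorter" or "none" (none iff p > alpha).
#' @slot densityQuery,densityReference two-column matrices (grid, density).
#' @slot test,scale,alpha the options used.
#' @export
setClass("DistributionComparison",
  representation(region = "character",
                 nQuery = "integer", nReference = "integer",
                 nZeroQuery = "integer", nZeroReference = "integer",
                 tStatistic = "numeric", pValue = "numeric",
                 direction = "character",
                 densityQuery = "matrix", densityReference = "matrix",
                 test = "character", scale = "character", alpha = "numeric"))

setValidity("DistributionComparison", function(object) {
  msg <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (!object@direction %in% c("longer", "shorter", "none"))
    msg <- c(msg, "direction must be longer/shorter/none")
  if ((object@pValue > object@alpha) != (object@direction == "none"))
    msg <- c(msg, "direction must be 'none' exactly when p > alpha")
  if (length(msg)) msg else TRUE
})

#' ExonCountSpectrum: exon-count distribution with goodness-of-fit test
#'
#' Per-gene mean exon counts binned into 1..9 and "10+", with a chi-squared
#' goodness-of-fit test of the query bin counts against reference proportions.
#'
#' @slot bins bin labels (after any upward merging of empty expected bins).
#' @slot observed query bin counts.
#' @slot expected expected counts (reference proportions scaled to the query
#'   total).
#' @slot chi2,pValue,df test statistic, p-value, degrees of freedom.
#' @slot merged TRUE if bins had to be merged because of empty expected cells.
#' @export
setClass("ExonCountSpectrum",
  representation(bins = "character", observed = "numeric",
                 expected = "numeric", chi2 = "numeric",
                 pValue = "numeric", df = "integer", merged = "logical"))

setValidity("ExonCountSpectrum", function(object) {
  msg <- character()
  if (length(object@bins) != length(object@observed) ||
      length(object@bins) != length(object@expected))
    msg <- c(msg, "bins, observed and expected must be parallel")
  if (any(object@expected <= 0))
    msg <- c(msg, "all expected counts must be > 0 (bins are merged upward)")
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-6)
    msg <- c(msg, "observed and expected must sum to the same total")
  if (length(msg)) msg else TRUE
})

#' MechanismCall: classified length-variation mechanism for an isoform pair
#'
#' Result of [classifyMechanism()] on an (old, new) isoform pair of one gene:
#' per-region S/L/= length codes and the structural splice-event class, with
#' the genomic evidence that drove the call.
#'
#' @slot geneSymbol,oldId,newId identifiers of the compared pair.
#' @slot regionCodes named character, codes "S"/"L"/"=" for
#'   full, utr5, cds, utr3 (new relative to old).
#' @slot eventClass one of identical, alternative_polyadenylation,
#'   alternative_start_codon, cassette_exon_inclusion, cassette_exon_skipping,
#'   alt_5prime_donor, alt_3prime_acceptor, mutually_exclusive_terminal_exons,
#'   complex.
#' @slot cryptic TRUE when a junction endpoint private to the new isoform lies
#'   strictly inside an exon of the old isoform (cryptic-site activation).
#' @slot evidence list of genomic positions/exon indices supporting the call.
#' @export
setClass("MechanismCall",
  representation(geneSymbol = "character", oldId = "character",
                 newId = "character", regionCodes = "character",
                 eventClass = "character", cryptic = "logical",
                 evidence = "list"))

EVENT_CLASSES <- c("identical", "alternative_polyadenylation",
                   "alternative_start_codon", "cassette_exon_inclusion",
                   "cassette_exon_skipping", "alt_5prime_donor",
                   "alt_3prime_acceptor", "mutually_exclusive_terminal_exons",
                   "complex")

setValidity("MechanismCall", function(object) {
  msg <- character()
  if (!object@eventClass %in% EVENT_CLASSES)
    msg <- c(msg, paste("unknown eventClass:", object@eventClass))
  if (!identical(names(object@regionCodes), REGIONS))
    msg <- c(msg, "regionCodes must be named full/utr5/cds/utr3")
  if (!all(object@regionCodes %in% c("S", "L", "=")))
    msg <- c(msg, "regionCodes must be S, L or =")
  if (length(msg)) msg else TRUE
})
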