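#' @include AllClasses.R
NULL

#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @export
setGeneric("isCoding", function(x) standardGeneric("isCoding"))
#' @export
setGeneric("splicedLength", function(x) standardGeneric("splicedLength"))

#' Region lengths of one or more transcript models
#'
#' Computes the lengths, in nucleotides, of the 5'UTR, CDS (start through stop
#' codon inclusive), 3'UTR and full spliced mRNA, plus the exon count. For a
#' coding transcript `len_5utr = cds_start - 1`,
#' `len_cds = cds_end - cds_start + 1` and
#' `len_3utr = spliced length - cds_end`, so the three regions always sum to
#' the full length. Non-coding transcripts are retained with zero UTR/CDS
#' lengths and `len_full` equal to the spliced length, flagged by
#' `coding = FALSE` so they can be excluded from region statistics.
#'
#' @param x a [TranscriptModel-class] or [TranscriptModelSet-class].
#' @return a data.frame with columns `transcript_id`, `gene_symbol`,
#'   `len_full`, `len_5utr`, `len_cds`, `len_3utr`, `n_exons`, `coding`.
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))

#' Spliced mRNA sequence of a transcript model
#'
#' Concatenates the exon sequences in transcription order, reverse
#' complementing on the minus strand, to give the mature mRNA 5'->3'.
#'
#' @param x a [TranscriptModel-class].
#' @param genome a named [Biostrings::DNAStringSet] holding the contigs.
#' @return a [Biostrings::DNAString].
#' @export
setGeneric("splicedSequence", function(x, genome) standardGeneric("splicedSequence"))

#' Splice junctions of a transcript model
#'
#' One junction per adjacent exon pair, in genomic coordinates: the donor is
#' the last base of the upstream exon (in transcription order) and the
#' acceptor the first base of the downstream exon, strand-aware.
#'
#' @param x a [TranscriptModel-class].
#' @return a data.frame with columns `donor` and `acceptor` (genomic
#'   positions), zero rows for single-exon transcripts.
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
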