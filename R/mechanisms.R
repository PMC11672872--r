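#' @include transcript-models.R annotation-io.R
NULL

#' SpliceSignal: an extracted donor/acceptor window with consensus score
#'
#' @slot side "donor" or "acceptor".
#' @slot sequence the extracted window, mRNA-sense (exonic part first for
#'   donors, last for acceptors).
#' @slot consensus the IUPAC consensus it was scored against.
#' @slot score fraction of positions compatible with the consensus, in [0,1].
#' @export
setClass("SpliceSignal",
  representation(side = "character", sequence = "character",
                 consensus = "character", score = "numeric"))

setValidity("SpliceSignal", function(object) {
  if (nchar(object@sequence) != nchar(object@consensus))
    return("sequence and consensus must have equal length")
  if (object@score < 0 || object@score > 1) return("score must lie in [0,1]")
  TRUE
})

setMethod("show", "SpliceSignal", function(object) {
  hits <- mapply(iupacMatches, strsplit(object@sequence, "")[[1]],
                 strsplit(object@consensus, "")[[1]])
  bars <- paste(ifelse(hits, "|", " "), collapse = "")
  cat(sprintf("SpliceSignal (%s) score %.2f\n  %s\n  %s\n  %s\n",
              object@side, object@score, object@sequence, bars,
              object@consensus))
})

# does observed base obs satisfy IUPAC consensus letter cons (U == T)?
iupacMatches <- function(obs, cons) {
  cons <- sub("U", "T", toupper(cons))
  obs <- sub("U", "T", toupper(obs))
  exp <- Biostrings::IUPAC_CODE_MAP[cons]
  if (is.na(exp)) return(FALSE)
  grepl(obs, exp, fixed = TRUE)
}

consensusWindow <- function(side, exonic, intronic) {
  if (side == "donor") {
    ex <- "MAG"; intr <- "GTRAGT"
    exC <- substring(ex, max(1, nchar(ex) - exonic + 1), nchar(ex))
    exC <- paste0(strrep("N", max(0, exonic - nchar(ex))), exC)
    inC <- substring(intr, 1, min(intronic, nchar(intr)))
    inC <- paste0(inC, strrep("N", max(0, intronic - nchar(intr))))
    paste0(exC, inC)
  } else {
    # polypyrimidine tract ending in YAG, then the first exonic base (G)
    inC <- paste0(strrep("Y", max(0, intronic - 3)),
                  substring("YAG", max(1, 4 - intronic), 3))
    exC <- paste0("G", strrep("N", max(0, exonic - 1)))
    paste0(inC, exC)
  }
}

#' Extract and score a splice signal
#'
#' Cuts the genomic window around a junction endpoint and scores it against
#' the canonical splice-site consensus, position by position, with IUPAC
#' degeneracy (R = A/G, Y = C/T, M = A/C, N = any; U is treated as T). The
#' default windows are the standard consensus presentations: donors are
#' 9-mers (last 3 exonic + first 6 intronic nt, consensus `MAG|GTRAGT`),
#' acceptors 15-mers (last 14 intronic + 1 exonic nt, a polypyrimidine tract
#' ending in `YAG|G`).
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param chrom contig name.
#' @param pos genomic position of the junction endpoint (last exonic base
#'   for donors, first exonic base for acceptors).
#' @param side "donor" or "acceptor".
#' @param strand "+" or "-".
#' @param exonic,intronic window sizes on each side of the splice site;
#'   defaults 3+6 (donor) and 1+14 (acceptor).
#' @return a [SpliceSignal-class].
#' @export
extractSpliceSignal <- function(genome, chrom, pos, side = c("donor", "acceptor"),
                                strand = "+", exonic = NULL, intronic = NULL) {
  side <- match.arg(side)
  if (is.null(exonic)) exonic <- if (side == "donor") 3L else 1L
  if (is.null(intronic)) intronic <- if (side == "donor") 6L else 14L
  if (!chrom %in% names(genome)) stop("contig '", chrom, "' not in genome")
  ctg <- genome[[chrom]]
  if (side == "donor") {
    rng <- if (strand == "+") c(pos - exonic + 1L, pos + intronic)
           else c(pos - intronic, pos + exonic - 1L)
  } else {
    rng <- if (strand == "+") c(pos - intronic, pos + exonic - 1L)
           else c(pos - exonic + 1L, pos + intronic)
  }
  if (rng[1] < 1L || rng[2] > length(ctg))
    stop("splice-signal window overruns contig '", chrom, "'")
  s <- Biostrings::subseq(ctg, rng[1], rng[2])
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  seqc <- as.character(s)
  cons <- consensusWindow(side, exonic, intronic)
  oc <- strsplit(seqc, "")[[1]]
  cc <- strsplit(cons, "")[[1]]
  hits <- mapply(iupacMatches, oc, cc)
  new("SpliceSignal", side = side, sequence = seqc, consensus = cons,
      score = sum(hits) / length(cc))
}

# ---- mechanism classification ------------------------------------------

junctionKeys <- function(j) {
  if (!nrow(j)) character() else paste(j$donor, j$acceptor, sep = ":")
}

exonKeys <- function(m) paste(m@exonStarts, m@exonEnds, sep = "-")

interiorToExon <- function(pos, m) {
  any(pos > m@exonStarts & pos < m@exonEnds)
}

regionCodesFor <- function(old, new) {
  lo <- regionLengthsOne(old); ln <- regionLengthsOne(new)
  v <- function(a, b) if (a > b) "L" else if (a < b) "S" else "="
  c(full = v(ln$len_full, lo$len_full), utr5 = v(ln$len_5utr, lo$len_5utr),
    cds = v(ln$len_cds, lo$len_cds), utr3 = v(ln$len_3utr, lo$len_3utr))
}

# genomic position of a CDS transcript coordinate, NA for non-coding
cdsGenomicPos <- function(m, which = c("start", "end")) {
  which <- match.arg(which)
  if (!isCoding(m)) return(NA_integer_)
  txToGenome(m, if (which == "start") m@cdsStartTx else m@cdsEndTx)
}

#' Classify the splicing mechanism separating two isoforms of one gene
#'
#' Given the old and new transcript models of a switching gene, decides which
#' structural event explains their difference, through a deterministic
#' decision cascade (first match wins):
#'
#' 1. identical exon chains and CDS -> `identical`;
#' 2. identical splice junctions, exon chains differing only at the
#'    transcript 3' end, stop codon shared -> `alternative_polyadenylation`;
#' 3. identical junctions with a different CDS start ->
#'    `alternative_start_codon` (covers both pure start-codon re-selection
#'    and a shifted transcription start with a downstream start codon);
#' 4. exactly one internal exon of one isoform absent from the other, all
#'    remaining exons identical -> `cassette_exon_inclusion` /
#'    `cassette_exon_skipping` (direction old -> new);
#' 5. a single changed junction pair sharing its acceptor ->
#'    `alt_5prime_donor`; sharing its donor -> `alt_3prime_acceptor`, unless
#'    the downstream exons are terminal and genomically disjoint, in which
#'    case -> `mutually_exclusive_terminal_exons`;
#' 6. junctions private to one isoform extending past the other's structure:
#'    classified by the endpoint that falls strictly inside a partner exon
#'    (donor -> `alt_5prime_donor`, acceptor -> `alt_3prime_acceptor`);
#' 7. anything else -> `complex`.
#'
#' Independently of the class, the call is tagged *cryptic* when an endpoint
#' of a junction private to the new isoform lies strictly inside an exon of
#' the old isoform — the signature of cryptic/latent splice-site activation.
#'
#' @param old,new [TranscriptModel-class] objects of the same gene, contig
#'   and strand.
#' @return a [MechanismCall-class].
#' @export
classifyMechanism <- function(old, new) {
  if (old@geneSymbol != new@geneSymbol || old@chrom != new@chrom ||
      old@strand != new@strand)
    stop("isoforms are not comparable (different gene, contig or strand)")
  codes <- regionCodesFor(old, new)
  jOld <- junctions(old); jNew <- junctions(new)
  kOld <- junctionKeys(jOld); kNew <- junctionKeys(jNew)
  onlyOld <- jOld[!kOld %in% kNew, , drop = FALSE]
  onlyNew <- jNew[!kNew %in% kOld, , drop = FALSE]
  cryptic <- any(vapply(seq_len(nrow(onlyNew)), function(i)
    interiorToExon(onlyNew$donor[i], old) ||
      interiorToExon(onlyNew$acceptor[i], old), logical(1)))
  evid <- list(junctions_old_only = onlyOld, junctions_new_only = onlyNew)
  mk <- function(cls) new("MechanismCall", geneSymbol = old@geneSymbol,
                          oldId = old@transcriptId, newId = new@transcriptId,
                          regionCodes = codes, eventClass = cls,
                          cryptic = isTRUE(cryptic), evidence = evid)

  sameExons <- identical(exonKeys(old), exonKeys(new))
  sameCds <- identical(old@cdsStartTx, new@cdsStartTx) &&
             identical(old@cdsEndTx, new@cdsEndTx)
  if (sameExons && sameCds) return(mk("identical"))

  if (!nrow(onlyOld) && !nrow(onlyNew)) {
    # identical junction sets: differences confined to the CDS annotation or
    # to the outer transcript boundaries
    if (sameExons)
      return(mk(if (old@cdsStartTx != new@cdsStartTx)
        "alternative_start_codon" else "complex"))
    nO <- length(old@exonStarts); nN <- length(new@exonStarts)
    end3DiffersOnly <- nO == nN &&
      identical(exonKeys(old)[-nO], exonKeys(new)[-nN])
    start5Differs <- exonKeys(old)[1] != exonKeys(new)[1]
    stopShared <- isCoding(old) && isCoding(new) &&
      identical(cdsGenomicPos(old, "end"), cdsGenomicPos(new, "end"))
    if (end3DiffersOnly && stopShared)
      return(mk("alternative_polyadenylation"))
    startShared <- isCoding(old) && isCoding(new) &&
      identical(cdsGenomicPos(old, "start"), cdsGenomicPos(new, "start"))
    if (start5Differs && isCoding(old) && isCoding(new) && !startShared)
      return(mk("alternative_start_codon"))
    return(mk("complex"))
  }

  # cassette exon: exactly one internal exon of one model missing from the
  # other, everything else identical
  dOld <- setdiff(exonKeys(old), exonKeys(new))
  dNew <- setdiff(exonKeys(new), exonKeys(old))
  if (length(dOld) + length(dNew) == 1L) {
    carrier <- if (length(dNew)) new else old
    dkey <- c(dOld, dNew)
    pos <- match(dkey, exonKeys(carrier))
    if (pos > 1L && pos < length(carrier@exonStarts)) {
      evid$cassette_exon <- c(start = carrier@exonStarts[pos],
                              end = carrier@exonEnds[pos])
      call <- mk(if (length(dNew)) "cassette_exon_inclusion"
                 else "cassette_exon_skipping")
      call@evidence <- evid
      return(call)
    }
  }

  if (nrow(onlyOld) == 1L && nrow(onlyNew) == 1L) {
    if (onlyOld$acceptor == onlyNew$acceptor &&
        onlyOld$donor != onlyNew$donor)
      return(mk("alt_5prime_donor"))
    if (onlyOld$donor == onlyNew$donor &&
        onlyOld$acceptor != onlyNew$acceptor) {
      exO <- downstreamExon(old, onlyOld$acceptor)
      exN <- downstreamExon(new, onlyNew$acceptor)
      terminalO <- !is.null(exO) && exO["index"] == length(old@exonStarts)
      terminalN <- !is.null(exN) && exN["index"] == length(new@exonStarts)
      disjoint <- !is.null(exO) && !is.null(exN) &&
        (exO["end"] < exN["start"] || exN["end"] < exO["start"])
      if (terminalO && terminalN && disjoint)
        return(mk("mutually_exclusive_terminal_exons"))
      return(mk("alt_3prime_acceptor"))
    }
    return(mk("complex"))
  }

  # junctions private to a single model (structure extended past the other)
  priv <- if (nrow(onlyNew) && !nrow(onlyOld)) list(j = onlyNew, partner = old)
          else if (nrow(onlyOld) && !nrow(onlyNew)) list(j = onlyOld, partner = new)
          else NULL
  if (!is.null(priv)) {
    j1 <- priv$j[1, ]  # first private junction in transcription order
    donorIn <- interiorToExon(j1$donor, priv$partner)
    accIn <- interiorToExon(j1$acceptor, priv$partner)
    if (donorIn && !accIn) return(mk("alt_5prime_donor"))
    if (accIn && !donorIn) return(mk("alt_3prime_acceptor"))
  }
  mk("complex")
}

# the exon whose tx-5' boundary is the given acceptor position
downstreamExon <- function(m, acceptor) {
  bound <- if (m@strand == "+") m@exonStarts else m@exonEnds
  i <- which(bound == acceptor)
  if (!length(i)) return(NULL)
  c(index = i[1], start = m@exonStarts[i[1]], end = m@exonEnds[i[1]])
}

setMethod("show", "MechanismCall", function(object) {
  cat(sprintf("MechanismCall %s: %s -> %s\n  class: %s%s\n  codes: FL:%s 5'UTR:%s CDS:%s 3'UTR:%s\n",
              object@geneSymbol, object@oldId, object@newId,
              object@eventClass, if (object@cryptic) " [cryptic]" else "",
              object@regionCodes["full"], object@regionCodes["utr5"],
              object@regionCodes["cds"], object@regionCodes["utr3"]))
})

#' Classify mechanisms for a table of switching isoform pairs
#'
#' @param pairs data.frame with columns `gene_symbol`, `old_id`, `new_id`
#'   (e.g. from [switchTable()]).
#' @param models a [TranscriptModelSet-class] resolving every id.
#' @return a list of [MechanismCall-class] objects.
#' @export
classifyMechanismPairs <- function(pairs, models) {
  missing <- setdiff(unique(c(pairs$old_id, pairs$new_id)), names(models))
  if (length(missing))
    stop("no transcript model for: ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(pairs)), function(i)
    classifyMechanism(models[[pairs$old_id[i]]], models[[pairs$new_id[i]]]))
}

#' Count alternative-polyadenylation calls
#'
#' @param calls a list of [MechanismCall-class] objects from one comparison
#'   run.
#' @return integer count of calls classified `alternative_polyadenylation`.
#' @export
countApaEvents <- function(calls) {
  sum(vapply(calls, function(x) x@eventClass == "alternative_polyadenylation",
             logical(1)))
}

#' Flatten mechanism calls to a table
#'
#' @param calls list of [MechanismCall-class] objects.
#' @return data.frame with identifiers, the four region codes, event class
#'   and cryptic tag.
#' @export
mechanismTable <- function(calls) {
  if (!length(calls))
    return(data.frame(gene_symbol = character(), old_id = character(),
                      new_id = character(), FL = character(),
                      utr5 = character(), cds = character(),
                      utr3 = character(), event_class = character(),
                      cryptic = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(x)
    data.frame(gene_symbol = x@geneSymbol, old_id = x@oldId, new_id = x@newId,
               FL = unname(x@regionCodes["full"]),
               utr5 = unname(x@regionCodes["utr5"]),
               cds = unname(x@regionCodes["cds"]),
               utr3 = unname(x@regionCodes["utr3"]),
               event_class = x@eventClass, cryptic = x@cryptic,
               stringsAsFactors = FALSE)))
}
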