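#' @include deg.R
NULL

#' Genes shared between two condition lists
#'
#' Gene symbols with at least one record in each of two condition lists of
#' the same regulation direction — the genes whose expression change persists
#' across the two time points.
#'
#' @param a,b [ConditionList-class] objects sharing a direction.
#' @return character vector of shared gene symbols (sorted).
#' @export
sharedGenes <- function(a, b) {
  if (a@direction != b@direction)
    stop("condition lists must share a regulation direction")
  sort(intersect(unique(a@records$gene_symbol), unique(b@records$gene_symbol)))
}

#' Detect isoform switching between two conditions
#'
#' For every gene shared between conditions A and B, compares the sets of
#' isoform identifiers (seqnames) recorded in each condition. A gene whose
#' sets differ has undergone an isoform switch: isoforms present only in B
#' are "de novo", isoforms present only in A are "silenced". The switch class
#' is `de_novo_isoform` (de novo only), `isoform_loss` (silenced only),
#' `mixed` (both) or `no_switch` (identical sets). Non-switching shared genes
#' are reported too, so shared-gene counts are recoverable by filtering.
#'
#' @param a,b [ConditionList-class] objects sharing a direction (A is the
#'   earlier condition).
#' @return a [S4Vectors::DataFrame] with one row per shared gene: columns
#'   `gene_symbol`, `isoforms_a`, `isoforms_b`, `de_novo`, `silenced`
#'   (CharacterList columns) and `switch_class`.
#' @export
detectSwitches <- function(a, b) {
  genes <- sharedGenes(a, b)
  isoA <- lapply(genes, function(g)
    sort(a@records$seqname[a@records$gene_symbol == g]))
  isoB <- lapply(genes, function(g)
    sort(b@records$seqname[b@records$gene_symbol == g]))
  deNovo <- mapply(function(x, y) setdiff(y, x), isoA, isoB, SIMPLIFY = FALSE)
  silenced <- mapply(function(x, y) setdiff(x, y), isoA, isoB, SIMPLIFY = FALSE)
  cls <- mapply(function(d, s) {
    if (!length(d) && !length(s)) "no_switch"
    else if (length(d) && !length(s)) "de_novo_isoform"
    else if (!length(d) && length(s)) "isoform_loss"
    else "mixed"
  }, deNovo, silenced)
  S4Vectors::DataFrame(
    gene_symbol = genes,
    isoforms_a = IRanges::CharacterList(isoA),
    isoforms_b = IRanges::CharacterList(isoB),
    de_novo = IRanges::CharacterList(deNovo),
    silenced = IRanges::CharacterList(silenced),
    switch_class = unname(cls))
}

# the isoform pairs a switching gene contributes to the switch table:
# "new" isoforms are the de novo ones when any exist (else the full B set),
# "old" isoforms the silenced ones when any exist (else the full A set).
# This reproduces single old->new pairs for de novo switches and
# silenced-vs-surviving pairs for isoform losses, without self-pairs.
switchPairs <- function(events) {
  rows <- NULL
  for (i in seq_len(nrow(events))) {
    if (events$switch_class[i] == "no_switch") next
    dn <- events$de_novo[[i]]; si <- events$silenced[[i]]
    news <- if (length(dn)) dn else events$isoforms_b[[i]]
    olds <- if (length(si)) si else events$isoforms_a[[i]]
    rows <- rbind(rows, expand.grid(gene_symbol = events$gene_symbol[i],
                                    old_id = olds, new_id = news,
                                    stringsAsFactors = FALSE))
  }
  rows
}

#' Per-region length-change codes for switching isoform pairs
#'
#' For each switching gene and each (old, new) isoform pair, emits the
#' S/L/= code per region: `L` when the new isoform's region is longer than
#' the old one's, `S` when shorter, `=` when exactly equal in nt (no
#' tolerance).
#'
#' @param events DataFrame from [detectSwitches()].
#' @param lengths region-length table from [regionLengths()] covering every
#'   switching seqname.
#' @return data.frame with columns `gene_symbol`, `old_id`, `new_id`,
#'   `FL`, `utr5`, `cds`, `utr3`.
#' @export
switchTable <- function(events, lengths) {
  pairs <- switchPairs(events)
  empty <- data.frame(gene_symbol = character(), old_id = character(),
                      new_id = character(), FL = character(),
                      utr5 = character(), cds = character(),
                      utr3 = character(), stringsAsFactors = FALSE)
  if (is.null(pairs) || !nrow(pairs)) return(empty)
  need <- unique(c(pairs$old_id, pairs$new_id))
  missing <- setdiff(need, lengths$transcript_id)
  if (length(missing))
    stop("no region lengths for seqname(s): ", paste(missing, collapse = ", "))
  idx <- match(pairs$old_id, lengths$transcript_id)
  jdx <- match(pairs$new_id, lengths$transcript_id)
  code <- function(new, old) ifelse(new > old, "L", ifelse(new < old, "S", "="))
  data.frame(gene_symbol = pairs$gene_symbol,
             old_id = pairs$old_id, new_id = pairs$new_id,
             FL = code(lengths$len_full[jdx], lengths$len_full[idx]),
             utr5 = code(lengths$len_5utr[jdx], lengths$len_5utr[idx]),
             cds = code(lengths$len_cds[jdx], lengths$len_cds[idx]),
             utr3 = code(lengths$len_3utr[jdx], lengths$len_3utr[idx]),
             stringsAsFactors = FALSE)
}
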