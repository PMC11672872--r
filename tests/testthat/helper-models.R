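# shared builders for toy transcript models and genomes

toyGtfLines <- function() c(
  'chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
  'chr1\ttoy\texon\t201\t300\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
  'chr1\ttoy\tCDS\t51\t100\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
  'chr1\ttoy\tCDS\t201\t250\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
  'chr1\ttoy\texon\t400\t460\t.\t+\t.\tgene_id "G2"; transcript_id "T2";')

writeToyGtf <- function(lines = toyGtfLines()) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

# random contig + a minus-strand two-exon coding model on it
minusStrandToy <- function(seed = 11) {
  set.seed(seed)
  seqchars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  genome <- Biostrings::DNAStringSet(c(ctgM = paste(seqchars, collapse = "")))
  # tx order on '-': genomically descending
  m <- TranscriptModel("TM1", "GM1", "ctgM", "-",
                       exonStarts = c(301L, 51L), exonEnds = c(380L, 170L),
                       cdsStartTx = 21L, cdsEndTx = 140L)
  list(model = m, genome = genome, chars = seqchars)
}

# flip a model to the opposite strand of a reverse-complemented contig
flipModel <- function(m, contigLen) {
  flip <- function(p) contigLen - p + 1L
  TranscriptModel(m@transcriptId, m@geneSymbol, m@chrom,
                  if (m@strand == "+") "-" else "+",
                  flip(m@exonEnds), flip(m@exonStarts),
                  m@cdsStartTx, m@cdsEndTx)
}

smallSimConfig <- function(seed = 5, nGenes = 160,
                           switches = c(C10_C24 = 4L, T10_T24 = 2L)) {
  simulationConfig(seed = seed, nGenes = nGenes,
                   listSizes = c(C10 = 30L, C24 = 60L, T10 = 20L, T24 = 40L),
                   sharedGenes = c(C10_C24 = 10L, T10_T24 = 8L),
                   plantedSwitches = switches)
}

randomDegRecords <- function(n, cond = "C10", seed = 1) {
  set.seed(seed)
  if (n == 0)
    return(data.frame(seqname = character(), gene_symbol = character(),
                      fold_change_abs = numeric(), p_value = numeric(),
                      direction = character(), condition = character(),
                      stringsAsFactors = FALSE))
  data.frame(seqname = sprintf("NM_r%05d", seq_len(n)),
             gene_symbol = sprintf("g%04d", sample(ceiling(n * 0.8), n,
                                                   replace = TRUE)),
             fold_change_abs = stats::runif(n, 0.2, 6),
             p_value = stats::runif(n, 0, 0.4),
             direction = "down", condition = cond, stringsAsFactors = FALSE)
}
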