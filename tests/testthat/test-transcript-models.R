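test_that("a two-exon GTF gene yields the hand-walked spliced CDS coordinates", {
  m <- readAnnotation(writeToyGtf(), "gtf")
  t1 <- m[["T1"]]
  # hand-walk: exon1 is tx 1..100, exon2 tx 101..200; CDS 51..100 + 201..250
  expect_equal(splicedLength(t1), 200L)
  expect_equal(t1@cdsStartTx, 51L)
  expect_equal(t1@cdsEndTx, 150L)
  rl <- regionLengths(t1)
  expect_equal(rl$len_5utr, 50L)
  expect_equal(rl$len_cds, 100L)
  expect_equal(rl$len_3utr, 50L)
})

test_that("a transcript without CDS features is kept as non-coding", {
  m <- readAnnotation(writeToyGtf(), "gtf")
  t2 <- m[["T2"]]
  expect_false(isCoding(t2))
  rl <- regionLengths(t2)
  expect_equal(rl$len_full, 61L)
  expect_equal(rl$len_cds, 0L)
  expect_false(rl$coding)
})

test_that("a CDS spanning the whole mRNA leaves both UTRs empty", {
  m <- TranscriptModel("tx", "g", "c", "+", 1L, 90L, 1L, 90L)
  rl <- regionLengths(m)
  expect_equal(rl$len_5utr, 0L)
  expect_equal(rl$len_3utr, 0L)
  expect_equal(rl$len_cds, rl$len_full)
})

test_that("minus-strand spliced sequence equals the reverse-complement oracle", {
  toy <- minusStrandToy()
  m <- toy$model
  got <- as.character(splicedSequence(m, toy$genome))
  # independent oracle: slice the raw character vector per exon, reverse
  # complement by hand, concatenate in transcription order
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(lo, hi) paste(rev(unname(comp[toy$chars[lo:hi]])), collapse = "")
  expect_equal(got, paste0(rc(301, 380), rc(51, 170)))
  expect_equal(nchar(got), splicedLength(m))
})

test_that("plus-strand spliced sequence equals independent per-exon joining", {
  set.seed(3)
  chars <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  genome <- Biostrings::DNAStringSet(c(ctg = paste(chars, collapse = "")))
  m <- TranscriptModel("tp", "gp", "ctg", "+",
                       c(11L, 101L, 201L), c(40L, 150L, 260L))
  oracle <- paste(c(chars[11:40], chars[101:150], chars[201:260]),
                  collapse = "")
  expect_equal(as.character(splicedSequence(m, genome)), oracle)
  # single exon covering a whole contig is the identity / its reverse
  # complement on the minus strand
  one <- TranscriptModel("to", "go", "ctg", "+", 1L, 300L)
  expect_equal(as.character(splicedSequence(one, genome)),
               paste(chars, collapse = ""))
  oneM <- TranscriptModel("tm", "gm", "ctg", "-", 1L, 300L)
  expect_equal(as.character(splicedSequence(oneM, genome)),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(paste(chars, collapse = "")))))
})

test_that("region lengths always conserve len_full = 5'UTR + CDS + 3'UTR", {
  cfg <- smallSimConfig(seed = 17, nGenes = 100,
                        switches = c(C10_C24 = 0L, T10_T24 = 0L))
  sim <- simulateGenomeAndAnnotation(cfg, sequence = FALSE)
  rl <- regionLengths(sim$models)
  expect_gte(sum(rl$coding), 100L)
  cod <- rl[rl$coding, ]
  expect_equal(cod$len_5utr + cod$len_cds + cod$len_3utr, cod$len_full)
  expect_true(all(rl$n_exons >= 1))
})

test_that("region lengths are invariant under genome reverse-complement flips", {
  cfg <- smallSimConfig(seed = 19, nGenes = 40,
                        switches = c(C10_C24 = 0L, T10_T24 = 0L))
  sim <- simulateGenomeAndAnnotation(cfg, sequence = FALSE)
  for (m in as.list(sim$models)[1:20]) {
    L <- max(m@exonEnds) + 50L
    fl <- flipModel(m, L)
    expect_equal(regionLengths(fl)[, -1:-2], regionLengths(m)[, -1:-2])
  }
})

test_that("simulated transcripts carry their codons where annotated", {
  cfg <- smallSimConfig(seed = 23, nGenes = 60)
  sim <- simulateGenomeAndAnnotation(cfg, sequence = TRUE)
  for (m in as.list(sim$models)) {
    if (!isCoding(m)) next
    s <- as.character(splicedSequence(m, sim$genome))
    expect_identical(substr(s, m@cdsStartTx, m@cdsStartTx + 2), "ATG")
    expect_true(substr(s, m@cdsEndTx - 2, m@cdsEndTx) %in%
                  c("TAA", "TAG", "TGA"))
    # lengths derived from annotation match the sequence-level measurement
    rl <- regionLengths(m)
    expect_equal(rl$len_full, nchar(s))
    expect_equal(rl$len_5utr + rl$len_cds + rl$len_3utr, nchar(s))
  }
})

test_that("the tabular dialect round-trips models exactly", {
  fx <- switchFixture(3, 3)
  path <- tempfile(fileext = ".tsv")
  writeAnnotationTable(fx$models, path)
  back <- readAnnotation(path, "table")
  expect_identical(names(back), names(fx$models))
  for (id in names(back))
    expect_equal(back[[id]], fx$models[[id]])
})

test_that("model invariants reject malformed structures", {
  expect_error(TranscriptModel("x", "g", "c", "*", 1L, 10L), "strand")
  expect_error(TranscriptModel("x", "g", "c", "+", 10L, 1L), "exon")
  expect_error(TranscriptModel("x", "g", "c", "+", c(1L, 5L), c(10L, 20L)),
               "non-overlapping")
  expect_error(TranscriptModel("x", "g", "c", "+", 1L, 10L, 5L, 40L), "CDS")
  # minus strand must be genomically descending
  expect_error(TranscriptModel("x", "g", "c", "-", c(1L, 50L), c(10L, 60L)),
               "transcription order")
})

test_that("a CDS outside the exons is a model-consistency error naming the transcript", {
  lines <- c(
    'chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id "G"; transcript_id "TX9";',
    'chr1\ttoy\tCDS\t150\t200\t.\t+\t.\tgene_id "G"; transcript_id "TX9";')
  expect_error(readAnnotation(writeToyGtf(lines), "gtf"), "TX9")
})

test_that("malformed tabular coordinates raise a parse error naming the line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste("transcript_id", "gene_symbol", "chrom", "strand",
                     "exon_starts", "exon_ends", "cds_start_tx", "cds_end_tx",
                     sep = "\t"),
               paste("t1", "g1", "c", "+", "1,oops", "10,20", "NA", "NA",
                     sep = "\t")), path)
  expect_error(readAnnotation(path, "table"), "line 2")
})

test_that("GFF3 exon/CDS features assemble into the same model as GTF", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\ttoy\tgene\t1\t300\t.\t+\t.\tID=gene:G1",
    "chr1\ttoy\tmRNA\t1\t300\t.\t+\t.\tID=T1;Parent=gene:G1",
    "chr1\ttoy\texon\t1\t100\t.\t+\t.\tParent=T1",
    "chr1\ttoy\texon\t201\t300\t.\t+\t.\tParent=T1",
    "chr1\ttoy\tCDS\t51\t100\t.\t+\t.\tID=cds1;Parent=T1",
    "chr1\ttoy\tCDS\t201\t250\t.\t+\t.\tID=cds1;Parent=T1"), path)
  m <- readAnnotation(path, "gff3")
  t1 <- m[["T1"]]
  expect_equal(t1@cdsStartTx, 51L)
  expect_equal(t1@cdsEndTx, 150L)
  expect_equal(geneSymbol(t1), "G1")
})
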