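#' @include transcript-models.R deg.R
NULL

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic genome/annotation/expression-list
#' generator. The defaults encode the study conditions the pipeline is
#' validated against: four downregulated-transcript lists of sizes
#' 489/1285/300/690, 114 and 153 genes shared within the C and T condition
#' pairs, 7 and 3 planted isoform switches, a bimodal 3'UTR length
#' distribution with modes near 100 and 1000 bp, a 5'UTR distribution
#' peaking near 100 bp, and a condition-specific multiplier on the long-3'UTR
#' mixture weight that makes the later control time point (C24 analogue)
#' 3'UTR-longer than the reference.
#'
#' @param seed integer seed; all generator functions are deterministic given
#'   the config.
#' @param nGenes number of genes to simulate.
#' @param listSizes named transcript counts per condition list.
#' @param sharedGenes named counts of genes shared within each condition pair.
#' @param plantedSwitches named counts of isoform-switch events per pair.
#' @param utr3Mixture two-component log10-normal mixture for 3'UTR lengths:
#'   `meanlog10`, `sdlog10` (length 2 each) and `weight` of the long
#'   component.
#' @param utr5Dist,cdsDist log10-normal parameters (`meanlog10`, `sdlog10`)
#'   for 5'UTR and CDS lengths.
#' @param exonCountProbs probabilities over exon counts 1..15.
#' @param lengthShift per-condition multiplier applied to the long-3'UTR
#'   component weight when sampling that condition's list.
#' @param mechanismMix proportions over planted switch-event classes.
#' @param intronRange uniform intron-length bounds in nt.
#' @param multiIsoformFraction fraction of non-switch genes given a second
#'   (non-coding, exon-skipped) isoform, so per-gene mean exon counts can be
#'   fractional.
#' @return a validated config (list of class `"SimulationConfig"`).
#' @export
simulationConfig <- function(seed = 1L,
    nGenes = 2500L,
    listSizes = c(C10 = 489L, C24 = 1285L, T10 = 300L, T24 = 690L),
    sharedGenes = c(C10_C24 = 114L, T10_T24 = 153L),
    plantedSwitches = c(C10_C24 = 7L, T10_T24 = 3L),
    utr3Mixture = list(meanlog10 = c(2, 3), sdlog10 = c(0.22, 0.22),
                       weight = 0.5),
    utr5Dist = list(meanlog10 = 2, sdlog10 = 0.2),
    cdsDist = list(meanlog10 = 3.1, sdlog10 = 0.25),
    exonCountProbs = local({p <- stats::dpois(1:15, 6); p / sum(p)}),
    lengthShift = c(C10 = 0.6, C24 = 1.6, T10 = 1.0, T24 = 1.0),
    mechanismMix = c(alt_5prime_donor = 0.25, alt_3prime_acceptor = 0.25,
                     cassette_exon_inclusion = 0.15,
                     cassette_exon_skipping = 0.15,
                     alternative_start_codon = 0.10,
                     mutually_exclusive_terminal_exons = 0.10,
                     alternative_polyadenylation = 0.0),
    intronRange = c(60L, 2000L),
    multiIsoformFraction = 0.15) {
  stopifnot(length(seed) == 1L, nGenes >= 0,
            all(listSizes >= 0), all(sharedGenes >= 0),
            all(plantedSwitches >= 0),
            utr3Mixture$weight >= 0, utr3Mixture$weight <= 1,
            abs(sum(exonCountProbs) - 1) < 1e-8,
            all(mechanismMix >= 0), sum(mechanismMix) > 0,
            intronRange[1] >= 4, intronRange[2] >= intronRange[1],
            multiIsoformFraction >= 0, multiIsoformFraction <= 1)
  pairDefs <- list(C10_C24 = c("C10", "C24"), T10_T24 = c("T10", "T24"))
  for (p in names(sharedGenes)) {
    conds <- pairDefs[[p]]
    if (!is.null(conds) && all(conds %in% names(listSizes)) &&
        sharedGenes[p] > min(listSizes[conds]))
      stop("shared genes for ", p, " exceed the smaller list size")
    if (p %in% names(plantedSwitches) && plantedSwitches[p] > sharedGenes[p])
      stop("planted switches for ", p, " exceed the shared-gene count")
  }
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              listSizes = listSizes, sharedGenes = sharedGenes,
              plantedSwitches = plantedSwitches, utr3Mixture = utr3Mixture,
              utr5Dist = utr5Dist, cdsDist = cdsDist,
              exonCountProbs = exonCountProbs, lengthShift = lengthShift,
              mechanismMix = mechanismMix / sum(mechanismMix),
              intronRange = as.integer(intronRange),
              multiIsoformFraction = multiIsoformFraction)
  class(cfg) <- "SimulationConfig"
  cfg
}

rlog10 <- function(n, d) 10^stats::rnorm(n, d$meanlog10, d$sdlog10)

# split total length L into k parts of at least minLen each
splitLength <- function(L, k, minLen = 20L) {
  k <- max(1L, min(k, L %/% minLen))
  extra <- L - k * minLen
  add <- if (k == 1L) extra else
    as.integer(stats::rmultinom(1, extra, rep(1, k)))
  as.integer(minLen + add)
}

# lay out tx-ordered segment lengths on a contig; returns genomic
# starts/ends in transcription order (descending genomically on '-')
layoutSegments <- function(segLens, intronLens, strand, origin = 101L) {
  k <- length(segLens)
  glens <- if (strand == "-") rev(segLens) else segLens
  gintr <- if (strand == "-") rev(intronLens) else intronLens
  starts <- integer(k); ends <- integer(k)
  pos <- origin
  for (i in seq_len(k)) {
    starts[i] <- pos; ends[i] <- pos + glens[i] - 1L
    if (i < k) pos <- ends[i] + gintr[i] + 1L
  }
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  list(starts = starts, ends = ends)
}

# trim an exon boundary on its tx-5' ("acceptor") or tx-3' ("donor") side
trimExon <- function(starts, ends, i, side, delta, strand) {
  if ((side == "donor") == (strand == "+")) ends[i] <- ends[i] - delta
  else starts[i] <- starts[i] + delta
  list(starts = starts, ends = ends)
}

# Scaffold for a planted switch pair. Six tx-ordered segments: E1 carries the
# 5'UTR plus 60 nt of CDS, E2 (150) and E3 (90) are internal CDS exons, E4
# holds the rest of the CDS including the stop, E5 is pure 3'UTR, E5b is a
# spare downstream terminal exon used by METE/APA edits.
buildSwitchPair <- function(gene, ids, eventClass, cfg, strand) {
  u5 <- max(10L, round(rlog10(1, cfg$utr5Dist)))
  cds <- max(390L, 3L * round(rlog10(1, cfg$cdsDist) / 3))
  long <- stats::runif(1) < cfg$utr3Mixture$weight
  dr3 <- function(lng) {
    i <- if (lng) 2L else 1L
    max(30L, round(10^stats::rnorm(1, cfg$utr3Mixture$meanlog10[i],
                                   cfg$utr3Mixture$sdlog10[i])))
  }
  u3 <- dr3(long)
  u3b <- dr3(!long)
  if (u3b == u3) u3b <- u3b + 57L
  segs <- c(u5 + 60L, 150L, 90L, cds - 300L, u3, u3b)
  introns <- c(sample(cfg$intronRange[1]:cfg$intronRange[2], 4, replace = TRUE),
               600L)
  lay <- layoutSegments(segs, introns, strand)
  ex <- function(idx) list(starts = lay$starts[idx], ends = lay$ends[idx])

  full <- 1:5
  woE3 <- c(1L, 2L, 4L, 5L)
  aIdx <- if (eventClass == "cassette_exon_inclusion") woE3 else full
  cdsA <- if (eventClass == "cassette_exon_inclusion") cds - 90L else cds
  a <- ex(aIdx)
  old <- TranscriptModel(ids[1], gene, paste0("ctg_", gene), strand,
                         a$starts, a$ends, u5 + 1L, u5 + cdsA)

  bIdx <- switch(eventClass,
                 cassette_exon_skipping = woE3,
                 mutually_exclusive_terminal_exons = c(1:4, 6L),
                 full)
  b <- ex(bIdx)
  cdsB <- cds; csB <- u5 + 1L
  if (eventClass == "cassette_exon_skipping") cdsB <- cds - 90L
  if (eventClass == "alt_5prime_donor") {
    b <- trimExon(b$starts, b$ends, 2L, "donor", 60L, strand)
    cdsB <- cds - 60L
  }
  if (eventClass == "alt_3prime_acceptor") {
    b <- trimExon(b$starts, b$ends, 3L, "acceptor", 60L, strand)
    cdsB <- cds - 60L
  }
  if (eventClass == "alternative_start_codon") { csB <- csB + 30L; cdsB <- cds - 30L }
  if (eventClass == "alternative_polyadenylation") {
    n <- length(b$starts)
    if (strand == "+") b$ends[n] <- b$ends[n] + 400L
    else b$starts[n] <- b$starts[n] - 400L
  }
  new <- TranscriptModel(ids[2], gene, paste0("ctg_", gene), strand,
                         b$starts, b$ends, csB, csB + cdsB - 1L)
  list(old = old, new = new, utr3Long = long)
}

buildSimpleGene <- function(gene, id, cfg, strand) {
  u5 <- max(5L, round(rlog10(1, cfg$utr5Dist)))
  cds <- max(60L, 3L * round(rlog10(1, cfg$cdsDist) / 3))
  long <- stats::runif(1) < cfg$utr3Mixture$weight
  i <- if (long) 2L else 1L
  u3 <- max(30L, round(10^stats::rnorm(1, cfg$utr3Mixture$meanlog10[i],
                                       cfg$utr3Mixture$sdlog10[i])))
  L <- u5 + cds + u3
  k <- sample(seq_along(cfg$exonCountProbs), 1, prob = cfg$exonCountProbs)
  lens <- splitLength(L, k)
  k <- length(lens)
  introns <- if (k > 1)
    sample(cfg$intronRange[1]:cfg$intronRange[2], k - 1, replace = TRUE)
  else integer()
  lay <- layoutSegments(lens, introns, strand)
  m <- TranscriptModel(id, gene, paste0("ctg_", gene), strand,
                       lay$starts, lay$ends, u5 + 1L, u5 + cds)
  list(model = m, utr3Long = long, k = k)
}

# non-coding second isoform lacking one internal exon (fractional per-gene
# mean exon counts in the spectrum)
skipTwin <- function(m, id) {
  k <- length(m@exonStarts)
  if (k < 3L) return(NULL)
  drop <- 1L + sample.int(k - 2L, 1)
  TranscriptModel(id, m@geneSymbol, m@chrom, m@strand,
                  m@exonStarts[-drop], m@exonEnds[-drop])
}

#' Simulate a toy genome and multi-isoform annotation
#'
#' Generates `nGenes` genes, each on its own contig: region lengths are
#' drawn from the configured distributions, exon chains are laid out with
#' uniform intron lengths, and a configured number of genes carries a planted
#' isoform-switch pair realised by a structural edit of the configured event
#' class. When `sequence = TRUE` the contig sequences are generated with the
#' start/stop codons physically present at the annotated CDS bounds and
#' canonical GT..AG dinucleotides at every intron.
#'
#' @param cfg a [simulationConfig()].
#' @param sequence generate contig sequences (slower; needed only for
#'   sequence-level work such as splice-signal extraction).
#' @return a list of class `"LengthomeSimulation"` with elements `models`
#'   ([TranscriptModelSet-class]), `genome` ([Biostrings::DNAStringSet] or
#'   NULL), and `truth` (list with per-transcript table and planted switch
#'   pairs).
#' @export
simulateGenomeAndAnnotation <- function(cfg, sequence = TRUE) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  nSwitch <- sum(cfg$plantedSwitches)
  if (cfg$nGenes < nSwitch)
    stop("nGenes too small for the configured planted switches")
  models <- list(); txrows <- list(); switchRows <- list()
  if (cfg$nGenes > 0) {
    genes <- sprintf("GENE%05d", seq_len(cfg$nGenes))
    switchGenes <- if (nSwitch) sort(sample(cfg$nGenes, nSwitch)) else integer()
    strands <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
    classes <- if (nSwitch)
      sample(names(cfg$mechanismMix), nSwitch, replace = TRUE,
             prob = cfg$mechanismMix)
    else character()
    txn <- 0L
    si <- 0L
    for (g in seq_len(cfg$nGenes)) {
      if (g %in% switchGenes) {
        si <- si + 1L
        ids <- sprintf("NM_%06d", txn + 1:2); txn <- txn + 2L
        pair <- buildSwitchPair(genes[g], ids, classes[si], cfg, strands[g])
        models[[length(models) + 1L]] <- pair$old
        models[[length(models) + 1L]] <- pair$new
        txrows[[length(txrows) + 1L]] <- data.frame(
          transcript_id = ids, gene_symbol = genes[g],
          utr3_long = pair$utr3Long, designated = c(TRUE, FALSE),
          stringsAsFactors = FALSE)
        switchRows[[length(switchRows) + 1L]] <- data.frame(
          gene_symbol = genes[g], old_id = ids[1], new_id = ids[2],
          event_class = classes[si], stringsAsFactors = FALSE)
      } else {
        id <- sprintf("NM_%06d", txn + 1L); txn <- txn + 1L
        sg <- buildSimpleGene(genes[g], id, cfg, strands[g])
        models[[length(models) + 1L]] <- sg$model
        ids <- id
        if (stats::runif(1) < cfg$multiIsoformFraction) {
          twin <- skipTwin(sg$model, sprintf("NR_%06d", txn + 1L))
          if (!is.null(twin)) {
            txn <- txn + 1L
            models[[length(models) + 1L]] <- twin
            ids <- c(ids, transcriptId(twin))
          }
        }
        txrows[[length(txrows) + 1L]] <- data.frame(
          transcript_id = ids, gene_symbol = genes[g],
          utr3_long = sg$utr3Long,
          designated = c(TRUE, rep(FALSE, length(ids) - 1L)),
          stringsAsFactors = FALSE)
      }
    }
  }
  set <- TranscriptModelSet(models)
  genome <- if (sequence && length(set)) simulateGenome(set, cfg$seed) else NULL
  out <- list(models = set, genome = genome,
              truth = list(
                transcripts = if (length(txrows)) do.call(rbind, txrows)
                              else data.frame(),
                switchPairs = if (length(switchRows)) do.call(rbind, switchRows)
                              else data.frame(gene_symbol = character(),
                                              old_id = character(),
                                              new_id = character(),
                                              event_class = character())),
              config = cfg)
  class(out) <- "LengthomeSimulation"
  out
}

writeSense <- function(chars, pos, base, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars[pos] <- if (strand == "+") base else unname(comp[base])
  chars
}

# random contig sequences with planted start/stop codons and GT..AG introns
simulateGenome <- function(models, seed) {
  set.seed(seed + 7L)
  chroms <- vapply(models, function(m) m@chrom, character(1))
  seqs <- lapply(split(seq_along(models), chroms), function(idx) {
    len <- max(vapply(idx, function(i) max(models[[i]]@exonEnds), integer(1))) + 100L
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (i in idx) {
      m <- models[[i]]
      if (isCoding(m)) {
        gs <- txToGenome(m, m@cdsStartTx + 0:2)
        ge <- txToGenome(m, m@cdsEndTx - 2:0)
        for (p in 1:3) {
          chars <- writeSense(chars, gs[p], c("A", "T", "G")[p], m@strand)
          chars <- writeSense(chars, ge[p], c("T", "A", "A")[p], m@strand)
        }
      }
      j <- junctions(m)
      for (r in seq_len(nrow(j))) {
        d <- j$donor[r]; a <- j$acceptor[r]
        if (m@strand == "+") {
          chars <- writeSense(chars, d + 1L, "G", "+")
          chars <- writeSense(chars, d + 2L, "T", "+")
          chars <- writeSense(chars, a - 2L, "A", "+")
          chars <- writeSense(chars, a - 1L, "G", "+")
        } else {
          chars <- writeSense(chars, d - 1L, "G", "-")
          chars <- writeSense(chars, d - 2L, "T", "-")
          chars <- writeSense(chars, a + 2L, "A", "-")
          chars <- writeSense(chars, a + 1L, "G", "-")
        }
      }
    }
    paste(chars, collapse = "")
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Simulate per-condition differential-expression lists
#'
#' Builds the four condition lists with exactly the configured sizes,
#' shared-gene overlaps and planted switch events, on top of a simulated
#' annotation. Every record passes the volcano filter by construction
#' (FC >= 2, p <= 0.05, direction "down"). The condition-specific 3'UTR
#' length shift is realised by biasing each condition's gene sampling toward
#' the long or short 3'UTR mixture component according to
#' `lengthShift`.
#'
#' @param cfg the [simulationConfig()] used for the annotation.
#' @param sim result of [simulateGenomeAndAnnotation()].
#' @return list with `lists` (named [ConditionList-class]s) and `truth`
#'   (planted switch pairs per condition pair).
#' @export
simulateDegLists <- function(cfg, sim) {
  stopifnot(inherits(sim, "LengthomeSimulation"))
  set.seed(cfg$seed + 13L)
  tx <- sim$truth$transcripts
  sw <- sim$truth$switchPairs
  pairDefs <- list(C10_C24 = c("C10", "C24"), T10_T24 = c("T10", "T24"))
  nSw <- cfg$plantedSwitches
  swAssign <- split(seq_len(nrow(sw)),
                    rep(names(nSw), nSw))[names(nSw)[nSw > 0]]
  designated <- tx[tx$designated & !(tx$gene_symbol %in% sw$gene_symbol), ]
  pool <- designated  # available non-switch genes, consumed as sampled
  mkRecords <- function(seqnames, genes, condLabel) {
    n <- length(seqnames)
    data.frame(seqname = seqnames, gene_symbol = genes,
               fold_change_abs = stats::runif(n, 2, 10),
               p_value = stats::runif(n, 1e-5, 0.05),
               direction = "down", condition = condLabel,
               stringsAsFactors = FALSE)
  }
  sampleIdx <- function(x, n) x[sample.int(length(x), n)]
  drawBiased <- function(n, w) {
    # sample n genes from the pool, targeting long-component weight w
    if (n == 0L) return(pool[0, ])
    nLong <- min(round(n * w), sum(pool$utr3_long))
    nShort <- n - nLong
    if (nShort > sum(!pool$utr3_long))
      stop("gene pool exhausted; increase nGenes")
    iL <- sampleIdx(which(pool$utr3_long), nLong)
    iS <- sampleIdx(which(!pool$utr3_long), nShort)
    sel <- pool[c(iL, iS), ]
    pool <<- pool[-c(iL, iS), ]
    sel
  }
  lists <- list(); truthPairs <- list()
  for (pname in names(pairDefs)) {
    conds <- pairDefs[[pname]]
    if (!all(conds %in% names(cfg$listSizes))) next
    sA <- cfg$listSizes[[conds[1]]]; sB <- cfg$listSizes[[conds[2]]]
    s <- if (pname %in% names(cfg$sharedGenes)) cfg$sharedGenes[[pname]] else 0L
    swIdx <- if (pname %in% names(swAssign)) swAssign[[pname]] else integer()
    k <- length(swIdx)
    wA <- min(1, cfg$utr3Mixture$weight *
                (if (conds[1] %in% names(cfg$lengthShift))
                   cfg$lengthShift[[conds[1]]] else 1))
    wB <- min(1, cfg$utr3Mixture$weight *
                (if (conds[2] %in% names(cfg$lengthShift))
                   cfg$lengthShift[[conds[2]]] else 1))
    nonSwShared <- drawBiased(s - k, (wA + wB) / 2)
    aOnly <- drawBiased(sA - s, wA)
    bOnly <- drawBiased(sB - (s - k) - 2L * k, wB)
    swTab <- sw[swIdx, , drop = FALSE]
    recA <- mkRecords(c(swTab$old_id, nonSwShared$transcript_id,
                        aOnly$transcript_id),
                      c(swTab$gene_symbol, nonSwShared$gene_symbol,
                        aOnly$gene_symbol), conds[1])
    recB <- mkRecords(c(swTab$old_id, swTab$new_id,
                        nonSwShared$transcript_id, bOnly$transcript_id),
                      c(swTab$gene_symbol, swTab$gene_symbol,
                        nonSwShared$gene_symbol, bOnly$gene_symbol), conds[2])
    lists[[conds[1]]] <- ConditionList(recA, conds[1], "down")
    lists[[conds[2]]] <- ConditionList(recB, conds[2], "down")
    truthPairs[[pname]] <- swTab
  }
  list(lists = lists, truth = truthPairs)
}

#' Write a condition list as a microarray-style TSV
#'
#' Columns `seqname`, `GeneSymbol`, `FoldChange`, `PValue`, `regulation`,
#' readable back with [readDegTable()].
#'
#' @param x a [ConditionList-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDegTable <- function(x, path) {
  r <- x@records
  out <- data.frame(seqname = r$seqname, GeneSymbol = r$gene_symbol,
                    FoldChange = r$fold_change_abs, PValue = r$p_value,
                    regulation = r$direction, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation to disk
#'
#' Writes `genome.fa` (when sequences were generated), `models.tsv` (tabular
#' dialect), `models.gtf`, one DEG TSV per condition and `truth.tsv`.
#'
#' @param sim a `"LengthomeSimulation"`.
#' @param deg optional result of [simulateDegLists()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, deg = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAnnotationTable(sim$models, file.path(dir, "models.tsv"))
  writeAnnotationGtf(sim$models, file.path(dir, "models.gtf"))
  if (!is.null(sim$genome))
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  utils::write.table(sim$truth$switchPairs, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(deg))
    for (nm in names(deg$lists))
      writeDegTable(deg$lists[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}
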