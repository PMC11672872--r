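test_that("junction sets have one junction per adjacent exon pair", {
  one <- TranscriptModel("t1", "g", "c", "+", 1L, 500L)
  expect_equal(nrow(junctions(one)), 0L)
  four <- TranscriptModel("t4", "g", "c", "+",
                          c(1L, 201L, 401L, 601L), c(100L, 300L, 500L, 700L))
  expect_equal(nrow(junctions(four)), 3L)
  expect_equal(junctions(four)$donor, c(100L, 300L, 500L))
  expect_equal(junctions(four)$acceptor, c(201L, 401L, 601L))
})

test_that("minus-strand junctions match a brute-force coordinate mapping", {
  toy <- minusStrandToy()
  m <- toy$model
  j <- junctions(m)
  # oracle: walk every spliced position back to the genome and find the two
  # genomic positions flanking each exon/exon boundary
  gpos <- integer(splicedLength(m))
  p <- 1L
  for (i in seq_along(m@exonStarts)) {
    span <- m@exonEnds[i]:m@exonStarts[i]   # '-': tx runs high -> low
    gpos[p:(p + length(span) - 1L)] <- span
    p <- p + length(span)
  }
  w1 <- m@exonEnds[1] - m@exonStarts[1] + 1L
  expect_equal(j$donor, gpos[w1])
  expect_equal(j$acceptor, gpos[w1 + 1L])
})

test_that("every isoform is identical to itself", {
  fx <- switchFixture(3, 3)
  for (m in as.list(fx$models)) {
    call <- classifyMechanism(m, m)
    expect_equal(call@eventClass, "identical")
    expect_equal(unname(call@regionCodes), rep("=", 4))
    expect_false(call@cryptic)
  }
})

fixtureExpectations <- data.frame(
  old = c("NM_001037955", "NM_001164038", "NM_001171053", "NM_177466",
          "NM_001166623", "NM_001163757", "NM_001079694", "NM_001042708",
          "NM_027557"),
  new = c("NM_134068", "NM_001164037", "NM_001171052", "NM_001003955",
          "NM_011252", "NM_001163758", "NM_009159", "NM_001042707",
          "NM_001164231"),
  class = c("alt_5prime_donor", "alt_3prime_acceptor", "alt_5prime_donor",
            "cassette_exon_inclusion", "alt_3prime_acceptor",
            "alternative_start_codon", "alt_3prime_acceptor",
            "mutually_exclusive_terminal_exons", "alt_5prime_donor"),
  codes = c("S=SS", "LL==", "L=LL", "L=L=", "SS==", "SLS=", "SS==",
            "S=LS", "L=SL"),
  stringsAsFactors = FALSE)

test_that("the nine published isoform pairs classify to their reported mechanisms", {
  fx <- switchFixture(3, 3)
  for (i in seq_len(nrow(fixtureExpectations))) {
    e <- fixtureExpectations[i, ]
    call <- classifyMechanism(fx$models[[e$old]], fx$models[[e$new]])
    expect_equal(call@eventClass, e$class, label = e$new)
    expect_equal(paste(call@regionCodes, collapse = ""), e$codes,
                 label = e$new)
  }
})

test_that("the cryptic tag marks junction endpoints inside partner exons", {
  fx <- switchFixture(3, 3)
  mta <- classifyMechanism(fx$models[["NM_001171053"]],
                           fx$models[["NM_001171052"]])
  expect_true(mta@cryptic)
  jn <- mta@evidence$junctions_new_only
  old <- fx$models[["NM_001171053"]]
  inside <- (jn$donor > old@exonStarts & jn$donor < old@exonEnds) |
            (jn$acceptor > old@exonStarts & jn$acceptor < old@exonEnds)
  expect_true(any(inside))
  # an outward acceptor extension (Ly6e) activates no interior site
  ly <- classifyMechanism(fx$models[["NM_001164038"]],
                          fx$models[["NM_001164037"]])
  expect_false(ly@cryptic)
})

test_that("swapping old and new flips codes and inclusion/skipping", {
  fx <- switchFixture(3, 3)
  flip <- c(S = "L", L = "S", "=" = "=")
  swapClass <- c(cassette_exon_inclusion = "cassette_exon_skipping",
                 cassette_exon_skipping = "cassette_exon_inclusion")
  for (i in seq_len(nrow(fixtureExpectations))) {
    e <- fixtureExpectations[i, ]
    fwd <- classifyMechanism(fx$models[[e$old]], fx$models[[e$new]])
    rev <- classifyMechanism(fx$models[[e$new]], fx$models[[e$old]])
    expect_equal(unname(rev@regionCodes), unname(flip[fwd@regionCodes]))
    if (fwd@eventClass %in% names(swapClass))
      expect_equal(rev@eventClass, unname(swapClass[fwd@eventClass]))
  }
})

test_that("incomparable isoforms raise an error", {
  a <- TranscriptModel("a", "g1", "c1", "+", 1L, 100L)
  b <- TranscriptModel("b", "g2", "c1", "+", 1L, 100L)
  expect_error(classifyMechanism(a, b), "comparable")
})

test_that("planted event classes are recovered on 200 synthetic pairs", {
  cfg <- simulationConfig(seed = 71, nGenes = 210,
                          listSizes = c(C10 = 200L, C24 = 205L),
                          sharedGenes = c(C10_C24 = 200L),
                          plantedSwitches = c(C10_C24 = 200L))
  sim <- simulateGenomeAndAnnotation(cfg, sequence = FALSE)
  sw <- sim$truth$switchPairs
  expect_equal(nrow(sw), 200L)
  calls <- classifyMechanismPairs(sw, sim$models)
  got <- vapply(calls, function(x) x@eventClass, character(1))
  expect_gte(mean(got == sw$event_class), 0.95)
  for (cls in unique(sw$event_class)) {   # per-class precision and recall
    tp <- sum(got == cls & sw$event_class == cls)
    expect_gte(tp / sum(sw$event_class == cls), 0.95)  # recall
    expect_gte(tp / sum(got == cls), 0.95)             # precision
  }
})

test_that("alternative polyadenylation is counted only when planted", {
  fx <- switchFixture(3, 3)
  calls <- classifyMechanismPairs(
    fixtureExpectations[, c("old", "new")] |>
      stats::setNames(c("old_id", "new_id")), fx$models)
  expect_equal(countApaEvents(calls), 0L)
  expect_equal(countApaEvents(list()), 0L)
  mix <- c(alternative_polyadenylation = 1)
  cfg <- simulationConfig(seed = 73, nGenes = 10,
                          listSizes = c(C10 = 5L, C24 = 6L),
                          sharedGenes = c(C10_C24 = 2L),
                          plantedSwitches = c(C10_C24 = 1L),
                          mechanismMix = mix)
  sim <- simulateGenomeAndAnnotation(cfg, sequence = FALSE)
  calls <- classifyMechanismPairs(sim$truth$switchPairs, sim$models)
  expect_equal(countApaEvents(calls), 1L)
})

test_that("splice-signal windows score against the consensus with IUPAC degeneracy", {
  gen <- Biostrings::DNAStringSet(
    c(ctg = "AAAACAGGTAAGTCCCCTTTTTTTTTTTCAGGAAAACCCCCCCCCCCC"))
  d <- extractSpliceSignal(gen, "ctg", 7, "donor", "+")
  expect_equal(d@score, 1.0)
  expect_equal(d@sequence, "CAGGTAAGT")
  a <- extractSpliceSignal(gen, "ctg", 32, "acceptor", "+")
  expect_equal(a@score, 1.0)
  # all-C window: per-position hand oracle against M A G G T R A G T
  dC <- extractSpliceSignal(gen, "ctg", 39, "donor", "+")
  expect_equal(dC@sequence, "CCCCCCCCC")
  oracle <- 0
  for (letter in strsplit("MAGGTRAGT", "")[[1]]) {
    hit <- switch(letter, M = TRUE, A = FALSE, G = FALSE, T = FALSE,
                  R = FALSE, FALSE)  # which consensus letters admit C
    oracle <- oracle + hit
  }
  expect_equal(dC@score, oracle / 9)
  expect_error(extractSpliceSignal(gen, "ctg", 2, "donor", "+"), "overruns")
  expect_error(extractSpliceSignal(gen, "missing", 10, "donor"), "missing")
})

test_that("simulated junctions expose canonical GT donors on both strands", {
  cfg <- smallSimConfig(seed = 43, nGenes = 40)
  sim <- simulateGenomeAndAnnotation(cfg, sequence = TRUE)
  for (m in as.list(sim$models)[1:25]) {
    j <- junctions(m)
    for (r in seq_len(nrow(j))) {
      d <- extractSpliceSignal(sim$genome, m@chrom, j$donor[r], "donor",
                               m@strand)
      expect_equal(substr(d@sequence, 4, 5), "GT")
      a <- extractSpliceSignal(sim$genome, m@chrom, j$acceptor[r], "acceptor",
                               m@strand)
      expect_equal(substr(a@sequence, 13, 14), "AG")
    }
  }
})
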