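rmix3utr <- function(n, wLong = 0.5, mu = c(2, 3), sd = c(0.22, 0.22)) {
  z <- stats::rbinom(n, 1, wLong) + 1L
  10^stats::rnorm(n, mu[z], sd[z])
}

test_that("comparing a sample with itself gives t = 0, p = 1, direction none", {
  set.seed(1)
  x <- rmix3utr(200)
  cc <- compareLengths(x, x, "utr3")
  expect_equal(cc@tStatistic, 0)
  expect_equal(cc@pValue, 1)
  expect_equal(cc@direction, "none")
})

test_that("a 3x multiplicative shift reproduces the closed-form Welch statistic", {
  set.seed(2)
  r <- rmix3utr(400)
  q <- 3 * r
  cc <- compareLengths(q, r, "utr3")
  lq <- log10(q); lr <- log10(r)
  se <- sqrt(stats::var(lq) / length(lq) + stats::var(lr) / length(lr))
  expect_equal(cc@tStatistic, log10(3) / se, tolerance = 1e-9)
  expect_equal(cc@direction, "longer")
})

test_that("direction is antisymmetric under query/reference swap", {
  set.seed(3)
  r <- rmix3utr(300, wLong = 0.5)
  q <- rmix3utr(300, wLong = 0.85)
  ab <- compareLengths(q, r, "utr3")
  ba <- compareLengths(r, q, "utr3")
  expect_equal(ab@pValue, ba@pValue, tolerance = 1e-12)
  expect_equal(abs(ab@tStatistic), abs(ba@tStatistic), tolerance = 1e-12)
  expect_equal(ab@direction, "longer")
  expect_equal(ba@direction, "shorter")
})

test_that("density curves integrate to one over the shared grid", {
  set.seed(4)
  cc <- compareLengths(rmix3utr(250), rmix3utr(500), "utr3")
  trap <- function(m) sum(diff(m[, 1]) * (m[-1, 2] + m[-nrow(m), 2]) / 2)
  expect_equal(trap(cc@densityQuery), 1, tolerance = 0.01)
  expect_equal(trap(cc@densityReference), 1, tolerance = 0.01)
})

test_that("zero-length UTRs are excluded from the test but counted", {
  set.seed(5)
  q <- c(rep(0, 7), rmix3utr(100))
  cc <- compareLengths(q, rmix3utr(200), "utr3")
  expect_equal(cc@nZeroQuery, 7L)
  expect_equal(cc@nQuery, 100L)
  expect_error(compareLengths(c(0, 0, 1, 2), rmix3utr(10), "utr3"), "utr3")
})

test_that("type-I error at alpha 0.05 is calibrated under the null", {
  set.seed(6)
  hits <- 0L
  for (i in 1:1000) {
    q <- rmix3utr(100)
    r <- rmix3utr(300)
    hits <- hits + (compareLengths(q, r, "utr3", gridN = 16L)@pValue <= 0.05)
  }
  expect_gte(hits / 1000, 0.03)
  expect_lte(hits / 1000, 0.07)
})

test_that("a planted long-3'UTR weight shift of 0.5 -> 0.8 is detected at n = 500", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    r <- rmix3utr(500, wLong = 0.5)
    q <- rmix3utr(500, wLong = 0.8)
    cc <- compareLengths(q, r, "utr3", gridN = 16L)
    hits <- hits + (cc@direction == "longer" && cc@pValue <= 0.05)
  }
  expect_gte(hits, 95L)
})

test_that("the toy 2-bin spectrum gives chi-squared exactly 16", {
  sp <- spectrumFromCounts(c(30, 70), c(50, 50))
  expect_identical(sp@chi2, 16)           # 400/50 + 400/50, by hand
  expect_equal(sp@pValue, stats::pchisq(16, 1, lower.tail = FALSE))
})

test_that("a query proportional to the reference gives chi2 = 0, p = 1", {
  mk <- function(prefix, nex, genes) {
    TranscriptModelSet(unlist(lapply(seq_along(nex), function(i) {
      lapply(seq_len(genes[i]), function(j) {
        k <- nex[i]
        starts <- seq(1L, by = 200L, length.out = k)
        TranscriptModel(sprintf("%s_%d_%d", prefix, i, j),
                        sprintf("%sg_%d_%d", prefix, i, j), "c", "+",
                        starts, starts + 99L)
      })
    }), recursive = FALSE))
  }
  q <- mk("q", c(2L, 5L), c(3L, 6L))
  ref <- mk("r", c(2L, 5L), c(6L, 12L))   # same proportions, doubled
  sp <- exonCountSpectrum(q, ref)
  expect_equal(sp@chi2, 0)
  expect_equal(sp@pValue, 1)
})

test_that("spectrum chi2 equals an independent sum over (O-E)^2/E", {
  cfg <- smallSimConfig(seed = 31, nGenes = 80)
  sim <- simulateGenomeAndAnnotation(cfg, sequence = FALSE)
  half <- TranscriptModelSet(as.list(sim$models)[1:40])
  sp <- exonCountSpectrum(half, sim$models)
  acc <- 0
  for (i in seq_along(sp@observed))   # independent accumulation
    acc <- acc + (sp@observed[i] - sp@expected[i])^2 / sp@expected[i]
  expect_equal(sp@chi2, acc)
  expect_equal(sum(sp@observed), sum(sp@expected), tolerance = 1e-9)
})

test_that("an excess of 1-3-exon genes is flagged in at least 90/100 runs", {
  refp <- stats::dpois(1:9, 6); refp <- c(refp, 1 - sum(refp))
  boost <- refp; boost[1:3] <- boost[1:3] * 3
  boost <- boost / sum(boost)
  hits <- 0L
  for (s in 1:100) {
    set.seed(2000 + s)
    obs <- as.integer(stats::rmultinom(1, 300, boost))
    hits <- hits + (spectrumFromCounts(obs, refp)@pValue <= 0.05)
  }
  expect_gte(hits, 90L)
})

test_that("empty expected bins are merged upward with a message", {
  mk1 <- function(prefix, nex) TranscriptModelSet(lapply(seq_along(nex),
    function(i) {
      starts <- seq(1L, by = 200L, length.out = nex[i])
      TranscriptModel(sprintf("%s%d", prefix, i), sprintf("%sg%d", prefix, i),
                      "c", "+", starts, starts + 99L)
    }))
  q <- mk1("q", c(1L, 1L, 2L, 9L, 10L, 12L))
  ref <- mk1("r", c(1L, 2L, 2L, 9L, 9L, 10L, 11L))  # no 3..8-exon genes
  expect_message(sp <- exonCountSpectrum(q, ref), "merged")
  expect_true(all(sp@expected > 0))
})

test_that("the report writes one stats row and one plot per comparison", {
  set.seed(8)
  cc1 <- compareLengths(rmix3utr(100), rmix3utr(100), "utr3", gridN = 32L)
  cc2 <- compareLengths(rmix3utr(100), rmix3utr(100), "cds", gridN = 32L)
  out <- tempfile()
  files <- lengthomeReport(list(C24_utr3 = cc1, C24_cds = cc2), list(), out)
  stats <- utils::read.delim(file.path(out, "length_comparisons.tsv"))
  expect_equal(nrow(stats), 2L)
  expect_true(file.exists(file.path(out, "density_C24_utr3.pdf")))
  expect_true(file.exists(file.path(out, "density_C24_cds.pdf")))
  expect_error(lengthomeReport(list(), list(), out), "at least one")
})
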