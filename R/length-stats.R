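#' @include AllClasses.R
NULL

# round-half-up (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

#' Compare query and reference length distributions
#'
#' Two-sample location test of query region lengths against the reference
#' exome, on the log10 scale by default, with kernel density estimates of
#' both samples over a shared grid for plotting. Zero lengths (empty UTRs)
#' are excluded from the log-scale test and reported separately. The
#' direction is "longer"/"shorter" when the query mean exceeds/falls below
#' the reference mean *and* p <= alpha, otherwise "none".
#'
#' @param query,reference numeric vectors of lengths in nt.
#' @param region region label stored in the result
#'   ("full", "utr5", "cds" or "utr3").
#' @param alpha significance level (default 0.05).
#' @param test "welch" (default, unequal variances) or "student".
#' @param scale "log10" (default) or "linear".
#' @param gridN number of KDE grid points (default 256).
#' @return a [DistributionComparison-class].
#' @export
compareLengths <- function(query, reference, region = "full", alpha = 0.05,
                           test = c("welch", "student"),
                           scale = c("log10", "linear"), gridN = 256L) {
  test <- match.arg(test)
  scale <- match.arg(scale)
  region <- match.arg(region, REGIONS)
  zq <- sum(query == 0, na.rm = TRUE)
  zr <- sum(reference == 0, na.rm = TRUE)
  q <- query[!is.na(query) & query > 0]
  r <- reference[!is.na(reference) & reference > 0]
  if (length(q) < 3L || length(r) < 3L)
    stop("fewer than 3 usable lengths for region '", region,
         "' (query ", length(q), ", reference ", length(r), ")")
  tq <- if (scale == "log10") log10(q) else q
  tr <- if (scale == "log10") log10(r) else r
  ht <- stats::t.test(tq, tr, var.equal = (test == "student"))
  tstat <- unname(ht$statistic)
  p <- ht$p.value
  dir <- if (p > alpha) "none"
         else if (mean(tq) > mean(tr)) "longer" else "shorter"
  bwq <- stats::bw.nrd0(tq); bwr <- stats::bw.nrd0(tr)
  pad <- 3 * max(bwq, bwr)   # keep the KDE mass inside the shared grid
  grid <- seq(min(c(tq, tr)) - pad, max(c(tq, tr)) + pad, length.out = gridN)
  dq <- stats::density(tq, bw = bwq, from = grid[1],
                       to = grid[length(grid)], n = gridN)
  dr <- stats::density(tr, bw = bwr, from = grid[1],
                       to = grid[length(grid)], n = gridN)
  new("DistributionComparison", region = region,
      nQuery = length(q), nReference = length(r),
      nZeroQuery = as.integer(zq), nZeroReference = as.integer(zr),
      tStatistic = tstat, pValue = p, direction = dir,
      densityQuery = cbind(grid = dq$x, density = dq$y),
      densityReference = cbind(grid = dr$x, density = dr$y),
      test = test, scale = scale, alpha = alpha)
}

setMethod("show", "DistributionComparison", function(object) {
  cat(sprintf(
    "DistributionComparison [%s] n=%d vs %d: t=%.3f, p=%.3g -> %s (%s, %s)\n",
    object@region, object@nQuery, object@nReference, object@tStatistic,
    object@pValue, object@direction, object@test, object@scale))
})

# per-gene mean exon count, rounded half-up, binned into 1..9 and "10+"
exonCountBins <- function(models) {
  rl <- regionLengths(models)
  means <- tapply(rl$n_exons, rl$gene_symbol, mean)
  b <- pmin(roundHalfUp(means), 10)
  b <- pmax(b, 1)
  labs <- c(as.character(1:9), "10+")
  counts <- tabulate(b, nbins = 10)
  stats::setNames(counts, labs)
}

#' Exon-count spectrum of query genes against a reference
#'
#' Computes, for query and reference gene sets, the per-gene mean exon count
#' across a gene's isoforms (decimal means arise from genes with multiple
#' alternatively spliced variants and are rounded half-up for binning), bins
#' genes into categories 1..9 and "10+", and tests the query bin counts
#' against the reference bin proportions (scaled to the query total) with a
#' chi-squared goodness-of-fit test. Bins whose expected count is zero are
#' merged upward into the next bin, with a message.
#'
#' @param queryModels,referenceModels [TranscriptModelSet-class] objects (every
#'   gene must have at least one transcript).
#' @return an [ExonCountSpectrum-class].
#' @export
exonCountSpectrum <- function(queryModels, referenceModels) {
  obs <- exonCountBins(queryModels)
  refc <- exonCountBins(referenceModels)
  refp <- refc / sum(refc)
  labs <- names(obs)
  merged <- FALSE
  # merge bins with zero expected proportion upward (into the next bin)
  while (any(refp == 0) && length(refp) > 1L) {
    i <- which(refp == 0)[1]
    j <- if (i < length(refp)) i + 1L else i - 1L
    lo <- min(i, j); hi <- max(i, j)
    labs[lo] <- paste0(sub("\\+$", "", labs[lo]), "-", labs[hi])
    obs[lo] <- obs[lo] + obs[hi]
    refp[lo] <- refp[lo] + refp[hi]
    obs <- obs[-hi]; refp <- refp[-hi]; labs <- labs[-hi]
    merged <- TRUE
  }
  if (merged) message("empty expected bins merged upward in exon spectrum")
  expd <- refp * sum(obs)
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  new("ExonCountSpectrum", bins = labs, observed = as.numeric(obs),
      expected = as.numeric(expd), chi2 = chi2, pValue = p,
      df = as.integer(df), merged = merged)
}

#' Chi-squared goodness of fit for pre-binned counts
#'
#' Spectrum test for counts that are already binned (observed counts vs
#' expected proportions), used when the query is a table rather than a model
#' set.
#'
#' @param observed named numeric vector of bin counts.
#' @param expectedProp expected bin proportions (rescaled to sum to 1).
#' @return an [ExonCountSpectrum-class].
#' @export
spectrumFromCounts <- function(observed, expectedProp) {
  stopifnot(length(observed) == length(expectedProp), all(expectedProp > 0))
  expectedProp <- expectedProp / sum(expectedProp)
  expd <- expectedProp * sum(observed)
  chi2 <- sum((observed - expd)^2 / expd)
  df <- length(observed) - 1L
  labs <- if (is.null(names(observed))) as.character(seq_along(observed))
          else names(observed)
  new("ExonCountSpectrum", bins = labs, observed = as.numeric(observed),
      expected = as.numeric(expd), chi2 = chi2,
      pValue = stats::pchisq(chi2, df = df, lower.tail = FALSE),
      df = as.integer(df), merged = FALSE)
}

setMethod("show", "ExonCountSpectrum", function(object) {
  cat(sprintf("ExonCountSpectrum over %d bin(s): chi2=%.3f (df=%d), p=%.3g\n",
              length(object@bins), object@chi2, object@df, object@pValue))
})

#' Write a length-ome report
#'
#' Writes one TSV of distribution-comparison statistics (one row per
#' comparison, plus one per exon spectrum) and one density-overlay plot per
#' comparison (query vs reference, PDF device for portability).
#'
#' @param comparisons named list of [DistributionComparison-class] objects;
#'   names label the comparisons (e.g. "C24_utr3").
#' @param spectra optional named list of [ExonCountSpectrum-class] objects.
#' @param out output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
lengthomeReport <- function(comparisons, spectra = list(), out) {
  if (!length(comparisons)) stop("need at least one comparison to report")
  if (is.null(names(comparisons)))
    names(comparisons) <- vapply(comparisons, function(x) x@region, character(1))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stats <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cc <- comparisons[[nm]]
    data.frame(comparison = nm, region = cc@region, n_query = cc@nQuery,
               n_reference = cc@nReference, n_zero_query = cc@nZeroQuery,
               t = cc@tStatistic, p = cc@pValue, direction = cc@direction,
               test = cc@test, scale = cc@scale, stringsAsFactors = FALSE)
  }))
  statsPath <- file.path(out, "length_comparisons.tsv")
  utils::write.table(stats, statsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- statsPath
  for (nm in names(comparisons)) {
    cc <- comparisons[[nm]]
    f <- file.path(out, paste0("density_", nm, ".pdf"))
    grDevices::pdf(f, width = 6, height = 4)
    xlab <- if (cc@scale == "log10") "log10 length (bp)" else "length (bp)"
    ylim <- range(0, cc@densityQuery[, 2], cc@densityReference[, 2])
    graphics::plot(cc@densityReference, type = "l", col = "red3",
                   xlab = xlab, ylab = "density", ylim = ylim,
                   main = sprintf("%s (p = %.3g)", nm, cc@pValue))
    graphics::lines(cc@densityQuery, col = "blue3")
    graphics::legend("topright", legend = c("reference", "query"),
                     col = c("red3", "blue3"), lty = 1, bty = "n")
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (length(spectra)) {
    spec <- do.call(rbind, lapply(names(spectra), function(nm) {
      sp <- spectra[[nm]]
      data.frame(comparison = nm, bin = sp@bins, observed = sp@observed,
                 expected = sp@expected, chi2 = sp@chi2, p = sp@pValue,
                 stringsAsFactors = FALSE)
    }))
    specPath <- file.path(out, "exon_spectra.tsv")
    utils::write.table(spec, specPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, specPath)
  }
  invisible(files)
}
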