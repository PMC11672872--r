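#' @include annotation-io.R deg.R
NULL

# which isoforms of each fixture gene appear in the earlier (A) and later (B)
# condition of its pair; the later condition retains the earlier isoform for
# de novo switches and loses two of three for the Ly6e-style isoform loss
FIXTURE_DESIGN <- list(
  C10_C24 = list(
    Dusp22    = list(a = "NM_001037955",
                     b = c("NM_001037955", "NM_134068")),
    Ly6e      = list(a = c("NM_001164037", "NM_001164038", "NM_001164040"),
                     b = "NM_001164037"),
    Mta3      = list(a = "NM_001171053",
                     b = c("NM_001171053", "NM_001171052")),
    Rab11fip5 = list(a = "NM_177466",
                     b = c("NM_177466", "NM_001003955")),
    Rbmx      = list(a = "NM_001166623",
                     b = c("NM_001166623", "NM_011252")),
    Skor      = list(a = "NM_001163757",
                     b = c("NM_001163757", "NM_001163758")),
    Srsf5     = list(a = "NM_001079694",
                     b = c("NM_001079694", "NM_009159"))),
  T10_T24 = list(
    Ilf3      = list(a = "NM_001042708",
                     b = c("NM_001042708", "NM_001042707")),
    Pwwp2a    = list(a = "NM_027557",
                     b = c("NM_027557", "NM_001164231")),
    Rbmx      = list(a = "NM_001166623",
                     b = c("NM_001166623", "NM_011252"))))

#' The packaged isoform-switching worked-example fixture
#'
#' Loads the synthetic reconstruction of the nine published switching genes
#' (19 transcript isoforms across the two condition pairs) shipped with the
#' package, and builds the four condition lists around them: each pair's
#' earlier/later lists contain the switching genes' isoform complements plus
#' a configurable number of single-isoform, non-switching distractor genes
#' shared by both conditions. The transcript structures are synthetic —
#' invented coordinates engineered to reproduce the published per-region
#' S/L/= codes, mechanism classes, and the Mta3 region lengths (3'UTR
#' 93 -> 820 nt, CDS 1542 -> 1757 nt); they are not the true genomic
#' structures.
#'
#' @param nDistractorsC,nDistractorsT single-isoform non-switching genes
#'   added to both conditions of the C and T pair (defaults 107 and 150,
#'   giving 114 and 153 shared genes).
#' @return list with `models` (the 19-isoform [TranscriptModelSet-class]),
#'   `lists` (named [ConditionList-class]s C10, C24, T10, T24) and `design`
#'   (the per-pair isoform complements).
#' @export
switchFixture <- function(nDistractorsC = 107L, nDistractorsT = 150L) {
  path <- system.file("extdata", "synthetic_switch_models.tsv",
                      package = "lengthome", mustWork = TRUE)
  models <- readAnnotation(path, dialect = "table")
  nd <- c(C10_C24 = nDistractorsC, T10_T24 = nDistractorsT)
  lists <- list()
  for (pname in names(FIXTURE_DESIGN)) {
    conds <- strsplit(pname, "_")[[1]]
    des <- FIXTURE_DESIGN[[pname]]
    dGenes <- sprintf("%s_bg%04d", sub("_.*", "", pname), seq_len(nd[[pname]]))
    dSeqs <- sprintf("NR_%s%04d", sub("_.*", "", pname), seq_len(nd[[pname]]))
    mk <- function(which, cond) {
      seqs <- unlist(lapply(des, `[[`, which), use.names = FALSE)
      genes <- rep(names(des), lengths(lapply(des, `[[`, which)))
      rec <- data.frame(
        seqname = c(seqs, dSeqs),
        gene_symbol = c(genes, dGenes),
        fold_change_abs = 2.5, p_value = 0.01,
        direction = "down", condition = cond, stringsAsFactors = FALSE)
      ConditionList(rec, cond, "down")
    }
    lists[[conds[1]]] <- mk("a", conds[1])
    lists[[conds[2]]] <- mk("b", conds[2])
  }
  list(models = models, lists = lists, design = FIXTURE_DESIGN)
}
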