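#' @include AllClasses.R
NULL

#' Read a microarray-style differential-expression table
#'
#' Reads one condition's differential-expression output: one row per
#' transcript isoform with its gene symbol, absolute (non-log) fold change,
#' p-value and regulation direction. Rows with a missing seqname or gene
#' symbol are dropped with a message; duplicate seqnames keep the row with
#' the smaller p-value (with a warning), so downstream lists have unique
#' isoform identifiers.
#'
#' @param path TSV file.
#' @param condition condition label to stamp on the records (e.g. "C10").
#' @param columns named character vector mapping the required record fields
#'   (`seqname`, `gene_symbol`, `fold_change_abs`, `p_value`, `direction`)
#'   to the column names used in the file.
#' @return a data.frame of records with the five canonical columns plus
#'   `condition`.
#' @export
readDegTable <- function(path, condition,
                         columns = c(seqname = "seqname",
                                     gene_symbol = "GeneSymbol",
                                     fold_change_abs = "FoldChange",
                                     p_value = "PValue",
                                     direction = "regulation")) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(tab))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  rec <- data.frame(seqname = as.character(tab[[columns[["seqname"]]]]),
                    gene_symbol = as.character(tab[[columns[["gene_symbol"]]]]),
                    fold_change_abs = tab[[columns[["fold_change_abs"]]]],
                    p_value = tab[[columns[["p_value"]]]],
                    direction = tolower(as.character(tab[[columns[["direction"]]]])),
                    stringsAsFactors = FALSE)
  if (!is.numeric(rec$fold_change_abs) || !is.numeric(rec$p_value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(rec$fold_change_abs))) |
                 is.na(suppressWarnings(as.numeric(rec$p_value))))
    stop("non-numeric fold change or p-value in ", path,
         " at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  blank <- is.na(rec$seqname) | rec$seqname == "" |
           is.na(rec$gene_symbol) | rec$gene_symbol == ""
  if (any(blank)) {
    message(sum(blank), " row(s) with missing seqname/gene symbol dropped from ",
            basename(path))
    rec <- rec[!blank, , drop = FALSE]
  }
  if (anyDuplicated(rec$seqname)) {
    warning("duplicate seqnames in ", basename(path),
            "; keeping the smallest p-value per seqname")
    rec <- rec[order(rec$p_value), , drop = FALSE]
    rec <- rec[!duplicated(rec$seqname), , drop = FALSE]
  }
  rec$condition <- condition
  rownames(rec) <- NULL
  rec
}

#' Volcano filtering of differential-expression records
#'
#' Keeps records with absolute fold change at or above `fcMin` and p-value at
#' or below `pMax` (both boundaries inclusive), for a single regulation
#' direction, and wraps the survivors in a [ConditionList-class]. The filter
#' is idempotent: refiltering a filtered list changes nothing.
#'
#' @param records data.frame of records from [readDegTable()].
#' @param fcMin minimum absolute fold change (default 2.0).
#' @param pMax maximum p-value (default 0.05).
#' @param direction which regulation direction to keep (default "down").
#' @return a [ConditionList-class].
#' @export
volcanoFilter <- function(records, fcMin = 2.0, pMax = 0.05,
                          direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (fcMin < 1) stop("fcMin must be >= 1")
  if (pMax <= 0 || pMax > 1) stop("pMax must lie in (0, 1]")
  keep <- records$fold_change_abs >= fcMin & records$p_value <= pMax &
          records$direction == direction
  rec <- records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  cond <- if (nrow(rec)) rec$condition[1] else
    if (nrow(records)) records$condition[1] else "NA"
  if (nrow(rec)) rec$condition <- cond
  new("ConditionList", condition = cond, direction = direction, records = rec)
}

#' Build a ConditionList directly from records
#'
#' For inputs that are already filtered (e.g. generator output); validity
#' still enforces unique seqnames and a single direction.
#' @param records record data.frame.
#' @param condition,direction list labels.
#' @return a [ConditionList-class].
#' @export
ConditionList <- function(records, condition, direction = "down") {
  if (nrow(records)) {
    records$condition <- condition
    records$direction <- direction
  }
  rownames(records) <- NULL
  new("ConditionList", condition = condition, direction = direction,
      records = records)
}

#' @describeIn ConditionList the record data.frame.
#' @param x a ConditionList.
#' @export
degRecords <- function(x) x@records

#' @describeIn ConditionList the condition label.
#' @export
condition <- function(x) x@condition

setMethod("show", "ConditionList", function(object) {
  cat(sprintf("ConditionList %s (%sregulated): %d transcript(s), %d gene(s)\n",
              object@condition, object@direction, nrow(object@records),
              length(unique(object@records$gene_symbol))))
})

#' Merge two condition lists and sort by gene symbol
#'
#' Concatenates the records of two lists of the same direction and stably
#' sorts them by gene symbol (case-insensitive), breaking ties by condition
#' and then seqname — the spreadsheet-style merge used to line up isoforms of
#' a gene across two time points. Size is conserved: the result always has
#' `nrow(a) + nrow(b)` records.
#'
#' @param a,b [ConditionList-class] objects sharing a direction.
#' @return a data.frame of merged, ordered records.
#' @export
mergeAndSort <- function(a, b) {
  if (a@direction != b@direction)
    stop("cannot merge lists with different regulation directions")
  rec <- rbind(a@records, b@records)
  if (!nrow(rec)) return(rec)
  ord <- order(tolower(rec$gene_symbol), rec$condition, rec$seqname,
               method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
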