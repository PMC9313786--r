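#' Read a staged count matrix and its sample sheet
#'
#' Expects a tab-separated counts file with a header row, first column
#' \code{transcript_id}, second column \code{length_bp}, and one integer count
#' column per sample; and a tab-separated sample sheet with columns
#' \code{sample_id}, \code{stage}, \code{replicate} and optionally
#' \code{system}. Lines starting with \code{#} are skipped. Columns of the
#' count matrix are reordered to follow the sheet; samples present in only one
#' of the two files raise a reconciliation error.
#'
#' @param path path to the counts TSV.
#' @param sheet_path path to the sample sheet TSV.
#' @return A validated \linkS4class{StageCounts}.
#' @export
readCounts <- function(path, sheet_path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("counts file needs transcript_id, length_bp and >=1 sample column")
  if (names(tab)[1] != "transcript_id" || names(tab)[2] != "length_bp")
    stop("first two columns must be 'transcript_id' and 'length_bp'")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cts <- as.matrix(tab[, -(1:2), drop = FALSE])
  for (j in seq_len(ncol(cts))) {
    col <- suppressWarnings(as.numeric(cts[, j]))
    bad <- which(!is.finite(col) | col < 0 | abs(col - round(col)) > 1e-8)
    if (length(bad) > 0L)
      stop("non-integer or negative count at transcript '", ids[bad[1]],
           "', sample '", colnames(cts)[j], "': ", cts[bad[1], j])
  }
  storage.mode(cts) <- "numeric"
  rownames(cts) <- ids
  sheet <- readSampleSheet(sheet_path)
  StageCounts(cts, lengths_bp = tab[[2]], sheet = sheet)
}

#' Read a sample sheet
#'
#' @param path TSV with columns sample_id, stage, replicate, optionally system.
#' @return data.frame with stage validated against \code{\link{stageLevels}}.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "replicate")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  .checkStage(sheet$stage)
  sheet
}

#' Read a long-format RT-qPCR Cq table
#'
#' Expects a TSV with columns \code{gene_id}, \code{sample_id}, \code{cq}; one
#' row per technical replicate. Rows sharing (gene, sample) are grouped as
#' technical replicates of one cell.
#'
#' @param path path to the Cq TSV.
#' @return A validated \linkS4class{CqTable}.
#' @export
readCq <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty Cq file: ", path)
  if (!all(c("gene_id", "sample_id", "cq") %in% names(d)))
    stop("Cq file needs columns gene_id, sample_id, cq")
  CqTable(d)
}

#' Read a transcript-to-functional-bin annotation table
#'
#' @param path TSV with columns transcript_id, bincode and optionally
#'   description; a transcript may appear on several rows (several bins).
#' @return data.frame with character columns transcript_id, bincode,
#'   description.
#' @export
readAnnotation <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "bincode") %in% names(d)))
    stop("annotation needs columns transcript_id, bincode")
  if (!"description" %in% names(d)) d$description <- ""
  if (any(!nzchar(d$bincode))) stop("empty bincode in annotation table")
  d[, c("transcript_id", "bincode", "description")]
}

#' Write a staged count matrix and sample sheet
#'
#' Inverse of \code{\link{readCounts}}: emits the same TSV dialects, so that
#' write-then-read is the identity on ids, lengths, counts and sheet.
#'
#' @param object a \linkS4class{StageCounts}.
#' @param path,sheet_path output TSV paths.
#' @return Invisibly, \code{path}.
#' @export
writeCounts <- function(object, path, sheet_path) {
  tab <- data.frame(transcript_id = rownames(object),
                    length_bp = transcriptLengths(object),
                    counts(object), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- sampleSheet(object)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Cq table in long format
#'
#' @param object a \linkS4class{CqTable}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeCq <- function(object, path) {
  utils::write.table(cqData(object), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix
#'
#' @param object a \linkS4class{StageExpression}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(object, path) {
  tab <- data.frame(transcript_id = rownames(object),
                    exprValues(object), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse transcript ids to gene models
#'
#' Strips a trailing isoform suffix (".t1", ".t2", ...) so that counts of
#' distinct gene models backing a transcript list can be reported, e.g.
#' "585 transcripts from 556 gene models".
#'
#' @param transcript_ids character vector of transcript ids.
#' @return Character vector of gene-model ids.
#' @export
#' @examples
#' geneModelOf(c("Cc000593.t1", "Cc000593.t2", "Cc020138.t1"))
geneModelOf <- function(transcript_ids) {
  sub("\\.t[0-9]+$", "", transcript_ids)
}
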