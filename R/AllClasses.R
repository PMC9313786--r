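#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Admissible haustorium development stages
#'
#' The four sample types of the staged design, in developmental order:
#' non-infective stem (niS), swelling (SWE), attaching (ATT) and
#' penetrating (PEN).
#'
#' @return Character vector of the four stage labels, in developmental order.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() c("niS", "SWE", "ATT", "PEN")

.checkStage <- function(stage) {
  bad <- setdiff(as.character(stage), stageLevels())
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(unique(bad), collapse = ", "),
         "; admissible values are {", paste(stageLevels(), collapse = ", "),
         "}", call. = FALSE)
  }
  factor(as.character(stage), levels = stageLevels())
}

#' @rdname StageCounts
#' @export
setClass("StageCounts", contains = "SummarizedExperiment")

#' @rdname StageExpression
#' @export
setClass("StageExpression", contains = "SummarizedExperiment",
         representation(measure = "character"))

#' @rdname CqTable
#' @export
setClass("CqTable", representation(data = "data.frame"))

#' @rdname StabilityRanking
#' @export
setClass("StabilityRanking",
         representation(table = "data.frame",
                        pairwiseVariation = "numeric",
                        exclusionOrder = "character"))

setValidity("StageCounts", function(object) {
  msg <- character(0)
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  rd <- rowData(object)
  if (!"length_bp" %in% names(rd))
    msg <- c(msg, "rowData column 'length_bp' is required")
  else if (any(rd$length_bp <= 0))
    msg <- c(msg, "transcript lengths must be positive")
  cd <- colData(object)
  need <- c("stage", "replicate")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData needs columns 'stage' and 'replicate'")
  else {
    if (!all(as.character(cd$stage) %in% stageLevels()))
      msg <- c(msg, "stage labels outside {niS, SWE, ATT, PEN}")
    if (any(cd$replicate < 1))
      msg <- c(msg, "replicate indices must be positive")
    tab <- table(as.character(cd$stage))
    if (any(tab < 2L))
      msg <- c(msg, paste0("stage(s) with fewer than 2 replicates: ",
                           paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "transcript ids must be unique")
  if (length(msg)) msg else TRUE
})

setValidity("StageExpression", function(object) {
  ok <- c("CPM", "RPKM", "log2CPM", "log2RPKM", "zscore")
  if (length(object@measure) != 1L || !object@measure %in% ok)
    return(paste0("measure must be one of {", paste(ok, collapse = ", "), "}"))
  TRUE
})

setValidity("CqTable", function(object) {
  d <- object@data
  msg <- character(0)
  if (!all(c("gene_id", "sample_id", "cq") %in% names(d)))
    msg <- c(msg, "data needs columns gene_id, sample_id, cq")
  else {
    if (nrow(d) == 0L) msg <- c(msg, "Cq table is empty")
    if (any(!is.finite(d$cq)) || any(d$cq <= 0) || any(d$cq > 45))
      msg <- c(msg, "all Cq values must lie in (0, 45]")
  }
  if (length(msg)) msg else TRUE
})

#' Staged count matrix
#'
#' Container for a transcript x sample matrix of raw read counts together with
#' transcript lengths and the sample sheet (stage, replicate, system), built on
#' \linkS4class{SummarizedExperiment}. Counts must be non-negative integers,
#' lengths positive, stage labels among \code{\link{stageLevels}()}, and every
#' stage present must carry at least two replicates so that within-group
#' variance is estimable.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths_bp positive integer vector of transcript lengths (bp), one
#'   per row of \code{counts}.
#' @param sheet data.frame with columns \code{sample_id}, \code{stage},
#'   \code{replicate} and optionally \code{system}; \code{counts} columns are
#'   reordered to follow the sheet.
#'
#' @return A \code{StageCounts} object.
#' @export
#' @examples
#' sc <- StageCounts(
#'   counts = matrix(0:7, 2, 4, dimnames = list(c("t1", "t2"), paste0("s", 1:4))),
#'   lengths_bp = c(500L, 1500L),
#'   sheet = data.frame(sample_id = paste0("s", 1:4),
#'                      stage = rep(c("niS", "SWE"), each = 2),
#'                      replicate = rep(1:2, 2)))
#' sc
StageCounts <- function(counts, lengths_bp, sheet) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry transcript row names and sample column names")
  sheet <- as.data.frame(sheet)
  if (!all(c("sample_id", "stage", "replicate") %in% names(sheet)))
    stop("sample sheet needs columns sample_id, stage, replicate")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  missing_in_sheet <- setdiff(colnames(counts), sheet$sample_id)
  missing_in_mat <- setdiff(sheet$sample_id, colnames(counts))
  if (length(missing_in_sheet) || length(missing_in_mat))
    stop("samples do not reconcile between counts and sheet; ",
         "missing from sheet: [", paste(missing_in_sheet, collapse = ", "),
         "], missing from counts: [", paste(missing_in_mat, collapse = ", "), "]")
  counts <- counts[, sheet$sample_id, drop = FALSE]
  if (!"system" %in% names(sheet)) sheet$system <- "host-free"
  cd <- DataFrame(stage = .checkStage(sheet$stage),
                  replicate = as.integer(sheet$replicate),
                  system = sheet$system,
                  row.names = sheet$sample_id)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(length_bp = as.integer(lengths_bp),
                        row.names = rownames(counts)),
    colData = cd)
  new("StageCounts", se)
}

#' Expression matrix with a tagged measure
#'
#' A real-valued transcript x sample matrix derived from a
#' \linkS4class{StageCounts}, tagged with the measure it carries (CPM, RPKM,
#' log2CPM, log2RPKM or zscore). Created by the normalization functions, e.g.
#' \code{\link{toCPM}}; rarely constructed directly.
#'
#' @param values numeric matrix, transcripts x samples.
#' @param measure one of \code{"CPM"}, \code{"RPKM"}, \code{"log2CPM"},
#'   \code{"log2RPKM"}, \code{"zscore"}.
#' @param template optional \code{StageCounts} or \code{StageExpression}
#'   providing row/column annotation (sample sheet, lengths).
#'
#' @return A \code{StageExpression} object.
#' @export
StageExpression <- function(values, measure, template = NULL) {
  values <- as.matrix(values)
  se <- if (is.null(template)) {
    SummarizedExperiment(assays = list(expr = values))
  } else {
    SummarizedExperiment(assays = list(expr = values),
                         rowData = rowData(template),
                         colData = colData(template))
  }
  new("StageExpression", se, measure = measure)
}

#' RT-qPCR quantification-cycle table
#'
#' Long-format store of quantification cycles (Cq) per gene x sample cell,
#' keeping all technical replicates. Cells absent from the table are treated as
#' "not measured" downstream. All Cq values must lie in (0, 45].
#'
#' @param data data.frame with columns \code{gene_id}, \code{sample_id},
#'   \code{cq}; one row per technical replicate.
#'
#' @return A \code{CqTable} object.
#' @export
#' @examples
#' cq <- CqTable(data.frame(gene_id = "g1", sample_id = c("s1", "s1"),
#'                          cq = c(20.1, 20.3)))
#' cqMeans(cq)
CqTable <- function(data) {
  data <- as.data.frame(data)[, c("gene_id", "sample_id", "cq")]
  data$gene_id <- as.character(data$gene_id)
  data$sample_id <- as.character(data$sample_id)
  data$cq <- as.numeric(data$cq)
  new("CqTable", data = data)
}

#' Accessors for the core containers
#'
#' \code{counts} returns the raw integer count matrix of a
#' \code{StageCounts}; \code{exprValues} the numeric matrix of a
#' \code{StageExpression}; \code{measure} its measure tag;
#' \code{transcriptLengths} the per-transcript lengths in bp;
#' \code{stageOf} the per-sample stage factor; \code{sampleSheet} the sample
#' sheet as a plain data.frame.
#'
#' @param object a \code{StageCounts} or \code{StageExpression}.
#' @return The corresponding component (matrix, factor or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "StageCounts",
          function(object) assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "StageExpression",
          function(object) assay(object, "expr"))

#' @rdname accessors
#' @export
setGeneric("measure", function(object) standardGeneric("measure"))
#' @rdname accessors
#' @export
setMethod("measure", "StageExpression", function(object) object@measure)

#' @rdname accessors
#' @export
setGeneric("transcriptLengths", function(object) standardGeneric("transcriptLengths"))
#' @rdname accessors
#' @export
setMethod("transcriptLengths", "SummarizedExperiment", function(object) {
  len <- rowData(object)$length_bp
  names(len) <- rownames(object)
  len
})

#' @rdname accessors
#' @export
setGeneric("stageOf", function(object) standardGeneric("stageOf"))
#' @rdname accessors
#' @export
setMethod("stageOf", "SummarizedExperiment", function(object) {
  st <- factor(as.character(colData(object)$stage), levels = stageLevels())
  names(st) <- colnames(object)
  droplevels(st)
})

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))
#' @rdname accessors
#' @export
setMethod("sampleSheet", "SummarizedExperiment", function(object) {
  cd <- as.data.frame(colData(object))
  data.frame(sample_id = rownames(cd), cd, row.names = NULL)
})

#' Cq table accessors
#'
#' \code{cqData} returns the long-format data.frame; \code{cqMeans} the
#' gene x sample matrix of technical-replicate mean Cq values (NA where a
#' cell was not measured).
#'
#' @param object a \code{CqTable}.
#' @return \code{cqData}: data.frame; \code{cqMeans}: numeric matrix.
#' @name cq-accessors
NULL

#' @rdname cq-accessors
#' @export
setGeneric("cqData", function(object) standardGeneric("cqData"))
#' @rdname cq-accessors
#' @export
setMethod("cqData", "CqTable", function(object) object@data)

#' @rdname cq-accessors
#' @export
setGeneric("cqMeans", function(object) standardGeneric("cqMeans"))
#' @rdname cq-accessors
#' @export
setMethod("cqMeans", "CqTable", function(object) {
  d <- object@data
  genes <- unique(d$gene_id)
  samples <- unique(d$sample_id)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  agg <- stats::aggregate(cq ~ gene_id + sample_id, data = d, FUN = mean)
  m[cbind(agg$gene_id, agg$sample_id)] <- agg$cq
  m
})

#' Reference-gene stability ranking
#'
#' Result container of \code{\link{rankStability}} /
#' \code{\link{integrateRanks}}: per-candidate geNorm M, NormFinder SV and
#' BestKeeper r, the per-method competition ranks, and the geometric-mean
#' integrated rank (GM). When produced by \code{rankStability} it also carries
#' geNorm's pairwise variations V(n/n+1) and stepwise exclusion order.
#'
#' @param object a \code{StabilityRanking}.
#' @return \code{stabilityTable}: the per-candidate data.frame, ordered by GM;
#'   \code{pairwiseVariation}: named numeric vector of V(n/n+1) values.
#' @name StabilityRanking
NULL

#' @rdname StabilityRanking
#' @export
setGeneric("stabilityTable", function(object) standardGeneric("stabilityTable"))
#' @rdname StabilityRanking
#' @export
setMethod("stabilityTable", "StabilityRanking", function(object) object@table)

#' @rdname StabilityRanking
#' @export
setGeneric("pairwiseVariation", function(object) standardGeneric("pairwiseVariation"))
#' @rdname StabilityRanking
#' @export
setMethod("pairwiseVariation", "StabilityRanking",
          function(object) object@pairwiseVariation)

setMethod("show", "StageCounts", function(object) {
  st <- table(as.character(colData(object)$stage))
  cat("StageCounts:", nrow(object), "transcripts x", ncol(object), "samples\n")
  cat("  stages:", paste(sprintf("%s(%d)", names(st), st), collapse = " "), "\n")
})

setMethod("show", "StageExpression", function(object) {
  cat("StageExpression [", object@measure, "]: ", nrow(object),
      " transcripts x ", ncol(object), " samples\n", sep = "")
})

setMethod("show", "CqTable", function(object) {
  d <- object@data
  cat("CqTable:", length(unique(d$gene_id)), "genes x",
      length(unique(d$sample_id)), "samples,", nrow(d), "measurements\n")
})

setMethod("show", "StabilityRanking", function(object) {
  cat("StabilityRanking over", nrow(object@table), "candidates\n")
  print(object@table, row.names = FALSE)
  if (length(object@pairwiseVariation)) {
    cat("pairwise variation:",
        paste(sprintf("%s=%.3f", names(object@pairwiseVariation),
                      object@pairwiseVariation), collapse = " "), "\n")
  }
})
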