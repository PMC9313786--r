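#' Relative abundance from Cq values
#'
#' Per gene x sample cell, technical replicates are averaged; each gene's
#' abundance is then expressed relative to the sample with its highest
#' expression (lowest mean Cq): \code{RQ = efficiency^(Cq_min - Cq)}, so the
#' maximal sample sits at exactly 1 and all quantities are in (0, 1]. Cells
#' not measured stay NA and are ignored by downstream correlations.
#'
#' @param cq a \linkS4class{CqTable}.
#' @param efficiency amplification efficiency (default 2, perfect doubling).
#' @return Numeric matrix genes x samples of relative quantities.
#' @export
relativeAbundance <- function(cq, efficiency = 2) {
  m <- cqMeans(cq)
  if (any(rowSums(!is.na(m)) == 0L))
    stop("gene(s) without any measured sample")
  cqmin <- apply(m, 1, min, na.rm = TRUE)
  efficiency^(cqmin - m)
}

#' Normalize target quantities to reference genes
#'
#' Per sample, the normalization factor is the geometric mean of the
#' reference genes' relative quantities; every target quantity in that
#' sample is divided by the factor. The references are removed from the
#' output.
#'
#' @param rq relative-abundance matrix from \code{\link{relativeAbundance}}.
#' @param reference_genes character vector of reference gene ids (>= 1),
#'   each measured in every sample.
#' @return Normalized matrix over the non-reference genes; attribute
#'   \code{"factors"} holds the per-sample normalization factors.
#' @export
normalizeToReferences <- function(rq, reference_genes) {
  miss <- setdiff(reference_genes, rownames(rq))
  if (length(miss) > 0L || length(reference_genes) == 0L)
    stop("reference gene(s) absent: ", paste(miss, collapse = ", "))
  ref <- rq[reference_genes, , drop = FALSE]
  if (any(is.na(ref))) {
    bad <- which(is.na(ref), arr.ind = TRUE)
    stop("reference '", rownames(ref)[bad[1, 1]], "' not measured in sample '",
         colnames(ref)[bad[1, 2]], "'")
  }
  factors <- exp(colMeans(log(ref)))
  out <- sweep(rq[setdiff(rownames(rq), reference_genes), , drop = FALSE],
               2, factors, "/")
  attr(out, "factors") <- factors
  out
}

#' Classify samples into development stages from marker expression
#'
#' Normalized relative quantities of the marker panel are log2-transformed
#' and z-scored per gene across samples. Each sample is assigned to the stage
#' whose marker set attains the highest mean z-score in that sample
#' (deterministic counterpart of reading the marker z-pattern off a heatmap);
#' a complete-linkage Euclidean dendrogram of the samples is returned
#' alongside for the heatmap-style view. Ties are broken toward the earlier
#' stage in developmental order and flagged ambiguous.
#'
#' @param norm_rq normalized relative-abundance matrix
#'   (\code{\link{normalizeToReferences}}).
#' @param marker_panel named list mapping stage labels to marker gene ids.
#' @return data.frame: sample_id, call, ambiguous; attributes
#'   \code{"score"} (stage x sample mean-z matrix), \code{"zscore"}
#'   (gene x sample z matrix) and \code{"tree"} (sample dendrogram, when
#'   >= 2 samples).
#' @export
classifyStages <- function(norm_rq, marker_panel) {
  stopifnot(is.list(marker_panel), length(marker_panel) >= 2L)
  .checkStage(names(marker_panel))
  panel <- unique(unlist(marker_panel))
  miss <- setdiff(panel, rownames(norm_rq))
  if (length(miss) > 0L)
    stop("panel gene(s) missing from matrix: ", paste(miss, collapse = ", "))
  x <- log2(norm_rq[panel, , drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite log2 quantities in marker panel")
  mu <- rowMeans(x)
  s <- .rowSds(x)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  stages <- intersect(stageLevels(), names(marker_panel))
  score <- do.call(rbind, lapply(stages, function(S) {
    colMeans(z[marker_panel[[S]], , drop = FALSE])
  }))
  rownames(score) <- stages
  tol <- 1e-9
  best <- apply(score, 2, max)
  call <- vapply(seq_len(ncol(score)), function(j) {
    stages[which(score[, j] >= best[j] - tol)[1]]
  }, character(1))
  ambiguous <- vapply(seq_len(ncol(score)), function(j) {
    sum(score[, j] >= best[j] - tol) > 1L
  }, logical(1))
  out <- data.frame(sample_id = colnames(norm_rq),
                    call = factor(call, levels = stageLevels()),
                    ambiguous = ambiguous, row.names = NULL)
  attr(out, "score") <- score
  attr(out, "zscore") <- z
  if (ncol(z) >= 2L)
    attr(out, "tree") <- hierarchicalCluster(z, axis = "columns")
  out
}
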